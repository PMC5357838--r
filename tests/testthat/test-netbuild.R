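test_that("model parameter validation enforces documented ranges", {
  expect_error(model_params(alpha = 1.2), "alpha")
  expect_error(model_params(beta = -0.1), "beta")
  expect_error(model_params(gamma = 0), "gamma")
  expect_error(model_params(eta = -1), "eta")
  p <- model_params()
  expect_equal(p[c("alpha", "beta", "gamma", "eta", "sigma")],
               list(alpha = 0.1, beta = 0.6, gamma = 100, eta = 6, sigma = 10))
})

test_that("family/cluster co-association ratio counts members linked to the disease", {
  assoc <- assoc_table(c("m1", "m2", "m5"), c("d1", "d1", "d1"))
  expect_equal(family_cluster_ratio(c("m1", "m2", "m3", "m4"), "d1", assoc), 0.5)
  expect_equal(family_cluster_ratio(c("m3", "m4"), "d1", assoc), 0)
  expect_equal(family_cluster_ratio(c("m1", "m2"), "d1", assoc), 1)
  expect_error(family_cluster_ratio(character(), "d1", assoc), "empty")
})

test_that("association edge weights follow gamma * (1 + eta R_p + sigma R_q)", {
  assoc <- assoc_table(c("m1", "m2", "m3"), c("d1", "d1", "d2"))
  fams <- gene_sets(list(f1 = c("m1", "m2")))           # R_p(d1) = 1... both in
  # m1 in no family/cluster data: base gamma
  expect_equal(association_edge_weight("m3", "d2", NULL, NULL, assoc,
                                       model_params(gamma = 100)), 100)
  # family ratio 0.5: gamma 100, eta 6 -> 100 * (1 + 3) = 400
  fams_half <- gene_sets(list(f1 = c("m1", "m4", "m5", "m2")))
  assoc2 <- assoc_table(c("m1", "m2"), c("d1", "d1"))
  expect_equal(association_edge_weight("m1", "d1", fams_half, NULL, assoc2,
                                       model_params(gamma = 100, eta = 6)), 400)
  # both memberships: gamma 1, eta 1, sigma 4, R_p = .5, R_q = .25 -> 2.5
  fams3 <- gene_sets(list(f = c("m1", "m2")))         # only m1 linked: R_p = 1/2
  clus3 <- gene_sets(list(c = c("m1", "m4", "m5", "m6")))  # R_q = 1/4
  assoc3 <- assoc_table("m1", "d1")
  expect_equal(association_edge_weight("m1", "d1", fams3, clus3, assoc3,
                                       model_params(gamma = 1, eta = 1, sigma = 4)),
               1 * (1 + 1 * 0.5 + 4 * 0.25))
  expect_error(association_edge_weight("m9", "d1", NULL, NULL, assoc,
                                       model_params()), "not a known association")
})

test_that("a microRNA in several families uses the maximum-ratio family", {
  assoc <- assoc_table(c("m1", "m2", "m3"), c("d1", "d1", "d1"))
  fams <- gene_sets(list(low = c("m1", "x1", "x2", "x3"),   # ratio 1/4
                         high = c("m1", "m2")))             # ratio 1
  w <- association_edge_weight("m1", "d1", fams, NULL, assoc,
                               model_params(gamma = 1, eta = 1, sigma = 0))
  expect_equal(w, 1 * (1 + 1 * 1))
})

test_that("vectorized edge weighting agrees with the scalar definition", {
  set.seed(21)
  b <- generate_benchmark(benchmark_spec(n_mirna = 15, n_disease = 8,
                                         n_modules = 3, group_size_range = c(2, 4), seed = 4))
  p <- model_params(gamma = 2, eta = 3, sigma = 5)
  w_vec <- mirflow:::association_edge_weights(b$assoc, b$families, b$clusters, p)
  w_scl <- vapply(seq_len(nrow(b$assoc)), function(i) {
    association_edge_weight(b$assoc$mirna[i], b$assoc$disease[i],
                            b$families, b$clusters, b$assoc, p)
  }, 0)
  expect_equal(w_vec, w_scl)
  expect_true(all(w_vec >= p$gamma))
})

test_that("network assembly thresholds similarity layers and unions node sets", {
  net <- tiny_network()
  expect_equal(nrow(net$nodes), 4L)
  expect_equal(nrow(net$edges), 4L)
  expect_setequal(net$edges$layer,
                  c("mirna_sim", "disease_sim", "association"))

  # alpha above every off-diagonal similarity removes the microRNA layer
  hi <- tiny_network(model_params(alpha = 0.9, beta = 0.4, gamma = 1))
  expect_equal(sum(hi$edges$layer == "mirna_sim"), 0L)
  # alpha = 0 keeps every positive-similarity pair
  lo <- tiny_network(model_params(alpha = 0, beta = 0, gamma = 1))
  expect_equal(sum(lo$edges$layer == "mirna_sim"), 1L)
})

test_that("raising the similarity thresholds never adds edges", {
  b <- generate_benchmark(benchmark_spec(n_mirna = 20, n_disease = 12,
                                         n_modules = 4, group_size_range = c(2, 4), seed = 9))
  prev <- Inf
  for (a in c(0.1, 0.3, 0.5, 0.8)) {
    net <- assemble_network(b$mirna_sim, b$disease_sim, b$assoc,
                            params = model_params(alpha = a, beta = a))
    n_sim <- sum(net$edges$layer != "association")
    expect_lte(n_sim, prev)
    prev <- n_sim
  }
})

test_that("nodes missing from a similarity matrix survive as association-only nodes", {
  msim <- make_sim(c("m1", "m2"), list(list("m1", "m2", 0.5)))
  dsim <- make_sim(c("d1"))
  assoc <- assoc_table(c("m1", "m9"), c("d1", "d2"))
  expect_warning(expect_warning(
    net <- assemble_network(msim, dsim, assoc, params = model_params(gamma = 1)),
    "m9"), "d2")
  expect_setequal(net$nodes$id, c("m1", "m2", "m9", "d1", "d2"))
  expect_equal(sum(net$edges$layer == "association"), 2L)
})

test_that("directify splits edges, scales and rounds capacities, and wires source/sink", {
  net <- tiny_network()
  g <- directify(net, "d1", c("m1", "m2"))
  # 4 undirected edges -> 8 arcs, plus source arc and two sink arcs
  expect_equal(nrow(g$arcs), 2L * 4L + 1L + 2L)
  finite <- g$arcs$capacity[g$arcs$from != g$source & g$arcs$to != g$sink]
  expect_equal(g$infinity, 1 + sum(finite))
  expect_true(all(g$arcs$capacity[g$arcs$from == g$source] == g$infinity))

  # per undirected edge, the two arcs carry 2 x the scaled weight
  e <- net$edges[1, ]
  both <- g$arcs$capacity[(g$arcs$from == e$u & g$arcs$to == e$v) |
                          (g$arcs$from == e$v & g$arcs$to == e$u)]
  expect_equal(sum(both), 2 * round(e$weight * 1000))

  expect_error(directify(net, "d1", c("d1", "m1")), "candidate")
  expect_error(directify(net, "zz", "m1"), "not in network")
})

test_that("capacity rounding is half-to-even and zero-capacity arcs are dropped", {
  msim <- make_sim(c("m1", "m2"), list(list("m1", "m2", 0.6667)))
  assoc <- assoc_table("m1", "d1")
  net <- assemble_network(msim, NULL, assoc, params = model_params(gamma = 1, alpha = 0))
  g <- directify(net, "d1", "m2")
  expect_equal(g$arcs$capacity[g$arcs$from == "m1" & g$arcs$to == "m2"], 667)

  tiny_w <- make_sim(c("m1", "m2"), list(list("m1", "m2", 1e-5)))
  net2 <- assemble_network(tiny_w, NULL, assoc, params = model_params(gamma = 1, alpha = 0))
  g2 <- directify(net2, "d1", "m2")
  expect_equal(sum(g2$arcs$from == "m1" & g2$arcs$to == "m2"), 0L)
})

test_that("one-way direction modes drop only association arcs in the disallowed direction", {
  net <- tiny_network()
  g <- directify(net, "d1", c("m1", "m2"),
                 model_params(alpha = 0.4, beta = 0.4, gamma = 1,
                              direction_mode = "disease_to_mirna_only"))
  # association arcs mirna -> disease removed; similarity arcs untouched
  expect_equal(sum(g$arcs$from == "m1" & g$arcs$to == "d1"), 0L)
  expect_equal(sum(g$arcs$from == "d1" & g$arcs$to == "m1"), 1L)
  expect_equal(sum(g$arcs$from == "m1" & g$arcs$to == "m2"), 1L)
  expect_equal(sum(g$arcs$from == "m2" & g$arcs$to == "m1"), 1L)
})

test_that("association weights exceed gamma exactly when co-association exists", {
  b <- generate_benchmark(benchmark_spec(n_mirna = 20, n_disease = 12,
                                         n_modules = 4, group_size_range = c(2, 4), seed = 2))
  p <- model_params(gamma = 10, eta = 2, sigma = 3)
  net <- assemble_network(b$mirna_sim, b$disease_sim, b$assoc,
                          b$families, b$clusters, p)
  aw <- net$edges[net$edges$layer == "association", ]
  expect_true(all(aw$weight >= p$gamma))
  for (i in seq_len(nrow(aw))) {
    groups <- c(unclass(b$families), unclass(b$clusters))
    mine <- Filter(function(g) aw$u[i] %in% g, groups)
    ratios <- vapply(mine, family_cluster_ratio, 0,
                     disease_id = aw$v[i], assoc = b$assoc)
    if (aw$weight[i] > p$gamma) expect_gt(max(c(ratios, 0)), 0)
    else expect_equal(max(c(ratios, 0)), 0)
  }
})
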