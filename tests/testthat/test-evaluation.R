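test_that("ROC/PR sweep handles perfect separation and validates inputs", {
  curves <- roc_pr_from_ranks(c(0.1, 0.2), c(0.6, 0.9))
  expect_equal(curves$roc$auc, 1)
  expect_equal(curves$pr$auc, 1)
  expect_equal(curves$roc$x[1], 0)
  expect_equal(curves$roc$y[1], 0)
  expect_equal(tail(curves$roc$x, 1), 1)
  expect_equal(tail(curves$roc$y, 1), 1)
  expect_error(roc_pr_from_ranks(numeric(), 0.5), "at least one")
  expect_error(roc_pr_from_ranks(0.5, numeric()), "at least one")
})

test_that("ROC AUC equals the normalized Mann-Whitney statistic with ties", {
  set.seed(17)
  for (i in 1:100) {
    pos <- sample(seq(0.05, 1, by = 0.05), sample(3:20, 1), replace = TRUE)
    neg <- sample(seq(0.05, 1, by = 0.05), sample(3:20, 1), replace = TRUE)
    expect_equal(roc_pr_from_ranks(pos, neg)$roc$auc,
                 mann_whitney_auc(pos, neg))
  }
})

test_that("indistinguishable score distributions give chance-level AUC", {
  set.seed(7)
  pos <- runif(1e4)
  neg <- runif(1e4)
  expect_lt(abs(roc_pr_from_ranks(pos, neg)$roc$auc - 0.5), 0.02)
})

test_that("TPR and FPR both reach 1 at the loosest threshold", {
  set.seed(23)
  pos <- runif(50); neg <- runif(80)
  curves <- roc_pr_from_ranks(pos, neg)
  expect_equal(tail(curves$roc$x, 1), 1)
  expect_equal(tail(curves$roc$y, 1), 1)
  expect_true(all(diff(curves$roc$x) >= 0))
  expect_true(all(diff(curves$roc$y) >= 0))
})

test_that("F1-optimal threshold maximizes the harmonic mean of precision and recall", {
  # perfect separation: F1 = 1 at the cut between groups
  perfect <- f1_optimal_threshold(c(0.1, 0.2), c(0.8, 0.9))
  expect_equal(perfect$f1, 1)
  expect_lt(perfect$threshold, 0.8)
  # enumerated by hand: cut at 0.3 gives tp=3 fp=0 fn=1 -> F1 = 6/7
  res <- f1_optimal_threshold(c(.1, .2, .3, .9), c(.4, .6, .7, .8))
  expect_equal(res$f1, 6 / 7)
  expect_equal(res$threshold, 0.3)
  # F1 = 2/3 is attained at both cut .1 (tp1 fp0) and cut .4 (tp2 fp2);
  # the tie resolves to the smallest threshold
  res2 <- f1_optimal_threshold(c(.1, .4), c(.2, .3))
  expect_equal(res2$f1, 2 / 3)
  expect_equal(res2$threshold, 0.1)
})

test_that("leave-one-out CV on a minimal instance yields the enumerable outcomes", {
  msim <- make_sim(c("m1", "m2"), list(list("m1", "m2", 0.5)))
  dsim <- make_sim(c("d1"))
  assoc <- assoc_table("m1", "d1")
  cv <- loocv(assoc, msim, dsim, params = model_params(gamma = 1), seed = 1)
  expect_equal(nrow(cv$folds), 1L)
  expect_true(cv$folds$rank %in% c(1L, 2L))
  expect_true(cv$folds$rank_ratio %in% c(0.5, 1.0))
  expect_equal(cv$folds$n_candidates, 2L)
})

test_that("held-out family ratios are recomputed without the held-out edge", {
  # one family {m1, m2}; only association m1-d1: removing it must drop the
  # family ratio to 0, so the remaining network carries no association edge
  msim <- make_sim(c("m1", "m2"), list(list("m1", "m2", 0.9)))
  dsim <- make_sim(c("d1"))
  fams <- gene_sets(list(f = c("m1", "m2")))
  assoc <- assoc_table("m1", "d1")
  cv <- loocv(assoc, msim, dsim, families = fams,
              params = model_params(gamma = 1, eta = 10), seed = 1)
  # with the single association removed there is no flow at all: worst rank
  expect_equal(cv$folds$rank_ratio, 1.0)
})

test_that("ab initio folds coincide with LOOCV folds for single-association queries", {
  b <- generate_benchmark(benchmark_spec(n_mirna = 20, n_disease = 12,
                                         n_modules = 4, group_size_range = c(2, 4), seed = 3))
  p <- model_params(gamma = 1)
  cv1 <- loocv(b$assoc, b$mirna_sim, b$disease_sim, params = p, seed = 1)
  cv2 <- ab_initio_cv(b$assoc, b$mirna_sim, b$disease_sim, params = p, seed = 1)
  expect_equal(nrow(cv1$folds), nrow(cv2$folds))
  counts <- table(b$assoc$disease)
  singles <- names(counts)[counts == 1]
  for (q in singles) {
    f1 <- cv1$folds[cv1$folds$query_id == q, ]
    f2 <- cv2$folds[cv2$folds$query_id == q, ]
    expect_equal(f1$rank, f2$rank)
    expect_equal(f1$rank_ratio, f2$rank_ratio)
  }
})

test_that("ab initio AUC does not exceed LOOCV AUC in most seeds", {
  wins <- 0L
  for (s in 1:10) {
    b <- generate_benchmark(benchmark_spec(n_mirna = 24, n_disease = 16,
                                           n_modules = 4, group_size_range = c(2, 4), seed = s))
    p <- model_params()
    a1 <- loocv(b$assoc, b$mirna_sim, b$disease_sim, b$families, b$clusters,
                p, seed = s)$auc
    a2 <- ab_initio_cv(b$assoc, b$mirna_sim, b$disease_sim, b$families,
                       b$clusters, p, seed = s)$auc
    if (a2 <= a1) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("permutation preserves layer sizes exactly", {
  b <- generate_benchmark(benchmark_spec(n_mirna = 15, n_disease = 10,
                                         n_modules = 3, group_size_range = c(2, 4), seed = 2))
  set.seed(4)
  perm <- mirflow:::permute_associations(b$assoc, rownames(b$mirna_sim),
                                         rownames(b$disease_sim))
  expect_equal(nrow(perm), nrow(b$assoc))
  expect_equal(anyDuplicated(paste(perm$mirna, perm$disease)), 0L)

  psim <- mirflow:::permute_sim_matrix(b$mirna_sim)
  expect_equal(sort(psim[upper.tri(psim)]),
               sort(unclass(b$mirna_sim)[upper.tri(b$mirna_sim)]))
  for (a in c(0.2, 0.5)) {
    expect_equal(sum(psim[upper.tri(psim)] >= a),
                 sum(unclass(b$mirna_sim)[upper.tri(b$mirna_sim)] >= a))
  }
  expect_error(
    permutation_experiment(b$assoc, b$mirna_sim, b$disease_sim, n_reps = 0),
    "n_reps")
})

test_that("ablating the association layer collapses every score to zero and AUC to 0.5", {
  b <- generate_benchmark(benchmark_spec(n_mirna = 15, n_disease = 10,
                                         n_modules = 3, group_size_range = c(2, 4), seed = 2))
  cv <- ablation(b$assoc, b$mirna_sim, b$disease_sim, b$families, b$clusters,
                 drop = "associations")
  expect_true(all(cv$folds$rank_ratio == 1))
  expect_true(all(cv$negatives == 1))
  expect_equal(cv$auc, 0.5)
})

test_that("dropping a similarity layer leaves the association layer intact", {
  b <- generate_benchmark(benchmark_spec(n_mirna = 15, n_disease = 10,
                                         n_modules = 3, group_size_range = c(2, 4), seed = 2))
  net_full <- assemble_network(b$mirna_sim, b$disease_sim, b$assoc)
  net_nods <- assemble_network(b$mirna_sim, NULL, b$assoc)
  expect_equal(sum(net_nods$edges$layer == "association"),
               sum(net_full$edges$layer == "association"))
  expect_equal(sum(net_nods$edges$layer == "disease_sim"), 0L)
})

test_that("grid search enumerates the Cartesian product and returns the argmax", {
  b <- generate_benchmark(benchmark_spec(n_mirna = 15, n_disease = 10,
                                         n_modules = 3, group_size_range = c(2, 4), seed = 5))
  gs <- grid_search(b$assoc, b$mirna_sim, b$disease_sim,
                    grid = list(alpha = c(0.1, 0.5), gamma = c(1, 100)),
                    seed = 1)
  expect_equal(nrow(gs$table), 4L)
  expect_equal(max(gs$table$auc),
               gs$table$auc[gs$table$alpha == gs$best_params$alpha &
                            gs$table$gamma == gs$best_params$gamma])
  single <- grid_search(b$assoc, b$mirna_sim, b$disease_sim,
                        grid = list(gamma = 7), seed = 1)
  expect_equal(single$best_params$gamma, 7)
  expect_error(grid_search(b$assoc, b$mirna_sim, b$disease_sim,
                           grid = list()), "empty")
  expect_error(grid_search(b$assoc, b$mirna_sim, b$disease_sim,
                           grid = list(zeta = 1)), "unknown")
})

test_that("hypergeometric upper tail matches its closed-form special cases", {
  expect_equal(hypergeometric_enrichment(0, 5, 5, 10), 1)
  expect_equal(hypergeometric_enrichment(5, 5, 5, 10), 1 / choose(10, 5))
  expect_error(hypergeometric_enrichment(6, 5, 5, 10), "inconsistent")
  expect_error(hypergeometric_enrichment(2, 5, 5, 4), "inconsistent")
})

test_that("hypergeometric upper tail matches brute-force summation", {
  set.seed(31)
  for (i in 1:200) {
    N <- sample(60, 1)
    K <- sample(N, 1); n <- sample(N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeometric_enrichment(k, n, K, N),
                 hyper_upper_tail_brute(k, n, K, N), tolerance = 1e-12)
  }
})

test_that("pooled curves include every fold's candidates", {
  b <- generate_benchmark(benchmark_spec(n_mirna = 12, n_disease = 8,
                                         n_modules = 3, group_size_range = c(2, 4), seed = 7))
  cv <- loocv(b$assoc, b$mirna_sim, b$disease_sim, seed = 1)
  expect_equal(length(cv$positives), nrow(cv$folds))
  expect_equal(length(cv$negatives), sum(cv$folds$n_candidates - 1L))
  expect_true(all(cv$positives > 0 & cv$positives <= 1))
})

test_that("random candidate pools have the requested size and include the held-out entity", {
  b <- generate_benchmark(benchmark_spec(n_mirna = 20, n_disease = 10,
                                         n_modules = 4, group_size_range = c(2, 4), seed = 4))
  cv <- loocv(b$assoc, b$mirna_sim, b$disease_sim, candidate_pool = 5, seed = 2)
  expect_true(all(cv$folds$n_candidates == 6L))
  cv_rerun <- loocv(b$assoc, b$mirna_sim, b$disease_sim, candidate_pool = 5,
                    seed = 2)
  expect_equal(cv$folds, cv_rerun$folds)  # seeded pools are reproducible
  expect_error(loocv(b$assoc, b$mirna_sim, b$disease_sim,
                     candidate_pool = 500, seed = 2), "exceeds")
})
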