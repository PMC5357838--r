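# Shared fixtures and independent oracles, built in code at test time.

# labelled similarity matrix from an upper-triangular specification
make_sim <- function(labels, pairs = list()) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (p in pairs) m[p[[1]], p[[2]]] <- m[p[[2]], p[[1]]] <- p[[3]]
  diag(m) <- 1
  sim_matrix(m)
}

# the four-node two-layer fixture: two microRNAs (similarity 0.5), two
# diseases (similarity 0.5), associations m1-d1 and m2-d2
tiny_network <- function(params = model_params(alpha = 0.4, beta = 0.4,
                                               gamma = 1)) {
  assemble_network(
    make_sim(c("m1", "m2"), list(list("m1", "m2", 0.5))),
    make_sim(c("d1", "d2"), list(list("d1", "d2", 0.5))),
    assoc_table(c("m1", "m2"), c("d1", "d2")),
    params = params)
}

# exhaustive min-cut over all s/t partitions (oracle for graphs <= 8 nodes)
brute_force_min_cut <- function(n, from, to, cap, s, t) {
  others <- setdiff(seq_len(n), c(s, t))
  best <- Inf
  for (mask in 0:(2^length(others) - 1)) {
    side <- c(s, others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0])
    best <- min(best, sum(cap[from %in% side & !(to %in% side)]))
  }
  best
}

# random directed capacity graph wrapped as a capacity_graph object
random_capacity_graph <- function(n, m, max_cap = 10) {
  from <- sample(n, m, replace = TRUE)
  to <- sample(n, m, replace = TRUE)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  cap <- if (length(from)) sample(max_cap, length(from), replace = TRUE) else integer()
  nodes <- paste0("n", seq_len(n))
  structure(list(nodes = nodes,
                 arcs = data.frame(from = nodes[from], to = nodes[to],
                                   capacity = cap, stringsAsFactors = FALSE),
                 source = nodes[1L], sink = nodes[n],
                 query = nodes[1L], candidates = nodes[n],
                 infinity = sum(cap) + 1),
            class = "capacity_graph")
}

# Mann-Whitney AUC with half credit for ties (rank-statistic oracle)
mann_whitney_auc <- function(positives, negatives) {
  wins <- outer(positives, negatives, function(p, q) (p < q) + 0.5 * (p == q))
  mean(wins)
}

# flow feasibility + conservation checks on a flow_result
expect_valid_flow <- function(flow, graph) {
  a <- flow$arcs
  expect_true(all(a$flow >= 0))
  expect_true(all(a$flow <= a$capacity))
  inner <- setdiff(graph$nodes, c(graph$source, graph$sink))
  for (v in inner) {
    expect_equal(sum(a$flow[a$to == v]), sum(a$flow[a$from == v]))
  }
  expect_equal(flow$value, sum(a$flow[a$from == graph$source]) -
                 sum(a$flow[a$to == graph$source]))
  expect_equal(flow$value, sum(a$flow[a$to == graph$sink]) -
                 sum(a$flow[a$from == graph$sink]))
}

# upper-tail hypergeometric by direct combinatorial summation
hyper_upper_tail_brute <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
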