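# Validation machinery: rank-ratio ROC / precision-recall curves,
# leave-one-out and ab initio cross-validation, permutation nulls, layer
# ablations, parameter grid search, hypergeometric enrichment.
#
# Orientation convention: rank ratio = rank / number of candidates, so the
# SMALLER the rank ratio the better the prediction. A pair is "predicted
# positive" at threshold T when its rank ratio is <= T. Within one fold,
# candidates with tied scores all receive the tie group's worst rank
# (ties.method = "max"): this keeps pooled curves invariant to identifier
# labels, and a fold in which every candidate ties (no flow at all)
# contributes exactly chance-level information.

run_with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

eval_curve <- function(thresholds, x, y, auc) {
  structure(list(thresholds = thresholds, x = x, y = y, auc = auc),
            class = "eval_curve")
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)
}

#' ROC and precision-recall curves from pooled rank ratios
#'
#' Sweeps the rank-ratio threshold over all distinct pooled values (plus the
#' all-negative cut at 0). At threshold `T`, a rank ratio `<= T` is a
#' positive prediction; TPR/recall is the fraction of positives predicted,
#' FPR the fraction of negatives predicted, precision the fraction of
#' predictions that are positives. The area under each curve is computed by
#' the trapezoidal rule; the ROC area equals the normalized Mann-Whitney
#' statistic (ties credited one half).
#'
#' @param positives,negatives nonempty numeric vectors of rank ratios
#'   (smaller = better).
#' @return list with elements `roc` and `pr`, each an `eval_curve` (fields
#'   `thresholds`, `x`, `y`, `auc`).
#' @export
roc_pr_from_ranks <- function(positives, negatives) {
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("need at least one positive and one negative rank ratio", call. = FALSE)
  }
  vals <- sort(unique(c(positives, negatives)))
  tp <- vapply(vals, function(v) sum(positives <= v), 0)
  fp <- vapply(vals, function(v) sum(negatives <= v), 0)
  P <- length(positives); N <- length(negatives)
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  roc <- eval_curve(c(0, vals), fpr, tpr, trapezoid(fpr, tpr))
  pred <- tp + fp
  keep <- pred > 0
  recall <- tp[keep] / P
  precision <- tp[keep] / pred[keep]
  # anchor the PR curve at recall 0 with the earliest attainable precision
  if (length(recall) == 0L || recall[1L] > 0) {
    recall <- c(0, recall)
    precision <- c(if (length(precision)) precision[1L] else 0, precision)
    thr <- c(0, vals[keep])
  } else thr <- vals[keep]
  pr <- eval_curve(thr, recall, precision, trapezoid(recall, precision))
  list(roc = roc, pr = pr)
}

#' F1-optimal rank-ratio threshold
#'
#' Maximizes `F1 = 2 * precision * recall / (precision + recall)` over the
#' distinct pooled rank-ratio cuts; ties pick the smallest threshold. The
#' returned threshold is on the internal scale (smaller rank ratio =
#' better); its complement `1 - threshold` is the same cut expressed as a
#' "top fraction excluded" score.
#'
#' @inheritParams roc_pr_from_ranks
#' @return list with `threshold` and `f1`.
#' @export
f1_optimal_threshold <- function(positives, negatives) {
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("need at least one positive and one negative rank ratio", call. = FALSE)
  }
  vals <- sort(unique(c(positives, negatives)))
  P <- length(positives)
  f1s <- vapply(vals, function(v) {
    tp <- sum(positives <= v); fp <- sum(negatives <= v)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp); rec <- tp / P
    2 * prec * rec / (prec + rec)
  }, 0)
  best <- which.max(f1s)  # which.max takes the first (smallest) threshold on ties
  list(threshold = vals[best], f1 = f1s[best])
}

# precomputed similarity-layer edges + node universe, reused across CV folds
network_skeleton <- function(mirna_sim, disease_sim, assoc, params) {
  mirnas <- sort(unique(c(if (!is.null(mirna_sim)) rownames(mirna_sim),
                          assoc$mirna)), method = "radix")
  diseases <- sort(unique(c(if (!is.null(disease_sim)) rownames(disease_sim),
                            assoc$disease)), method = "radix")
  list(sim_edges = rbind(
         sim_layer_edges(mirna_sim, params$alpha, "mirna_sim"),
         sim_layer_edges(disease_sim, params$beta, "disease_sim")),
       nodes = data.frame(id = c(mirnas, diseases),
                          kind = rep(c("mirna", "disease"),
                                     c(length(mirnas), length(diseases))),
                          stringsAsFactors = FALSE),
       mirnas = mirnas, diseases = diseases)
}

skeleton_network <- function(skel, assoc, families, clusters, params) {
  assoc_edges <- if (nrow(assoc)) data.frame(
    u = assoc$mirna, v = assoc$disease,
    weight = association_edge_weights(assoc, families, clusters, params),
    layer = "association", stringsAsFactors = FALSE) else NULL
  structure(list(nodes = skel$nodes,
                 edges = rbind(skel$sim_edges, assoc_edges)),
            class = "hetero_network")
}

cv_fold <- function(network, query, held_out, candidates, params, score_mode) {
  rl <- prioritize(network, query, candidates, params, score_mode)
  n <- nrow(rl)
  tie_rank <- rank(-rl$score, ties.method = "max")
  ratios <- setNames(tie_rank / n, rl$candidate_id)
  list(rank = unname(tie_rank[rl$candidate_id == held_out]),
       rank_ratio = unname(ratios[held_out]),
       negatives = unname(ratios[names(ratios) != held_out]),
       n_candidates = n)
}

cv_result <- function(folds, params, mode) {
  positives <- vapply(folds, `[[`, 0, "rank_ratio")
  negatives <- unlist(lapply(folds, `[[`, "negatives"), use.names = FALSE)
  curves <- roc_pr_from_ranks(positives, negatives)
  structure(list(
    folds = data.frame(
      query_id = vapply(folds, `[[`, "", "query"),
      held_out_id = vapply(folds, `[[`, "", "held_out"),
      rank = vapply(folds, `[[`, 0, "rank"),
      rank_ratio = positives,
      n_candidates = vapply(folds, `[[`, 0, "n_candidates"),
      stringsAsFactors = FALSE),
    positives = positives, negatives = negatives,
    roc = curves$roc, pr = curves$pr, auc = curves$roc$auc,
    params = params, mode = mode),
    class = "cv_result")
}

# orientation helpers: in "mirna" mode the query is a disease and the
# candidates are microRNAs; "disease" mode is the mirror image
cv_orient <- function(assoc, skel, mode) {
  if (mode == "mirna") {
    list(query = assoc$disease, held = assoc$mirna, pool = skel$mirnas,
         assoc_query = assoc$disease, assoc_held = assoc$mirna)
  } else {
    list(query = assoc$mirna, held = assoc$disease, pool = skel$diseases,
         assoc_query = assoc$mirna, assoc_held = assoc$disease)
  }
}

draw_candidates <- function(pool_all, held_out, candidate_pool) {
  others <- setdiff(pool_all, held_out)
  if (identical(candidate_pool, "all")) return(c(others, held_out))
  k <- as.integer(candidate_pool)
  if (k > length(others)) {
    stop("candidate pool size ", k, " exceeds the ", length(others),
         " available entities", call. = FALSE)
  }
  c(sample(others, k), held_out)
}

#' Leave-one-out cross-validation of the flow prioritizer
#'
#' For every known association, that single edge is treated as unknown: the
#' network is rebuilt without it (family and cluster co-association ratios
#' are recomputed on the reduced table, so the held-out edge cannot leak
#' through the weights), the held-out entity is prioritized against the
#' candidates, and its rank is recorded. Candidates are all entities not
#' associated with the query (`candidate_pool = "all"`) or a random subset
#' of the stated size plus the held-out entity.
#'
#' @param assoc an [assoc_table()] (the gold standard).
#' @param mirna_sim,disease_sim [sim_matrix()] layers (either may be `NULL`).
#' @param families,clusters optional [gene_sets()] collections.
#' @param params a [model_params()].
#' @param mode `"mirna"` (query diseases, rank candidate microRNAs) or
#'   `"disease"` (query microRNAs, rank candidate diseases).
#' @param candidate_pool `"all"` or an integer pool size.
#' @param seed integer seed for candidate sampling (`NULL` for the current
#'   RNG state).
#' @param score_mode passed to [prioritize()].
#' @param drop_layer optional layer name (`"mirna_sim"`, `"disease_sim"`,
#'   `"associations"`) whose edges are removed from every rebuilt network
#'   (used by [ablation()]).
#' @return a `cv_result`: per-fold table, pooled positive/negative rank
#'   ratios, ROC and PR `eval_curve`s, and `auc` (the ROC area).
#' @export
loocv <- function(assoc, mirna_sim = NULL, disease_sim = NULL,
                  families = NULL, clusters = NULL, params = model_params(),
                  mode = c("mirna", "disease"), candidate_pool = "all",
                  seed = NULL, score_mode = "single_flow", drop_layer = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(assoc, "assoc_table"))
  if (nrow(assoc) == 0L) stop("empty association table", call. = FALSE)
  if (!is.null(drop_layer) && drop_layer == "mirna_sim") mirna_sim <- NULL
  if (!is.null(drop_layer) && drop_layer == "disease_sim") disease_sim <- NULL
  drop_assoc <- !is.null(drop_layer) && drop_layer == "associations"
  skel <- network_skeleton(mirna_sim, disease_sim, assoc, params)
  orient <- cv_orient(assoc, skel, mode)
  run_with_seed(seed, {
    folds <- lapply(seq_len(nrow(assoc)), function(i) {
      train <- assoc[-i, , drop = FALSE]
      class(train) <- class(assoc)
      net <- skeleton_network(skel,
                              if (drop_assoc) assoc[0, , drop = FALSE] else train,
                              families, clusters, params)
      query <- orient$query[i]; held <- orient$held[i]
      linked <- orient$assoc_held[orient$assoc_query == query]
      pool_all <- setdiff(orient$pool, setdiff(linked, held))
      cands <- draw_candidates(pool_all, held, candidate_pool)
      c(cv_fold(net, query, held, cands, params, score_mode),
        list(query = query, held_out = held))
    })
    cv_result(folds, params, mode)
  })
}

#' Ab initio cross-validation (isolated-query setting)
#'
#' Like [loocv()], but before prioritizing, ALL known associations of the
#' query entity are removed from the network, emulating a query with no
#' prior annotations. One fold per (query, held-out) association pair; the
#' candidate set of a fold is the same as in [loocv()].
#'
#' @inheritParams loocv
#' @return a `cv_result`.
#' @export
ab_initio_cv <- function(assoc, mirna_sim = NULL, disease_sim = NULL,
                         families = NULL, clusters = NULL,
                         params = model_params(),
                         mode = c("mirna", "disease"), candidate_pool = "all",
                         seed = NULL, score_mode = "single_flow") {
  mode <- match.arg(mode)
  stopifnot(inherits(assoc, "assoc_table"))
  if (nrow(assoc) == 0L) stop("empty association table", call. = FALSE)
  skel <- network_skeleton(mirna_sim, disease_sim, assoc, params)
  orient <- cv_orient(assoc, skel, mode)
  run_with_seed(seed, {
    folds <- unlist(lapply(unique(orient$query), function(q) {
      q_rows <- orient$assoc_query == q
      train <- assoc[!q_rows, , drop = FALSE]
      class(train) <- class(assoc)
      net <- skeleton_network(skel, train, families, clusters, params)
      linked <- orient$assoc_held[q_rows]
      lapply(linked, function(held) {
        pool_all <- setdiff(orient$pool, setdiff(linked, held))
        cands <- draw_candidates(pool_all, held, candidate_pool)
        c(cv_fold(net, q, held, cands, params, score_mode),
          list(query = q, held_out = held))
      })
    }), recursive = FALSE)
    cv_result(folds, params, mode)
  })
}

permute_sim_matrix <- function(sim) {
  v <- unclass(sim)
  ut <- upper.tri(v)
  v[ut] <- sample(v[ut])
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  diag(v) <- 1
  sim_matrix(v)
}

permute_associations <- function(assoc, mirnas, diseases) {
  n_pairs <- length(mirnas) * length(diseases)
  if (nrow(assoc) > n_pairs) stop("more associations than possible pairs", call. = FALSE)
  pick <- sample.int(n_pairs, nrow(assoc))
  assoc_table(mirnas[((pick - 1L) %% length(mirnas)) + 1L],
              diseases[((pick - 1L) %/% length(mirnas)) + 1L])
}

#' Permutation null experiment
#'
#' Per replicate, one layer of the network is randomized while keeping its
#' edge count unchanged — the association layer is redrawn as a uniform
#' random bipartite edge set of the original size; a similarity layer has
#' its weights permuted over the same node-pair slots — and the full
#' leave-one-out cross-validation is rerun. With the biological connectivity
#' destroyed, the resulting ROC AUCs scatter around 0.5.
#'
#' @inheritParams loocv
#' @param layer `"associations"`, `"mirna_sim"` or `"disease_sim"`.
#' @param n_reps number of permutation replicates, `>= 1`.
#' @param seed integer; replicate `r` uses seed `seed + r - 1`.
#' @return numeric vector of pooled LOOCV ROC AUCs, one per replicate.
#' @export
permutation_experiment <- function(assoc, mirna_sim = NULL, disease_sim = NULL,
                                   families = NULL, clusters = NULL,
                                   params = model_params(),
                                   layer = c("associations", "mirna_sim",
                                             "disease_sim"),
                                   n_reps = 10, seed = 1,
                                   mode = "mirna", candidate_pool = "all") {
  layer <- match.arg(layer)
  if (n_reps < 1) stop("n_reps must be at least 1", call. = FALSE)
  skel <- network_skeleton(mirna_sim, disease_sim, assoc, params)
  vapply(seq_len(n_reps), function(r) {
    rep_seed <- seed + r - 1L
    inputs <- run_with_seed(rep_seed, switch(
      layer,
      associations = list(assoc = permute_associations(assoc, skel$mirnas,
                                                       skel$diseases),
                          mirna_sim = mirna_sim, disease_sim = disease_sim),
      mirna_sim = list(assoc = assoc,
                       mirna_sim = permute_sim_matrix(mirna_sim),
                       disease_sim = disease_sim),
      disease_sim = list(assoc = assoc, mirna_sim = mirna_sim,
                         disease_sim = permute_sim_matrix(disease_sim))))
    loocv(inputs$assoc, inputs$mirna_sim, inputs$disease_sim,
          families, clusters, params, mode = mode,
          candidate_pool = candidate_pool, seed = rep_seed)$auc
  }, 0)
}

#' Single-layer ablation
#'
#' Reruns [loocv()] with one layer's edges removed from every rebuilt
#' network. Removing the association layer disconnects every candidate from
#' the query (all flow scores become 0), which under the tie convention
#' yields a chance-level pooled AUC of 0.5.
#'
#' @inheritParams loocv
#' @param drop `"mirna_sim"`, `"disease_sim"` or `"associations"`.
#' @return a `cv_result`.
#' @export
ablation <- function(assoc, mirna_sim = NULL, disease_sim = NULL,
                     families = NULL, clusters = NULL,
                     params = model_params(),
                     drop = c("mirna_sim", "disease_sim", "associations"),
                     mode = "mirna", candidate_pool = "all", seed = NULL) {
  drop <- match.arg(drop)
  loocv(assoc, mirna_sim, disease_sim, families, clusters, params,
        mode = mode, candidate_pool = candidate_pool, seed = seed,
        drop_layer = drop)
}

#' Exhaustive parameter grid search
#'
#' Evaluates every combination of the supplied parameter values (Cartesian
#' product; each axis iterated in ascending order) with [loocv()] or
#' [ab_initio_cv()] and returns the parameters attaining the highest ROC
#' AUC, ties resolved by iteration order.
#'
#' @inheritParams loocv
#' @param grid named list of numeric vectors over any of `alpha`, `beta`,
#'   `gamma`, `eta`, `sigma`; omitted parameters keep their `params` value.
#' @param cv `"loocv"` or `"abinitio"`.
#' @return list with `best_params` (a [model_params()]) and `table` (one row
#'   per combination with its AUC).
#' @export
grid_search <- function(assoc, mirna_sim = NULL, disease_sim = NULL,
                        families = NULL, clusters = NULL,
                        params = model_params(), grid,
                        mode = "mirna", cv = c("loocv", "abinitio"),
                        candidate_pool = "all", seed = NULL) {
  cv <- match.arg(cv)
  if (length(grid) == 0L || any(lengths(grid) == 0L)) {
    stop("empty parameter grid", call. = FALSE)
  }
  bad <- setdiff(names(grid), c("alpha", "beta", "gamma", "eta", "sigma"))
  if (length(bad)) stop("unknown grid parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  grid <- lapply(grid, function(v) sort(unique(v)))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  aucs <- vapply(seq_len(nrow(combos)), function(i) {
    p <- params
    for (nm in names(combos)) p[[nm]] <- combos[[nm]][i]
    fn <- if (cv == "loocv") loocv else ab_initio_cv
    fn(assoc, mirna_sim, disease_sim, families, clusters, p,
       mode = mode, candidate_pool = candidate_pool, seed = seed)$auc
  }, 0)
  combos$auc <- aucs
  best <- which.max(aucs)
  best_params <- params
  for (nm in setdiff(names(combos), "auc")) best_params[[nm]] <- combos[[nm]][best]
  list(best_params = best_params, table = combos)
}

#' Hypergeometric enrichment of prediction overlap
#'
#' Upper-tail probability `P(X >= k)` that at least `k` of `n` predictions
#' fall among the `K` annotated items of a universe of size `N`, with `X`
#' hypergeometric. Computed in log space for numerical stability at extreme
#' significance.
#'
#' @param overlap observed overlap `k`.
#' @param predicted number of predictions `n`.
#' @param annotated number of annotated items `K`.
#' @param universe universe size `N`.
#' @return the p-value.
#' @export
hypergeometric_enrichment <- function(overlap, predicted, annotated, universe) {
  k <- overlap; n <- predicted; K <- annotated; N <- universe
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  if (k == 0) return(1)
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}
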