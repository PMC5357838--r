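# Rank-average ensembling of several predictors' ranked lists.

#' Rank profile of one prediction method
#'
#' A method's ranking expressed as rank ratios (rank / list length, smaller
#' = better) over a set of items, with an optional aggregation weight —
#' typically the method's cross-validation AUC.
#'
#' @param method_name label for the method.
#' @param rank_ratios named numeric vector in `(0, 1]`.
#' @param weight nonnegative aggregation weight, or `NA` for unweighted use.
#' @return a `rank_profile`.
#' @export
rank_profile <- function(method_name, rank_ratios, weight = NA_real_) {
  if (is.null(names(rank_ratios))) stop("rank_ratios must be named", call. = FALSE)
  names(rank_ratios) <- normalize_id(names(rank_ratios))
  if (anyDuplicated(names(rank_ratios))) stop("duplicate item ids", call. = FALSE)
  if (any(rank_ratios <= 0 | rank_ratios > 1)) {
    stop("rank ratios must lie in (0, 1]", call. = FALSE)
  }
  if (!is.na(weight) && weight < 0) stop("weight must be nonnegative", call. = FALSE)
  structure(list(method_name = method_name, rank_ratios = rank_ratios,
                 weight = weight), class = "rank_profile")
}

#' Helper: rank profile from a ranked list
#'
#' @param rl a [ranked_list()].
#' @inheritParams rank_profile
#' @export
as_rank_profile <- function(rl, method_name = "method", weight = NA_real_) {
  stopifnot(inherits(rl, "ranked_list"))
  rank_profile(method_name, setNames(rl$rank_ratio, rl$candidate_id), weight)
}

#' Combine predictors by (weighted) rank averaging
#'
#' The combined score of an item is the weighted mean of its rank ratios
#' across methods, `sum(w_m * rr_m) / sum(w_m)` (all `w_m = 1` when
#' unweighted); smaller combined score = better. All profiles must cover
#' the identical item set. Weights are normalized to sum 1, so only their
#' proportions matter; using each method's AUC as its weight gives the
#' AUC-weighted rank average.
#'
#' @param profiles list of at least two [rank_profile()]s.
#' @param weighted if `TRUE`, use the profiles' weights (all must be present
#'   with a positive sum).
#' @return a [ranked_list()] sorted by combined score ascending (the `score`
#'   column holds the combined rank-ratio score).
#' @export
rank_average <- function(profiles, weighted = FALSE) {
  if (length(profiles) < 2L) stop("need at least two profiles", call. = FALSE)
  stopifnot(all(vapply(profiles, inherits, TRUE, "rank_profile")))
  items <- sort(names(profiles[[1L]]$rank_ratios), method = "radix")
  for (p in profiles[-1L]) {
    other <- names(p$rank_ratios)
    if (!setequal(items, other)) {
      diffs <- c(setdiff(items, other), setdiff(other, items))
      stop("profiles cover different item sets; symmetric difference: ",
           paste(diffs, collapse = ", "), call. = FALSE)
    }
  }
  w <- if (weighted) {
    wts <- vapply(profiles, `[[`, 0, "weight")
    if (anyNA(wts)) stop("weighted averaging needs a weight on every profile",
                         call. = FALSE)
    if (sum(wts) <= 0) stop("profile weights must have positive sum", call. = FALSE)
    wts / sum(wts)
  } else rep(1 / length(profiles), length(profiles))
  combined <- Reduce(`+`, Map(function(p, wi) wi * p$rank_ratios[items],
                              profiles, w))
  ranked_list(items, unname(combined), decreasing = FALSE)
}
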