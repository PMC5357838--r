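# MicroRNAome layer: target-overlap functional similarity.
# Phenome layer: information-content-weighted semantic similarity over
# MeSH-style tree numbers, optionally blended with a precomputed phenotypic
# similarity for OMIM-mapped disease pairs.

#' Target-overlap similarity between two microRNAs
#'
#' Functional similarity of two microRNAs from their predicted target-gene
#' sets. With `n_com` shared targets and set sizes `n_i`, `n_j`:
#' Jaccard form `n_com / (n_i + n_j - n_com)` (default) or Dice form
#' `2 n_com / (n_i + n_j)`. Two empty sets score 0.
#'
#' @param targets_i,targets_j character vectors of target-gene ids.
#' @param metric `"jaccard"` (default) or `"dice"`.
#' @return a score in `[0, 1]`.
#' @export
target_overlap_similarity <- function(targets_i, targets_j,
                                      metric = c("jaccard", "dice")) {
  metric <- match.arg(metric)
  ti <- unique(normalize_id(targets_i))
  tj <- unique(normalize_id(targets_j))
  ni <- length(ti); nj <- length(tj)
  if (ni + nj == 0L) return(0)
  ncom <- length(intersect(ti, tj))
  if (metric == "jaccard") ncom / (ni + nj - ncom) else 2 * ncom / (ni + nj)
}

#' Build the microRNA functional similarity matrix from target sets
#'
#' Pairwise [target_overlap_similarity()] over the listed microRNAs; the
#' diagonal is forced to 1 (a microRNA is maximally similar to itself even
#' when its target set is empty).
#'
#' @param targets a [gene_sets()] mapping microRNA id to target-gene ids.
#' @param mirnas character vector of microRNA ids; defaults to all set names.
#' @param metric passed to [target_overlap_similarity()].
#' @return a [sim_matrix()] over `mirnas`.
#' @export
build_mirna_similarity <- function(targets, mirnas = names(targets),
                                   metric = c("jaccard", "dice")) {
  metric <- match.arg(metric)
  stopifnot(inherits(targets, "gene_sets"))
  mirnas <- normalize_id(mirnas)
  missing <- setdiff(mirnas, names(targets))
  if (length(missing)) {
    stop("microRNA(s) without a target set: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- length(mirnas)
  m <- matrix(0, n, n, dimnames = list(mirnas, mirnas))
  sets <- lapply(targets[mirnas], function(x) unique(normalize_id(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      m[i, j] <- m[j, i] <- target_overlap_similarity(sets[[i]], sets[[j]], metric)
    }
  }
  diag(m) <- 1
  sim_matrix(m)
}

#' Information content of disease terms over a DAG corpus
#'
#' The information content of a term `S` is `IC(S) = -log(p(S))` where `p(S)`
#' is the fraction of disease DAGs (ancestor closures of the corpus diseases)
#' in which `S` appears. Natural logarithm; a term present in every DAG has
#' `IC = 0`.
#'
#' @param dag a [mesh_dag()].
#' @param corpus disease ids forming the corpus; defaults to all mapped
#'   diseases.
#' @return an `ic_table`: named numeric vector of IC values with attribute
#'   `corpus_size`.
#' @export
compute_ic_table <- function(dag, corpus = names(dag$terms)) {
  stopifnot(inherits(dag, "mesh_dag"))
  corpus <- normalize_id(corpus)
  if (length(corpus) == 0L) stop("empty DAG corpus", call. = FALSE)
  dags <- lapply(corpus, function(d) mesh_ancestors(dag, d))
  counts <- table(unlist(dags))
  ic <- -log(as.numeric(counts) / length(corpus))
  ic[ic < 0] <- 0  # guard against -0
  structure(setNames(ic, names(counts)), corpus_size = length(corpus),
            class = "ic_table")
}

#' @rdname compute_ic_table
#' @param term a single disease term id.
#' @param ic an `ic_table`.
#' @return `information_content()` returns the scalar IC of one term; a term
#'   appearing in no DAG of the corpus is an error (its likelihood is zero).
#' @export
information_content <- function(term, ic) {
  stopifnot(inherits(ic, "ic_table"))
  term <- normalize_id(term)
  if (!term %in% names(ic)) {
    stop("term appears in no DAG of the corpus: ", term, call. = FALSE)
  }
  unname(ic[[term]])
}

#' Semantic profile of a disease
#'
#' The semantic value of a disease `S` aggregates contributions from its
#' ancestor set `T_S` (all ancestors including `S` itself). Under the default
#' `"ic"` model each ancestor `t` contributes its information content
#' `IC(t)`; under the `"decay"` model the disease itself contributes 1 and
#' each ancestor contributes `delta^k` where `k` is its minimal tree-number
#' segment distance from `S` (the classical hop-decayed semantic value).
#'
#' @param disease a disease id present in `dag`.
#' @param dag a [mesh_dag()].
#' @param ic an `ic_table` from [compute_ic_table()] (required for the `"ic"`
#'   model).
#' @param model `"ic"` or `"decay"`.
#' @param delta decay factor in `(0, 1)` for the `"decay"` model.
#' @return a `semantic_profile`: list with `disease`, `contributions` (named
#'   numeric over the ancestor set) and `dv_total`.
#' @export
semantic_profile <- function(disease, dag, ic = NULL,
                             model = c("ic", "decay"), delta = 0.5) {
  model <- match.arg(model)
  disease <- normalize_id(disease)
  anc <- mesh_ancestors(dag, disease)
  if (model == "ic") {
    if (is.null(ic)) stop("model 'ic' needs an ic_table", call. = FALSE)
    contrib <- vapply(anc, function(t) information_content(t, ic), 0)
  } else {
    if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)", call. = FALSE)
    contrib <- vapply(anc, function(t) {
      delta^tree_hop_distance(dag, disease, t)
    }, 0)
  }
  structure(list(disease = disease,
                 contributions = setNames(as.numeric(contrib), anc),
                 dv_total = sum(contrib)),
            class = "semantic_profile")
}

# minimal number of dot-segments separating an ancestor's tree number from
# one of the disease's tree numbers (0 for the disease itself)
tree_hop_distance <- function(dag, disease, ancestor) {
  if (identical(disease, ancestor)) return(0L)
  tn_d <- dag$terms[[disease]]
  tn_a <- dag$terms[[ancestor]]
  best <- Inf
  for (a in tn_a) {
    pref <- paste0(a, ".")
    for (d in tn_d) {
      if (startsWith(d, pref)) {
        hops <- lengths(regmatches(substring(d, nchar(a) + 1L),
                                   gregexpr(".", substring(d, nchar(a) + 1L),
                                            fixed = TRUE)))
        best <- min(best, hops)
      }
    }
  }
  if (!is.finite(best)) {
    stop(ancestor, " is not a prefix ancestor of ", disease, call. = FALSE)
  }
  best
}

#' Semantic similarity between two diseases
#'
#' With `T_A`, `T_B` the ancestor sets and `DV_A`, `DV_B` the per-ancestor
#' contributions of the two profiles,
#' `SS(A, B) = sum over t in T_A intersect T_B of (DV_A(t) + DV_B(t)) /
#' (DV(A) + DV(B))`. Identical profiles score 1; disjoint DAGs score 0.
#' When both total semantic values are zero (every ancestor has zero IC) the
#' similarity is defined as 0 with a warning.
#'
#' @param a,b `semantic_profile` objects.
#' @return a score in `[0, 1]`.
#' @export
semantic_similarity <- function(a, b) {
  stopifnot(inherits(a, "semantic_profile"), inherits(b, "semantic_profile"))
  denom <- a$dv_total + b$dv_total
  if (denom <= 0) {
    warning("both semantic values are zero; similarity defined as 0", call. = FALSE)
    return(0)
  }
  shared <- intersect(names(a$contributions), names(b$contributions))
  if (length(shared) == 0L) return(0)
  num <- sum(a$contributions[shared]) + sum(b$contributions[shared])
  min(1, num / denom)
}

#' Blend semantic and phenotypic disease similarity
#'
#' For disease pairs where both diseases carry an OMIM number and a
#' phenotypic score is available, the combined similarity is the arithmetic
#' mean `(SS + PS) / 2`; for every other pair the semantic similarity is used
#' directly. The diagonal stays 1.
#'
#' @param ss semantic [sim_matrix()] covering all diseases.
#' @param ps phenotypic [sim_matrix()] covering a subset of the diseases (or
#'   `NULL` for none).
#' @param omim_mapped character vector of disease ids that have an OMIM
#'   number; defaults to the labels of `ps`.
#' @return a [sim_matrix()] with the labels of `ss`.
#' @export
combine_semantic_phenotypic <- function(ss, ps = NULL,
                                        omim_mapped = rownames(ps)) {
  stopifnot(inherits(ss, "sim_matrix"))
  if (is.null(ps)) return(ss)
  stopifnot(inherits(ps, "sim_matrix"))
  if (any(ps < -1e-9 | ps > 1 + 1e-9)) stop("phenotypic values outside [0, 1]", call. = FALSE)
  omim_mapped <- normalize_id(omim_mapped)
  both <- intersect(intersect(rownames(ss), rownames(ps)), omim_mapped)
  out <- unclass(ss)
  if (length(both) >= 2L) {
    out[both, both] <- (out[both, both] + unclass(ps)[both, both]) / 2
  }
  diag(out) <- 1
  sim_matrix(out)
}

#' Build the disease semantic (and phenotypic) similarity matrix
#'
#' End-to-end phenome layer: per-disease semantic profiles over the
#' tree-number DAG, pairwise semantic similarity, then the OMIM blend of
#' [combine_semantic_phenotypic()]. Diseases in `diseases` that carry no tree
#' number are retained as isolated terms: similarity 0 to everything, 1 to
#' themselves, with a warning.
#'
#' @param dag a [mesh_dag()].
#' @param diseases disease universe (defaults to all mapped diseases).
#' @param model,delta passed to [semantic_profile()].
#' @param ps,omim_mapped passed to [combine_semantic_phenotypic()].
#' @return a [sim_matrix()] over `diseases`.
#' @export
build_disease_similarity <- function(dag, diseases = names(dag$terms),
                                     model = c("ic", "decay"), delta = 0.5,
                                     ps = NULL, omim_mapped = rownames(ps)) {
  model <- match.arg(model)
  diseases <- normalize_id(diseases)
  mapped <- intersect(diseases, names(dag$terms))
  unmapped <- setdiff(diseases, mapped)
  if (length(unmapped)) {
    warning("disease(s) without tree numbers kept as isolated terms: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  }
  ic <- if (model == "ic" && length(mapped)) compute_ic_table(dag, mapped) else NULL
  profiles <- lapply(mapped, semantic_profile, dag = dag, ic = ic,
                     model = model, delta = delta)
  names(profiles) <- mapped
  n <- length(diseases)
  m <- matrix(0, n, n, dimnames = list(diseases, diseases))
  zero_dv <- mapped[vapply(profiles, function(p) p$dv_total <= 0, TRUE)]
  if (length(zero_dv)) {
    warning("disease(s) with zero total semantic value: ",
            paste(zero_dv, collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(mapped)) {
    for (j in seq_len(i - 1L)) {
      pi <- profiles[[mapped[i]]]; pj <- profiles[[mapped[j]]]
      s <- if (pi$dv_total + pj$dv_total <= 0) 0 else
        suppressWarnings(semantic_similarity(pi, pj))
      m[mapped[i], mapped[j]] <- m[mapped[j], mapped[i]] <- s
    }
  }
  diag(m) <- 1
  combine_semantic_phenotypic(sim_matrix(m), ps, omim_mapped)
}
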