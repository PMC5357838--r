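# Assembly of the undirected microRNAome-phenome network UG and its
# transformation into the directed integer-capacity flow network DG.

#' Model parameters for network assembly and flow scoring
#'
#' * `alpha` — minimum microRNA functional similarity kept as an edge.
#' * `beta` — minimum disease similarity kept as an edge.
#' * `gamma` — base capacity of a known microRNA-disease association edge.
#' * `eta` — family correction: an association whose microRNA sits in a
#'   family with co-association ratio `R_p` is weighted
#'   `gamma * (1 + eta * R_p + sigma * R_q)`.
#' * `sigma` — the analogous genomic-cluster correction (ratio `R_q`).
#' * `capacity_scale` — integerization factor applied to finite capacities
#'   before max flow (round-half-to-even).
#' * `direction_mode` — `"both"` keeps association arcs in both directions;
#'   `"disease_to_mirna_only"` / `"mirna_to_disease_only"` drop one direction
#'   on association edges (similarity-layer arcs are always bidirectional).
#' * `metric` — target-overlap similarity form for pipelines that build the
#'   microRNAome from target sets.
#'
#' Defaults are the grid-search optimum for microRNA prioritization under
#' leave-one-out cross-validation: `alpha = 0.1`, `beta = 0.6`,
#' `gamma = 100`, `eta = 6`, `sigma = 10`.
#'
#' @param alpha,beta thresholds in `[0, 1]`.
#' @param gamma base association capacity, `> 0`.
#' @param eta,sigma nonnegative correction factors.
#' @param capacity_scale positive integerization factor.
#' @param direction_mode association-arc direction policy.
#' @param metric `"jaccard"` or `"dice"`.
#' @return a `model_params` list.
#' @export
model_params <- function(alpha = 0.1, beta = 0.6, gamma = 100, eta = 6,
                         sigma = 10, capacity_scale = 1000,
                         direction_mode = c("both", "disease_to_mirna_only",
                                            "mirna_to_disease_only"),
                         metric = c("jaccard", "dice")) {
  direction_mode <- match.arg(direction_mode)
  metric <- match.arg(metric)
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1) {
    stop("alpha and beta must lie in [0, 1]", call. = FALSE)
  }
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (eta < 0 || sigma < 0) stop("eta and sigma must be nonnegative", call. = FALSE)
  if (capacity_scale <= 0) stop("capacity_scale must be positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, eta = eta,
                 sigma = sigma, capacity_scale = capacity_scale,
                 direction_mode = direction_mode, metric = metric),
            class = "model_params")
}

#' Co-association ratio of a microRNA family or cluster with a disease
#'
#' The fraction of group members already known to be associated with the
#' disease: `R = n_associated_members / group_size`.
#'
#' @param group_members nonempty character vector of microRNA ids.
#' @param disease_id a disease id.
#' @param assoc an [assoc_table()].
#' @return a ratio in `[0, 1]`.
#' @export
family_cluster_ratio <- function(group_members, disease_id, assoc) {
  stopifnot(inherits(assoc, "assoc_table"))
  group_members <- unique(normalize_id(group_members))
  if (length(group_members) == 0L) stop("empty family/cluster group", call. = FALSE)
  disease_id <- normalize_id(disease_id)
  linked <- assoc$mirna[assoc$disease == disease_id]
  sum(group_members %in% linked) / length(group_members)
}

# max co-association ratio over the groups containing each microRNA, for all
# association rows at once; returns a numeric vector aligned with assoc rows
group_ratio_vector <- function(assoc, groups) {
  if (is.null(groups) || length(groups) == 0L) return(numeric(nrow(assoc)))
  mirnas <- sort(unique(assoc$mirna))
  diseases <- sort(unique(assoc$disease))
  amat <- matrix(FALSE, length(mirnas), length(diseases),
                 dimnames = list(mirnas, diseases))
  amat[cbind(assoc$mirna, assoc$disease)] <- TRUE
  out <- numeric(nrow(assoc))
  for (g in groups) {
    g <- unique(g)
    present <- intersect(g, mirnas)
    if (length(present) == 0L) next
    # ratio of the group's members associated with each disease
    counts <- if (length(present) == 1L) as.numeric(amat[present, ]) else
      colSums(amat[present, , drop = FALSE])
    ratio <- counts / length(g)
    rows <- which(assoc$mirna %in% g)
    if (length(rows)) {
      out[rows] <- pmax(out[rows], ratio[match(assoc$disease[rows], diseases)])
    }
  }
  out
}

#' Corrected weight of one association edge
#'
#' Base weight `gamma`; membership in a family with co-association ratio
#' `R_p > 0` raises it to `gamma * (1 + eta * R_p)`, cluster membership to
#' `gamma * (1 + sigma * R_q)`, and both to
#' `gamma * (1 + eta * R_p + sigma * R_q)`. A microRNA in several families
#' (clusters) uses the maximum-ratio group of each kind. The pair must be a
#' known association: family/cluster data reweights existing edges, it never
#' creates new ones.
#'
#' @param mirna,disease an association pair present in `assoc`.
#' @param families,clusters [gene_sets()] collections (or `NULL`).
#' @param assoc an [assoc_table()].
#' @param params a [model_params()].
#' @return the edge weight, `>= gamma`.
#' @export
association_edge_weight <- function(mirna, disease, families = NULL,
                                    clusters = NULL, assoc,
                                    params = model_params()) {
  mirna <- normalize_id(mirna); disease <- normalize_id(disease)
  hit <- assoc$mirna == mirna & assoc$disease == disease
  if (!any(hit)) {
    stop("(", mirna, ", ", disease, ") is not a known association", call. = FALSE)
  }
  max_ratio <- function(groups) {
    if (is.null(groups)) return(0)
    mine <- Filter(function(g) mirna %in% g, unclass(groups))
    if (length(mine) == 0L) return(0)
    max(vapply(mine, family_cluster_ratio, 0, disease_id = disease, assoc = assoc))
  }
  params$gamma * (1 + params$eta * max_ratio(families) +
                    params$sigma * max_ratio(clusters))
}

# all association edge weights at once (vectorized over assoc rows)
association_edge_weights <- function(assoc, families, clusters, params) {
  rp <- group_ratio_vector(assoc, if (is.null(families)) NULL else unclass(families))
  rq <- group_ratio_vector(assoc, if (is.null(clusters)) NULL else unclass(clusters))
  params$gamma * (1 + params$eta * rp + params$sigma * rq)
}

# similarity-layer edges at or above a threshold, as a data frame
sim_layer_edges <- function(sim, threshold, layer) {
  if (is.null(sim)) {
    return(data.frame(u = character(), v = character(), weight = numeric(),
                      layer = character(), stringsAsFactors = FALSE))
  }
  labs <- rownames(sim)
  keep <- which(upper.tri(sim) & unclass(sim) >= threshold, arr.ind = TRUE)
  data.frame(u = labs[keep[, 1L]], v = labs[keep[, 2L]],
             weight = unclass(sim)[keep],
             layer = rep_len(layer, nrow(keep)),
             stringsAsFactors = FALSE)
}

#' Assemble the undirected microRNAome-phenome network
#'
#' Three layers on one node set: microRNA-microRNA similarity edges with
#' similarity `>= alpha`, disease-disease similarity edges with similarity
#' `>= beta`, and known association edges weighted by
#' [association_edge_weight()]. Associated nodes missing from their
#' similarity matrix are kept (with a warning) as association-only nodes.
#'
#' @param mirna_sim microRNA [sim_matrix()] (or `NULL` for none).
#' @param disease_sim disease [sim_matrix()] (or `NULL` for none).
#' @param assoc an [assoc_table()].
#' @param families,clusters optional [gene_sets()] collections.
#' @param params a [model_params()].
#' @return a `hetero_network`: list with `nodes` (id, kind) and `edges`
#'   (u, v, weight, layer).
#' @export
assemble_network <- function(mirna_sim, disease_sim, assoc, families = NULL,
                             clusters = NULL, params = model_params()) {
  stopifnot(inherits(assoc, "assoc_table"), inherits(params, "model_params"))
  mir_labels <- if (is.null(mirna_sim)) character() else rownames(mirna_sim)
  dis_labels <- if (is.null(disease_sim)) character() else rownames(disease_sim)
  lost_m <- setdiff(unique(assoc$mirna), mir_labels)
  lost_d <- setdiff(unique(assoc$disease), dis_labels)
  if (length(lost_m) && !is.null(mirna_sim)) {
    warning("microRNA(s) absent from the similarity matrix kept as ",
            "association-only nodes: ", paste(lost_m, collapse = ", "),
            call. = FALSE)
  }
  if (length(lost_d) && !is.null(disease_sim)) {
    warning("disease(s) absent from the similarity matrix kept as ",
            "association-only nodes: ", paste(lost_d, collapse = ", "),
            call. = FALSE)
  }
  mirnas <- sort(unique(c(mir_labels, assoc$mirna)))
  diseases <- sort(unique(c(dis_labels, assoc$disease)))
  clash <- intersect(mirnas, diseases)
  if (length(clash)) {
    stop("identifier(s) used as both microRNA and disease: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  edges <- rbind(
    sim_layer_edges(mirna_sim, params$alpha, "mirna_sim"),
    sim_layer_edges(disease_sim, params$beta, "disease_sim"),
    if (nrow(assoc)) data.frame(
      u = assoc$mirna, v = assoc$disease,
      weight = association_edge_weights(assoc, families, clusters, params),
      layer = "association", stringsAsFactors = FALSE)
  )
  edges <- edges[edges$weight > 0, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    nodes = data.frame(id = c(mirnas, diseases),
                       kind = rep(c("mirna", "disease"),
                                  c(length(mirnas), length(diseases))),
                       stringsAsFactors = FALSE),
    edges = edges),
    class = "hetero_network")
}

#' Directed integer-capacity flow network for one query
#'
#' Splits every undirected edge into two opposite arcs with capacity
#' `round(weight * capacity_scale)` (round-half-to-even; arcs that round to 0
#' are dropped), then attaches an artificial source `s` with an
#' infinite-capacity arc to the query node and an infinite-capacity arc from
#' every candidate to an artificial sink `t`. "Infinite" is
#' `1 + sum of all finite scaled capacities`, which no s-t flow can saturate.
#' Under a one-way `direction_mode`, the disallowed direction is dropped on
#' association edges only.
#'
#' @param network a `hetero_network` from [assemble_network()].
#' @param query_id node to attach the source to.
#' @param candidate_ids nodes feeding the sink; nonempty, not containing the
#'   query.
#' @param params a [model_params()].
#' @return a `capacity_graph`: list with `nodes`, `arcs` (from, to,
#'   capacity), `source`, `sink`, `query`, `candidates`, `infinity`.
#' @export
directify <- function(network, query_id, candidate_ids,
                      params = model_params()) {
  stopifnot(inherits(network, "hetero_network"))
  query_id <- normalize_id(query_id)
  candidate_ids <- unique(normalize_id(candidate_ids))
  if (!query_id %in% network$nodes$id) stop("query not in network: ", query_id, call. = FALSE)
  if (length(candidate_ids) == 0L) stop("empty candidate set", call. = FALSE)
  if (query_id %in% candidate_ids) stop("query cannot be a candidate", call. = FALSE)
  absent <- setdiff(candidate_ids, network$nodes$id)
  if (length(absent)) {
    stop("candidate(s) not in network: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  e <- network$edges
  cap <- round(e$weight * params$capacity_scale)
  keep <- cap > 0
  e <- e[keep, , drop = FALSE]; cap <- cap[keep]
  from <- c(e$u, e$v)
  to <- c(e$v, e$u)
  acap <- c(cap, cap)
  layer <- c(e$layer, e$layer)
  if (params$direction_mode != "both") {
    kinds <- setNames(network$nodes$kind, network$nodes$id)
    drop_kind <- if (params$direction_mode == "disease_to_mirna_only") "mirna" else "disease"
    drop <- layer == "association" & kinds[from] == drop_kind
    from <- from[!drop]; to <- to[!drop]; acap <- acap[!drop]
  }
  s <- "__source__"; t <- "__sink__"
  if (any(c(s, t) %in% network$nodes$id)) {
    stop("reserved node id in network", call. = FALSE)
  }
  infinity <- 1 + sum(acap)
  arcs <- data.frame(
    from = c(from, s, candidate_ids),
    to = c(to, query_id, rep(t, length(candidate_ids))),
    capacity = c(acap, infinity, rep(infinity, length(candidate_ids))),
    stringsAsFactors = FALSE)
  structure(list(nodes = c(sort(network$nodes$id, method = "radix"), s, t),
                 arcs = arcs,
                 source = s, sink = t, query = query_id,
                 candidates = sort(candidate_ids, method = "radix"),
                 infinity = infinity),
            class = "capacity_graph")
}
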