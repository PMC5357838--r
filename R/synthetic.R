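# Self-contained benchmark generator with planted module structure: the
# method's core assumption — functionally related microRNAs tend to be
# associated with phenotypically similar diseases — is literally planted,
# so signal recovery is testable without any external downloads.

#' Specification of the planted synthetic benchmark
#'
#' MicroRNAs and diseases are assigned to latent modules; within-module
#' similarity is drawn around `sim_in`, between-module around `sim_out`
#' (normal noise `sim_noise`, clipped to `[0, 1]`); a module-matched
#' microRNA-disease pair is associated with probability `p_in`, a
#' mismatched pair with `p_out`; families and clusters are within-module
#' microRNA subsets. Defaults give a desk-scale benchmark (60 microRNAs,
#' 40 diseases, 8 modules) whose association density and block-structured,
#' mostly-small similarity values mirror a sparse curated catalogue.
#'
#' @param n_mirna,n_disease entity counts.
#' @param n_modules number of planted modules.
#' @param p_in,p_out association probability for module-matched /
#'   mismatched pairs (`p_out < p_in`).
#' @param sim_in,sim_out mean similarity within / between modules
#'   (`sim_out < sim_in`).
#' @param sim_noise standard deviation of the similarity noise.
#' @param n_families,n_clusters number of family / cluster sets.
#' @param group_size_range inclusive size range of each family/cluster.
#' @param seed integer seed; the whole benchmark is a deterministic
#'   function of the spec.
#' @return a `benchmark_spec`.
#' @export
benchmark_spec <- function(n_mirna = 60, n_disease = 40, n_modules = 8,
                           p_in = 0.3, p_out = 0.01,
                           sim_in = 0.6, sim_out = 0.1, sim_noise = 0.1,
                           n_families = 6, n_clusters = 6,
                           group_size_range = c(3, 6), seed = 1) {
  stopifnot(n_mirna >= 1, n_disease >= 1, n_modules >= 1,
            length(group_size_range) == 2L,
            group_size_range[1] <= group_size_range[2])
  if (p_out >= p_in) stop("p_out must be smaller than p_in", call. = FALSE)
  if (sim_out >= sim_in) stop("sim_out must be smaller than sim_in", call. = FALSE)
  if (any(c(p_in, p_out) < 0) || any(c(p_in, p_out) > 1)) {
    stop("association probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_mirna = n_mirna, n_disease = n_disease,
                 n_modules = n_modules, p_in = p_in, p_out = p_out,
                 sim_in = sim_in, sim_out = sim_out, sim_noise = sim_noise,
                 n_families = n_families, n_clusters = n_clusters,
                 group_size_range = group_size_range, seed = seed),
            class = "benchmark_spec")
}

# balanced module assignment: sizes differ by at most one, order shuffled
assign_modules <- function(n, k) {
  sample(rep_len(seq_len(k), n))
}

block_similarity <- function(labels, modules, sim_in, sim_out, sim_noise) {
  n <- length(labels)
  means <- ifelse(outer(modules, modules, `==`), sim_in, sim_out)
  v <- matrix(0, n, n, dimnames = list(labels, labels))
  ut <- which(upper.tri(v))
  v[ut] <- pmin(1, pmax(0, rnorm(length(ut), means[ut], sim_noise)))
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  diag(v) <- 1
  sim_matrix(v)
}

sample_groups <- function(prefix, n_groups, mirnas, modules, size_range) {
  if (n_groups == 0L) return(NULL)
  by_module <- split(mirnas, modules)
  sizes <- sample(seq(size_range[1], size_range[2]), n_groups, replace = TRUE)
  feasible <- function(sz) which(lengths(by_module) >= sz)
  sets <- lapply(seq_len(n_groups), function(g) {
    ok <- feasible(sizes[g])
    if (length(ok) == 0L) {
      stop("group size ", sizes[g], " exceeds every module size", call. = FALSE)
    }
    mod <- ok[sample.int(length(ok), 1L)]
    sample(by_module[[mod]], sizes[g])
  })
  gene_sets(setNames(sets, paste0(prefix, seq_len(n_groups))))
}

#' Generate the planted synthetic benchmark
#'
#' Deterministic in the spec's seed. Returns both similarity layers, the
#' association table, family and cluster sets, and the latent module
#' assignments (for diagnostics; the pipeline never sees them).
#'
#' @param spec a [benchmark_spec()].
#' @return list with `mirna_sim`, `disease_sim`, `assoc`, `families`,
#'   `clusters`, `mirna_modules`, `disease_modules`.
#' @export
generate_benchmark <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  run_with_seed(spec$seed, {
    mirnas <- sprintf("mir-%03d", seq_len(spec$n_mirna))
    diseases <- sprintf("dis-%03d", seq_len(spec$n_disease))
    mod_m <- assign_modules(spec$n_mirna, spec$n_modules)
    mod_d <- assign_modules(spec$n_disease, spec$n_modules)
    mirna_sim <- block_similarity(mirnas, mod_m, spec$sim_in, spec$sim_out,
                                  spec$sim_noise)
    disease_sim <- block_similarity(diseases, mod_d, spec$sim_in,
                                    spec$sim_out, spec$sim_noise)
    p <- ifelse(outer(mod_m, mod_d, `==`), spec$p_in, spec$p_out)
    hit <- which(matrix(runif(length(p)) < p, nrow(p)), arr.ind = TRUE)
    assoc <- assoc_table(mirnas[hit[, 1L]], diseases[hit[, 2L]])
    families <- sample_groups("fam", spec$n_families, mirnas, mod_m,
                              spec$group_size_range)
    clusters <- sample_groups("clu", spec$n_clusters, mirnas, mod_m,
                              spec$group_size_range)
    list(mirna_sim = mirna_sim, disease_sim = disease_sim, assoc = assoc,
         families = families, clusters = clusters,
         mirna_modules = setNames(mod_m, mirnas),
         disease_modules = setNames(mod_d, diseases))
  })
}

#' Generate a random MeSH-style tree fixture
#'
#' Builds a random rooted tree of dot-delimited tree numbers with the
#' requested depth and branching factor, and attaches diseases to random
#' nodes (one tree number each). Supports end-to-end testing of the
#' information-content and semantic-value machinery.
#'
#' @param n_diseases number of diseases to attach.
#' @param depth tree depth (`>= 1`; depth 1 is the root alone).
#' @param branching children per internal node.
#' @param seed integer seed.
#' @return list with `dag` (a [mesh_dag()]) and `diseases` (the universe).
#' @export
generate_mesh_fixture <- function(n_diseases = 20, depth = 4, branching = 3,
                                  seed = 1) {
  stopifnot(depth >= 1, branching >= 1, n_diseases >= 1)
  run_with_seed(seed, {
    codes <- "C01"
    level <- codes
    if (depth > 1) for (k in seq_len(depth - 1L)) {
      level <- unlist(lapply(level, function(p) {
        paste0(p, ".", sprintf("%03d", seq_len(branching)))
      }))
      codes <- c(codes, level)
    }
    attach_to <- sample(codes, n_diseases, replace = TRUE)
    dag <- mesh_dag(setNames(as.list(attach_to),
                             sprintf("dis-%03d", seq_len(n_diseases))))
    list(dag = dag, diseases = names(dag$terms))
  })
}

#' Write a full benchmark to disk in the package's file dialects
#'
#' Serializes every artifact of [generate_benchmark()] into a directory:
#' `associations.tsv`, `mirna_sim.tsv`, `disease_sim.tsv`, `families.gmt`,
#' `clusters.gmt`.
#'
#' @param bench result of [generate_benchmark()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_associations(bench$assoc, file.path(dir, "associations.tsv"))
  write_similarity_matrix(bench$mirna_sim, file.path(dir, "mirna_sim.tsv"))
  write_similarity_matrix(bench$disease_sim, file.path(dir, "disease_sim.tsv"))
  if (!is.null(bench$families)) write_gmt(bench$families, file.path(dir, "families.gmt"))
  if (!is.null(bench$clusters)) write_gmt(bench$clusters, file.path(dir, "clusters.gmt"))
  invisible(dir)
}
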