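#' @useDynLib mirflow, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats phyper rbinom rnorm runif setNames
#' @importFrom utils head
"_PACKAGE"

# Shared identifier convention: identifiers are compared after trimming
# surrounding whitespace and case-folding to lower case, because public
# microRNA/disease catalogues mix casings ("hsa-miR-21" vs "hsa-mir-21")
# and silent join failures across files are worse than aggressive folding.

#' Normalize microRNA/disease identifiers
#'
#' Trims surrounding whitespace and folds to lower case. All readers and
#' constructors in the package pass identifiers through this function, so
#' that joins across files never fail on casing.
#'
#' @param x character vector of identifiers.
#' @return normalized character vector.
#' @export
normalize_id <- function(x) {
  tolower(trimws(as.character(x)))
}

read_tsv_lines <- function(path) {
  if (!file.exists(path)) {
    stop("file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Known microRNA-disease association table
#'
#' Constructs the gold-standard association table: one row per experimentally
#' supported (microRNA, disease) pair. Duplicate pairs (after identifier
#' normalization) are dropped, keeping first-seen order.
#'
#' @param mirna,disease character vectors of equal length.
#' @return an `assoc_table`: a data frame with columns `mirna` and `disease`.
#' @export
assoc_table <- function(mirna, disease) {
  if (length(mirna) != length(disease)) {
    stop("mirna and disease must have equal length", call. = FALSE)
  }
  mirna <- normalize_id(mirna)
  disease <- normalize_id(disease)
  if (any(!nzchar(mirna)) || any(!nzchar(disease))) {
    stop("empty identifier in association table", call. = FALSE)
  }
  key <- paste(mirna, disease, sep = "\r")
  keep <- !duplicated(key)
  out <- data.frame(mirna = mirna[keep], disease = disease[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Read a two-column microRNA-disease association TSV
#'
#' Each non-comment line must carry at least two tab-separated fields:
#' the microRNA identifier and the disease identifier. Duplicated pairs are
#' dropped with a message; lines with fewer than two fields are an error.
#'
#' @param path path to a UTF-8, tab-delimited file; `#` starts a comment line.
#' @return an [assoc_table()].
#' @export
read_associations <- function(path) {
  parsed <- read_tsv_lines(path)
  if (length(parsed$lines) == 0L) {
    warning("no association records in ", path, call. = FALSE)
    return(assoc_table(character(), character()))
  }
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop("malformed association line ", parsed$lineno[bad], " in ", path,
         ": expected 2 tab-separated fields", call. = FALSE)
  }
  mirna <- vapply(fields, `[[`, "", 1L)
  disease <- vapply(fields, `[[`, "", 2L)
  out <- assoc_table(mirna, disease)
  n_dropped <- length(mirna) - nrow(out)
  message("read ", nrow(out), " associations from ", path,
          if (n_dropped > 0L) paste0(" (", n_dropped, " duplicates dropped)") else "")
  out
}

#' Named collections of identifier sets
#'
#' Container used for microRNA families, genomic clusters and
#' microRNA-to-target-gene sets. Members are normalized and deduplicated;
#' set names must be unique.
#'
#' @param sets named list of character vectors.
#' @return a `gene_sets` object (named list of character vectors).
#' @export
gene_sets <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every set needs a non-empty name", call. = FALSE)
  }
  names(sets) <- normalize_id(names(sets))
  if (anyDuplicated(names(sets))) {
    stop("duplicate set name: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(sets, function(m) unique(normalize_id(m)))
  class(sets) <- "gene_sets"
  sets
}

#' Read a GMT set file
#'
#' GMT dialect: `name<TAB>description<TAB>member1<TAB>member2...` per line.
#' Empty member lists are permitted (with a warning); duplicate set names are
#' an error.
#'
#' @param path path to the GMT file.
#' @return a [gene_sets()] collection.
#' @export
read_gmt <- function(path) {
  parsed <- read_tsv_lines(path)
  if (length(parsed$lines) == 0L) {
    warning("no sets in ", path, call. = FALSE)
    return(gene_sets(setNames(list(), character())))
  }
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[[`, "", 1L)
  members <- lapply(fields, function(f) if (length(f) > 2L) f[-(1:2)] else character())
  if (any(lengths(members) == 0L)) {
    warning("set(s) with no members in ", path, ": ",
            paste(nm[lengths(members) == 0L], collapse = ", "), call. = FALSE)
  }
  gene_sets(setNames(members, nm))
}

#' MeSH-style disease tree-number map
#'
#' Stores, per disease term, the set of dot-delimited tree numbers (such as
#' `C04.588.180`) attached to it. Ancestry is purely prefix-derived: the
#' parent of a tree number is the code with its last dot-segment removed, so
#' the induced ancestor relation is acyclic by construction.
#'
#' @param terms named list mapping disease id to a character vector of tree
#'   numbers.
#' @return a `mesh_dag` object.
#' @export
mesh_dag <- function(terms) {
  if (is.null(names(terms))) stop("terms must be a named list", call. = FALSE)
  names(terms) <- normalize_id(names(terms))
  terms <- lapply(terms, function(tn) {
    tn <- trimws(toupper(as.character(tn)))
    segs <- strsplit(tn, ".", fixed = TRUE)
    if (any(vapply(segs, function(s) any(!nzchar(s)) || length(s) == 0L, TRUE))) {
      stop("tree number with empty segment: ",
           paste(tn[vapply(segs, function(s) any(!nzchar(s)) || length(s) == 0L, TRUE)],
                 collapse = ", "), call. = FALSE)
    }
    unique(tn)
  })
  # merge multiply-listed diseases
  if (anyDuplicated(names(terms))) {
    terms <- tapply(terms, names(terms), function(x) unique(unlist(x)), simplify = FALSE)
    terms <- terms[order(names(terms))]
  }
  structure(list(terms = terms), class = "mesh_dag")
}

#' Read a disease-to-tree-number TSV
#'
#' Lines of `disease_id<TAB>tree_number`; a disease may appear on multiple
#' lines, in which case its tree numbers are unioned.
#'
#' @param path path to the file.
#' @return a [mesh_dag()].
#' @export
read_mesh_tree <- function(path) {
  parsed <- read_tsv_lines(path)
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L]
    stop("malformed tree-number line ", parsed$lineno[bad], " in ", path,
         call. = FALSE)
  }
  dis <- normalize_id(vapply(fields, `[[`, "", 1L))
  tn <- vapply(fields, `[[`, "", 2L)
  mesh_dag(split(tn, dis))
}

tree_prefixes <- function(tn) {
  # all proper prefixes of a dot-delimited tree number, shortest first
  segs <- strsplit(tn, ".", fixed = TRUE)[[1L]]
  if (length(segs) <= 1L) return(character())
  vapply(seq_len(length(segs) - 1L),
         function(k) paste(segs[seq_len(k)], collapse = "."), "")
}

#' Ancestor terms of a disease in the tree-number DAG
#'
#' `mesh_ancestors(dag, d)` returns the set of disease terms whose tree
#' numbers are prefixes of any of `d`'s tree numbers, including `d` itself.
#' Prefix codes that are not attached to any disease in the map are skipped.
#'
#' @param dag a [mesh_dag()].
#' @param disease a disease identifier present in `dag`.
#' @return character vector of ancestor disease ids (always contains `disease`).
#' @export
mesh_ancestors <- function(dag, disease) {
  stopifnot(inherits(dag, "mesh_dag"))
  disease <- normalize_id(disease)
  if (!disease %in% names(dag$terms)) {
    stop("disease not in MeSH map: ", disease, call. = FALSE)
  }
  idx <- tree_number_index(dag)
  codes <- unique(unlist(lapply(dag$terms[[disease]], tree_prefixes)))
  anc <- unique(unlist(idx[intersect(codes, names(idx))]))
  sort(unique(c(disease, anc)))
}

# tree number -> disease ids carrying it (memoised on the dag object would
# need an environment; recomputation is cheap at the scales involved)
tree_number_index <- function(dag) {
  tn <- unlist(dag$terms, use.names = FALSE)
  dis <- rep(names(dag$terms), lengths(dag$terms))
  split(dis, tn)
}

#' Symmetric similarity matrix with labels
#'
#' Validates the invariants shared by both network layers: square, labelled,
#' symmetric, all values in `[0, 1]`, unit diagonal.
#'
#' @param values square numeric matrix with identical row/column names.
#' @param symmetrize if `TRUE`, an asymmetric input is replaced by the average
#'   of itself and its transpose, with a warning.
#' @return a `sim_matrix` (a numeric matrix with class attribute).
#' @export
sim_matrix <- function(values, symmetrize = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("similarity matrix needs row and column labels", call. = FALSE)
  }
  rownames(values) <- normalize_id(rownames(values))
  colnames(values) <- normalize_id(colnames(values))
  if (!identical(rownames(values), colnames(values))) {
    stop("row and column labels differ", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate labels", call. = FALSE)
  if (any(values < -1e-9) || any(values > 1 + 1e-9)) {
    stop("similarity values outside [0, 1]", call. = FALSE)
  }
  values[values < 0] <- 0
  values[values > 1] <- 1
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-12, check.attributes = FALSE))) {
    if (!symmetrize) stop("similarity matrix is not symmetric", call. = FALSE)
    warning("asymmetric similarity matrix symmetrized by averaging", call. = FALSE)
    values <- (values + t(values)) / 2
  }
  diag(values) <- 1
  class(values) <- c("sim_matrix", class(matrix()))
  values
}

#' Read / write a labelled square similarity TSV
#'
#' The on-disk format is a tab-delimited table with a header row of labels and
#' a leading label column; values are written with 12 significant digits so a
#' write-then-read round trip reproduces the matrix. Asymmetric input is
#' symmetrized by averaging with a warning; values outside `[0, 1]` (beyond
#' 1e-9) are an error.
#'
#' @param path path to the TSV.
#' @return a [sim_matrix()].
#' @export
read_similarity_matrix <- function(path) {
  parsed <- read_tsv_lines(path)
  if (length(parsed$lines) < 2L) stop("similarity file too short: ", path, call. = FALSE)
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  labels <- fields[[1L]][-1L]
  body <- fields[-1L]
  if (any(lengths(body) != length(labels) + 1L)) {
    stop("non-square similarity body in ", path, call. = FALSE)
  }
  rlab <- vapply(body, `[[`, "", 1L)
  vals <- t(vapply(body, function(f) as.numeric(f[-1L]), numeric(length(labels))))
  if (length(labels) == 1L) vals <- matrix(vals, 1L, 1L)
  if (anyNA(vals)) stop("non-numeric similarity value in ", path, call. = FALSE)
  dimnames(vals) <- list(rlab, labels)
  sim_matrix(vals, symmetrize = TRUE)
}

#' @rdname read_similarity_matrix
#' @param m a [sim_matrix()] to serialize.
#' @export
write_similarity_matrix <- function(m, path) {
  stopifnot(inherits(m, "sim_matrix"))
  labs <- rownames(m)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("id", labs), collapse = "\t"), con)
  body <- apply(format(m, digits = 12, scientific = FALSE, trim = TRUE), 1L,
                paste, collapse = "\t")
  writeLines(paste(labs, body, sep = "\t"), con)
  invisible(path)
}

#' Ranked candidate list
#'
#' Candidates sorted by score; ties are broken lexicographically by identifier
#' so output files are reproducible. `rank_ratio` is `rank / n`.
#'
#' @param candidate_id character vector of candidate identifiers.
#' @param score numeric scores (larger = stronger association unless
#'   `decreasing = FALSE`).
#' @param decreasing sort direction; `TRUE` for flow scores, `FALSE` for
#'   combined rank-ratio scores where smaller is better.
#' @return a `ranked_list`: data frame with columns `rank`, `candidate_id`,
#'   `score`, `rank_ratio`.
#' @export
ranked_list <- function(candidate_id, score, decreasing = TRUE) {
  candidate_id <- normalize_id(candidate_id)
  if (length(candidate_id) != length(score)) stop("length mismatch", call. = FALSE)
  if (anyDuplicated(candidate_id)) stop("duplicate candidate ids", call. = FALSE)
  ord <- order(if (decreasing) -score else score, candidate_id, method = "radix")
  n <- length(score)
  out <- data.frame(rank = seq_len(n),
                    candidate_id = candidate_id[ord],
                    score = score[ord],
                    rank_ratio = seq_len(n) / n,
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Write a ranked list TSV
#'
#' Columns `rank`, `candidate_id`, `score`, `rank_ratio`, sorted by rank.
#'
#' @param ranked a nonempty [ranked_list()].
#' @param path output path.
#' @export
write_ranked_list <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (nrow(ranked) == 0L) stop("refusing to write an empty ranked list", call. = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("rank\tcandidate_id\tscore\trank_ratio", con)
  writeLines(paste(ranked$rank, ranked$candidate_id,
                   format(ranked$score, digits = 12, scientific = FALSE, trim = TRUE),
                   format(ranked$rank_ratio, digits = 12, scientific = FALSE, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a ranked list TSV written by [write_ranked_list()]
#'
#' @param path path to the TSV.
#' @return a `ranked_list`.
#' @export
read_ranked_list <- function(path) {
  parsed <- read_tsv_lines(path)
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  if (identical(fields[[1L]][1L], "rank")) fields <- fields[-1L]
  if (any(lengths(fields) < 4L)) stop("malformed ranked list in ", path, call. = FALSE)
  out <- data.frame(rank = as.integer(vapply(fields, `[[`, "", 1L)),
                    candidate_id = vapply(fields, `[[`, "", 2L),
                    score = as.numeric(vapply(fields, `[[`, "", 3L)),
                    rank_ratio = as.numeric(vapply(fields, `[[`, "", 4L)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Write an association table / gene-set collection (round-trip partners)
#'
#' @param assoc an [assoc_table()].
#' @param path output path.
#' @export
write_associations <- function(assoc, path) {
  stopifnot(inherits(assoc, "assoc_table"))
  writeLines(paste(assoc$mirna, assoc$disease, sep = "\t"),
             con <- file(path, "w", encoding = "UTF-8"))
  close(con)
  invisible(path)
}

#' @rdname write_associations
#' @param sets a [gene_sets()] collection.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_sets"))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, con <- file(path, "w", encoding = "UTF-8"))
  close(con)
  invisible(path)
}
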