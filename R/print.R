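#' @export
print.hetero_network <- function(x, ...) {
  cat("microRNAome-phenome network:",
      sum(x$nodes$kind == "mirna"), "microRNAs,",
      sum(x$nodes$kind == "disease"), "diseases\n")
  tab <- table(x$edges$layer)
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], " edges\n", sep = "")
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cross-validation (", x$mode, " prioritization): ",
      nrow(x$folds), " folds\n", sep = "")
  cat("  ROC AUC: ", sprintf("%.4f", x$auc),
      "   PR AUC: ", sprintf("%.4f", x$pr$auc), "\n", sep = "")
  invisible(x)
}

#' @export
print.flow_result <- function(x, ...) {
  cat("maximum information flow: value", x$value,
      "over", nrow(x$arcs), "arcs\n")
  invisible(x)
}
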