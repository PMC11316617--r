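# Readers/writers for the package's plain-text formats.

#' Read an expression matrix from TSV
#'
#' @param path TSV with a header; first column holds condition (or gene) ids.
#' @param genes_as `"columns"` (default, rows = conditions) or `"rows"`
#'   (matrix is transposed after reading so the in-memory orientation is
#'   always conditions x genes).
#' @return Numeric matrix, conditions x genes.
#' @export
read_expression_matrix <- function(path, genes_as = c("columns", "rows")) {
  genes_as <- match.arg(genes_as)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   row.names = 1)
  X <- as.matrix(df)
  if (genes_as == "rows") X <- t(X)
  as_expression_matrix(X)
}

#' Write an expression matrix to TSV (genes as columns)
#'
#' @param X conditions-by-genes matrix.
#' @param path output file; first column is the condition id.
#' @export
write_expression_matrix <- function(X, path) {
  X <- as_expression_matrix(X)
  df <- data.frame(condition = rownames(X), X, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a ground-truth DAG as an edge-list TSV (source, target, weight)
#'
#' @param gt a `latentdag_ground_truth` with weights.
#' @param path output file.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "latentdag_ground_truth"), !is.null(gt$weights))
  el <- igraph::as_edgelist(gt$dag)
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  w <- gt$weights[cbind(el[, 1], el[, 2])]
  writeLines(c("# source\ttarget\tweight",
               paste(el[, 1], el[, 2], format(w, digits = 17), sep = "\t")),
             path)
}

#' Write a plain-text run manifest (key = value lines)
#'
#' @param values named list of scalars (seeds, parameters, thresholds).
#' @param path output file.
#' @export
write_run_manifest <- function(values, path) {
  stopifnot(!is.null(names(values)), all(nzchar(names(values))))
  writeLines(paste0(names(values), " = ",
                    vapply(values, function(v) paste(format(v), collapse = ","),
                           "")), path)
}
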