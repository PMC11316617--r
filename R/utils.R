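# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

# Canonical unordered-pair keys ("a|b" with a < b lexicographically).
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Undirected edge list of an igraph object as a canonical 2-column character
# matrix, sorted; directions dropped, duplicates collapsed.
canonical_edges <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  m <- unique(cbind(from = a, to = b))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

default_gene_ids <- function(d) sprintf("g%d", seq_len(d))

# Coerce to the conditions x genes matrix convention (rows = samples).
as_expression_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop_param("expression matrix must be a numeric matrix (conditions x genes)")
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop_param("expression matrix contains missing or non-finite values")
  }
  if (is.null(colnames(X))) colnames(X) <- default_gene_ids(ncol(X))
  if (anyDuplicated(colnames(X))) stop_param("gene ids must be unique")
  if (is.null(rownames(X))) rownames(X) <- sprintf("c%d", seq_len(nrow(X)))
  X
}

check_square_weights <- function(W) {
  if (is.data.frame(W)) W <- as.matrix(W)
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    stop_param("W must be a square numeric matrix")
  }
  if (any(!is.finite(W))) stop_param("W must have finite entries")
  if (any(diag(W) != 0)) stop_param("W must have an exactly-zero diagonal")
  if (is.null(colnames(W))) {
    dimnames(W) <- list(default_gene_ids(nrow(W)), default_gene_ids(nrow(W)))
  }
  W
}
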