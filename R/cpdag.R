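# DAG -> CPDAG conversion: keep the skeleton, orient the v-structures, and
# close under the Meek orientation rules. The directed edges of the result
# are exactly the compelled edges (oriented the same way in every
# Markov-equivalent DAG); the rest stay undirected.

#' Convert a DAG to its completed partially directed acyclic graph
#'
#' @param dag directed acyclic `igraph`.
#' @return List of class `latentdag_cpdag` with `gene_ids`, `directed`
#'   (tibble from/to of compelled edges) and `undirected` (tibble a/b of
#'   reversible edges, canonical order).
#' @export
to_cpdag <- function(dag) {
  if (!is_dag(dag)) stop_param("input graph must be acyclic")
  genes <- igraph::V(dag)$name
  d <- length(genes)
  A <- matrix(FALSE, d, d, dimnames = list(genes, genes))
  el <- igraph::as_edgelist(dag)
  if (nrow(el)) A[cbind(match(el[, 1], genes), match(el[, 2], genes))] <- TRUE
  # pattern codes: 0 none, 1 undirected, 2 directed i -> j (P[i,j] = 2)
  adj <- A | t(A)
  P <- matrix(0L, d, d)
  P[adj] <- 1L
  # v-structures i -> k <- j with i, j non-adjacent
  for (k in seq_len(d)) {
    pa <- which(A[, k])
    if (length(pa) < 2) next
    for (pair in utils::combn(pa, 2, simplify = FALSE)) {
      if (!adj[pair[1], pair[2]]) {
        P[pair[1], k] <- 2L; P[k, pair[1]] <- 0L
        P[pair[2], k] <- 2L; P[k, pair[2]] <- 0L
      }
    }
  }
  P <- meek_closure(P, adj)
  dir_idx <- which(P == 2L, arr.ind = TRUE)
  und_idx <- which(P == 1L & upper.tri(P), arr.ind = TRUE)
  structure(list(
    gene_ids = genes,
    directed = tibble::tibble(from = genes[dir_idx[, 1]],
                              to = genes[dir_idx[, 2]]),
    undirected = tibble::tibble(a = genes[und_idx[, 1]],
                                b = genes[und_idx[, 2]])),
    class = "latentdag_cpdag")
}

# Meek rules R1-R3 to a fixed point. P: 0/1/2 as above; adj: skeleton.
meek_closure <- function(P, adj) {
  d <- nrow(P)
  repeat {
    changed <- FALSE
    und <- which(P == 1L & upper.tri(P) | P == 1L & lower.tri(P), arr.ind = TRUE)
    for (r in seq_len(nrow(und))) {
      b <- und[r, 1]; c <- und[r, 2]
      if (P[b, c] != 1L) next
      oriented <- FALSE
      # R1: a -> b, b - c, a and c non-adjacent  =>  b -> c
      for (a in which(P[, b] == 2L)) {
        if (!adj[a, c] && a != c) { oriented <- TRUE; break }
      }
      # R2: b -> a -> c and b - c  =>  b -> c
      if (!oriented) {
        for (a in which(P[b, ] == 2L)) {
          if (P[a, c] == 2L) { oriented <- TRUE; break }
        }
      }
      # R3: b - a1, b - a2, a1 -> c, a2 -> c, a1 and a2 non-adjacent => b -> c
      if (!oriented) {
        cand <- which(P[b, ] == 1L & P[, c] == 2L)
        if (length(cand) >= 2) {
          for (pair in utils::combn(cand, 2, simplify = FALSE)) {
            if (!adj[pair[1], pair[2]]) { oriented <- TRUE; break }
          }
        }
      }
      if (oriented) {
        P[b, c] <- 2L; P[c, b] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  P
}

#' @export
print.latentdag_cpdag <- function(x, ...) {
  cat("<latentdag_cpdag>\n")
  cat("  genes:", length(x$gene_ids), "\n")
  cat("  compelled (directed) edges:", nrow(x$directed), "\n")
  cat("  reversible (undirected) edges:", nrow(x$undirected), "\n")
  invisible(x)
}
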