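# Node-embedding extraction from trained graph-regression models and a
# density-style flat clustering of genes, scored by within-cluster pair
# scores (co-expression or external pair-confidence tables).

#' Extract node embeddings from a trained model
#'
#' Returns the post-activation output of the last graph-convolution layer,
#' one row per gene in universe order; `k` equals the configured width of
#' that layer.
#'
#' @param model a trained `latentdag_gnn` (not the MLP baseline, which has no
#'   convolution layer).
#' @param features genes-by-conditions node features.
#' @param prop_matrix propagation operator (see [propagation_operator()]).
#' @return Numeric genes-by-k matrix with gene rownames.
#' @export
extract_embeddings <- function(model, features, prop_matrix) {
  stopifnot(inherits(model, "latentdag_gnn"))
  if (is.na(model$conv_end)) {
    stop_param("the MLP baseline has no convolution layer to embed from")
  }
  fw <- forward_layers(model$layers, features, prop_matrix)
  E <- fw$cache[[model$conv_end + 1]]
  rownames(E) <- rownames(features)
  E
}

# Neighborhood-preserving low-dimensional embedding: diffusion map of the
# symmetrized kNN graph of the standardized data. Eigenvectors of the
# normalized adjacency are weighted by their eigenvalue raised to a diffusion
# time, so slow (cluster-scale) modes dominate the geometry and fast
# within-cluster modes are damped. Serves as the pluggable backend of the
# clustering pipeline (contract: local neighbor structure preserved).
knn_spectral_embedding <- function(Z, embed_dim, n_neighbors,
                                   diffusion_time = 8) {
  n <- nrow(Z)
  D <- as.matrix(stats::dist(Z))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(n_neighbors + 1)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))                    # symmetrize
  deg <- rowSums(A)
  deg[deg == 0] <- 1
  S <- diag(1 / sqrt(deg)) %*% A %*% diag(1 / sqrt(deg))
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)   # eigenvalues in [-1, 1]
  k <- min(embed_dim, n - 1)
  idx <- seq(2, length.out = k)          # drop the stationary mode
  w <- ev$values[idx]^diffusion_time
  E <- ev$vectors[, idx, drop = FALSE] %*% diag(w, k)
  # fix sign for determinism
  for (j in seq_len(ncol(E))) {
    pivot <- which.max(abs(E[, j]))
    if (E[pivot, j] < 0) E[, j] <- -E[, j]
  }
  E
}

#' Cluster gene embeddings into a fixed number of flat clusters
#'
#' Pipeline: per-dimension standardization, a neighborhood-preserving
#' low-dimensional embedding (spectral embedding of the `n_neighbors`-nearest
#' -neighbor graph), then density-based hierarchical clustering — single
#' linkage on mutual-reachability distances with core distances at the
#' `min_samples`-th neighbor — cut at the shallowest level yielding exactly
#' `n_clusters` clusters of at least `min_cluster_size` genes. Genes in
#' smaller fragments at the cut are labeled unclustered (`-1`).
#'
#' @param E genes-by-k embedding matrix (rownames = gene ids).
#' @param n_clusters requested number of flat clusters.
#' @param embed_dim dimension of the low-dimensional embedding (default 20).
#' @param n_neighbors neighborhood size of the embedding graph (default 7).
#' @param repulsive_fraction accepted for interface compatibility with
#'   repulsion-based embedding backends; unused by the spectral backend.
#' @param min_cluster_size minimum size of a reported cluster (default 10).
#' @param min_samples core-distance neighbor count (default 10).
#' @param seed integer seed.
#' @return List of class `latentdag_clusters` with `assignment` (tibble:
#'   `gene`, `cluster`; `-1` = unclustered, otherwise contiguous ids from 0),
#'   `n_clusters`, `unclustered_fraction`, `params`.
#' @export
cluster_embeddings <- function(E, n_clusters, embed_dim = 20, n_neighbors = 7,
                               repulsive_fraction = 5, min_cluster_size = 10,
                               min_samples = 10, seed = 1L) {
  stopifnot(is.matrix(E), !is.null(rownames(E)))
  n <- nrow(E)
  if (n <= min_cluster_size) stop_param("need more genes than min_cluster_size")
  Z <- scale(E)
  Z[, !is.finite(colSums(Z))] <- 0       # constant dims standardize to 0
  Y <- withr::with_seed(seed, {
    knn_spectral_embedding(Z, embed_dim, n_neighbors)
  })
  D <- as.matrix(stats::dist(Y))
  core <- apply(D, 1, function(r) sort(r)[min(min_samples + 1, n)])
  MR <- pmax(D, outer(core, rep(1, n)), outer(rep(1, n), core))
  diag(MR) <- 0
  hc <- stats::hclust(stats::as.dist(MR), method = "single")
  # shallowest cut giving exactly n_clusters clusters of admissible size
  ks <- seq(if (n_clusters > 1) n_clusters else 1, n - 1)
  cuts <- stats::cutree(hc, k = ks)
  if (length(ks) == 1) cuts <- matrix(cuts, ncol = 1)
  n_big <- apply(cuts, 2, function(m) sum(table(m) >= min_cluster_size))
  hit <- which(n_big == n_clusters)
  if (!length(hit)) {
    stop_param("cannot produce ", n_clusters, " clusters of size >= ",
               min_cluster_size, "; maximum achievable is ", max(n_big))
  }
  memb <- cuts[, hit[1]]
  sizes <- table(memb)
  chosen <- list(big = names(sizes)[sizes >= min_cluster_size])
  lab <- rep(-1L, n)
  ord <- order(-table(memb)[chosen$big])     # 0 = largest cluster
  for (j in seq_along(ord)) {
    lab[memb == as.integer(chosen$big[ord[j]])] <- j - 1L
  }
  assignment <- tibble::tibble(gene = rownames(E), cluster = lab)
  structure(list(assignment = assignment, n_clusters = n_clusters,
                 unclustered_fraction = mean(lab == -1L),
                 params = list(embed_dim = embed_dim,
                               n_neighbors = n_neighbors,
                               repulsive_fraction = repulsive_fraction,
                               min_cluster_size = min_cluster_size,
                               min_samples = min_samples, seed = seed)),
            class = "latentdag_clusters")
}

#' @export
print.latentdag_clusters <- function(x, ...) {
  cat("<latentdag_clusters>\n")
  cat("  genes:", nrow(x$assignment), "\n")
  cat("  clusters:", x$n_clusters, "\n")
  cat("  unclustered fraction:",
      format(x$unclustered_fraction, digits = 3), "\n")
  invisible(x)
}

#' Build a symmetric pair-score lookup table
#'
#' @param pairs data frame with columns `gene_a`, `gene_b`, `score`.
#' @return Object of class `latentdag_pair_scores`.
#' @export
pair_score_table <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(pairs)),
            all(is.finite(pairs$score)))
  keys <- pair_key(as.character(pairs$gene_a), as.character(pairs$gene_b))
  if (anyDuplicated(keys)) {
    agg <- tapply(pairs$score, keys, mean)
    keys <- names(agg)
    scores <- as.numeric(agg)
  } else {
    scores <- pairs$score
  }
  structure(list(scores = setNames(scores, keys)),
            class = "latentdag_pair_scores")
}

#' Score all within-cluster gene pairs
#'
#' For every cluster of size `m`, scores all `choose(m, 2)` gene pairs with
#' the pair table; pairs absent from the table receive `default_score` and
#' are counted. Unclustered genes (label `-1`) are excluded.
#'
#' @param clusters a `latentdag_clusters` (or a tibble with `gene`,
#'   `cluster`).
#' @param scores a [pair_score_table()].
#' @param default_score value for missing pairs (default 0).
#' @return Tibble with `cluster`, `gene_a`, `gene_b`, `score`, `missing`.
#' @export
within_cluster_pair_scores <- function(clusters, scores, default_score = 0) {
  assignment <- if (inherits(clusters, "latentdag_clusters")) {
    clusters$assignment
  } else clusters
  stopifnot(inherits(scores, "latentdag_pair_scores"))
  out <- list()
  for (cl in sort(unique(assignment$cluster[assignment$cluster >= 0]))) {
    genes <- sort(assignment$gene[assignment$cluster == cl])
    if (length(genes) < 2) next
    pairs <- t(combn(genes, 2))
    keys <- pair_key(pairs[, 1], pairs[, 2])
    sc <- scores$scores[keys]
    miss <- is.na(sc)
    sc[miss] <- default_score
    out[[length(out) + 1]] <- tibble::tibble(
      cluster = cl, gene_a = pairs[, 1], gene_b = pairs[, 2],
      score = as.numeric(sc), missing = miss)
  }
  if (!length(out)) {
    return(tibble::tibble(cluster = integer(0), gene_a = character(0),
                          gene_b = character(0), score = numeric(0),
                          missing = logical(0)))
  }
  do.call(rbind, out)
}
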