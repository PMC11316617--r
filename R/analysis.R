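# Structural and statistical analysis of the learned network: communities,
# separator genes and the modules they isolate, conditional-independence
# checks via partial correlation, centrality shells, knockout responses, and
# the length-two overlap test against combined reference networks.

#' Leiden community detection
#'
#' Modularity-optimizing Leiden partition of an undirected network,
#' deterministic per seed. Isolated genes form singleton communities.
#'
#' @param net undirected `igraph`.
#' @param resolution modularity resolution parameter.
#' @param seed integer seed.
#' @return Named integer vector (gene -> community id).
#' @export
leiden_communities <- function(net, resolution = 1, seed = 1L) {
  if (igraph::vcount(net) == 0) return(setNames(integer(0), character(0)))
  cl <- withr::with_seed(seed, {
    igraph::cluster_leiden(net, objective_function = "modularity",
                           resolution = resolution, n_iterations = 10)
  })
  setNames(as.integer(igraph::membership(cl)), igraph::V(net)$name)
}

main_component <- function(net) {
  comp <- igraph::components(net)
  members <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(net, members)
}

#' Find separator genes
#'
#' Iterates over every gene in the network's main connected component and
#' reports a gene when its removal splits that component into at least two
#' components, each containing at least `min_component_size` genes.
#'
#' @param net undirected `igraph`.
#' @param min_component_size minimum size of every resulting component
#'   (default 7).
#' @return Tibble with columns `separator`, `n_components`, `min_size`, and a
#'   list-column `components` of gene-set character vectors.
#' @export
find_separators <- function(net, min_component_size = 7) {
  empty <- tibble::tibble(separator = character(0), n_components = integer(0),
                          min_size = integer(0), components = list())
  if (igraph::vcount(net) == 0) return(empty)
  g <- main_component(net)
  out <- lapply(igraph::V(g)$name, function(v) {
    h <- igraph::delete_vertices(g, v)
    comp <- igraph::components(h)
    if (comp$no >= 2 && all(comp$csize >= min_component_size)) {
      sets <- split(igraph::V(h)$name, comp$membership)
      tibble::tibble(separator = v, n_components = comp$no,
                     min_size = min(comp$csize),
                     components = list(unname(sets)))
    } else NULL
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Condense separator-isolated genes into modules
#'
#' For every separator, the components produced by its removal — other than
#' the largest remaining component — are emitted as modules, tagged with
#' their separating gene. Separators whose removal isolates an identical gene
#' set are merged into one module with a multi-gene conditioning set.
#'
#' @param net undirected `igraph`.
#' @param separators output of [find_separators()] (computed when missing).
#' @param min_component_size forwarded to [find_separators()].
#' @return Tibble with list-columns `genes` (module gene set) and
#'   `separators` (conditioning gene set), plus `size`.
#' @export
extract_modules <- function(net, separators = NULL, min_component_size = 7) {
  if (is.null(separators)) {
    separators <- find_separators(net, min_component_size)
  }
  mods <- list()
  for (i in seq_len(nrow(separators))) {
    comps <- separators$components[[i]]
    sizes <- vapply(comps, length, 0L)
    keep <- setdiff(seq_along(comps), which.max(sizes))
    for (k in keep) {
      key <- paste(sort(comps[[k]]), collapse = "\r")
      if (is.null(mods[[key]])) {
        mods[[key]] <- list(genes = sort(comps[[k]]),
                            separators = separators$separator[i])
      } else {
        mods[[key]]$separators <- union(mods[[key]]$separators,
                                        separators$separator[i])
      }
    }
  }
  if (!length(mods)) {
    return(tibble::tibble(genes = list(), separators = list(),
                          size = integer(0)))
  }
  tibble::tibble(
    genes = unname(lapply(mods, `[[`, "genes")),
    separators = unname(lapply(mods, `[[`, "separators")),
    size = unname(vapply(mods, function(m) length(m$genes), 0L)))
}

#' Partial correlation of two genes given a conditioning set
#'
#' Correlation of the residuals of `x_i` and `x_j` after linear regression on
#' the conditioning genes; with an empty conditioning set this is exactly the
#' Pearson correlation.
#'
#' @param X conditions-by-genes matrix.
#' @param i,j gene ids (or column indices).
#' @param conditioning character vector of gene ids (may be empty).
#' @return Scalar partial correlation.
#' @export
partial_correlation <- function(X, i, j, conditioning = character()) {
  X <- as_expression_matrix(X)
  if (is.numeric(i)) i <- colnames(X)[i]
  if (is.numeric(j)) j <- colnames(X)[j]
  if (is.numeric(conditioning)) conditioning <- colnames(X)[conditioning]
  if (i %in% conditioning || j %in% conditioning) {
    stop_param("i and j must not be in the conditioning set")
  }
  if (length(conditioning) == 0) return(cor(X[, i], X[, j]))
  if (length(conditioning) >= nrow(X) - 2) {
    stop_param("conditioning set too large for the sample size")
  }
  Z <- cbind(1, X[, conditioning, drop = FALSE])
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop_param("singular conditioning design")
  ri <- qr.resid(qz, X[, i])
  rj <- qr.resid(qz, X[, j])
  cor(ri, rj)
}

#' Plain and separator-conditioned correlations for a module
#'
#' For every pair of one in-module gene and one outside gene, computes the
#' plain Pearson correlation and the partial correlation conditional on the
#' separator set (which may contain several genes). An empty separator set
#' makes the two columns identical.
#'
#' @param X conditions-by-genes matrix.
#' @param module character vector of in-module genes.
#' @param separators character vector of conditioning genes.
#' @param outside character vector of genes outside the module.
#' @return Tibble with columns `module_gene`, `outside_gene`, `r_plain`,
#'   `r_partial`; attribute `summary` holds the mean absolute values.
#' @export
module_independence_report <- function(X, module, separators, outside) {
  X <- as_expression_matrix(X)
  outside <- setdiff(outside, c(module, separators))
  grid <- expand.grid(module_gene = module, outside_gene = outside,
                      stringsAsFactors = FALSE)
  r_plain <- numeric(nrow(grid))
  r_partial <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    r_plain[k] <- cor(X[, grid$module_gene[k]], X[, grid$outside_gene[k]])
    r_partial[k] <- if (length(separators)) {
      partial_correlation(X, grid$module_gene[k], grid$outside_gene[k],
                          separators)
    } else r_plain[k]
  }
  out <- tibble::tibble(module_gene = grid$module_gene,
                        outside_gene = grid$outside_gene,
                        r_plain = r_plain, r_partial = r_partial)
  attr(out, "summary") <- c(mean_abs_plain = mean(abs(r_plain)),
                            mean_abs_partial = mean(abs(r_partial)))
  out
}

#' Shortest-path betweenness centrality
#'
#' Exact Brandes betweenness on the undirected skeleton; normalization off by
#' default (a path-of-three middle node scores 1).
#'
#' @param net `igraph` graph (treated as undirected).
#' @param normalized logical.
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  b <- igraph::betweenness(net, directed = FALSE, normalized = normalized)
  setNames(as.numeric(b), igraph::V(net)$name)
}

#' High-betweenness genes
#'
#' The "high" cutoff is the top `top_fraction` of genes with nonzero
#' betweenness (the quantity is not uniquely defined by a fixed threshold, so
#' the fraction is exposed and should be reported with results).
#'
#' @param net `igraph` graph.
#' @param top_fraction fraction of nonzero-betweenness genes kept
#'   (default 0.05).
#' @param normalized forwarded to [betweenness_centrality()].
#' @return Character vector of gene ids.
#' @export
high_betweenness_genes <- function(net, top_fraction = 0.05,
                                   normalized = FALSE) {
  b <- betweenness_centrality(net, normalized)
  nz <- b[b > 0]
  if (!length(nz)) return(character(0))
  k <- max(1L, ceiling(top_fraction * length(nz)))
  names(sort(nz, decreasing = TRUE))[seq_len(k)]
}

#' Neighbor shells around a seed gene set
#'
#' Classifies every gene as `seed`, `shell1` (direct neighbors of seeds not
#' already seeds), `shell2` (neighbors of shell1 not in seeds or shell1), or
#' `other`.
#'
#' @param net `igraph` graph.
#' @param seeds character vector of seed genes.
#' @param depth number of shells (currently 2).
#' @return Named character vector over all genes in the network.
#' @export
neighbor_shells <- function(net, seeds, depth = 2) {
  genes <- igraph::V(net)$name
  stopifnot(all(seeds %in% genes), depth == 2)
  nb <- function(set) {
    if (!length(set)) return(character(0))
    unique(unlist(lapply(set, function(v) {
      igraph::neighbors(net, v, mode = "all")$name
    })))
  }
  shell1 <- setdiff(nb(seeds), seeds)
  shell2 <- setdiff(nb(shell1), c(seeds, shell1))
  lab <- rep("other", length(genes))
  names(lab) <- genes
  lab[shell2] <- "shell2"
  lab[shell1] <- "shell1"
  lab[seeds] <- "seed"
  lab
}

#' Knockout response z-score
#'
#' `Z(A | B) = (Expression(A | B) - Mean(A | Ctrl)) / Std(A | Ctrl)`: gene
#' A's mean expression under gene B knockdown, z-scored against the control
#' condition.
#'
#' @param pd a `latentdag_perturbation` (see
#'   [simulate_perturbation_dataset()]) or any list with `condition_means`,
#'   `control_mean`, `control_sd`.
#' @param target_gene gene A.
#' @param knocked_gene gene B.
#' @return Scalar z-score.
#' @export
knockout_response <- function(pd, target_gene, knocked_gene) {
  sdev <- pd$control_sd[[target_gene]]
  if (!is.finite(sdev) || sdev <= 0) {
    stop_param("control standard deviation of ", target_gene,
               " is zero; z-score undefined")
  }
  (pd$condition_means[knocked_gene, target_gene] -
     pd$control_mean[[target_gene]]) / sdev
}

#' Length-two overlap test against random nulls
#'
#' A gene pair sitting at the two ends of a length-two path in the combined
#' network (base plus replaceable component) counts as an overlap when the
#' backbone network connects the pair directly. The null distribution
#' replaces the replaceable component with an Erdős–Rényi network of the same
#' node and edge count, `n_random` times; significance is a one-sided normal
#' tail probability of the z-score.
#'
#' @param base undirected `igraph` kept fixed across null replicates.
#' @param replaceable undirected `igraph` re-sampled as an ER null.
#' @param backbone undirected `igraph` whose edges are tested for overlap.
#' @param n_random number of null replicates (default 50).
#' @param seed integer seed.
#' @return Tibble with `observed`, `null_mean`, `null_sd`, `z`,
#'   `p_one_sided`.
#' @export
length_two_overlap_test <- function(base, replaceable, backbone,
                                    n_random = 50, seed = 1L) {
  observed <- count_length_two_overlaps(
    combine_networks(list(base, replaceable)), backbone)
  n_nodes <- igraph::vcount(replaceable)
  n_edges <- igraph::ecount(replaceable)
  ids <- igraph::V(replaceable)$name
  nulls <- vapply(seq_len(n_random), function(r) {
    null_net <- random_network(n_nodes, n_edges, "erdos_renyi",
                               seed = seed * 1000 + r, gene_ids = ids)
    count_length_two_overlaps(combine_networks(list(base, null_net)), backbone)
  }, 0)
  null_mean <- mean(nulls)
  null_sd <- sd(nulls)
  if (!is.finite(null_sd) || null_sd == 0) {
    stop_param("degenerate null: all ", n_random,
               " replicates gave overlap count ", null_mean)
  }
  z <- (observed - null_mean) / null_sd
  tibble::tibble(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, z = z,
                 p_one_sided = pnorm(z, lower.tail = FALSE))
}

# Count backbone edges (a, c) with a common neighbor b in `net` (a != c).
count_length_two_overlaps <- function(net, backbone) {
  el <- canonical_edges(backbone)
  if (nrow(el) == 0) return(0L)
  net_genes <- igraph::V(net)$name
  adj <- lapply(setNames(seq_along(net_genes), net_genes), function(i) {
    igraph::neighbors(net, i, mode = "all")$name
  })
  hits <- vapply(seq_len(nrow(el)), function(k) {
    a <- el[k, 1]; c <- el[k, 2]
    if (!(a %in% net_genes) || !(c %in% net_genes)) return(FALSE)
    length(intersect(setdiff(adj[[a]], c), setdiff(adj[[c]], a))) > 0
  }, TRUE)
  sum(hits)
}

#' Rank genes by absolute expression and variance
#'
#' Combines the per-gene rank of mean absolute expression with the rank of
#' expression variance by rank-sum (both descending: rank 1 is the most
#' expressed / most variable); ties are broken by gene id.
#'
#' @param X conditions-by-genes matrix.
#' @return Tibble ordered best-first with columns `gene`, `mean_abs`,
#'   `variance`, `rank_expression`, `rank_variance`, `rank_sum`, `rank`.
#' @export
rank_by_expression_and_variance <- function(X) {
  X <- as_expression_matrix(X)
  mean_abs <- unname(colMeans(abs(X)))
  v <- unname(apply(X, 2, var))
  r_e <- rank(-mean_abs, ties.method = "min")
  r_v <- rank(-v, ties.method = "min")
  out <- tibble::tibble(gene = colnames(X), mean_abs = mean_abs, variance = v,
                        rank_expression = r_e, rank_variance = r_v,
                        rank_sum = r_e + r_v)
  out <- out[order(out$rank_sum, out$gene), ]
  out$rank <- seq_len(nrow(out))
  out
}
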