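# Ground-truth simulators: DAGs, linear-SEM expression, perturbation screens
# and node-level properties, so every pipeline stage is testable against a
# known generating model.
#
# Conventions (used everywhere in the package): expression matrices are
# conditions x genes (rows = samples); edge i -> j means W[i, j] != 0, i.e.
# gene i is a parent of gene j and samples satisfy x = W^T x + e, X ~ XW.

#' Simulate a random ground-truth DAG
#'
#' Erdős–Rényi DAGs draw exactly `m` distinct gene pairs uniformly and orient
#' them along a random topological order. Scale-free DAGs use preferential
#' attachment over a random topological order with the per-node attachment
#' count chosen to approximate `m` (exact edge-count matching is only
#' guaranteed for the Erdős–Rényi model).
#'
#' @param d number of genes (>= 2).
#' @param m number of edges, at most `d * (d - 1) / 2`.
#' @param model `"erdos_renyi"` or `"scale_free"`.
#' @param seed integer seed; results are reproducible per seed.
#' @param gene_ids optional character vector of gene labels.
#' @return Object of class `latentdag_ground_truth` with `dag` (directed
#'   `igraph`), `gene_ids`, and empty weights.
#' @export
simulate_dag <- function(d, m, model = c("erdos_renyi", "scale_free"),
                         seed = 1L, gene_ids = default_gene_ids(d)) {
  model <- match.arg(model)
  if (d < 2) stop_param("d must be >= 2")
  max_m <- d * (d - 1) / 2
  if (m < 0 || m > max_m) {
    stop_param("m = ", m, " exceeds the maximum ", max_m, " for d = ", d)
  }
  stopifnot(length(gene_ids) == d, !anyDuplicated(gene_ids))
  el <- withr::with_seed(seed, {
    ord <- sample.int(d)           # ord[k] = gene at topological position k
    if (model == "erdos_renyi") {
      pick <- sample.int(max_m, m)
      all_pairs <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
      cbind(ord[all_pairs[pick, 1]], ord[all_pairs[pick, 2]])
    } else {
      sf_attachment_edges(d, m, ord)
    }
  })
  g <- igraph::make_empty_graph(n = d, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = gene_ids)
  if (nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  structure(list(dag = g, gene_ids = gene_ids, weights = NULL,
                 noise_sd = NULL, module_labels = NULL),
            class = "latentdag_ground_truth")
}

# Preferential attachment along a topological order: node at position k
# attaches to earlier positions with probability proportional to degree + 1.
# Returns an integer edge matrix in gene indices (parent, child).
sf_attachment_edges <- function(d, m, ord) {
  base <- m %/% (d - 1)
  extra <- m %% (d - 1)
  deg <- rep(0, d)
  edges <- matrix(0L, nrow = 0, ncol = 2)
  for (k in 2:d) {
    want <- base + (k - 1 <= extra)
    want <- min(want, k - 1)
    if (want == 0) next
    prob <- deg[seq_len(k - 1)] + 1
    parents <- sample(seq_len(k - 1), want, prob = prob)
    deg[parents] <- deg[parents] + 1
    deg[k] <- deg[k] + want
    edges <- rbind(edges, cbind(parents, k))
  }
  cbind(ord[edges[, 1]], ord[edges[, 2]])
}

#' Assign SEM coefficients to a ground-truth DAG
#'
#' Each edge weight is drawn uniformly from `[-hi, -lo] U [lo, hi]`;
#' non-edges are exactly zero. A positive lower magnitude is required since
#' arbitrarily weak edges are unidentifiable.
#'
#' @param gt a `latentdag_ground_truth` from [simulate_dag()].
#' @param magnitude_range numeric `c(lo, hi)` with `0 < lo <= hi`.
#' @param seed integer seed.
#' @param noise_sd exogenous noise standard deviation, recycled per gene.
#' @return The ground truth with `weights` (d x d matrix) and `noise_sd` set.
#' @export
assign_weights <- function(gt, magnitude_range = c(0.5, 2), seed = 1L,
                           noise_sd = 1) {
  stopifnot(inherits(gt, "latentdag_ground_truth"))
  lo <- magnitude_range[1]; hi <- magnitude_range[2]
  if (!(lo > 0) || hi < lo) {
    stop_param("need 0 < lo <= hi: weak edges are unidentifiable")
  }
  d <- length(gt$gene_ids)
  el <- igraph::as_edgelist(gt$dag, names = FALSE)
  W <- matrix(0, d, d, dimnames = list(gt$gene_ids, gt$gene_ids))
  if (nrow(el) > 0) {
    w <- withr::with_seed(seed, {
      runif(nrow(el), lo, hi) * sample(c(-1, 1), nrow(el), replace = TRUE)
    })
    W[el] <- w
  }
  gt$weights <- W
  gt$noise_sd <- rep_len(noise_sd, d)
  gt
}

#' Simulate expression samples from a linear SEM
#'
#' Draws `n` i.i.d. samples of `x = W^T x + e` with Gaussian exogenous noise,
#' i.e. `X = E (I - W)^{-1}` row-wise, so that `X (I - W) = E` holds up to
#' round-off.
#'
#' @param gt ground truth with weights (see [assign_weights()]).
#' @param n number of samples (conditions).
#' @param seed integer seed.
#' @return Conditions-by-genes numeric matrix.
#' @export
simulate_expression <- function(gt, n, seed = 1L) {
  stopifnot(inherits(gt, "latentdag_ground_truth"), !is.null(gt$weights))
  if (!is_dag(gt$dag)) stop_param("ground truth must be acyclic")
  d <- length(gt$gene_ids)
  E <- withr::with_seed(seed, {
    matrix(rnorm(n * d), n, d) %*% diag(gt$noise_sd, d)
  })
  X <- E %*% solve(diag(d) - gt$weights)
  dimnames(X) <- list(sprintf("c%d", seq_len(n)), gt$gene_ids)
  X
}

#' Simulate a perturbation (knockdown) screen
#'
#' Generates one set of unperturbed control samples plus, for every gene `g`,
#' a condition in which the exogenous term of `g` has mean `knockdown_shift`
#' (negative: a knockdown lowers expression), propagated downstream through
#' the SEM. Records per-condition mean expression of every gene and the
#' control-referenced z-scores `(mean(A | B) - mean(A | ctrl)) / sd(A | ctrl)`.
#'
#' @param gt ground truth with weights.
#' @param n_control number of control samples.
#' @param knockdown_shift negative mean shift of the knocked gene's noise term.
#' @param seed integer seed.
#' @param n_per_condition samples per knockdown condition (default 200).
#' @return Object of class `latentdag_perturbation` with elements `control`
#'   (matrix), `condition_means` (knocked gene x target gene), `control_mean`,
#'   `control_sd`, and `z` (z-normalized condition means).
#' @export
simulate_perturbation_dataset <- function(gt, n_control = 1000,
                                          knockdown_shift = -5, seed = 1L,
                                          n_per_condition = 200) {
  stopifnot(inherits(gt, "latentdag_ground_truth"), !is.null(gt$weights))
  if (knockdown_shift >= 0) {
    stop_param("knockdown_shift must be negative (a knockdown lowers expression)")
  }
  d <- length(gt$gene_ids)
  inv <- solve(diag(d) - gt$weights)
  out <- withr::with_seed(seed, {
    ctrl <- (matrix(rnorm(n_control * d), n_control, d) %*%
               diag(gt$noise_sd, d)) %*% inv
    means <- matrix(0, d, d)
    for (g in seq_len(d)) {
      E <- matrix(rnorm(n_per_condition * d), n_per_condition, d) %*%
        diag(gt$noise_sd, d)
      E[, g] <- E[, g] + knockdown_shift
      means[g, ] <- colMeans(E %*% inv)
    }
    list(ctrl = ctrl, means = means)
  })
  dimnames(out$ctrl) <- list(sprintf("ctrl%d", seq_len(n_control)), gt$gene_ids)
  dimnames(out$means) <- list(gt$gene_ids, gt$gene_ids)
  mu <- colMeans(out$ctrl)
  sdev <- apply(out$ctrl, 2, sd)
  z <- sweep(sweep(out$means, 2, mu), 2, sdev, "/")
  structure(list(control = out$ctrl, condition_means = out$means,
                 control_mean = mu, control_sd = sdev, z = z,
                 knockdown_shift = knockdown_shift),
            class = "latentdag_perturbation")
}

#' Simulate a per-gene scalar property with tunable graph signal
#'
#' Builds `y_i = mix * mean_feature(neighbors of i) +
#' (1 - mix) * mean_feature(i) + noise`, where `mean_feature` is the gene's
#' mean across conditions. Isolated genes use their own mean for the neighbor
#' term. With `mix` near 1 the target is dominated by network structure,
#' which is what the graph-regression benchmark is designed to detect.
#'
#' @param network undirected `igraph` over the genes.
#' @param features conditions-by-genes feature matrix.
#' @param mix graph-signal fraction in `[0, 1]`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return Named numeric vector (gene -> property).
#' @export
simulate_node_property <- function(network, features, mix = 0.8,
                                   noise_sd = 0.1, seed = 1L) {
  features <- as_expression_matrix(features)
  if (mix < 0 || mix > 1) stop_param("mix must be in [0, 1]")
  genes <- colnames(features)
  stopifnot(all(igraph::V(network)$name %in% genes))
  own <- colMeans(features)
  nb_mean <- own
  for (g in igraph::V(network)$name) {
    nb <- igraph::neighbors(network, g, mode = "all")$name
    if (length(nb) > 0) nb_mean[g] <- mean(own[nb])
  }
  eps <- withr::with_seed(seed, rnorm(length(genes), 0, noise_sd))
  y <- mix * nb_mean + (1 - mix) * own + eps
  names(y) <- genes
  y
}

#' Compare a learned DAG against the ground truth
#'
#' Structural Hamming distance counts edge insertions, deletions, and
#' reversals needed to turn the learned graph into the truth; precision,
#' recall and F1 are computed on exactly-directed edges.
#'
#' @param learned,truth directed `igraph` graphs over the same gene universe.
#' @return Tibble with columns `shd`, `precision`, `recall`, `f1`,
#'   `n_learned`, `n_true`.
#' @export
structure_metrics <- function(learned, truth) {
  gl <- sort(igraph::V(learned)$name)
  gt <- sort(igraph::V(truth)$name)
  if (!identical(gl, gt)) stop_param("gene universes differ")
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0) character(0) else paste(el[, 1], el[, 2], sep = "\r")
  }
  le <- key(learned); te <- key(truth)
  rev_key <- function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)
    vapply(parts, function(p) paste(p[2], p[1], sep = "\r"), "")
  }
  tp <- sum(le %in% te)
  reversed <- sum(le %in% rev_key(te) & !(le %in% te))
  extra <- length(le) - tp - reversed            # insertions to delete
  missing <- length(te) - tp - reversed          # deletions to insert
  shd <- extra + missing + reversed
  precision <- if (length(le)) tp / length(le) else NA_real_
  recall <- if (length(te)) tp / length(te) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  tibble::tibble(shd = shd, precision = precision, recall = recall, f1 = f1,
                 n_learned = length(le), n_true = length(te))
}
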