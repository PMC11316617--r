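#' Configuration for the linear-SEM structure learner
#'
#' Collects the tunable parameters of [fit_linear_sem()]: the L1 weight
#' `lambda1`, the log-determinant parameter `s`, and the internals of the
#' path-following optimization (a decreasing sequence of score weights `mu`
#' so that the acyclicity term progressively dominates, each stage warm-started
#' from the previous solution and minimized with an adaptive-moment first-order
#' method).
#'
#' @param lambda1 non-negative L1-regularization weight (default 0.02).
#' @param s positive log-determinant parameter (default 1).
#' @param path_stages number of path-following stages (default 4).
#' @param mu_init initial score weight, multiplied by `mu_decay` per stage.
#' @param mu_decay multiplicative decay of `mu` in (0, 1).
#' @param inner_max_iter maximum optimizer iterations per stage.
#' @param step_size learning rate of the adaptive-moment optimizer (unused by
#'   the quasi-Newton solver).
#' @param tol relative objective-change convergence tolerance per stage.
#' @param constraint `"logdet"` (default) or `"expm"` acyclicity backend.
#' @param optimizer `"lbfgsb"` (default): bound-constrained quasi-Newton on
#'   the split `W = W+ - W-` formulation, which treats the L1 term exactly and
#'   leaves inactive coefficients at exactly zero; or `"adam"`: first-order
#'   adaptive-moment steps with a proximal soft-threshold for the L1 term and
#'   backtracking step halving at the domain boundary.
#' @param seed integer recorded in the run manifest (both optimizers are
#'   deterministic).
#' @return A list of class `latentdag_config`.
#' @export
learner_config <- function(lambda1 = 0.02, s = 1, path_stages = 4,
                           mu_init = 1, mu_decay = 0.1,
                           inner_max_iter = 5000, step_size = 0.05,
                           tol = 1e-7, constraint = c("logdet", "expm"),
                           optimizer = c("lbfgsb", "adam"), seed = 1L) {
  constraint <- match.arg(constraint)
  optimizer <- match.arg(optimizer)
  stopifnot(lambda1 >= 0, s > 0, path_stages >= 1,
            mu_init > 0, mu_decay > 0, mu_decay < 1,
            inner_max_iter >= 1, step_size > 0, tol > 0)
  structure(list(lambda1 = lambda1, s = s, path_stages = path_stages,
                 mu_init = mu_init, mu_decay = mu_decay,
                 inner_max_iter = inner_max_iter, step_size = step_size,
                 tol = tol, constraint = constraint, optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "latentdag_config")
}

h_value <- function(W, cfg) {
  if (cfg$constraint == "logdet") acyclicity_logdet(W, cfg$s)
  else acyclicity_expm(W)
}

# h and its gradient without the validation overhead of the exported
# functions; returns NULL when W leaves the domain (logdet backend).
h_and_grad <- function(W, cfg) {
  d <- nrow(W)
  if (cfg$constraint == "logdet") {
    M <- diag(cfg$s, d) - W * W
    dt <- determinant(M, logarithm = TRUE)
    if (dt$sign <= 0 || !is.finite(dt$modulus)) return(NULL)
    list(h = as.numeric(-dt$modulus + d * log(cfg$s)),
         grad = 2 * t(solve(M)) * W)
  } else {
    E <- as.matrix(Matrix::expm(Matrix::Matrix(W * W, sparse = FALSE)))
    list(h = sum(diag(E)) - d, grad = 2 * t(E) * W)
  }
}

#' Learn a sparse SEM weight matrix from expression data
#'
#' Minimizes the penalized least-squares score
#' \deqn{\frac{1}{2n}\lVert X - XW\rVert_F^2 + \lambda \lVert W\rVert_1}
#' subject to the continuous acyclicity constraint `h(W) = 0`
#' ([acyclicity_logdet()]). The constrained problem is solved by a
#' path-following scheme: each stage minimizes
#' \eqn{\mu(\mathrm{score} + \lambda\lVert W\rVert_1) + h(W)} with `mu`
#' decreasing geometrically, warm-starting from the previous stage, using an
#' adaptive-moment gradient method with backtracking step halving whenever an
#' iterate leaves the domain of `h`.
#'
#' @param X conditions-by-genes numeric matrix (rows = samples). An edge
#'   `i -> j` in the result means `W[i, j] != 0`, i.e. gene `i` is a parent of
#'   gene `j` in the fitted model `X ~ XW`.
#' @param cfg a [learner_config()].
#' @return Object of class `latentdag_fit` with elements `weights` (the fitted
#'   `d x d` matrix, zero diagonal), `config`, `h_final`, `objective_trace`
#'   (per-stage tibble), and `gene_ids`.
#' @seealso [adaptive_threshold()] to extract the binary DAG, [tidy.latentdag_fit()].
#' @export
fit_linear_sem <- function(X, cfg = learner_config()) {
  X <- as_expression_matrix(X)
  stopifnot(inherits(cfg, "latentdag_config"))
  n <- nrow(X); d <- ncol(X)
  if (n < 2) stop_param("need at least 2 samples")
  genes <- colnames(X)
  if (d == 1) {
    W <- matrix(0, 1, 1, dimnames = list(genes, genes))
    return(new_latentdag_fit(W, cfg, 0, tibble::tibble(
      stage = integer(0), mu = numeric(0), score = numeric(0),
      l1 = numeric(0), h = numeric(0))))
  }
  S <- crossprod(X) / n
  W <- matrix(0, d, d)
  mu <- cfg$mu_init
  trace <- vector("list", cfg$path_stages)
  stage_solver <- if (cfg$optimizer == "lbfgsb") minimize_stage_lbfgsb
                  else minimize_stage
  for (stage in seq_len(cfg$path_stages)) {
    W <- stage_solver(W, S, mu, cfg)
    score <- 0.5 * sum(diag(t(diag(d) - W) %*% S %*% (diag(d) - W)))
    trace[[stage]] <- tibble::tibble(
      stage = stage, mu = mu, score = score,
      l1 = sum(abs(W)), h = h_value(W, cfg))
    mu <- mu * cfg$mu_decay
  }
  dimnames(W) <- list(genes, genes)
  new_latentdag_fit(W, cfg, h_value(W, cfg), do.call(rbind, trace))
}

new_latentdag_fit <- function(W, cfg, h_final, trace) {
  structure(list(weights = W, config = cfg, h_final = h_final,
                 objective_trace = trace, gene_ids = colnames(W)),
            class = "latentdag_fit")
}

# One path stage via bound-constrained quasi-Newton on the split variables
# W = W+ - W-, W+/- >= 0, which turns the L1 term into a linear term and
# keeps inactive coefficients at exactly zero. Points outside the h-domain
# return a large finite barrier with a shrink-back gradient so the line
# search retreats (W = 0 is always feasible).
minimize_stage_lbfgsb <- function(W, S, mu, cfg) {
  d <- nrow(W)
  idx <- which(row(W) != col(W))
  np <- length(idx)
  par <- c(pmax(W[idx], 0), pmax(-W[idx], 0))
  build_W <- function(par) {
    Wk <- matrix(0, d, d)
    Wk[idx] <- par[seq_len(np)] - par[np + seq_len(np)]
    Wk
  }
  fn <- function(par) {
    Wk <- build_W(par)
    hg <- h_and_grad(Wk, cfg)
    if (is.null(hg)) return(1e10 + sum(par^2))
    R <- diag(d) - Wk
    score <- 0.5 * sum(diag(t(R) %*% S %*% R))
    mu * (score + cfg$lambda1 * sum(par)) + hg$h
  }
  gr <- function(par) {
    Wk <- build_W(par)
    hg <- h_and_grad(Wk, cfg)
    if (is.null(hg)) return(2 * par)
    G <- mu * (S %*% Wk - S) + hg$grad
    c(G[idx] + mu * cfg$lambda1, -G[idx] + mu * cfg$lambda1)
  }
  res <- stats::optim(par, fn, gr, method = "L-BFGS-B", lower = 0,
                      control = list(maxit = cfg$inner_max_iter,
                                     factr = max(10, cfg$tol * 1e11)))
  W_new <- build_W(res$par)
  if (is.null(h_and_grad(W_new, cfg))) {
    stop(structure(class = c("latentdag_opt_error", "error", "condition"),
                   list(message = paste0("optimization error: stage solution ",
                                         "outside the h-domain; returning ",
                                         "last valid iterate"),
                        call = NULL, last_iterate = W)))
  }
  W_new
}

# One path stage: proximal Adam on  mu * (score + lambda * |W|_1) + h(W).
# The smooth part (score + h) is followed with adaptive-moment steps; the L1
# term enters through a per-coordinate soft-threshold after each step, so
# inactive coefficients are exactly zero. Steps are halved when an iterate
# leaves the domain of h.
minimize_stage <- function(W, S, mu, cfg) {
  d <- nrow(W)
  lr <- cfg$step_size
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m <- matrix(0, d, d); v <- matrix(0, d, d)
  hg <- h_and_grad(W, cfg)
  if (is.null(hg)) {
    stop("optimization error: starting point outside the constraint domain",
         call. = FALSE)
  }
  obj <- function(W, h) {
    score <- 0.5 * sum(diag(t(diag(d) - W) %*% S %*% (diag(d) - W)))
    mu * (score + cfg$lambda1 * sum(abs(W))) + h
  }
  f_prev <- obj(W, hg$h)
  for (it in seq_len(cfg$inner_max_iter)) {
    grad <- mu * (S %*% W - S) + hg$grad
    diag(grad) <- 0
    m <- b1 * m + (1 - b1) * grad
    v <- b2 * v + (1 - b2) * grad * grad
    mhat <- m / (1 - b1^it)
    denom <- sqrt(v / (1 - b2^it)) + eps
    step <- lr * mhat / denom
    thr <- lr * mu * cfg$lambda1 / denom
    scale <- 1
    repeat {
      W_new <- W - scale * step
      W_new <- sign(W_new) * pmax(abs(W_new) - scale * thr, 0)
      diag(W_new) <- 0
      hg_new <- h_and_grad(W_new, cfg)
      if (!is.null(hg_new)) break
      scale <- scale / 2
      if (scale < 1e-10) {
        stop(structure(class = c("latentdag_opt_error", "error", "condition"),
                       list(message = paste0(
                              "optimization error: no recoverable step back ",
                              "into the h-domain; returning last valid iterate"),
                            call = NULL, last_iterate = W)))
      }
    }
    W <- W_new
    hg <- hg_new
    if (it %% 25 == 0) {
      f <- obj(W, hg$h)
      if (abs(f_prev - f) < cfg$tol * max(1, abs(f_prev))) break
      f_prev <- f
    }
  }
  W
}

#' Binarize a weight matrix at a fixed threshold
#'
#' Edge `i -> j` is kept iff `|W[i, j]| > threshold` (strict). No acyclicity
#' guarantee; see [adaptive_threshold()] for the DAG-preserving rule.
#'
#' @param W square weight matrix or a `latentdag_fit`.
#' @param threshold non-negative cut on absolute weights.
#' @return Directed `igraph` graph over the gene ids.
#' @export
binarize <- function(W, threshold) {
  if (inherits(W, "latentdag_fit")) W <- W$weights
  W <- check_square_weights(W)
  if (threshold < 0) stop_param("threshold must be non-negative")
  A <- abs(W) > threshold
  diag(A) <- FALSE
  igraph::graph_from_adjacency_matrix(A, mode = "directed")
}

#' Extract a binary DAG by adaptive thresholding
#'
#' Scans thresholds `t_start, t_start - t_step, ...` down to `t_floor` and
#' returns the binarized graph at the last threshold whose graph is still
#' acyclic — i.e. the threshold immediately before the first cyclic graph, or
#' `t_floor` when no cycle ever appears.
#'
#' The floor guards against descending into the solver's small-coefficient
#' noise: penalized least-squares solutions carry spurious entries at roughly
#' the L1 soft-threshold scale, and a floor far below that scale would admit
#' them all whenever they happen not to close a directed cycle. The default
#' of 0.05 sits just above that scale for the default `lambda1`; lower it
#' only with a correspondingly stronger penalty.
#'
#' @inheritParams binarize
#' @param t_start starting threshold (must give an acyclic graph).
#' @param t_step positive decrement.
#' @param t_floor lowest threshold considered.
#' @return Directed acyclic `igraph` graph with graph attribute
#'   `threshold_used`.
#' @export
adaptive_threshold <- function(W, t_start = 0.3, t_step = 0.01,
                               t_floor = 0.05) {
  if (inherits(W, "latentdag_fit")) W <- W$weights
  W <- check_square_weights(W)
  if (!(t_start > t_floor) || t_floor < 0 || t_step <= 0) {
    stop_param("need t_start > t_floor >= 0 and t_step > 0")
  }
  thresholds <- seq(t_start, t_floor, by = -t_step)
  if (thresholds[length(thresholds)] > t_floor) {
    thresholds <- c(thresholds, t_floor)
  }
  g_prev <- NULL; t_prev <- NA_real_
  for (t in thresholds) {
    g <- binarize(W, t)
    if (!is_dag(g)) {
      if (is.null(g_prev)) {
        stop_param("graph is already cyclic at t_start = ", t_start,
                   "; increase t_start")
      }
      g_prev <- igraph::set_graph_attr(g_prev, "threshold_used", t_prev)
      return(g_prev)
    }
    g_prev <- g; t_prev <- t
  }
  igraph::set_graph_attr(g_prev, "threshold_used", t_prev)
}

#' Is a directed graph acyclic?
#'
#' @param graph an `igraph` directed graph.
#' @return `TRUE` iff the graph has no directed cycle.
#' @export
is_dag <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  igraph::is_dag(graph)
}

#' @export
print.latentdag_fit <- function(x, ...) {
  cat("<latentdag_fit>\n")
  cat("  genes:", length(x$gene_ids), "\n")
  cat("  lambda1:", x$config$lambda1, " s:", x$config$s,
      " constraint:", x$config$constraint, "\n")
  cat("  final h(W):", format(x$h_final, digits = 4), "\n")
  nz <- sum(x$weights != 0)
  cat("  nonzero weights:", nz, "\n")
  invisible(x)
}

#' Tidy the fitted weight matrix into an edge tibble
#'
#' @param x a `latentdag_fit`.
#' @param threshold drop entries with `|w| <=` this value (default 0).
#' @param ... unused.
#' @return Tibble with columns `from`, `to`, `weight`, sorted by `|weight|`
#'   descending.
#' @exportS3Method generics::tidy
#' @export
tidy.latentdag_fit <- function(x, threshold = 0, ...) {
  W <- x$weights
  idx <- which(abs(W) > threshold, arr.ind = TRUE)
  out <- tibble::tibble(
    from = rownames(W)[idx[, 1]],
    to = colnames(W)[idx[, 2]],
    weight = W[idx])
  out[order(-abs(out$weight), out$from, out$to), ]
}

#' One-row summary of a structure-learning fit
#'
#' @param x a `latentdag_fit`.
#' @param ... unused.
#' @exportS3Method generics::glance
#' @export
glance.latentdag_fit <- function(x, ...) {
  tr <- x$objective_trace
  tibble::tibble(
    n_genes = length(x$gene_ids),
    n_nonzero = sum(x$weights != 0),
    lambda1 = x$config$lambda1,
    s = x$config$s,
    constraint = x$config$constraint,
    h_final = x$h_final,
    final_score = if (nrow(tr)) tr$score[nrow(tr)] else NA_real_)
}
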