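# Graph-convolutional node regression for benchmarking gene networks.
#
# Nodes are genes; node features are the gene's expression values across
# conditions; the target is a per-gene scalar. Models are small feedforward
# stacks (graph-convolution blocks followed by fully connected layers to a
# scalar) trained full-batch with an adaptive-moment optimizer and a masked
# MSE loss, implemented directly with dense matrix algebra.

#' Stratified train/validation/test split of genes
#'
#' Allocates each stratum proportionally to `fractions` (largest-remainder
#' rounding, so every stratum's split sizes are within one gene of exact
#' proportionality), deterministically per seed.
#'
#' @param genes character vector.
#' @param strata vector of stratum labels aligned with `genes` (e.g. a flag
#'   for membership in the learned backbone network).
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer seed.
#' @return List of class `latentdag_split` with `train`, `val`, `test`,
#'   `strata`, `seed`.
#' @export
stratified_split <- function(genes, strata = rep(1, length(genes)),
                             fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  stopifnot(length(strata) == length(genes))
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3) {
    stop_param("fractions must be three values summing to 1")
  }
  parts <- list(train = character(0), val = character(0), test = character(0))
  withr::with_seed(seed, {
    for (s in unique(strata)) {
      g <- sample(genes[strata == s])
      n <- length(g)
      cuts <- round(cumsum(fractions) * n)
      sizes <- diff(c(0, cuts))
      if (any(sizes == 0)) {
        stop_param("stratum '", s, "' too small: a split would be empty")
      }
      idx <- split(g, rep(1:3, times = sizes))
      parts$train <- c(parts$train, idx[["1"]])
      parts$val <- c(parts$val, idx[["2"]])
      parts$test <- c(parts$test, idx[["3"]])
    }
  })
  structure(list(train = parts$train, val = parts$val, test = parts$test,
                 strata = setNames(strata, genes), seed = as.integer(seed)),
            class = "latentdag_split")
}

#' Symmetric-normalized GCN propagation operator
#'
#' Builds \eqn{\hat D^{-1/2} (A + I) \hat D^{-1/2}} over `universe`. Genes
#' missing from the network (or isolated in it) keep a unit self-entry, so
#' their features pass through the convolution unchanged.
#'
#' @param net undirected `igraph`.
#' @param universe character vector of genes (defaults to the network's
#'   vertices).
#' @return Dense symmetric `d x d` matrix with gene dimnames.
#' @export
normalize_adjacency <- function(net, universe = igraph::V(net)$name) {
  A <- adjacency_dense(net, universe)
  diag(A) <- diag(A) + 1
  dinv <- 1 / sqrt(rowSums(A))
  P <- A * (dinv %o% dinv)
  dimnames(P) <- list(universe, universe)
  P
}

adjacency_dense <- function(net, universe) {
  d <- length(universe)
  A <- matrix(0, d, d, dimnames = list(universe, universe))
  el <- canonical_edges(net)
  el <- el[el[, 1] %in% universe & el[, 2] %in% universe, , drop = FALSE]
  if (nrow(el)) {
    A[cbind(el[, 1], el[, 2])] <- 1
    A[cbind(el[, 2], el[, 1])] <- 1
  }
  A
}

# Mean-aggregation operator D^-1 A (no self-loops); zero rows for isolated
# genes (the self map of the SAGE layer covers them).
row_normalized_adjacency <- function(net, universe = igraph::V(net)$name) {
  A <- adjacency_dense(net, universe)
  deg <- rowSums(A)
  deg[deg == 0] <- 1
  A / deg
}

# Attention mask: adjacency plus self-loops (logical).
adjacency_mask <- function(net, universe = igraph::V(net)$name) {
  A <- adjacency_dense(net, universe) > 0
  diag(A) <- TRUE
  A
}

#' Propagation operator matching a convolution variant
#'
#' @param net undirected `igraph`.
#' @param universe gene universe.
#' @param variant convolution variant (see [gnn_model()]).
#' @return Matrix: symmetric-normalized for GCN-style variants, mean
#'   aggregation for `sage_inductive`, a logical neighbor mask for
#'   `attention`, identity for `mlp`.
#' @export
propagation_operator <- function(net, universe = igraph::V(net)$name,
                                 variant = "gcn2") {
  switch(variant,
         mlp = diag(length(universe)),
         attention = adjacency_mask(net, universe),
         sage_inductive = row_normalized_adjacency(net, universe),
         normalize_adjacency(net, universe))
}

#' Construct an (untrained) graph-regression model
#'
#' Architectures share three hidden sizes `hidden = c(h1, h2, h3)` and end in
#' fully connected layers to a scalar:
#' * `gcn2`: two propagation + affine + ReLU blocks (h1, h2), then dense h3.
#' * `gcn3`, `gcn4`: one or two extra convolution blocks (width h2).
#' * `attention`: propagation replaced by learned per-edge attention weights
#'   normalized over each gene's neighbors.
#' * `simplified_k2`: the squared propagation operator applied once with a
#'   single affine map (width h2), omitting the intermediate activation.
#' * `sage_inductive`: mean neighbor aggregation with separate self/neighbor
#'   affine maps; accepts a training-subgraph operator.
#' * `mlp`: dense layers only (graph-free baseline).
#'
#' @param variant one of the above.
#' @param hidden integer vector of three hidden sizes.
#' @param d_in node-feature dimension (number of conditions).
#' @param seed seed for the random initialization.
#' @param activation `"relu"` (default) or `"linear"` (identity; useful for
#'   algebraic checks).
#' @return List of class `latentdag_gnn` with `layers`, `variant`, `hidden`,
#'   `conv_end` (index of the post-activation output of the last convolution
#'   layer, NA for `mlp`).
#' @export
gnn_model <- function(variant = c("gcn2", "gcn3", "gcn4", "attention",
                                  "simplified_k2", "sage_inductive", "mlp"),
                      hidden = c(32, 32, 32), d_in, seed = 1L,
                      activation = c("relu", "linear")) {
  variant <- match.arg(variant)
  activation <- match.arg(activation)
  stopifnot(length(hidden) == 3, all(hidden >= 1))
  h <- as.integer(hidden)
  act <- function() list(type = if (activation == "relu") "relu" else "id")
  affine <- function(fin, fout) list(type = "affine",
                                     W = glorot(fin, fout), b = rep(0, fout))
  sage <- function(fin, fout) list(type = "sage", Wself = glorot(fin, fout),
                                   Wneigh = glorot(fin, fout), b = rep(0, fout))
  attn <- function(fin, fout) list(type = "attn", W = glorot(fin, fout),
                                   a_src = 0.1 * stats::rnorm(fout),
                                   a_dst = 0.1 * stats::rnorm(fout),
                                   b = rep(0, fout))
  prop <- function(power = 1) list(type = "prop", power = power)
  layers <- withr::with_seed(seed, switch(
    variant,
    mlp = list(affine(d_in, h[1]), act(), affine(h[1], h[2]), act(),
               affine(h[2], h[3]), act(), affine(h[3], 1L)),
    gcn2 = list(prop(), affine(d_in, h[1]), act(), prop(), affine(h[1], h[2]),
                act(), affine(h[2], h[3]), act(), affine(h[3], 1L)),
    gcn3 = list(prop(), affine(d_in, h[1]), act(), prop(), affine(h[1], h[2]),
                act(), prop(), affine(h[2], h[2]), act(),
                affine(h[2], h[3]), act(), affine(h[3], 1L)),
    gcn4 = list(prop(), affine(d_in, h[1]), act(), prop(), affine(h[1], h[2]),
                act(), prop(), affine(h[2], h[2]), act(), prop(),
                affine(h[2], h[2]), act(), affine(h[2], h[3]), act(),
                affine(h[3], 1L)),
    simplified_k2 = list(prop(power = 2), affine(d_in, h[2]), act(),
                         affine(h[2], h[3]), act(), affine(h[3], 1L)),
    attention = list(attn(d_in, h[1]), act(), attn(h[1], h[2]), act(),
                     affine(h[2], h[3]), act(), affine(h[3], 1L)),
    sage_inductive = list(sage(d_in, h[1]), act(), sage(h[1], h[2]), act(),
                          affine(h[2], h[3]), act(), affine(h[3], 1L))))
  conv_end <- switch(variant, mlp = NA_integer_, gcn2 = 6L, gcn3 = 9L,
                     gcn4 = 12L, simplified_k2 = 3L, attention = 4L,
                     sage_inductive = 4L)
  structure(list(layers = layers, variant = variant, hidden = h,
                 d_in = d_in, conv_end = conv_end, activation = activation),
            class = "latentdag_gnn")
}

glorot <- function(fin, fout) {
  matrix(stats::rnorm(fin * fout, sd = sqrt(2 / (fin + fout))), fin, fout)
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))

lrelu_slope <- 0.2

attn_forward <- function(la, H, mask) {
  G <- H %*% la$W
  s <- drop(G %*% la$a_src)
  t_ <- drop(G %*% la$a_dst)
  pre <- outer(s, rep(1, length(t_))) + outer(rep(1, length(s)), t_)
  act <- ifelse(pre > 0, pre, lrelu_slope * pre)
  act[!mask] <- -Inf
  mx <- apply(act, 1, max)
  ex <- exp(act - mx)
  alpha <- ex / rowSums(ex)
  list(out = add_bias(alpha %*% G, la$b),
       aux = list(G = G, pre = pre, alpha = alpha))
}

forward_layers <- function(layers, H, P) {
  cache <- vector("list", length(layers) + 1)
  aux <- vector("list", length(layers))
  cache[[1]] <- H
  for (l in seq_along(layers)) {
    la <- layers[[l]]
    H <- switch(la$type,
      prop = { Hp <- H; for (k in seq_len(la$power)) Hp <- P %*% Hp; Hp },
      affine = add_bias(H %*% la$W, la$b),
      relu = pmax(H, 0),
      id = H,
      sage = {
        PH <- P %*% H
        aux[[l]] <- PH
        add_bias(H %*% la$Wself + PH %*% la$Wneigh, la$b)
      },
      attn = {
        r <- attn_forward(la, H, P)
        aux[[l]] <- r$aux
        r$out
      })
    cache[[l + 1]] <- H
  }
  list(out = H, cache = cache, aux = aux)
}

backward_layers <- function(layers, fw, P, dH) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    la <- layers[[l]]
    input <- fw$cache[[l]]
    if (la$type == "prop") {
      for (k in seq_len(la$power)) dH <- crossprod(P, dH)
    } else if (la$type == "affine") {
      grads[[l]] <- list(W = crossprod(input, dH), b = colSums(dH))
      dH <- tcrossprod(dH, la$W)
    } else if (la$type == "relu") {
      dH <- dH * (fw$cache[[l + 1]] > 0)
    } else if (la$type == "sage") {
      PH <- fw$aux[[l]]
      grads[[l]] <- list(Wself = crossprod(input, dH),
                         Wneigh = crossprod(PH, dH), b = colSums(dH))
      dH <- tcrossprod(dH, la$Wself) + crossprod(P, tcrossprod(dH, la$Wneigh))
    } else if (la$type == "attn") {
      a <- fw$aux[[l]]
      db <- colSums(dH)
      dG <- crossprod(a$alpha, dH)
      dalpha <- tcrossprod(dH, a$G)
      dE <- a$alpha * (dalpha - rowSums(dalpha * a$alpha))
      dpre <- dE * ifelse(a$pre > 0, 1, lrelu_slope)
      ds <- rowSums(dpre)
      dt_ <- colSums(dpre)
      dG <- dG + ds %o% la$a_src + dt_ %o% la$a_dst
      grads[[l]] <- list(W = crossprod(input, dG),
                         a_src = drop(crossprod(a$G, ds)),
                         a_dst = drop(crossprod(a$G, dt_)),
                         b = db)
      dH <- tcrossprod(dG, la$W)
    }
  }
  grads
}

#' Forward pass of a graph-regression model
#'
#' @param features genes-by-conditions node-feature matrix (one row per gene
#'   of the universe, in universe order).
#' @param prop_matrix propagation operator from [propagation_operator()].
#' @param model a `latentdag_gnn`.
#' @return Numeric vector of per-gene predictions.
#' @export
gcn_forward <- function(features, prop_matrix, model) {
  stopifnot(inherits(model, "latentdag_gnn"),
            nrow(features) == nrow(prop_matrix))
  drop(forward_layers(model$layers, features, prop_matrix)$out)
}

#' Train a graph-regression model with a masked MSE loss
#'
#' Full-batch adaptive-moment gradient descent on the mean squared error over
#' the training genes only; targets of other genes never enter the gradient.
#'
#' @param model a `latentdag_gnn` (or arguments to build one via `variant`,
#'   `hidden`, `seed`).
#' @param features genes-by-conditions node features.
#' @param y named numeric target vector over all genes.
#' @param prop_matrix propagation operator used during training (for the
#'   inductive SAGE variant this may be a training-subgraph operator).
#' @param train_genes character vector of training genes.
#' @param lr learning rate.
#' @param epochs training epochs.
#' @param val_genes optional validation genes; when given, `val_mse` is
#'   computed from predictions under `prop_eval`.
#' @param prop_eval operator used for prediction (defaults to `prop_matrix`).
#' @return List with `model` (trained), `predictions` (all genes, under
#'   `prop_eval`), `train_mse`, `val_mse` (NA without `val_genes`).
#' @export
train_gnn <- function(model, features, y, prop_matrix, train_genes,
                      lr = 0.01, epochs = 200, val_genes = NULL,
                      prop_eval = prop_matrix) {
  stopifnot(inherits(model, "latentdag_gnn"))
  genes <- rownames(features)
  stopifnot(!is.null(genes), all(train_genes %in% genes))
  layers <- model$layers
  H0 <- features
  # The leading propagation layer has no trainable parameters upstream, so
  # its output is constant across epochs: fold it into the input once.
  lead_prop <- length(layers) > 0 && layers[[1]]$type == "prop"
  if (lead_prop) {
    for (k in seq_len(layers[[1]]$power)) H0 <- prop_matrix %*% H0
    layers <- layers[-1]
  }
  tr_idx <- match(train_genes, genes)
  yt <- y[genes]
  m_state <- list(); v_state <- list()
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  nparam <- function(l) setdiff(names(layers[[l]]), c("type", "power"))
  for (ep in seq_len(epochs)) {
    fw <- forward_layers(layers, H0, prop_matrix)
    pred <- drop(fw$out)
    resid <- pred[tr_idx] - yt[tr_idx]
    loss <- mean(resid^2)
    if (!is.finite(loss)) {
      stop_param("training diverged (non-finite loss) at epoch ", ep,
                 "; variant=", model$variant, " lr=", lr,
                 " hidden=", paste(model$hidden, collapse = ","))
    }
    dPred <- matrix(0, length(yt), 1)
    dPred[tr_idx, 1] <- 2 * resid / length(tr_idx)
    grads <- backward_layers(layers, fw, prop_matrix, dPred)
    for (l in seq_along(layers)) {
      for (p in nparam(l)) {
        g <- grads[[l]][[p]]
        if (is.null(g)) next
        key <- paste0(l, ".", p)
        if (is.null(m_state[[key]])) {
          m_state[[key]] <- g * 0; v_state[[key]] <- g * 0
        }
        m_state[[key]] <- b1 * m_state[[key]] + (1 - b1) * g
        v_state[[key]] <- b2 * v_state[[key]] + (1 - b2) * g * g
        mhat <- m_state[[key]] / (1 - b1^ep)
        vhat <- v_state[[key]] / (1 - b2^ep)
        layers[[l]][[p]] <- layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  model$layers <- if (lead_prop) c(model$layers[1], layers) else layers
  pred <- gcn_forward(features, prop_eval, model)
  names(pred) <- genes
  train_mse <- mean((pred[train_genes] - y[train_genes])^2)
  val_mse <- if (!is.null(val_genes)) {
    mean((pred[val_genes] - y[val_genes])^2)
  } else NA_real_
  list(model = model, predictions = pred, train_mse = train_mse,
       val_mse = val_mse)
}

#' Regression metrics on a gene set
#'
#' @param predictions named numeric vector.
#' @param truth named numeric vector over the same genes.
#' @return Tibble with `mse` and `pearson_r` (`NA` when either vector is
#'   constant, rather than 0).
#' @export
evaluate_predictions <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth))
  if (!is.null(names(truth)) && !is.null(names(predictions))) {
    predictions <- predictions[names(truth)]
  }
  r <- if (length(truth) >= 2 && sd(predictions) > 0 && sd(truth) > 0) {
    cor(predictions, truth)
  } else NA_real_
  tibble::tibble(mse = mean((predictions - truth)^2), pearson_r = r)
}

#' Default hyperparameter search space
#'
#' @param hidden candidate hidden-layer sizes.
#' @param lr learning-rate range (sampled log-uniformly).
#' @param epochs inclusive integer range of training epochs.
#' @return List consumed by [hyperparameter_search()].
#' @export
search_space <- function(hidden = c(16, 32, 64, 128, 256),
                         lr = c(1e-4, 1e-1), epochs = c(50L, 500L)) {
  list(hidden = hidden, lr = lr, epochs = as.integer(epochs))
}

sample_config <- function(space) {
  list(hidden = sample(space$hidden, 3, replace = TRUE),
       lr = exp(runif(1, log(space$lr[1]), log(space$lr[2]))),
       epochs = sample(seq(space$epochs[1], space$epochs[2]), 1))
}

#' Seeded random search over model hyperparameters
#'
#' Samples `budget` configurations (hidden sizes, learning rate, epochs) and
#' returns the one with the smallest validation MSE after training on the
#' training genes. Configurations that diverge score `Inf`.
#'
#' @param space a [search_space()].
#' @param budget number of sampled configurations.
#' @param features,y,prop_matrix,model_seed,variant,activation model inputs
#'   (see [train_gnn()]).
#' @param split a `latentdag_split`.
#' @param seed search seed (config sequence is identical for equal seeds).
#' @param prop_train optional training-time operator (inductive SAGE).
#' @return List with `best` (config), `best_val_mse`, and the `trials`
#'   tibble.
#' @export
hyperparameter_search <- function(space, budget, features, y, prop_matrix,
                                  split, variant = "gcn2", seed = 1L,
                                  model_seed = seed,
                                  prop_train = prop_matrix,
                                  activation = "relu") {
  stopifnot(budget >= 1)
  configs <- withr::with_seed(seed, {
    lapply(seq_len(budget), function(i) sample_config(space))
  })
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    val <- tryCatch({
      model <- gnn_model(variant, cfg$hidden, d_in = ncol(features),
                         seed = model_seed, activation = activation)
      fit <- train_gnn(model, features, y, prop_train, split$train,
                       lr = cfg$lr, epochs = cfg$epochs,
                       val_genes = split$val, prop_eval = prop_matrix)
      fit$val_mse
    }, error = function(e) Inf)
    tibble::tibble(trial = i, h1 = cfg$hidden[1], h2 = cfg$hidden[2],
                   h3 = cfg$hidden[3], lr = cfg$lr, epochs = cfg$epochs,
                   val_mse = val)
  })
  trials <- do.call(rbind, rows)
  best_i <- which.min(trials$val_mse)
  list(best = configs[[best_i]], best_val_mse = trials$val_mse[best_i],
       trials = trials)
}

#' Replicated network-benchmark protocol
#'
#' For every input network (plus a graph-free MLP baseline) the protocol
#' repeats, over `n_splits` stratified splits and `n_inits` random
#' initializations per split: a random hyperparameter search (training on the
#' training genes, selection on validation MSE), a final training on
#' training + validation genes under the selected configuration, and
#' evaluation (MSE, Pearson r) on the held-out test genes.
#'
#' @param networks named list of undirected `igraph` graphs.
#' @param X conditions-by-genes feature matrix.
#' @param y named per-gene target vector.
#' @param strata stratum labels per gene; default flags membership (nonzero
#'   degree) in the first network.
#' @param n_splits,n_inits replication counts (5 x 10 by default).
#' @param budget hyperparameter-search trials per run.
#' @param space a [search_space()].
#' @param variant convolution variant for the network arms.
#' @param include_mlp add the MLP baseline arm (default TRUE).
#' @param scale `"none"` or `"minmax"` feature scaling.
#' @param seed master seed; every split/init/search seed derives from it.
#' @return Tibble of class `latentdag_eval` with one row per run:
#'   `network`, `split`, `init`, `mse`, `pearson_r` and the selected
#'   configuration. See [glance.latentdag_eval()] and [welch_compare()].
#' @export
run_protocol <- function(networks, X, y, strata = NULL, n_splits = 5,
                         n_inits = 10, budget = 20, space = search_space(),
                         variant = "gcn2", include_mlp = TRUE,
                         scale = c("none", "minmax"), seed = 1L) {
  scale <- match.arg(scale)
  X <- as_expression_matrix(X)
  genes <- colnames(X)
  stopifnot(!is.null(names(networks)), all(genes %in% names(y)))
  y <- y[genes]
  features <- t(X)                       # genes x conditions node features
  if (scale == "minmax") features <- scale_minmax(features)
  rownames(features) <- genes
  if (is.null(strata)) {
    deg <- igraph::degree(networks[[1]],
                          v = intersect(igraph::V(networks[[1]])$name, genes))
    strata <- as.integer(genes %in% names(deg)[deg > 0])
    # degenerate stratification (nearly all genes on one side) -> plain split
    if (min(table(strata)) < 10) strata <- rep(1L, length(genes))
  }
  arms <- c(networks, if (include_mlp) list(mlp = NULL))
  rows <- list()
  for (s in seq_len(n_splits)) {
    split <- stratified_split(genes, strata, seed = seed + s)
    for (arm in names(arms)) {
      arm_variant <- if (is.null(arms[[arm]])) "mlp" else variant
      prop_full <- if (arm_variant == "mlp") {
        diag(length(genes))
      } else {
        propagation_operator(arms[[arm]], genes, arm_variant)
      }
      for (init in seq_len(n_inits)) {
        run_seed <- seed * 100000L + s * 1000L + init
        prop_train <- training_operator(arms[[arm]], genes, arm_variant,
                                        split$train, prop_full)
        hs <- hyperparameter_search(space, budget, features, y, prop_full,
                                    split, variant = arm_variant,
                                    seed = run_seed, model_seed = run_seed,
                                    prop_train = prop_train)
        cfg <- hs$best
        prop_final <- training_operator(arms[[arm]], genes, arm_variant,
                                        c(split$train, split$val), prop_full)
        model <- gnn_model(arm_variant, cfg$hidden, d_in = ncol(features),
                           seed = run_seed)
        fit <- train_gnn(model, features, y, prop_final,
                         c(split$train, split$val), lr = cfg$lr,
                         epochs = cfg$epochs, prop_eval = prop_full)
        ev <- evaluate_predictions(fit$predictions[split$test], y[split$test])
        rows[[length(rows) + 1]] <- tibble::tibble(
          network = arm, split = s, init = init, mse = ev$mse,
          pearson_r = ev$pearson_r, h1 = cfg$hidden[1], h2 = cfg$hidden[2],
          h3 = cfg$hidden[3], lr = cfg$lr, epochs = cfg$epochs)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("latentdag_eval", class(out))
  attr(out, "n_splits") <- n_splits
  attr(out, "n_inits") <- n_inits
  attr(out, "seed") <- seed
  out
}

# Inductive-SAGE training operator: the graph restricted to the genes the
# model is trained on; identical to the full operator for other variants.
training_operator <- function(net, genes, variant, train_genes, prop_full) {
  if (variant != "sage_inductive" || is.null(net)) return(prop_full)
  sub <- igraph::induced_subgraph(net,
                                  intersect(igraph::V(net)$name, train_genes))
  row_normalized_adjacency(sub, genes)
}

#' Per-network summary of a benchmark report
#'
#' @param x a `latentdag_eval` tibble from [run_protocol()].
#' @param ... unused.
#' @return Tibble with per-network mean and standard error of MSE and
#'   Pearson r (standard errors are `NA` for single-run reports).
#' @exportS3Method generics::glance
#' @export
glance.latentdag_eval <- function(x, ...) {
  nets <- unique(x$network)
  do.call(rbind, lapply(nets, function(nw) {
    d <- x[x$network == nw, ]
    n <- nrow(d)
    se <- function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    }
    tibble::tibble(network = nw, n_runs = n, mean_mse = mean(d$mse),
                   se_mse = se(d$mse),
                   mean_r = mean(d$pearson_r, na.rm = TRUE),
                   se_r = se(d$pearson_r))
  }))
}

#' Pairwise Welch tests between benchmark arms
#'
#' Two-sided Welch t-tests on the per-run test MSEs of every network against
#' the reference arm.
#'
#' @param report a `latentdag_eval`.
#' @param reference reference network name (default: first arm).
#' @return Tibble with `network`, `mean_mse`, `delta_vs_reference`,
#'   `p_welch`.
#' @export
welch_compare <- function(report, reference = report$network[1]) {
  ref <- report$mse[report$network == reference]
  nets <- setdiff(unique(report$network), reference)
  do.call(rbind, lapply(nets, function(nw) {
    other <- report$mse[report$network == nw]
    p <- if (length(other) > 1 && length(ref) > 1 &&
             (sd(other) > 0 || sd(ref) > 0)) {
      t.test(other, ref, var.equal = FALSE)$p.value
    } else NA_real_
    tibble::tibble(network = nw, mean_mse = mean(other),
                   delta_vs_reference = mean(other) - mean(ref),
                   p_welch = p)
  }))
}

#' Bar plot of a benchmark report (mean test MSE with standard errors)
#'
#' @param object a `latentdag_eval`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.latentdag_eval <- function(object, ...) {
  g <- glance.latentdag_eval(object)
  ggplot2::ggplot(g, ggplot2::aes(x = stats::reorder(network, mean_mse),
                                  y = mean_mse)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_mse - se_mse,
                                        ymax = mean_mse + se_mse),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "mean test MSE") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
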