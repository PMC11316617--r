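# Graph-regression benchmarking: splits, propagation operators, forward
# passes, masked training, hyperparameter search and the replicated protocol.

two_node_graph <- function() {
  gene_network(data.frame(a = "g1", b = "g2"), universe = c("g1", "g2"))
}

# Small neighbor-mean benchmark fixture shared across tests.
gnn_fixture <- function(d = 80, m = 160, n_cond = 20, mix = 0.8, seed = 1) {
  skel <- igraph::as_undirected(simulate_dag(d, m, "erdos_renyi",
                                             seed = seed)$dag)
  gene_means <- withr::with_seed(seed + 1, rnorm(d))
  X <- withr::with_seed(seed + 2, {
    matrix(rep(gene_means, each = n_cond), n_cond, d) +
      matrix(rnorm(n_cond * d), n_cond, d)
  })
  colnames(X) <- igraph::V(skel)$name
  rownames(X) <- sprintf("c%d", seq_len(n_cond))
  y <- simulate_node_property(skel, X, mix = mix, noise_sd = 0.1,
                              seed = seed + 3)
  list(net = skel, X = X, features = t(X), y = y)
}

test_that("stratified splits preserve stratum proportions", {
  genes <- sprintf("g%d", 1:100)
  strata <- rep(c(1, 0), c(40, 60))
  sp <- stratified_split(genes, strata, seed = 1)
  expect_length(sp$test, 10)
  expect_equal(sum(sp$test %in% genes[1:40]), 4)
  expect_length(sp$train, 70)
  expect_length(sp$val, 20)
  expect_setequal(c(sp$train, sp$val, sp$test), genes)
  # deterministic per seed; different across seeds
  expect_identical(stratified_split(genes, strata, seed = 7)$test,
                   stratified_split(genes, strata, seed = 7)$test)
  expect_false(identical(stratified_split(genes, strata, seed = 1)$train,
                         stratified_split(genes, strata, seed = 2)$train))
  expect_error(stratified_split(genes, strata, fractions = c(0.5, 0.2, 0.2)),
               "summing to 1")
  expect_error(stratified_split(genes, c(rep(1, 99), 2)), "too small")
})

test_that("the propagation operator handles edges, isolates and symmetry", {
  empty <- gene_network(data.frame(a = character(0), b = character(0)),
                        universe = c("g1", "g2", "g3"))
  expect_equal(normalize_adjacency(empty), diag(3), ignore_attr = TRUE)
  P <- normalize_adjacency(two_node_graph())
  expect_equal(unname(P), matrix(0.5, 2, 2))
  net <- random_network(20, 40, seed = 3)
  Pn <- normalize_adjacency(net)
  expect_equal(Pn, t(Pn))
  # isolated gene appended to the universe keeps a unit self-entry
  Pu <- normalize_adjacency(net, c(igraph::V(net)$name, "iso"))
  expect_equal(Pu["iso", "iso"], 1)
  expect_true(all(Pu["iso", colnames(Pu) != "iso"] == 0))
})

test_that("forward passes propagate features as the operator dictates", {
  P <- normalize_adjacency(two_node_graph())
  H <- matrix(c(1, 3), 2, 1, dimnames = list(c("g1", "g2"), NULL))
  expect_equal(unname(P %*% H), matrix(c(2, 2), 2, 1))
  # empty graph: predictions for a gene ignore every other gene's features
  F0 <- matrix(rnorm(10), 5, 2, dimnames = list(sprintf("g%d", 1:5), NULL))
  model <- gnn_model("gcn2", c(4, 4, 4), d_in = 2, seed = 1)
  I5 <- diag(5)
  p1 <- gcn_forward(F0, I5, model)
  F2 <- F0; F2[2, ] <- F2[2, ] + 10
  p2 <- gcn_forward(F2, I5, model)
  expect_equal(p1[-2], p2[-2])
  expect_false(isTRUE(all.equal(p1[2], p2[2])))
})

test_that("simplified K=2 convolution equals a linear two-layer GCN stack", {
  net <- random_network(12, 20, seed = 5)
  P <- normalize_adjacency(net)
  F0 <- matrix(rnorm(12 * 3), 12, 3,
               dimnames = list(igraph::V(net)$name, NULL))
  sgc <- gnn_model("simplified_k2", c(3, 3, 3), d_in = 3, seed = 1,
                   activation = "linear")
  gcn <- gnn_model("gcn2", c(3, 3, 3), d_in = 3, seed = 1,
                   activation = "linear")
  ident <- function(la) { la$W <- diag(3); la$b <- rep(0, 3); la }
  sgc$layers[[2]] <- ident(sgc$layers[[2]])
  gcn$layers[[2]] <- ident(gcn$layers[[2]])
  gcn$layers[[5]] <- ident(gcn$layers[[5]])
  e_sgc <- extract_embeddings(sgc, F0, P)
  e_gcn <- extract_embeddings(gcn, F0, P)
  expect_equal(e_sgc, e_gcn, tolerance = 1e-6)
})

test_that("training minimizes a masked loss over training genes only", {
  fx <- gnn_fixture()
  genes <- rownames(fx$features)
  P <- normalize_adjacency(fx$net)
  split <- stratified_split(genes, seed = 2)
  # constant-zero target is fit to numerical zero
  y0 <- setNames(rep(0, length(genes)), genes)
  m0 <- gnn_model("gcn2", c(8, 8, 8), d_in = ncol(fx$features), seed = 1)
  f0 <- train_gnn(m0, fx$features, y0, P, split$train, lr = 0.02, epochs = 150)
  expect_lt(f0$train_mse, 1e-3)
  # permuting test-gene targets changes nothing about training
  y_perm <- fx$y
  y_perm[split$test] <- withr::with_seed(5, sample(y_perm[split$test]))
  m1 <- gnn_model("gcn2", c(8, 8, 8), d_in = ncol(fx$features), seed = 3)
  fa <- train_gnn(m1, fx$features, fx$y, P, split$train, lr = 0.01,
                  epochs = 60)
  fb <- train_gnn(m1, fx$features, y_perm, P, split$train, lr = 0.01,
                  epochs = 60)
  expect_identical(fa$model$layers, fb$model$layers)
  # deterministic given the same initialized model
  fc <- train_gnn(m1, fx$features, fx$y, P, split$train, lr = 0.01,
                  epochs = 60)
  expect_identical(fa$predictions, fc$predictions)
  # divergence (loss overflow) raises an informative error
  expect_error(train_gnn(m1, fx$features, fx$y * 1e200, P, split$train,
                         lr = 0.01, epochs = 50), "diverged")
})

test_that("every convolution variant trains and beats the empty graph", {
  fx <- gnn_fixture(d = 60, m = 150)
  genes <- rownames(fx$features)
  split <- stratified_split(genes, seed = 4)
  I0 <- diag(length(genes))
  for (variant in c("gcn2", "gcn3", "gcn4", "attention", "simplified_k2",
                    "sage_inductive")) {
    P <- propagation_operator(fx$net, genes, variant)
    model <- gnn_model(variant, c(16, 16, 16), d_in = ncol(fx$features),
                       seed = 7)
    fit <- train_gnn(model, fx$features, fx$y, P, split$train, lr = 0.02,
                     epochs = 120, val_genes = split$val)
    expect_true(is.finite(fit$val_mse))
  }
  # the graph carries signal: the fixed-propagation variants beat the same
  # model on an empty graph under an identical budget (deeper stacks can
  # over-smooth, and the mean aggregator needs larger budgets, so only the
  # shallow symmetric-propagation variants are asserted)
  for (variant in c("gcn2", "simplified_k2")) {
    P <- propagation_operator(fx$net, genes, variant)
    model <- gnn_model(variant, c(16, 16, 16), d_in = ncol(fx$features),
                       seed = 7)
    fit <- train_gnn(model, fx$features, fx$y, P, split$train, lr = 0.02,
                     epochs = 120, val_genes = split$val)
    m_empty <- gnn_model(variant, c(16, 16, 16), d_in = ncol(fx$features),
                         seed = 7)
    P_empty <- propagation_operator(
      gene_network(data.frame(a = character(0), b = character(0)),
                   universe = genes), genes, variant)
    f_empty <- train_gnn(m_empty, fx$features, fx$y, P_empty, split$train,
                         lr = 0.02, epochs = 120, val_genes = split$val)
    expect_lt(fit$val_mse, f_empty$val_mse)
  }
})

test_that("SAGE gradients match finite differences", {
  net <- random_network(6, 8, seed = 9)
  P <- latentdag:::row_normalized_adjacency(net)
  F0 <- withr::with_seed(10, matrix(rnorm(12), 6, 2,
                                    dimnames = list(igraph::V(net)$name, NULL)))
  y <- withr::with_seed(11, rnorm(6))
  layers <- gnn_model("sage_inductive", c(3, 3, 3), d_in = 2, seed = 12)$layers
  fw <- latentdag:::forward_layers(layers, F0, P)
  dOut <- matrix(2 * (drop(fw$out) - y) / 6, 6, 1)
  grads <- latentdag:::backward_layers(layers, fw, P, dOut)
  loss_at <- function(layers) {
    mean((drop(latentdag:::forward_layers(layers, F0, P)$out) - y)^2)
  }
  for (l in c(1, 3)) {
    for (p in c("Wself", "Wneigh", "b")) {
      th <- layers[[l]][[p]]
      for (k in seq_along(th)[seq_len(min(3, length(th)))]) {
        lp <- layers; lp[[l]][[p]][k] <- lp[[l]][[p]][k] + 1e-6
        lm <- layers; lm[[l]][[p]][k] <- lm[[l]][[p]][k] - 1e-6
        fd <- (loss_at(lp) - loss_at(lm)) / 2e-6
        expect_equal(grads[[l]][[p]][k], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("attention gradients match finite differences", {
  net <- random_network(6, 8, seed = 9)
  mask <- latentdag:::adjacency_mask(net)
  F0 <- withr::with_seed(10, matrix(rnorm(12), 6, 2,
                                    dimnames = list(igraph::V(net)$name, NULL)))
  y <- withr::with_seed(11, rnorm(6))
  model <- gnn_model("attention", c(3, 3, 3), d_in = 2, seed = 12)
  layers <- model$layers
  fw <- latentdag:::forward_layers(layers, F0, mask)
  dOut <- matrix(2 * (drop(fw$out) - y) / 6, 6, 1)
  grads <- latentdag:::backward_layers(layers, fw, mask, dOut)
  loss_at <- function(layers) {
    out <- drop(latentdag:::forward_layers(layers, F0, mask)$out)
    mean((out - y)^2)
  }
  for (l in c(1, 3)) {
    for (p in c("W", "a_src", "a_dst", "b")) {
      th <- layers[[l]][[p]]
      for (k in seq_along(th)[seq_len(min(4, length(th)))]) {
        lp <- layers; lp[[l]][[p]][k] <- lp[[l]][[p]][k] + 1e-6
        lm <- layers; lm[[l]][[p]][k] <- lm[[l]][[p]][k] - 1e-6
        fd <- (loss_at(lp) - loss_at(lm)) / 2e-6
        expect_equal(grads[[l]][[p]][k], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("evaluation metrics follow their definitions", {
  truth <- c(a = 1, b = 1)
  ev <- evaluate_predictions(c(a = 0, b = 2), truth)
  expect_equal(ev$mse, 1)
  perf <- evaluate_predictions(c(a = 1, b = 1, c = 3),
                               c(a = 1, b = 1, c = 3))
  expect_equal(perf$mse, 0)
  expect_equal(perf$pearson_r, 1)
  # constant predictions: r is missing, never zero
  evc <- evaluate_predictions(c(a = 2, b = 2), c(a = 1, b = 3))
  expect_true(is.na(evc$pearson_r))
})

test_that("random search is seeded, exhaustive at budget 1, and robust", {
  fx <- gnn_fixture(d = 40, m = 80, n_cond = 10)
  genes <- rownames(fx$features)
  split <- stratified_split(genes, seed = 1)
  P <- normalize_adjacency(fx$net)
  space <- search_space(hidden = c(4, 8), lr = c(0.005, 0.05),
                        epochs = c(30L, 60L))
  h1 <- hyperparameter_search(space, 1, fx$features, fx$y, P, split,
                              seed = 3)
  expect_equal(nrow(h1$trials), 1)
  expect_equal(h1$best_val_mse, h1$trials$val_mse[1])
  h2 <- hyperparameter_search(space, 4, fx$features, fx$y, P, split,
                              seed = 3)
  expect_identical(h2$trials[1, ], h1$trials[1, ])
  h3 <- hyperparameter_search(space, 4, fx$features, fx$y, P, split,
                              seed = 3)
  expect_identical(h2$trials, h3$trials)
  # divergent trials (loss overflow) score Inf instead of failing the search
  hb <- hyperparameter_search(space, 2, fx$features, fx$y * 1e200, P,
                              split, seed = 4)
  expect_true(all(is.infinite(hb$trials$val_mse)))
})

test_that("the replicated protocol reports runs, summaries and Welch tests", {
  fx <- gnn_fixture(d = 50, m = 120, n_cond = 10)
  er <- random_network(50, 120, "erdos_renyi", seed = 20,
                       gene_ids = igraph::V(fx$net)$name)
  space <- search_space(hidden = c(8, 16), lr = c(0.005, 0.05),
                        epochs = c(30L, 80L))
  rep1 <- run_protocol(list(true_graph = fx$net, random_er = er), fx$X, fx$y,
                       n_splits = 1, n_inits = 1, budget = 2, space = space,
                       seed = 1)
  expect_equal(nrow(rep1), 3)          # two networks + MLP baseline
  g1 <- glance(rep1)
  expect_true(all(is.na(g1$se_mse)))   # single run: SE undefined
  # reproducibility: identical master seed, identical report
  rep2 <- run_protocol(list(true_graph = fx$net, random_er = er), fx$X, fx$y,
                       n_splits = 1, n_inits = 1, budget = 2, space = space,
                       seed = 1)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
  wc <- welch_compare(rep1, "true_graph")
  expect_setequal(wc$network, c("random_er", "mlp"))
  expect_true(all(is.na(wc$p_welch)))  # single runs: no Welch test
  pl <- autoplot(rep1)
  expect_s3_class(pl, "ggplot")
})

test_that("identical arms are statistically indistinguishable", {
  fx <- gnn_fixture(d = 40, m = 80, n_cond = 10)
  space <- search_space(hidden = c(8), lr = c(0.01, 0.03),
                        epochs = c(30L, 50L))
  rep_ <- run_protocol(list(net_a = fx$net, net_b = fx$net), fx$X, fx$y,
                       n_splits = 2, n_inits = 3, budget = 2, space = space,
                       include_mlp = FALSE, seed = 2)
  wc <- welch_compare(rep_, "net_a")
  expect_gt(wc$p_welch[wc$network == "net_b"], 0.05)
})
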