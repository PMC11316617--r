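# Shared synthetic fixtures for the benchmarking and clustering tests.

# Neighbor-mean node-regression task: a gene graph, per-gene features with
# heterogeneous means, and a target dominated by network neighborhoods.
make_neighbor_mean_task <- function(d = 300, m = 600, n_cond = 50, mix = 0.8,
                                    noise_sd = 0.1, seed = 1) {
  skel <- igraph::as_undirected(simulate_dag(d, m, "erdos_renyi",
                                             seed = seed)$dag)
  gene_means <- withr::with_seed(seed + 1, rnorm(d))
  X <- withr::with_seed(seed + 2, {
    matrix(rep(gene_means, each = n_cond), n_cond, d) +
      matrix(rnorm(n_cond * d), n_cond, d)
  })
  colnames(X) <- igraph::V(skel)$name
  rownames(X) <- sprintf("c%d", seq_len(n_cond))
  y <- simulate_node_property(skel, X, mix = mix, noise_sd = noise_sd,
                              seed = seed + 3)
  list(net = skel, X = X, y = y)
}

# Five-module SEM: disjoint gene modules, module-specific expression
# signatures, and a graph confined to the modules.
make_module_sem <- function(n_modules = 5, module_size = 20,
                            intra_edges = 50, n_cond = 40,
                            signature = 0.8, seed = 1) {
  d <- n_modules * module_size
  genes <- sprintf("g%d", seq_len(d))
  labels <- rep(seq_len(n_modules), each = module_size)
  edges <- NULL
  for (mdl in seq_len(n_modules)) {
    sub <- simulate_dag(module_size, intra_edges, "erdos_renyi",
                        seed = seed * 100 + mdl,
                        gene_ids = genes[labels == mdl])$dag
    edges <- rbind(edges, igraph::as_edgelist(sub))
  }
  net <- gene_network(edges, universe = genes)
  X <- withr::with_seed(seed + 7, {
    sig <- matrix(rnorm(n_cond * n_modules), n_cond, n_modules)
    signature * sig[, labels] + matrix(rnorm(n_cond * d), n_cond, d)
  })
  colnames(X) <- genes
  rownames(X) <- sprintf("c%d", seq_len(n_cond))
  y <- simulate_node_property(net, X, mix = 0.8, noise_sd = 0.1,
                              seed = seed + 8)
  list(net = net, X = X, y = y, labels = setNames(labels, genes))
}

# Train a two-block GCN on the task and return the trained model + inputs.
train_fixture_gnn <- function(task, hidden = c(16, 16, 16), lr = 0.02,
                              epochs = 150, seed = 1) {
  genes <- colnames(task$X)
  features <- t(task$X)
  P <- normalize_adjacency(task$net, genes)
  split <- stratified_split(genes, seed = seed)
  model <- gnn_model("gcn2", hidden, d_in = ncol(features), seed = seed)
  fit <- train_gnn(model, features, task$y, P, c(split$train, split$val),
                   lr = lr, epochs = epochs, val_genes = split$test)
  list(model = fit$model, features = features, P = P, split = split,
       predictions = fit$predictions)
}
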