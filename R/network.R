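# Construction, loading, filtering and randomization of the comparison
# networks (co-expression, TF-target, PPI, combined, random nulls), plus
# gene-level preprocessing utilities.

#' Construct a gene network from an edge table
#'
#' @param edges two-column (optionally three with `weight`) data frame or
#'   matrix of gene pairs.
#' @param universe character vector of gene ids; defaults to genes seen in
#'   the edges. All vertices in `universe` exist in the graph even when
#'   isolated.
#' @param directed logical.
#' @param provenance free-text tag stored as a graph attribute.
#' @return An `igraph` graph.
#' @export
gene_network <- function(edges, universe = NULL, directed = FALSE,
                         provenance = "unknown") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0 && ncol(edges) < 2) stop_param("edges need >= 2 columns")
  seen <- if (nrow(edges)) unique(c(as.character(edges[[1]]),
                                    as.character(edges[[2]]))) else character(0)
  universe <- universe %||% sort(seen)
  if (!all(seen %in% universe)) stop_param("edge endpoints outside the universe")
  g <- igraph::make_empty_graph(n = length(universe), directed = directed)
  g <- igraph::set_vertex_attr(g, "name", value = universe)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(as.character(edges[[1]]),
                                    as.character(edges[[2]])))
    if (ncol(edges) >= 3) {
      g <- igraph::set_edge_attr(g, "weight", value = as.numeric(edges[[3]]))
    }
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = "first")
  igraph::set_graph_attr(g, "provenance", provenance)
}

#' Co-expression network by thresholded absolute correlation
#'
#' Connects two genes when the absolute Pearson correlation of their
#' expression across conditions exceeds `threshold`. Genes with zero variance
#' are dropped with a warning (their correlation is undefined).
#'
#' @param X conditions-by-genes matrix.
#' @param threshold correlation cut in (0, 1); edges need `|r| > threshold`.
#' @return Undirected `igraph` over the retained genes.
#' @export
coexpression_network <- function(X, threshold = 0.5) {
  X <- as_expression_matrix(X)
  if (nrow(X) < 3) stop_param("need at least 3 samples")
  if (threshold <= 0 || threshold >= 1) stop_param("threshold must be in (0,1)")
  v <- apply(X, 2, var)
  if (all(v == 0)) stop_param("all genes are constant; no correlations defined")
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped")
    X <- X[, v > 0, drop = FALSE]
  }
  C <- cor(X)
  A <- abs(C) > threshold
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::set_graph_attr(g, "provenance", "coexpression")
}

#' Pick a co-expression threshold at the turning point of the edge-count curve
#'
#' Computes the number of co-expression edges at each grid threshold and
#' returns the grid point with the largest discrete second difference of
#' `log(1 + edges)` — the elbow of the threshold-versus-edge-count curve.
#' When the second difference carries no distinct interior maximum (flat or
#' strictly monotone sequence) a no-turning-point flag is returned instead.
#'
#' @param X conditions-by-genes matrix.
#' @param grid ascending thresholds, at least 4 points.
#' @return List with `threshold` (NA when not found), `found` flag, and the
#'   per-grid tibble `curve` (threshold, n_edges, log_edges).
#' @export
threshold_turning_point <- function(X, grid) {
  if (length(grid) < 4) stop_param("grid needs at least 4 thresholds")
  if (is.unsorted(grid, strictly = TRUE)) stop_param("grid must be ascending")
  X <- as_expression_matrix(X)
  C <- abs(cor(X))
  diag(C) <- 0
  n_edges <- vapply(grid, function(t) sum(C > t) / 2, 0)
  y <- log1p(n_edges)
  d2 <- diff(diff(y))                       # at interior grid points 2..k-1
  flat <- max(d2) - min(d2) < 1e-12
  monotone <- all(diff(d2) >= 0) || all(diff(d2) <= 0)
  best <- which.max(d2)
  interior_peak <- !flat && !(monotone && (best == 1 || best == length(d2)))
  curve <- tibble::tibble(threshold = grid, n_edges = n_edges, log_edges = y)
  if (!interior_peak) {
    return(list(threshold = NA_real_, found = FALSE, curve = curve))
  }
  list(threshold = grid[best + 1], found = TRUE, curve = curve)
}

#' Load a network edge list from a TSV file
#'
#' Expects `source<TAB>target[<TAB>weight]` rows; `#`-prefixed comment lines
#' are ignored. Duplicate edges are collapsed and self-loops are dropped
#' (counted in a message).
#'
#' @param path file path.
#' @param directed logical.
#' @param provenance tag recorded on the graph.
#' @return An `igraph` graph.
#' @export
load_edge_list <- function(path, directed = FALSE, provenance = basename(path)) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  line_no <- which(keep)
  bad <- which(vapply(rows, length, 0L) < 2)
  if (length(bad)) {
    stop_param("malformed edge row at line ", line_no[bad[1]], " of ", path,
               " (fewer than 2 tab-separated fields)")
  }
  src <- vapply(rows, `[[`, "", 1)
  dst <- vapply(rows, `[[`, "", 2)
  has_w <- vapply(rows, length, 0L) >= 3
  w <- rep(NA_real_, length(rows))
  w[has_w] <- as.numeric(vapply(rows[has_w], `[[`, "", 3))
  loops <- src == dst
  if (any(loops)) message(sum(loops), " self-loop(s) dropped")
  df <- data.frame(from = src[!loops], to = dst[!loops],
                   stringsAsFactors = FALSE)
  if (all(has_w)) df$weight <- w[!loops]
  gene_network(df, directed = directed, provenance = provenance)
}

#' Load a TF-target table as a directed network
#'
#' @inheritParams load_edge_list
#' @return Directed `igraph` (TF -> target).
#' @export
load_tf_target <- function(path) {
  load_edge_list(path, directed = TRUE, provenance = "tf_target")
}

#' Write a network as a canonical edge-list TSV
#'
#' Rows are sorted (source, then target); undirected edges are written with
#' the lexicographically smaller gene first, so write/read round-trips are
#' byte-identical.
#'
#' @param net an `igraph` graph.
#' @param path output file.
#' @export
write_edge_list <- function(net, path) {
  if (igraph::is_directed(net)) {
    el <- igraph::as_edgelist(net)
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  } else {
    el <- canonical_edges(net)
  }
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
}

#' Restrict a network to a gene universe
#'
#' Keeps only edges with both endpoints in `genes` and resets the vertex set
#' to exactly `genes` (genes absent from the network become isolated nodes).
#'
#' @param net an `igraph` graph.
#' @param genes character vector.
#' @return An `igraph` graph over `genes`.
#' @export
filter_to_universe <- function(net, genes) {
  keep <- intersect(igraph::V(net)$name, genes)
  sub <- igraph::induced_subgraph(net, keep)
  missing <- setdiff(genes, keep)
  if (length(missing)) sub <- igraph::add_vertices(sub, length(missing),
                                                   name = missing)
  igraph::permute(sub, match(igraph::V(sub)$name, genes))
}

#' Random null network of a given size
#'
#' Erdős–Rényi nulls place exactly `n_edges` uniformly chosen distinct pairs;
#' scale-free nulls use preferential attachment with the edge count as close
#' as the mechanism allows. "Same size" as a reference network means same
#' node count and same edge count.
#'
#' @param n_nodes,n_edges size of the null.
#' @param model `"erdos_renyi"` or `"scale_free"`.
#' @param seed integer seed.
#' @param gene_ids optional node labels (default `g1..gn`).
#' @return Undirected `igraph`.
#' @export
random_network <- function(n_nodes, n_edges,
                           model = c("erdos_renyi", "scale_free"), seed = 1L,
                           gene_ids = default_gene_ids(n_nodes)) {
  model <- match.arg(model)
  max_m <- n_nodes * (n_nodes - 1) / 2
  if (n_edges < 0 || n_edges > max_m) stop_param("infeasible edge count")
  g <- withr::with_seed(seed, {
    if (model == "erdos_renyi") {
      igraph::sample_gnm(n_nodes, n_edges, directed = FALSE)
    } else {
      el <- sf_attachment_edges(n_nodes, n_edges, seq_len(n_nodes))
      gg <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
      if (nrow(el)) gg <- igraph::add_edges(gg, t(el))
      gg
    }
  })
  g <- igraph::set_vertex_attr(g, "name", value = gene_ids)
  igraph::set_graph_attr(g, "provenance", paste0("random_", model))
}

#' Undirected union of several networks
#'
#' Directions are dropped, duplicate edges collapsed; the universe is the
#' union of the input universes.
#'
#' @param nets list of `igraph` graphs.
#' @return Undirected `igraph`.
#' @export
combine_networks <- function(nets) {
  if (length(nets) < 1) stop_param("need at least one network")
  universe <- sort(unique(unlist(lapply(nets, function(g) igraph::V(g)$name))))
  edges <- do.call(rbind, lapply(nets, canonical_edges))
  gene_network(unique(edges), universe = universe, directed = FALSE,
               provenance = "combined")
}

#' Undirected edge-set overlap of two networks
#'
#' @param a,b `igraph` graphs.
#' @return Tibble with `shared_edges` and `jaccard`.
#' @export
network_overlap <- function(a, b) {
  ea <- apply(canonical_edges(a), 1, paste, collapse = "\r")
  eb <- apply(canonical_edges(b), 1, paste, collapse = "\r")
  shared <- length(intersect(ea, eb))
  uni <- length(union(ea, eb))
  tibble::tibble(shared_edges = shared,
                 jaccard = if (uni == 0) NA_real_ else shared / uni)
}

#' Select active and variable genes by percentile filters
#'
#' Computes per-gene mean and standard deviation across samples and keeps
#' genes whose mean exceeds the given percentile of all means, combined with
#' genes whose standard deviation exceeds the same percentile of all
#' standard deviations. The two filters are combined by union (default) or
#' intersection.
#'
#' @param X conditions-by-genes matrix.
#' @param percentile percentile in (0, 100); strictly-greater comparison.
#'   `0` keeps every gene.
#' @param mode `"union"` or `"intersection"`.
#' @return Character vector of gene ids (input column order).
#' @export
select_active_variable_genes <- function(X, percentile = 95,
                                         mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  X <- as_expression_matrix(X)
  if (percentile < 0 || percentile >= 100) {
    stop_param("percentile must be in [0, 100)")
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  if (percentile == 0) return(colnames(X))
  pass_mu <- mu > quantile(mu, percentile / 100)
  pass_sd <- sdv > quantile(sdv, percentile / 100)
  keep <- if (mode == "union") pass_mu | pass_sd else pass_mu & pass_sd
  colnames(X)[keep]
}

#' Average a per-base score track over gene regions
#'
#' Intervals are 0-based half-open `[start, end)` (bigWig/BED convention);
#' strand is ignored. Each gene's score is the arithmetic mean of the score
#' over the bases of its region that the track covers; genes with no covered
#' base get `NA`.
#'
#' @param scores data frame with columns `chrom`, `start`, `end`, `value`
#'   (bedGraph-style; non-overlapping intervals assumed).
#' @param gene_intervals data frame with columns `gene`, `chrom`, `start`,
#'   `end`.
#' @return Tibble with `gene`, `score`, `covered_bases`.
#' @export
aggregate_region_score <- function(scores, gene_intervals) {
  scores <- as.data.frame(scores)
  gi <- as.data.frame(gene_intervals)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(scores)),
            all(c("gene", "chrom", "start", "end") %in% names(gi)))
  out <- lapply(seq_len(nrow(gi)), function(i) {
    sc <- scores[scores$chrom == gi$chrom[i], , drop = FALSE]
    ov <- pmin(sc$end, gi$end[i]) - pmax(sc$start, gi$start[i])
    ov[ov < 0] <- 0
    covered <- sum(ov)
    val <- if (covered > 0) sum(ov * sc$value) / covered else NA_real_
    tibble::tibble(gene = gi$gene[i], score = val, covered_bases = covered)
  })
  do.call(rbind, out)
}

#' Min-max scale feature columns to [0, 1]
#'
#' Constant columns are mapped to 0.
#'
#' @param X numeric matrix (samples x features scaled per column).
#' @return Matrix of the same shape.
#' @export
scale_minmax <- function(X) {
  apply(X, 2, function(col) {
    rng <- range(col)
    if (rng[2] == rng[1]) rep(0, length(col)) else (col - rng[1]) / diff(rng)
  })
}
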