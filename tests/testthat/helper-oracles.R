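# Independent oracles used to cross-check package implementations. These are
# deliberately naive (enumeration, brute force) and share no code with the
# package internals they verify.

# Kahn's algorithm: TRUE iff the directed adjacency matrix is acyclic.
oracle_is_dag_kahn <- function(A) {
  A <- A != 0
  diag(A) <- FALSE
  repeat {
    indeg <- colSums(A)
    active <- rowSums(A) + indeg > 0
    src <- which(indeg == 0 & rowSums(A) > 0)
    if (!any(active)) return(TRUE)
    if (length(src) == 0) return(FALSE)
    A[src, ] <- FALSE
  }
}

# DFS back-edge cycle detector on an adjacency list.
oracle_is_dag_dfs <- function(A) {
  n <- nrow(A)
  state <- integer(n)  # 0 unseen, 1 on stack, 2 done
  ok <- TRUE
  visit <- function(v) {
    state[v] <<- 1L
    for (w in which(A[v, ] != 0)) {
      if (state[w] == 1L) ok <<- FALSE
      else if (state[w] == 0L) visit(w)
      if (!ok) return()
    }
    state[v] <<- 2L
  }
  for (v in seq_len(n)) {
    if (state[v] == 0L) visit(v)
    if (!ok) break
  }
  ok
}

igraph_adj <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# Brute-force separator search: delete every vertex of the main component
# and count components.
oracle_separators <- function(g, min_size) {
  comp <- igraph::components(g)
  main <- igraph::induced_subgraph(g, which(comp$membership ==
                                              which.max(comp$csize)))
  found <- character(0)
  for (v in igraph::V(main)$name) {
    h <- igraph::delete_vertices(main, v)
    cc <- igraph::components(h)
    if (cc$no >= 2 && all(cc$csize >= min_size)) found <- c(found, v)
  }
  sort(found)
}

# Betweenness by explicit enumeration of all shortest paths (BFS per pair).
oracle_betweenness <- function(g) {
  genes <- igraph::V(g)$name
  n <- length(genes)
  A <- igraph_adj(g)
  A <- (A + t(A)) > 0
  b <- setNames(numeric(n), genes)
  all_shortest <- function(s, t) {
    # BFS layers from s, then count/backtrack paths to t
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    preds <- vector("list", n)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(A[v, ])) {
        if (dist[w] == Inf) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) preds[[w]] <- c(preds[[w]], v)
      }
    }
    if (!is.finite(dist[t])) return(list())
    paths <- list()
    walk <- function(v, acc) {
      if (v == s) { paths[[length(paths) + 1]] <<- c(s, rev(acc)); return() }
      for (p in preds[[v]]) walk(p, c(acc, v))
    }
    walk(t, integer(0))
    paths
  }
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    paths <- all_shortest(s, t)
    if (!length(paths)) next
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      tab <- table(inner)
      b[as.integer(names(tab))] <- b[as.integer(names(tab))] +
        as.numeric(tab) / length(paths)
    }
  }
  b
}

# All directed graphs on n nodes with no 2-cycles, filtered to DAGs,
# as a list of adjacency matrices.
oracle_all_dags <- function(n) {
  pairs <- t(combn(n, 2))
  states <- expand.grid(rep(list(0:2), nrow(pairs)))  # 0 none, 1 ->, 2 <-
  out <- list()
  for (r in seq_len(nrow(states))) {
    A <- matrix(0, n, n)
    for (k in seq_len(nrow(pairs))) {
      s <- states[r, k]
      if (s == 1) A[pairs[k, 1], pairs[k, 2]] <- 1
      if (s == 2) A[pairs[k, 2], pairs[k, 1]] <- 1
    }
    if (oracle_is_dag_dfs(A)) out[[length(out) + 1]] <- A
  }
  out
}

# Compelled edges of a DAG by enumerating its full Markov equivalence class
# (same skeleton + same v-structures) over all DAGs of that size.
oracle_compelled <- function(A, all_dags = oracle_all_dags(nrow(A))) {
  skel <- function(M) (M + t(M)) > 0
  vstructs <- function(M) {
    out <- character(0)
    for (k in seq_len(ncol(M))) {
      pa <- which(M[, k] != 0)
      if (length(pa) < 2) next
      for (pr in combn(pa, 2, simplify = FALSE)) {
        if (M[pr[1], pr[2]] == 0 && M[pr[2], pr[1]] == 0) {
          out <- c(out, paste(min(pr), max(pr), k, sep = "-"))
        }
      }
    }
    sort(out)
  }
  A <- unname(A)
  sk <- skel(A); vs <- vstructs(A)
  class_members <- Filter(function(M) {
    identical(unname(skel(M)), sk) && identical(vstructs(M), vs)
  }, all_dags)
  stopifnot(length(class_members) >= 1)
  # an edge i->j is compelled iff present with same orientation in every member
  same <- Reduce(`&`, lapply(class_members, function(M) M == 1 & A == 1),
                 matrix(TRUE, nrow(A), ncol(A)))
  which(same, arr.ind = TRUE)
}

# Partial correlation from the precision matrix of [i, j, conditioning].
oracle_pcor_precision <- function(X, i, j, cond) {
  S <- stats::cov(X[, c(i, j, cond), drop = FALSE])
  P <- solve(S)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Erdős–Rényi undirected random graph fixture with named vertices.
random_undirected_fixture <- function(n, p, seed) {
  withr::with_seed(seed, {
    A <- matrix(runif(n * n) < p, n, n)
    A[lower.tri(A, diag = TRUE)] <- FALSE
    A <- A | t(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    igraph::set_vertex_attr(g, "name", value = sprintf("g%d", seq_len(n)))
  })
}

# Adjusted Rand index between two labelings.
oracle_ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Canonical sorted undirected edge list (test-local version).
canonical_edges_test <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(character(0))
  e <- unique(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
  sort(e)
}
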