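# Independent brute-force oracles for small graphs. Everything here works
# on a plain named adjacency matrix and deliberately avoids igraph, so the
# package's centralities, cores, distances and MCODE stages are checked
# against genuinely independent computations.

adj_matrix <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# BFS distances from every node; Inf where unreachable.
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(A[v, ] > 0)) {
          if (is.infinite(dist[u])) {
            dist[u] <- dist[v] + 1
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# All shortest paths between a and b by exhaustive simple-path search.
oracle_shortest_paths <- function(A, a, b) {
  n <- nrow(A)
  best <- list(len = Inf, paths = list())
  recurse <- function(path) {
    v <- path[length(path)]
    if (v == b) {
      if (length(path) < best$len) best <<- list(len = length(path), paths = list(path))
      else if (length(path) == best$len) best$paths[[length(best$paths) + 1L]] <<- path
      return()
    }
    if (length(path) >= best$len) return()
    for (u in which(A[v, ] > 0))
      if (!u %in% path) recurse(c(path, u))
  }
  recurse(a)
  best$paths
}

# Normalized betweenness by enumerating all shortest paths (endpoints
# excluded; normalization (n-1)(n-2)/2).
oracle_betweenness <- function(A) {
  n <- nrow(A)
  btw <- numeric(n)
  if (n >= 3L) {
    for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
      paths <- oracle_shortest_paths(A, a, b)
      if (length(paths) == 0L) next
      for (p in paths) {
        inner <- setdiff(p, c(a, b))
        btw[inner] <- btw[inner] + 1 / length(paths)
      }
    }
    btw <- btw / ((n - 1) * (n - 2) / 2)
  }
  names(btw) <- rownames(A)
  btw
}

# Closeness in the reachable-average convention: reachable count over the
# sum of distances to reachable nodes, 0 for isolated nodes.
oracle_closeness <- function(A) {
  D <- oracle_distances(A)
  vapply(seq_len(nrow(A)), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    if (length(d) == 0L) 0 else length(d) / sum(d)
  }, numeric(1))
}

# Coreness by repeated pruning: max k such that the node survives
# iterative deletion of all nodes with degree < k.
oracle_coreness <- function(A) {
  n <- nrow(A)
  core <- integer(n)
  for (k in seq_len(n)) {
    keep <- rep(TRUE, n)
    repeat {
      deg <- rowSums(A[, keep, drop = FALSE])[keep]
      drop <- names(deg)[deg < k]
      if (length(drop) == 0L) break
      keep[match(drop, rownames(A))] <- FALSE
    }
    core[keep] <- k
    if (!any(keep)) break
  }
  names(core) <- rownames(A)
  core
}

# MCODE vertex-weight oracle on the adjacency matrix: closed-neighbourhood
# submatrix, prune-based coreness, density of the highest core.
oracle_mcode_weights <- function(A, degree_cutoff = 2L) {
  n <- nrow(A)
  w <- stats::setNames(numeric(n), rownames(A))
  for (v in seq_len(n)) {
    if (sum(A[v, ]) < degree_cutoff) next
    hood <- sort(unique(c(v, which(A[v, ] > 0))))
    H <- A[hood, hood, drop = FALSE]
    core <- oracle_coreness(H)
    kmax <- max(core)
    if (kmax == 0L) next
    K <- H[core == kmax, core == kmax, drop = FALSE]
    nk <- nrow(K)
    w[v] <- kmax * (sum(K) / (nk * (nk - 1)))
  }
  w
}

# Step-by-step reference trace of greedy complex prediction: highest
# unvisited weight seeds (ties by name), repeated scans instead of a
# queue, inclusion iff weight >= seed threshold.
oracle_mcode_complexes <- function(A, w, cutoff = 0.2) {
  nm <- rownames(A)
  visited <- stats::setNames(rep(FALSE, length(nm)), nm)
  out <- list()
  repeat {
    open <- nm[!visited]
    if (length(open) == 0L) break
    seed <- open[order(-w[open], open)][1L]
    thr <- w[seed] * (1 - cutoff)
    members <- seed
    visited[seed] <- TRUE
    repeat {
      frontier <- nm[!visited & colSums(A[members, , drop = FALSE]) > 0 & w >= thr]
      if (length(frontier) == 0L) break
      visited[frontier] <- TRUE
      members <- c(members, frontier)
    }
    if (length(members) >= 2L)
      out[[length(out) + 1L]] <- sort(members)
  }
  out
}

# Seeded random named graph for oracle batteries.
random_named_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p, directed = FALSE)
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    g
  })
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

named_graph <- function(edges, isolated = character(0)) {
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  g
}

largest_comp_for_test <- function(g) {
  comp <- igraph::components(g)
  igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
}

# Polynomial independent betweenness for mid-size graphs: BFS distances,
# shortest-path counts sigma[s,v] accumulated in distance order, then the
# pair-dependency identity sigma[s,v]*sigma[v,t]/sigma[s,t] summed over
# pairs with d(s,v)+d(v,t)=d(s,t). O(n^3), no Brandes accumulation.
oracle_betweenness_counts <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (v in ord) {
      if (v == s || is.infinite(D[s, v])) next
      pred <- which(A[v, ] > 0 & D[s, ] == D[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1L)) for (t in seq(s + 1L, n)) {
      if (s == v || t == v || is.infinite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  if (n >= 3) btw <- btw / ((n - 1) * (n - 2) / 2)
  stats::setNames(btw, rownames(A))
}
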