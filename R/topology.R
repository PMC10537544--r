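#' Node centralities of an interaction network
#'
#' Degree, normalized betweenness and normalized closeness for every node,
#' using the Cytoscape NetworkAnalyzer conventions: betweenness is the
#' Brandes pair-dependency sum divided by `(n-1)(n-2)/2` with endpoints
#' excluded, and closeness is the reachable-average form — the number of
#' reachable nodes divided by the sum of distances to them, with isolated
#' nodes scored 0. Edge confidences are ignored: all shortest paths are
#' unweighted hop counts.
#'
#' @param g A non-empty `igraph` graph with named vertices.
#' @return A `data.frame` with columns `node`, `degree`, `betweenness`,
#'   `closeness`, one row per node in vertex order.
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' igraph::V(g)$name <- c("HUB", "A", "B", "C", "D")
#' centrality_table(g) # hub: degree 4, betweenness 1, closeness 1
#' @export
centrality_table <- function(g) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty graph")
  deg <- igraph::degree(g, loops = FALSE)
  if (n >= 3L) {
    btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                               normalized = TRUE)
  } else {
    btw <- rep(0, n)
  }
  clo <- suppressWarnings(igraph::closeness(g, weights = NA, normalized = TRUE))
  clo[!is.finite(clo)] <- 0 # isolated nodes
  data.frame(node = igraph::V(g)$name,
             degree = as.integer(unname(deg)),
             betweenness = unname(btw),
             closeness = unname(clo),
             stringsAsFactors = FALSE)
}

#' Topological property summary of a network
#'
#' The NetworkAnalyzer-style metric set used to characterise interaction
#' networks: node and edge counts, mean local clustering coefficient
#' (over nodes of degree >= 2; lower degrees have no defined local
#' coefficient and are excluded), diameter and radius (max/min eccentricity
#' over the largest connected component), degree centralization
#' `(n/(n-2)) * (max_degree/(n-1) - density)` clipped to \[0, 1\], the
#' number of ordered node pairs at finite distance, the characteristic
#' (mean) path length over those pairs, and degree heterogeneity
#' `sd(degree)/mean(degree)`.
#'
#' For a connected graph the shortest-path count equals `n*(n-1)`;
#' disconnected input triggers a warning and eccentricity-based metrics are
#' computed on the largest component.
#'
#' @param g A non-empty `igraph` graph.
#' @return A list of class `topology_summary` with elements `n_nodes`,
#'   `n_edges`, `clustering_coefficient`, `diameter`, `radius`,
#'   `centralization`, `shortest_path_count`, `characteristic_path_length`,
#'   `heterogeneity`.
#' @seealso [path_length_distribution()], [degree_distribution()]
#' @export
topology_summary <- function(g) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty graph")
  m <- igraph::ecount(g)
  deg <- igraph::degree(g, loops = FALSE)

  comp <- igraph::components(g)
  if (comp$no > 1L)
    warning("graph is disconnected (", comp$no,
            " components); diameter/radius computed on the largest component")
  lcc <- if (comp$no > 1L) largest_component(g) else g

  if (igraph::vcount(lcc) > 1L) {
    ecc <- igraph::eccentricity(lcc)
    diameter <- as.integer(max(ecc))
    radius <- as.integer(min(ecc))
  } else {
    diameter <- 0L
    radius <- 0L
  }

  dt <- igraph::distance_table(g, directed = FALSE)
  spc <- 2 * sum(dt$res)                       # ordered pairs, finite distance
  cpl <- if (spc > 0) sum(dt$res * seq_along(dt$res)) / sum(dt$res) else NA_real_

  loc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  loc <- loc[deg >= 2L]
  cc <- if (length(loc)) mean(loc) else 0

  if (n < 3L) {
    warning("centralization undefined for n < 3; reporting 0")
    centralization <- 0
  } else {
    density <- 2 * m / (n * (n - 1))
    centralization <- (n / (n - 2)) * (max(deg) / (n - 1) - density)
    centralization <- min(1, max(0, centralization))
  }

  md <- mean(deg)
  sdd <- stats::sd(deg)
  heterogeneity <- if (n == 1L || sdd == 0) 0 else sdd / md

  structure(list(
    n_nodes = n,
    n_edges = m,
    clustering_coefficient = cc,
    diameter = diameter,
    radius = radius,
    centralization = centralization,
    shortest_path_count = spc,
    characteristic_path_length = cpl,
    heterogeneity = heterogeneity
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("Topological properties\n")
  df <- as.data.frame(x)
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-28s %s\n", df$parameter[i], format(df$value[i])))
  invisible(x)
}

#' @export
as.data.frame.topology_summary <- function(x, ...) {
  data.frame(
    parameter = c("Number of nodes", "Number of edges",
                  "Clustering coefficient", "Network diameter",
                  "Network radius", "Network centralization",
                  "Shortest paths", "Characteristic path length",
                  "Network heterogeneity"),
    value = c(x$n_nodes, x$n_edges, x$clustering_coefficient, x$diameter,
              x$radius, x$centralization, x$shortest_path_count,
              x$characteristic_path_length, x$heterogeneity),
    stringsAsFactors = FALSE
  )
}

#' Write a topology summary as a two-column TSV
#'
#' @param x A `topology_summary` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_summary <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Degree histogram of a network
#'
#' Counts of nodes at each degree `k >= 1` (isolated nodes are excluded, as
#' in the usual log-log degree plot). Errors on an all-isolated graph.
#'
#' @param g A non-empty `igraph` graph.
#' @return A `data.frame` with columns `k` (strictly increasing) and
#'   `count`; counts sum to the number of nodes with degree >= 1.
#' @export
degree_distribution <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0L) stop("empty graph")
  deg <- igraph::degree(g, loops = FALSE)
  deg <- deg[deg >= 1L]
  if (length(deg) == 0L) stop("all nodes are isolated; no degree distribution")
  tab <- table(deg)
  data.frame(k = as.integer(names(tab)), count = as.integer(tab))
}

#' Fit a power law to a degree histogram
#'
#' Ordinary least squares of `ln(count)` on `ln(k)` over the histogram
#' points with `count > 0` and `k >= 1` — the straight-line fit on the
#' log-log degree plot used to assess scale-free topology (no binning, no
#' maximum-likelihood estimation). The model reported is
#' `count ~ a * k^-gamma`, so `gamma` is minus the fitted slope and is
#' positive for decaying degree distributions.
#'
#' @param d A degree histogram as returned by [degree_distribution()]:
#'   a `data.frame` with columns `k` and `count`. At least 3 distinct `k`
#'   with positive counts are required.
#' @return A list of class `power_law_fit` with elements `a` (prefactor),
#'   `gamma` (exponent), `r2_log` (coefficient of determination of the
#'   log-log regression) and `n_points`.
#' @examples
#' d <- data.frame(k = 1:10, count = round(100 * (1:10)^-2 * 1e6) / 1e6)
#' fit_power_law(d) # recovers a = 100, gamma = 2, r2 = 1
#' @export
fit_power_law <- function(d) {
  stopifnot(is.data.frame(d), all(c("k", "count") %in% names(d)))
  d <- d[d$count > 0 & d$k >= 1, , drop = FALSE]
  if (length(unique(d$k)) < 3L)
    stop("power-law fit needs >= 3 distinct degrees with positive counts")
  x <- log(d$k)
  y <- log(d$count)
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  sse <- sum(stats::residuals(fit)^2)
  r2 <- if (sst < 1e-12) 1 else 1 - sse / sst
  structure(list(
    a = exp(unname(stats::coef(fit)[1L])),
    gamma = -unname(stats::coef(fit)[2L]),
    r2_log = r2,
    n_points = nrow(d)
  ), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: count ~ %.4g * k^-%.4g  (R2 on log-log = %.4f, %d points)\n",
              x$a, x$gamma, x$r2_log, x$n_points))
  invisible(x)
}

#' Shortest-path length distribution
#'
#' Histogram of all ordered finite-distance node pairs by shortest-path
#' length — the "small world" diagnostic: most pairs of a small-world
#' interaction network sit 3-5 steps apart. On disconnected input the
#' distribution is computed on the largest component, with a warning.
#'
#' @param g A non-empty `igraph` graph.
#' @return A `data.frame` with columns `distance` and `count` (ordered
#'   pairs); counts sum to the connected graph's shortest-path count.
#' @export
path_length_distribution <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0L) stop("empty graph")
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning("graph is disconnected; path lengths computed on the largest component")
    g <- largest_component(g)
  }
  dt <- igraph::distance_table(g, directed = FALSE)
  res <- dt$res
  d <- data.frame(distance = seq_along(res), count = 2L * res)
  d[d$count > 0L, , drop = FALSE]
}
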