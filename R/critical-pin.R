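#' One median-filter pass over three centralities
#'
#' Selects the nodes whose degree AND betweenness AND closeness are each
#' strictly greater than that metric's median over the current graph — the
#' per-pass selection rule behind the critical interaction network. The
#' median of an even-length list is the mean of the middle two values.
#'
#' On highly regular graphs a metric can be degenerate (no node strictly
#' exceeds its own median, e.g. any vertex-transitive graph); an empty
#' selection is an error naming the degenerate metric(s).
#'
#' @param g An `igraph` graph with at least 3 nodes.
#' @return Character vector of surviving gene symbols.
#' @seealso [build_critical_pin()]
#' @export
median_filter_step <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) < 3L) stop("median filter needs >= 3 nodes")
  ct <- centrality_table(g)
  meds <- c(degree = stats::median(ct$degree),
            betweenness = stats::median(ct$betweenness),
            closeness = stats::median(ct$closeness))
  keep <- ct$degree > meds["degree"] &
    ct$betweenness > meds["betweenness"] &
    ct$closeness > meds["closeness"]
  if (!any(keep)) {
    degenerate <- c("degree", "betweenness", "closeness")[
      c(max(ct$degree) <= meds["degree"],
        max(ct$betweenness) <= meds["betweenness"],
        max(ct$closeness) <= meds["closeness"])]
    stop("median filter selected no node; degenerate metric(s): ",
         if (length(degenerate)) paste(degenerate, collapse = ", ")
         else "none individually (joint condition empty)")
  }
  ct$node[keep]
}

#' Build the critical interaction network by repeated median filtering
#'
#' Runs `passes` rounds of: recompute degree/betweenness/closeness on the
#' current graph, keep the nodes strictly above all three medians
#' ([median_filter_step()]), and take the induced subgraph (restricted to
#' its largest connected component when `lcc_only`). Centralities are
#' recomputed on the filtered graph before each pass, so the second pass
#' filters the primary critical network, not the original one.
#'
#' If a later pass would empty the graph (or the graph has shrunk below 3
#' nodes), filtering stops with a warning and the pre-pass graph is
#' returned; only a first-pass wipe-out is an error, since it signals a
#' degenerate input rather than a converged filter.
#'
#' @param g The input interaction network (`igraph`).
#' @param passes Number of filter rounds, default 2.
#' @param lcc_only Keep only the largest connected component after each
#'   pass? Default `TRUE`.
#' @return A list with `graph` (the final critical network) and `report`,
#'   a per-pass `data.frame` with columns `pass`, `n_nodes_in`,
#'   `n_edges_in`, `median_degree`, `median_betweenness`,
#'   `median_closeness`, `n_nodes_out`, `n_edges_out`.
#' @export
build_critical_pin <- function(g, passes = 2L, lcc_only = TRUE) {
  stopifnot(igraph::is_igraph(g), passes >= 1L)
  current <- g
  report <- data.frame()
  for (p in seq_len(passes)) {
    if (igraph::vcount(current) < 3L) {
      warning("pass ", p, ": graph has fewer than 3 nodes; stopping early")
      break
    }
    ct <- centrality_table(current)
    keep <- tryCatch(median_filter_step(current), error = function(e) e)
    if (inherits(keep, "error")) {
      if (p == 1L) stop(keep)
      warning("pass ", p, " emptied the graph (", conditionMessage(keep),
              "); returning the pass-", p - 1L, " network")
      break
    }
    nxt <- suppressWarnings(induce_network(current, keep, lcc_only = lcc_only))
    report <- rbind(report, data.frame(
      pass = p,
      n_nodes_in = igraph::vcount(current),
      n_edges_in = igraph::ecount(current),
      median_degree = stats::median(ct$degree),
      median_betweenness = stats::median(ct$betweenness),
      median_closeness = stats::median(ct$closeness),
      n_nodes_out = igraph::vcount(nxt),
      n_edges_out = igraph::ecount(nxt)
    ))
    current <- nxt
  }
  list(graph = current, report = report)
}

#' Select hub genes by triple-centrality top-k intersection
#'
#' For each of degree, betweenness and closeness, ranks the nodes in
#' descending order and takes the top `k` — with all nodes tied at the
#' rank-k boundary value included, so the result is deterministic and
#' invariant to node relabeling. The hubs are the genes present in all
#' three top lists; an empty intersection is allowed (reported via a
#' message).
#'
#' @param g An `igraph` graph with at least `k` nodes.
#' @param k Rank cutoff, default 10.
#' @return Sorted character vector of hub gene symbols (possibly empty).
#' @export
select_hubs <- function(g, k = 10L) {
  stopifnot(igraph::is_igraph(g), k >= 1L)
  if (igraph::vcount(g) < k)
    stop("graph has fewer than k = ", k, " nodes")
  ct <- centrality_table(g)
  top <- function(v) {
    thr <- sort(v, decreasing = TRUE)[k]
    ct$node[v >= thr]
  }
  hubs <- Reduce(intersect,
                 list(top(ct$degree), top(ct$betweenness), top(ct$closeness)))
  if (length(hubs) == 0L)
    message("no node is in the top ", k, " of all three centralities")
  sort(hubs)
}
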