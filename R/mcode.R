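# Loop-free density 2E/(n(n-1)) of an igraph graph; 0 for n < 2.
graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weights (core-clustering coefficient)
#'
#' Stage one of molecular complex detection. A vertex below the degree
#' cutoff weighs 0. Otherwise, let `H` be the subgraph induced by the
#' vertex and its neighbours (the closed neighbourhood), `k_max` the
#' highest k-core level present in `H`, and `K` that highest k-core; the
#' weight is `k_max * density(K)`, where density is loop-free
#' `2E/(n(n-1))`. Weighting by the core density rather than the plain
#' local clustering coefficient rewards locally dense regions while
#' damping the effect of spuriously attached low-degree vertices.
#'
#' @param g A simple undirected `igraph` graph with named vertices.
#' @param degree_cutoff Minimum degree for a non-zero weight, default 2.
#' @return Named numeric vector of weights, one per vertex.
#' @seealso [mcode()]
#' @export
mcode_vertex_weights <- function(g, degree_cutoff = 2L) {
  stopifnot(igraph::is_igraph(g), degree_cutoff >= 0L)
  deg <- igraph::degree(g, loops = FALSE)
  nm <- igraph::V(g)$name
  w <- stats::setNames(numeric(length(nm)), nm)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  for (i in seq_along(nm)) {
    if (deg[i] < degree_cutoff) next
    hverts <- unique(c(i, as.integer(adj[[i]])))
    H <- igraph::induced_subgraph(g, hverts)
    core <- igraph::coreness(H)
    kmax <- max(core)
    if (kmax == 0L) next
    K <- igraph::induced_subgraph(H, which(core == kmax))
    w[i] <- kmax * graph_density(K)
  }
  w
}

#' MCODE complex prediction
#'
#' Stage two: repeatedly seed from the highest-weight unvisited vertex
#' (ties broken lexicographically by symbol) and grow the complex
#' breadth-first, including any unvisited neighbour whose weight is at
#' least `seed_weight * (1 - node_score_cutoff)` (ties at the threshold
#' are included). Included vertices are marked visited, so with fluff off
#' the emitted complexes are node-disjoint. Complexes with fewer than two
#' members are not emitted.
#'
#' @param g A simple undirected `igraph` graph with named vertices.
#' @param weights Named weight vector from [mcode_vertex_weights()],
#'   covering all vertices of `g`.
#' @param node_score_cutoff Allowed proportional drop from the seed weight,
#'   in \[0, 1\]; default 0.2.
#' @return List of raw complexes, each a list with `seed`, `members`
#'   (sorted symbols), `n`, `density`, `score` (`density * n`).
#' @export
mcode_find_complexes <- function(g, weights, node_score_cutoff = 0.2) {
  stopifnot(igraph::is_igraph(g),
            node_score_cutoff >= 0, node_score_cutoff <= 1)
  nm <- igraph::V(g)$name
  if (!all(nm %in% names(weights)))
    stop("weights must cover all vertices")
  w <- weights[nm]
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  visited <- logical(length(nm))
  seed_order <- order(-w, nm)
  complexes <- list()
  for (s in seed_order) {
    if (visited[s]) next
    thr <- w[s] * (1 - node_score_cutoff)
    members <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      if (visited[v] || w[v] < thr) next
      visited[v] <- TRUE
      members <- c(members, v)
      nbr <- adj[[v]]
      nbr <- nbr[!visited[nbr]]
      queue <- c(queue, nbr[order(nm[nbr])])
    }
    if (length(members) >= 2L) {
      sub <- igraph::induced_subgraph(g, members)
      complexes[[length(complexes) + 1L]] <- list(
        seed = nm[s],
        members = sort(nm[members]),
        n = length(members),
        density = graph_density(sub),
        score = graph_density(sub) * length(members)
      )
    }
  }
  complexes
}

#' MCODE post-processing
#'
#' Stage three. Complexes that do not contain a `kcore_filter`-core are
#' discarded (a tree-shaped complex has no 2-core, for instance). With
#' `fluff` on, neighbours whose closed-neighbourhood density exceeds
#' `fluff_density` are pulled in (this can make modules overlap). With
#' `haircut` on, members with fewer than two intra-module neighbours are
#' removed iteratively. Density and score are recomputed and modules that
#' shrink below two members are dropped.
#'
#' @param modules Raw complexes from [mcode_find_complexes()].
#' @param g The graph the complexes were detected in.
#' @param kcore_filter Required core level, default 2.
#' @param haircut Remove singly-connected members? Default `TRUE`.
#' @param fluff Expand by dense neighbours? Default `FALSE`.
#' @param fluff_density Closed-neighbourhood density threshold used when
#'   `fluff` is on, default 0.2.
#' @return List of post-processed complexes in the input format.
#' @export
mcode_postprocess <- function(modules, g, kcore_filter = 2L, haircut = TRUE,
                              fluff = FALSE, fluff_density = 0.2) {
  stopifnot(igraph::is_igraph(g))
  nm <- igraph::V(g)$name
  out <- list()
  for (mod in modules) {
    members <- mod$members
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < kcore_filter) next
    if (fluff) {
      cand <- setdiff(
        nm[unique(unlist(igraph::adjacent_vertices(g, members)))], members)
      dense <- vapply(cand, function(v) {
        h <- igraph::induced_subgraph(
          g, unique(c(v, nm[as.integer(igraph::neighbors(g, v))])))
        graph_density(h)
      }, numeric(1))
      members <- sort(c(members, cand[dense > fluff_density]))
      sub <- igraph::induced_subgraph(g, members)
    }
    if (haircut) {
      repeat {
        d <- igraph::degree(sub)
        if (igraph::vcount(sub) == 0L || all(d >= 2L)) break
        sub <- igraph::induced_subgraph(sub, which(d >= 2L))
      }
      members <- sort(igraph::V(sub)$name)
    }
    if (length(members) < 2L) next
    out[[length(out) + 1L]] <- list(
      seed = mod$seed, members = members, n = length(members),
      density = graph_density(sub),
      score = graph_density(sub) * length(members))
  }
  out
}

#' Rank modules and apply the score filter
#'
#' Keeps modules whose score (`density * n`) is strictly greater than
#' `min_score` and sorts them by descending score, breaking ties by larger
#' size and then by seed symbol; ranks are assigned 1, 2, ...
#'
#' @param modules List of complexes (post-processed or raw).
#' @param min_score Strict lower bound on the module score, default 5.
#' @return Filtered, ranked list; each element gains a `rank` field.
#' @export
mcode_rank_and_filter <- function(modules, min_score = 5) {
  keep <- Filter(function(m) m$score > min_score, modules)
  if (length(keep) == 0L) return(list())
  ord <- order(-vapply(keep, `[[`, numeric(1), "score"),
               -vapply(keep, `[[`, numeric(1), "n"),
               vapply(keep, `[[`, "", "seed"))
  keep <- keep[ord]
  for (i in seq_along(keep)) keep[[i]]$rank <- i
  keep
}

#' Molecular complex detection (MCODE)
#'
#' Full three-stage pipeline — vertex weighting, greedy complex
#' prediction, post-processing — followed by the score filter. The
#' defaults are the standard plugin settings used for interaction-network
#' module analysis: degree cutoff 2, k-core filter 2, node score cutoff
#' 0.2, haircut on, fluff off, and modules kept only when their score is
#' strictly greater than 5.
#'
#' @inheritParams mcode_vertex_weights
#' @inheritParams mcode_find_complexes
#' @inheritParams mcode_postprocess
#' @inheritParams mcode_rank_and_filter
#' @return Ranked module list as in [mcode_rank_and_filter()].
#' @examples
#' g <- gen_scale_free(50, 2, seed = 1)
#' mcode(g, min_score = 0) # low threshold: report whatever was found
#' @export
mcode <- function(g, degree_cutoff = 2L, node_score_cutoff = 0.2,
                  kcore_filter = 2L, haircut = TRUE, fluff = FALSE,
                  fluff_density = 0.2, min_score = 5) {
  w <- mcode_vertex_weights(g, degree_cutoff = degree_cutoff)
  raw <- mcode_find_complexes(g, w, node_score_cutoff = node_score_cutoff)
  post <- mcode_postprocess(raw, g, kcore_filter = kcore_filter,
                            haircut = haircut, fluff = fluff,
                            fluff_density = fluff_density)
  mcode_rank_and_filter(post, min_score = min_score)
}

#' Module list as a data frame
#'
#' Flattens an MCODE module list into a table suitable for TSV export:
#' `rank`, `score`, `n`, `density`, `seed` and comma-joined `members`.
#'
#' @param modules Module list from [mcode()] or [mcode_rank_and_filter()].
#' @return A `data.frame`, zero rows when no module passed.
#' @export
module_table <- function(modules) {
  if (length(modules) == 0L)
    return(data.frame(rank = integer(), score = numeric(), n = integer(),
                      density = numeric(), seed = character(),
                      members = character(), stringsAsFactors = FALSE))
  data.frame(
    rank = vapply(modules, function(m) as.integer(m$rank %||% NA_integer_),
                  integer(1)),
    score = vapply(modules, `[[`, numeric(1), "score"),
    n = vapply(modules, function(m) as.integer(m$n), integer(1)),
    density = vapply(modules, `[[`, numeric(1), "density"),
    seed = vapply(modules, `[[`, "", "seed"),
    members = vapply(modules, function(m) paste(m$members, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
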