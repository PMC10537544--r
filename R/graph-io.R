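#' Read a protein-interaction edge list
#'
#' Parses a STRING-style tab-separated edge list into a simple undirected
#' [igraph][igraph::igraph-package] graph over gene symbols. Rows whose
#' confidence falls below `min_confidence` are discarded, self-loops are
#' dropped, and duplicate pairs (in either orientation) are merged keeping
#' the maximum confidence.
#'
#' The confidence scale is never auto-detected: STRING exports integer
#' `combined_score` values in 0-1000, while other sources use probabilities
#' in \[0, 1\]. Silently mistaking one for the other is the classic way to
#' end up with an empty or a complete network, so the caller must state the
#' dialect via `scale`.
#'
#' @param path Path to a TSV file with two columns `node_a`, `node_b` and an
#'   optional third confidence column. All rows must have the same number of
#'   fields.
#' @param min_confidence Minimum confidence (on the unit scale, after any
#'   rescaling) for an edge to be kept. Edges without a confidence column are
#'   treated as confidence 1. Default 0.9, the high-confidence STRING cutoff.
#' @param scale Either `"unit"` (scores already in \[0, 1\]) or
#'   `"string1000"` (STRING 0-1000 integers, divided by 1000 on read).
#' @param header Logical; does the file start with a header line? Default
#'   `FALSE`.
#' @return An undirected simple `igraph` graph with vertex names set to the
#'   gene symbols and, when the file has a third column, an edge attribute
#'   `confidence` on the unit scale.
#' @seealso [write_edge_list()], [induce_network()]
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB\t0.95", "B\tC\t0.85", "C\tC\t0.99"), f)
#' g <- read_edge_list(f, min_confidence = 0.9)
#' igraph::ecount(g) # 1: only A-B survives; the self-loop row is dropped
#' @export
read_edge_list <- function(path, min_confidence = 0.9,
                           scale = c("unit", "string1000"),
                           header = FALSE) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("edge list file not found: ", path)
  stopifnot(is.numeric(min_confidence), min_confidence >= 0, min_confidence <= 1)

  lines <- readLines(path)
  offset <- 0L
  if (header) {
    if (length(lines) < 1L) stop("edge list is empty: ", path)
    lines <- lines[-1L]
    offset <- 1L
  }
  keep <- nzchar(trimws(lines))
  lineno <- which(keep) + offset
  lines <- lines[keep]
  if (length(lines) == 0L) stop("edge list has no data rows: ", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  expected <- nf[1L]
  if (!expected %in% c(2L, 3L))
    stop("edge list line ", lineno[1L], ": expected 2 or 3 tab-separated fields, got ", expected)
  bad <- which(nf != expected)
  if (length(bad))
    stop("edge list line ", lineno[bad[1L]], ": expected ", expected,
         " tab-separated fields, got ", nf[bad[1L]])

  a <- trimws(vapply(fields, `[[`, "", 1L))
  b <- trimws(vapply(fields, `[[`, "", 2L))
  empty <- which(!nzchar(a) | !nzchar(b))
  if (length(empty))
    stop("edge list line ", lineno[empty[1L]], ": empty node symbol")

  if (expected == 3L) {
    conf <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    nav <- which(is.na(conf))
    if (length(nav))
      stop("edge list line ", lineno[nav[1L]], ": non-numeric confidence")
    hi <- if (scale == "unit") 1 else 1000
    oob <- which(conf < 0 | conf > hi)
    if (length(oob))
      stop("edge list line ", lineno[oob[1L]], ": confidence ", conf[oob[1L]],
           " outside [0, ", hi, "] for scale '", scale, "'")
    if (scale == "string1000") conf <- conf / 1000
  } else {
    conf <- rep(1, length(a))
  }

  ok <- a != b & conf >= min_confidence
  a <- a[ok]; b <- b[ok]; conf <- conf[ok]
  if (length(a) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))

  # unordered dedup keeping the maximum confidence
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  conf <- vapply(split(conf, key), max, numeric(1))
  pairs <- do.call(rbind, strsplit(names(conf), "\r", fixed = TRUE))

  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1L], to = pairs[, 2L], stringsAsFactors = FALSE),
    directed = FALSE
  )
  if (expected == 3L)
    igraph::E(g)$confidence <- unname(conf)
  g
}

#' Write a graph as a tab-separated edge list
#'
#' Inverse of [read_edge_list()]: one row per edge, columns `node_a`,
#' `node_b` and, when the graph carries a `confidence` edge attribute,
#' `combined_score` on the unit scale.
#'
#' @param g An undirected `igraph` graph with named vertices.
#' @param path Output file path.
#' @param header Write a header line? Default `FALSE`, matching
#'   [read_edge_list()]'s default.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, header = FALSE) {
  stopifnot(igraph::is_igraph(g))
  ends <- igraph::as_edgelist(g, names = TRUE)
  d <- data.frame(node_a = ends[, 1L], node_b = ends[, 2L],
                  stringsAsFactors = FALSE)
  if (!is.null(igraph::edge_attr(g, "confidence")))
    d$combined_score <- igraph::E(g)$confidence
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One symbol per line; anything after a `#` is a comment; blank lines are
#' skipped. Symbols are whitespace-trimmed but not case-normalized (see
#' [gene_set()] for normalization).
#'
#' @param path File path.
#' @return Character vector of symbols (possibly with duplicates, in file
#'   order).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes Character vector of symbols to write, one per line.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Induce a subnetwork on a set of gene symbols
#'
#' Restricts a network to `keep` and all edges internal to it — the
#' operation used both to carve the disease-specific interaction network
#' out of the interaction background and to apply each median-filter pass.
#' Symbols absent from the graph are ignored with a warning; an empty
#' result is an error, because every downstream stage presumes a non-empty
#' network.
#'
#' @param g An `igraph` graph with named vertices.
#' @param keep Character vector of symbols to retain.
#' @param lcc_only If `TRUE`, restrict further to the largest connected
#'   component; ties between equally large components are broken by the
#'   lexicographically smallest member symbol.
#' @return The induced `igraph` subgraph.
#' @export
induce_network <- function(g, keep, lcc_only = FALSE) {
  stopifnot(igraph::is_igraph(g))
  keep <- unique(as.character(keep))
  known <- intersect(keep, igraph::V(g)$name)
  unknown <- setdiff(keep, known)
  if (length(unknown))
    warning("ignoring ", length(unknown), " symbol(s) not in the network: ",
            paste(utils::head(sort(unknown), 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ..." else "")
  if (length(known) == 0L)
    stop("degenerate filter: no requested symbol is present in the network")
  sub <- igraph::induced_subgraph(g, known)
  if (lcc_only) sub <- largest_component(sub)
  sub
}

# Largest connected component; ties broken by the lexicographically
# smallest member symbol so the choice is deterministic.
largest_component <- function(g) {
  comp <- igraph::components(g)
  if (comp$no <= 1L) return(g)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    firsts <- vapply(big, function(i)
      min(igraph::V(g)$name[comp$membership == i]), character(1))
    big <- big[order(firsts)[1L]]
  }
  igraph::induced_subgraph(g, which(comp$membership == big))
}
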