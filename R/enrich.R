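#' Hypergeometric upper-tail probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the chance of seeing at
#' least `k` annotated genes in a query of size `n` drawn from a universe
#' of `N` genes of which `K` carry the annotation — the over-representation
#' test statistic. Evaluated through `phyper`'s upper tail, which works on
#' log scale internally, so tiny p-values keep full relative accuracy.
#'
#' @param k Observed hits in the term, `0 <= k <= min(K, n)`.
#' @param K Term size within the universe.
#' @param n Annotated query size.
#' @param N Universe size; `K <= N`, `n <= N`.
#' @return The upper-tail probability in (0, 1\].
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 20) # 1/choose(20, 5) = 1/15504
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (k < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N || k > min(K, n))
    stop("invalid hypergeometric parameters: need 0 <= k <= min(K, n) and K, n <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Storey-style q-values
#'
#' Estimates the proportion of true nulls as
#' `pi0 = mean(p > lambda) / (1 - lambda)` at `lambda = 0.5`, clips it to
#' (0, 1\], and scales the Benjamini-Hochberg step-up values by `pi0`,
#' monotonized from the largest p downward. When the `pi0` estimate
#' reaches 1 the q-values coincide with BH.
#'
#' @param p Numeric vector of p-values.
#' @param lambda Tuning point for the `pi0` estimate, default 0.5.
#' @return Numeric vector of q-values in \[0, 1\], same order as `p`.
#' @export
storey_q <- function(p, lambda = 0.5) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1), lambda > 0, lambda < 1)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  pi0 <- mean(p > lambda) / (1 - lambda)
  pi0 <- min(1, max(pi0, 1 / m))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m / (m:1) * p[o]))[ro]
  q
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one term per line,
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Term IDs must be
#' unique and every term must have at least one gene.
#'
#' @param path File path.
#' @return A named list (by term ID) of lists with `name` (description)
#'   and `genes` (character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], ": needs id, description and >= 1 gene")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id: ", ids[anyDuplicated(ids)])
  out <- lapply(fields, function(f)
    list(name = f[2L], genes = unique(f[-(1:2)])))
  stats::setNames(out, ids)
}

#' @rdname read_gmt
#' @param collection Collection in the [read_gmt()] format.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(id) {
    t <- collection[[id]]
    paste(c(id, t$name, t$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene set
#'
#' Hypergeometric upper-tail test of a query gene set against every term
#' of a collection, with Benjamini-Hochberg adjusted p-values and
#' Storey-style q-values computed across all tested terms. Terms passing
#' BOTH `adj_p < adj_p_cut` and `q < q_cut` are kept, sorted by ascending
#' adjusted p (ties by larger hit count `k`, then term ID), and the top
#' `top_n` are reported.
#'
#' The universe defaults to the union of the collection's genes; pass
#' `universe` to use an explicit background. The query is first restricted
#' to the universe; a query disjoint from it is an error.
#'
#' @param query Character vector of gene symbols.
#' @param collection Collection from [read_gmt()] or [gen_gmt()].
#' @param universe Optional explicit background gene vector.
#' @param adj_p_cut,q_cut Thresholds on adjusted p and q, both 0.05 by
#'   default.
#' @param top_n Number of passing terms to report, default 10; use `Inf`
#'   for all passing terms.
#' @return A `data.frame` with columns `term_id`, `description`,
#'   `gene_ratio` (the string `"k/n"`), `k`, `K`, `n`, `N`, `p`, `adj_p`,
#'   `q`, `hit_genes` (comma-joined). Zero rows when nothing passes.
#' @export
ora <- function(query, collection, universe = NULL,
                adj_p_cut = 0.05, q_cut = 0.05, top_n = 10) {
  stopifnot(length(query) >= 1L, length(collection) >= 1L,
            adj_p_cut > 0, adj_p_cut < 1, q_cut > 0, q_cut < 1)
  if (is.null(universe))
    universe <- unique(unlist(lapply(collection, `[[`, "genes")))
  universe <- unique(as.character(universe))
  N <- length(universe)
  q_genes <- intersect(unique(as.character(query)), universe)
  n <- length(q_genes)
  if (n == 0L) stop("query disjoint from universe")

  ids <- names(collection)
  rows <- lapply(ids, function(id) {
    term <- intersect(collection[[id]]$genes, universe)
    hits <- intersect(q_genes, term)
    k <- length(hits)
    data.frame(term_id = id, description = collection[[id]]$name,
               gene_ratio = paste0(k, "/", n),
               k = k, K = length(term), n = n, N = N,
               p = hypergeom_upper_tail(k, length(term), n, N),
               hit_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$adj_p <- stats::p.adjust(tab$p, method = "BH")
  tab$q <- storey_q(tab$p)
  tab <- tab[tab$adj_p < adj_p_cut & tab$q < q_cut, , drop = FALSE]
  tab <- tab[order(tab$adj_p, -tab$k, tab$term_id), , drop = FALSE]
  tab <- utils::head(tab, top_n)
  rownames(tab) <- NULL
  tab[, c("term_id", "description", "gene_ratio", "k", "K", "n", "N",
          "p", "adj_p", "q", "hit_genes")]
}
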