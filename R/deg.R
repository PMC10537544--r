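#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the same empirical distribution: each
#' column's sorted values become the per-rank cross-column means, with ties
#' within a column receiving the mean of their rank values. Delegates to
#' `limma::normalizeQuantiles(ties = TRUE)`, the standard microarray
#' implementation of this operation. Idempotent: normalizing twice equals
#' normalizing once.
#'
#' @param m Numeric matrix (log2 scale), probes or genes in rows, samples
#'   in columns; no missing values.
#' @return The normalized matrix with the same dimnames.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (anyNA(m)) stop("missing values are not supported")
  if (ncol(m) <= 1L) {
    warning("single-sample matrix: quantile normalization is the identity")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Collapse probe-level rows to gene symbols
#'
#' Applies the screening-stage probe rules: probes mapping to zero genes or
#' to more than one gene are dropped; when several probes map to one gene,
#' the probe with the highest mean expression across samples represents the
#' gene (ties broken by the lexicographically smallest probe ID).
#'
#' @param m Numeric matrix with probe IDs as rownames.
#' @param probe_map Named list: probe ID -> character vector of gene
#'   symbols. Probes absent from the map are treated as unmapped.
#' @return The matrix re-keyed by gene symbol.
#' @export
collapse_probes <- function(m, probe_map) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), is.list(probe_map))
  ngenes <- vapply(probe_map, length, integer(1))
  single <- names(probe_map)[ngenes == 1L]
  probes <- intersect(rownames(m), single)
  if (length(probes) == 0L) stop("no probe maps to exactly one gene")
  gene <- vapply(probe_map[probes], `[[`, "", 1L)
  means <- rowMeans(m[probes, , drop = FALSE])
  # per gene: highest mean, tie -> smallest probe ID
  ord <- order(gene, -means, probes)
  pick <- !duplicated(gene[ord])
  sel <- probes[ord][pick]
  out <- m[sel, , drop = FALSE]
  rownames(out) <- unname(gene[ord][pick])
  out
}

#' Two-group differential expression with screening thresholds
#'
#' Per-gene Welch two-sample t-test on log2 expression, with each group's
#' variance floored at `variance_floor` so that zero-variance genes remain
#' testable instead of producing infinite statistics. This is a documented
#' stand-in for moderated linear-model statistics: the thresholding rule —
#' Benjamini-Hochberg adjusted p below `p_cut` and |logFC| at or above
#' `lfc_cut` — is the screening contract this stage implements.
#'
#' `logFC` is `mean(group1) - mean(group2)` in log2 units, where group 1 is
#' the first level of `groups` (for character input, the first group in
#' order of appearance — put the tumor/case label first).
#'
#' @param m Numeric matrix (genes x samples, log2 scale).
#' @param groups Factor or character vector of length `ncol(m)` with
#'   exactly two levels, each represented by at least two samples.
#' @param p_cut Adjusted-p threshold (default 0.05).
#' @param lfc_cut Absolute log2-fold-change threshold (default 0.5).
#' @param variance_floor Lower bound on each group's variance
#'   (default 1e-8).
#' @return A `data.frame` with columns `gene`, `logFC`, `t`, `df`, `p`,
#'   `adj_p`, `direction` (`"up"`, `"down"` or `"ns"`).
#' @seealso [filter_degs()]
#' @export
differential_expression <- function(m, groups, p_cut = 0.05, lfc_cut = 0.5,
                                    variance_floor = 1e-8) {
  stopifnot(is.matrix(m), is.numeric(m), ncol(m) == length(groups),
            p_cut > 0, p_cut < 1, lfc_cut >= 0, variance_floor > 0)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample names")
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required, got ", nlevels(groups))
  n1 <- sum(groups == levels(groups)[1L])
  n2 <- sum(groups == levels(groups)[2L])
  if (n1 < 2L || n2 < 2L)
    stop("each group needs >= 2 samples (got ", n1, " and ", n2, ")")

  m1 <- m[, groups == levels(groups)[1L], drop = FALSE]
  m2 <- m[, groups == levels(groups)[2L], drop = FALSE]
  mu1 <- rowMeans(m1)
  mu2 <- rowMeans(m2)
  v1 <- pmax(apply(m1, 1L, stats::var), variance_floor)
  v2 <- pmax(apply(m2, 1L, stats::var), variance_floor)

  se2 <- v1 / n1 + v2 / n2
  tstat <- (mu1 - mu2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  adj_p <- stats::p.adjust(p, method = "BH")
  lfc <- mu1 - mu2

  direction <- rep("ns", nrow(m))
  direction[adj_p < p_cut & lfc >= lfc_cut] <- "up"
  direction[adj_p < p_cut & lfc <= -lfc_cut] <- "down"

  data.frame(gene = rownames(m), logFC = unname(lfc), t = unname(tstat),
             df = unname(df), p = unname(p), adj_p = unname(adj_p),
             direction = direction, stringsAsFactors = FALSE)
}

#' Split a DEG table into up- and down-regulated gene sets
#'
#' Applies the screening rule — adjusted p below `p_cut` and |logFC| at or
#' above `lfc_cut` — to a table from [differential_expression()]. The union
#' of the two sets is the profile's disease-related gene list.
#'
#' @param deg A `data.frame` with columns `gene`, `logFC`, `adj_p`.
#' @param p_cut,lfc_cut Thresholds, defaults 0.05 and 0.5.
#' @return A list with disjoint character vectors `up` and `down`.
#' @export
filter_degs <- function(deg, p_cut = 0.05, lfc_cut = 0.5) {
  stopifnot(is.data.frame(deg), nrow(deg) > 0,
            all(c("gene", "logFC", "adj_p") %in% names(deg)))
  sig <- deg$adj_p < p_cut
  list(up = deg$gene[sig & deg$logFC >= lfc_cut],
       down = deg$gene[sig & deg$logFC <= -lfc_cut])
}

#' Read / write expression inputs
#'
#' `read_expression()` reads a TSV whose first column is the probe/gene ID
#' and remaining columns are samples; `read_groups()` reads the two-column
#' `sample<TAB>group` companion file and returns the group vector aligned
#' to the matrix columns; `read_probe_map()` reads a
#' `probe<TAB>symbol[,symbol...]` file into the list format used by
#' [collapse_probes()].
#'
#' @param path File path.
#' @return For `read_expression`, a numeric matrix; for `read_groups`, a
#'   named character vector (names are sample IDs); for `read_probe_map`, a
#'   named list of symbol vectors.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- as.character(d[[1L]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression
#' @param m Matrix to write (first output column `id`).
#' @export
write_expression <- function(m, path) {
  d <- data.frame(id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @export
read_groups <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("groups file needs columns sample, group")
  stats::setNames(as.character(d[[2L]]), as.character(d[[1L]]))
}

#' @rdname read_expression
#' @export
read_probe_map <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("probe", "symbols"))
  syms <- strsplit(d$symbols, ",", fixed = TRUE)
  syms <- lapply(syms, function(s) trimws(s)[nzchar(trimws(s))])
  stats::setNames(syms, d$probe)
}
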