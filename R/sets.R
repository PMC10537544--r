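#' Labelled gene set
#'
#' A labelled set of gene symbols, e.g. one source database's herb targets
#' or one expression profile's DEG list. Symbols are whitespace-trimmed
#' and, by default, uppercased so that the same gene reported in different
#' cases by different sources collapses to one member; no alias or ID
#' mapping is attempted.
#'
#' @param members Character vector of symbols.
#' @param label Short label, e.g. the source database name.
#' @param normalize Trim and uppercase symbols? Default `TRUE`.
#' @return An object of class `gene_set`: a list with `label` and a sorted,
#'   de-duplicated `members` vector.
#' @export
gene_set <- function(members, label = "", normalize = TRUE) {
  members <- as.character(members)
  if (normalize) members <- toupper(trimws(members))
  members <- members[nzchar(members)]
  structure(list(label = label, members = sort(unique(members))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d symbols\n", x$label, length(x$members)))
  invisible(x)
}

#' Union of gene sets
#'
#' De-duplicated union of the members of one or more [gene_set()]s — the
#' operation that merges per-database target lists (or per-profile DEG
#' lists) into a single list. Order-invariant.
#'
#' @param sets A list of `gene_set` objects (at least one).
#' @return A `gene_set` whose label concatenates the input labels with
#'   `"+"`.
#' @export
union_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "gene_set")))
  members <- sort(unique(unlist(lapply(sets, `[[`, "members"))))
  gene_set(members,
           label = paste(vapply(sets, `[[`, "", "label"), collapse = "+"),
           normalize = FALSE)
}

#' Intersection of two gene sets
#'
#' The shared-target step: symbols present in both sets. An empty
#' intersection is an error, because the downstream interaction network
#' would be empty.
#'
#' @param a,b `gene_set` objects.
#' @return A `gene_set` labelled `"<a>&<b>"`.
#' @export
intersect_sets <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  members <- intersect(a$members, b$members)
  if (length(members) == 0L)
    stop("empty intersection between '", a$label, "' and '", b$label, "'")
  gene_set(members, label = paste0(a$label, "&", b$label), normalize = FALSE)
}

#' Per-source membership table
#'
#' Wide indicator table (gene x source) for Venn-style reporting of which
#' sources contributed each symbol.
#'
#' @param sets List of `gene_set` objects.
#' @return A `data.frame`: first column `gene`, then one 0/1 column per set
#'   label.
#' @export
membership_table <- function(sets) {
  stopifnot(length(sets) >= 1L)
  all_genes <- sort(unique(unlist(lapply(sets, `[[`, "members"))))
  out <- data.frame(gene = all_genes, stringsAsFactors = FALSE)
  for (s in sets)
    out[[s$label]] <- as.integer(all_genes %in% s$members)
  out
}
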