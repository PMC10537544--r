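#' Seeded scale-free interaction graph
#'
#' Preferential-attachment growth from an `(m+1)`-clique: each subsequent
#' node attaches to `m` distinct existing nodes chosen with probability
#' proportional to current degree. The result is connected with exactly
#' `choose(m+1, 2) + m*(n-m-1)` edges and an approximately power-law
#' degree distribution — the topology class interaction networks are
#' assumed to follow.
#'
#' @param n Number of nodes (`n > m`).
#' @param m Edges added per new node (`m >= 1`).
#' @param seed Integer seed; the same seed gives an identical graph. The
#'   caller's RNG state is untouched.
#' @param prefix Vertex-name prefix, default `"G"` (names `G00001`, ...).
#' @return A connected simple `igraph` graph with named vertices.
#' @export
gen_scale_free <- function(n, m, seed, prefix = "G") {
  stopifnot(n > m, m >= 1L)
  n <- as.integer(n); m <- as.integer(m)
  withr::with_seed(seed, {
    n0 <- m + 1L
    from <- integer(0); to <- integer(0)
    for (i in seq_len(n0 - 1L))
      for (j in seq(i + 1L, n0)) { from <- c(from, i); to <- c(to, j) }
    deg <- integer(n)
    deg[seq_len(n0)] <- m
    if (n > n0) {
      # preallocate: m edges per remaining node
      extra_from <- integer(m * (n - n0))
      extra_to <- integer(m * (n - n0))
      pos <- 0L
      for (v in seq(n0 + 1L, n)) {
        existing <- seq_len(v - 1L)
        targets <- sample(existing, m, prob = deg[existing])
        extra_from[pos + seq_len(m)] <- v
        extra_to[pos + seq_len(m)] <- targets
        pos <- pos + m
        deg[targets] <- deg[targets] + 1L
        deg[v] <- m
      }
      from <- c(from, extra_from)
      to <- c(to, extra_to)
    }
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::V(g)$name <- sprintf("%s%05d", prefix, seq_len(n))
    g
  })
}

#' Graph with planted dense modules
#'
#' A sparse Erdos-Renyi background with embedded near-cliques, each tied
#' to the background by a stated number of bridge edges — the ground-truth
#' benchmark for module detection. Module node sets are returned exactly,
#' so recovery can be scored by Jaccard overlap.
#'
#' @param n_background,p_background Background size and edge probability;
#'   defaults 300 and 0.01.
#' @param modules List of module specs, each a list with `size` (>= 3),
#'   `density` (internal edge fraction, default 1 = clique), `attach`
#'   (bridge edges to the background, default 2) and optionally `members`
#'   (explicit node names; auto-generated when absent). Explicit member
#'   sets must be pairwise disjoint.
#' @param seed Integer seed.
#' @return A list with `graph` (`igraph`) and `truth` (list of member
#'   vectors, one per module, in input order).
#' @export
gen_planted_modules <- function(n_background = 300L, p_background = 0.01,
                                modules = list(list(size = 8L),
                                               list(size = 7L),
                                               list(size = 6L)),
                                seed = 1L) {
  stopifnot(n_background >= 1L, p_background >= 0, p_background <= 1)
  sizes <- vapply(modules, function(m) as.integer(m$size), integer(1))
  if (any(sizes < 3L)) stop("module sizes must be >= 3")
  withr::with_seed(seed, {
    bg_names <- sprintf("B%04d", seq_len(n_background))
    g <- igraph::sample_gnp(n_background, p_background, directed = FALSE)
    igraph::V(g)$name <- bg_names
    truth <- vector("list", length(modules))
    for (i in seq_along(modules)) {
      spec <- modules[[i]]
      size <- as.integer(spec$size)
      density <- spec$density %||% 1
      attach <- as.integer(spec$attach %||% 2L)
      members <- spec$members %||% sprintf("M%d.%02d", i, seq_len(size))
      if (length(members) != size) stop("module ", i, ": members/size mismatch")
      truth[[i]] <- members
      g <- igraph::add_vertices(g, size, name = members)
      pairs <- utils::combn(members, 2L)
      if (density < 1) {
        n_int <- round(density * ncol(pairs))
        pairs <- pairs[, sample(ncol(pairs), n_int), drop = FALSE]
      }
      if (ncol(pairs))
        g <- igraph::add_edges(g, as.vector(pairs))
      if (attach > 0L) {
        anchors <- sample(members, attach, replace = TRUE)
        targets <- sample(bg_names, attach, replace = FALSE)
        g <- igraph::add_edges(g, as.vector(rbind(anchors, targets)))
      }
    }
    all_members <- unlist(truth)
    if (anyDuplicated(all_members))
      stop("planted module node sets overlap")
    g <- igraph::simplify(g)
    list(graph = g, truth = truth)
  })
}

#' Two-group expression matrix with planted differential expression
#'
#' Simulates a log2-scale two-group profile: per-gene baselines drawn from
#' Normal(7, 1), a planted fraction of genes shifted by `+lfc` (half) or
#' `-lfc` (half) in group 1, and i.i.d. Normal(0, sigma) noise. The
#' defaults (2000 genes, 10 vs 10 samples, 10% planted at |logFC| = 2,
#' sigma = 1) describe a clean two-group microarray comparison at typical
#' GEO cohort size.
#'
#' @param n_genes,n1,n2 Gene count and per-group sample sizes
#'   (`n1, n2 >= 2`).
#' @param de_fraction Fraction of genes differentially expressed.
#' @param lfc Planted absolute log2 fold change; `lfc = 0` plants nothing
#'   (an unshifted gene is not differentially expressed).
#' @param sigma Noise standard deviation.
#' @param seed Integer seed.
#' @return A list with `exprs` (matrix, genes x samples), `groups` (named
#'   character vector, `"tumor"` then `"normal"`), and `truth`
#'   (`data.frame` with `gene` and signed `lfc` for planted genes).
#' @export
gen_expression <- function(n_genes = 2000L, n1 = 10L, n2 = 10L,
                           de_fraction = 0.1, lfc = 2, sigma = 1, seed = 1L) {
  stopifnot(n_genes >= 1L, n1 >= 2L, n2 >= 2L,
            de_fraction >= 0, de_fraction <= 1, lfc >= 0, sigma >= 0)
  withr::with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    mu <- stats::rnorm(n_genes, 7, 1)
    n_de <- if (lfc == 0) 0L else round(de_fraction * n_genes)
    if (lfc > 0 && de_fraction > 0 && n_de < 1L) {
      warning("de_fraction * n_genes < 1: no gene planted")
      n_de <- 0L
    }
    delta <- numeric(n_genes)
    truth <- data.frame(gene = character(0), lfc = numeric(0))
    if (n_de > 0L) {
      idx <- sample(n_genes, n_de)
      n_up <- ceiling(n_de / 2)
      delta[idx[seq_len(n_up)]] <- lfc
      if (n_de > n_up) delta[idx[seq(n_up + 1L, n_de)]] <- -lfc
      truth <- data.frame(gene = genes[idx], lfc = delta[idx],
                          stringsAsFactors = FALSE)
    }
    samples <- c(sprintf("T%02d", seq_len(n1)), sprintf("N%02d", seq_len(n2)))
    exprs <- matrix(stats::rnorm(n_genes * (n1 + n2), sd = sigma),
                    nrow = n_genes,
                    dimnames = list(genes, samples))
    exprs <- exprs + mu
    exprs[, seq_len(n1)] <- exprs[, seq_len(n1)] + delta
    groups <- stats::setNames(c(rep("tumor", n1), rep("normal", n2)), samples)
    list(exprs = exprs, groups = groups, truth = truth)
  })
}

#' Overlapping pseudo-database target-set bundle
#'
#' Emulates the multi-database herb-target / multi-profile disease-gene
#' intersection design with exact ground truth. Each of `n_databases`
#' herb-target sets is the union of a shared core (fraction `overlap` of
#' the set size, common to all databases) and a database-specific block,
#' so the pairwise overlap is exactly the core. A designated shared subset
#' of the herb-target union is injected into every disease set; the
#' remaining disease genes are drawn outside the herb union, so
#' intersecting the herb union with the disease union recovers the shared
#' subset exactly.
#'
#' @param universe_size Symbol universe size (symbols `G00001`...).
#' @param n_databases,db_size Herb-target set count and size.
#' @param overlap Pairwise overlap fraction in \[0, 1\].
#' @param n_disease,disease_size Disease gene-set count and size.
#' @param shared_size Size of the planted herb-disease shared set.
#' @param seed Integer seed.
#' @return A list with `herb` (list of [gene_set()]), `disease` (list of
#'   `gene_set`), and `shared_truth` (sorted character vector).
#' @export
gen_target_sets <- function(universe_size = 2000L, n_databases = 4L,
                            db_size = 200L, overlap = 0.3,
                            n_disease = 2L, disease_size = 400L,
                            shared_size = 120L, seed = 1L) {
  stopifnot(db_size <= universe_size, overlap >= 0, overlap <= 1,
            n_databases >= 1L, n_disease >= 1L)
  core_size <- round(overlap * db_size)
  uniq_size <- db_size - core_size
  if (core_size + n_databases * uniq_size > universe_size)
    stop("infeasible overlap constraints: herb sets exceed the universe")
  withr::with_seed(seed, {
    universe <- sprintf("G%05d", seq_len(universe_size))
    pool <- sample(universe)
    core <- pool[seq_len(core_size)]
    if (core_size > 0L) pool <- pool[-seq_len(core_size)]
    herb <- vector("list", n_databases)
    for (i in seq_len(n_databases)) {
      uniq <- if (uniq_size > 0L) pool[seq_len(uniq_size)] else character(0)
      if (uniq_size > 0L) pool <- pool[-seq_len(uniq_size)]
      herb[[i]] <- gene_set(c(core, uniq), label = sprintf("DB%d", i))
    }
    herb_union <- sort(unique(unlist(lapply(herb, `[[`, "members"))))
    if (shared_size > length(herb_union))
      stop("shared_size exceeds the herb-target union")
    shared <- sort(sample(herb_union, shared_size))
    outside <- setdiff(universe, herb_union)
    extra_size <- disease_size - shared_size
    if (extra_size < 0L) stop("disease_size must be >= shared_size")
    if (n_disease * extra_size > length(outside))
      stop("infeasible overlap constraints: disease sets exceed the universe")
    disease <- vector("list", n_disease)
    for (i in seq_len(n_disease)) {
      extra <- if (extra_size > 0L) sample(outside, extra_size) else character(0)
      outside <- setdiff(outside, extra)
      disease[[i]] <- gene_set(c(shared, extra), label = sprintf("PROFILE%d", i))
    }
    list(herb = herb, disease = disease, shared_truth = shared)
  })
}

#' GMT collection with planted enriched terms
#'
#' Random gene-set terms over a universe plus planted terms built around
#' designated gene sets (e.g. a detected module), each padded with random
#' fillers. A query equal to a planted gene set makes its term the
#' optimum of the over-representation test.
#'
#' @param universe Character vector of background symbols.
#' @param n_terms Number of random terms, default 50.
#' @param size_range Two-element integer range of random-term sizes,
#'   default `c(10, 40)`; minimum 5.
#' @param planted List of gene vectors; one term `PLANTED01`, ... is built
#'   around each.
#' @param filler Extra random genes added to each planted term, default 5.
#' @param seed Integer seed.
#' @return A list with `collection` (format of [read_gmt()]) and `truth`
#'   (planted term IDs).
#' @export
gen_gmt <- function(universe, n_terms = 50L, size_range = c(10L, 40L),
                    planted = list(), filler = 5L, seed = 1L) {
  stopifnot(length(universe) >= max(size_range), min(size_range) >= 5L)
  withr::with_seed(seed, {
    collection <- list()
    for (i in seq_len(n_terms)) {
      sz <- sample(seq(size_range[1L], size_range[2L]), 1L)
      collection[[sprintf("T%04d", i)]] <-
        list(name = sprintf("random term %d", i),
             genes = sort(sample(universe, sz)))
    }
    truth <- character(0)
    for (i in seq_along(planted)) {
      id <- sprintf("PLANTED%02d", i)
      genes <- unique(as.character(planted[[i]]))
      pad <- sample(setdiff(universe, genes), filler)
      collection[[id]] <- list(name = sprintf("planted term %d", i),
                               genes = sort(unique(c(genes, pad))))
      truth <- c(truth, id)
    }
    list(collection = collection, truth = truth)
  })
}
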