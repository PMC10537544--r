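#' Write a complete synthetic input bundle for the pipeline
#'
#' Generates, and writes to disk, every input [run_pipeline()] needs, with
#' ground truth on the side: two two-group expression profiles with
#' planted differential expression, four pseudo-database herb-target lists
#' biased toward the planted DE genes (so the herb/disease intersection is
#' non-trivial), a confidence-scored interaction edge list consisting of a
#' scale-free backbone over the whole gene universe, a denser
#' disease-neighbourhood zone, and three planted cliques (sizes 8/7/6)
#' inside that zone, plus a GMT collection with one planted term per
#' clique. A ready-to-run `config.json` pointing at all the files is
#' written too.
#'
#' All randomness is driven by `seed` through per-generator derived seeds,
#' so a bundle is byte-reproducible and regenerating one component does
#' not perturb the others.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_genes Gene-universe size, default 2000.
#' @param n1,n2 Samples per group in each profile, default 10 and 10.
#' @param de_fraction,lfc,sigma Planted-DE parameters passed to
#'   [gen_expression()] (defaults 0.1, 2, 1).
#' @param db_size Herb-target set size per pseudo-database, default 200.
#' @param zone_size Size of the dense disease-neighbourhood zone,
#'   default 300.
#' @param zone_p Edge probability inside the zone, default 0.05 (dense
#'   enough for a connected shared-gene network, sparse enough that the
#'   planted cliques stay locally densest).
#' @return Invisibly, a list with `config` (path of `config.json`) and
#'   `truth` (planted DE tables, clique node sets, planted GMT term IDs).
#' @export
simulate_bundle <- function(out_dir, seed = 42L, n_genes = 2000L,
                            n1 = 10L, n2 = 10L, de_fraction = 0.1,
                            lfc = 2, sigma = 1, db_size = 200L,
                            zone_size = 300L, zone_p = 0.05) {
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE, recursive = TRUE)
  genes <- sprintf("G%05d", seq_len(n_genes))

  ## expression profiles ------------------------------------------------
  profiles <- list()
  truth_de <- list()
  for (i in 1:2) {
    sim <- gen_expression(n_genes = n_genes, n1 = n1, n2 = n2,
                          de_fraction = de_fraction, lfc = lfc,
                          sigma = sigma, seed = seed + i)
    expr_path <- file.path(out_dir, sprintf("expr_profile%d.tsv", i))
    grp_path <- file.path(out_dir, sprintf("groups_profile%d.tsv", i))
    write_expression(sim$exprs, expr_path)
    utils::write.table(
      data.frame(sample = names(sim$groups), group = unname(sim$groups)),
      grp_path, sep = "\t", quote = FALSE, row.names = FALSE)
    profiles[[i]] <- list(expr = expr_path, groups = grp_path)
    truth_de[[i]] <- sim$truth
    jsonlite::write_json(sim$truth,
                         file.path(out_dir, "truth",
                                   sprintf("de_profile%d.json", i)),
                         digits = NA)
  }
  # Re-run the screening exactly as the pipeline will (normalization
  # attenuates the planted fold changes, so the planted truth is NOT the
  # recovered DEG set) to learn which genes will reach the network stage;
  # cliques planted outside that set could never be detected downstream.
  recovered <- lapply(profiles, function(pr) {
    m <- quantile_normalize(read_expression(pr$expr))
    grp <- read_groups(pr$groups)[colnames(m)]
    sets <- filter_degs(differential_expression(m, grp))
    c(sets$up, sets$down)
  })
  deg_union <- sort(unique(unlist(recovered)))

  ## herb-target pseudo-databases ---------------------------------------
  target_paths <- character(4)
  db_sets <- withr::with_seed(seed + 10L, {
    lapply(1:4, function(i) {
      n_de_part <- min(round(db_size / 2), length(deg_union))
      c(sample(deg_union, n_de_part),
        sample(setdiff(genes, deg_union), db_size - n_de_part))
    })
  })
  for (i in 1:4) {
    target_paths[i] <- file.path(out_dir, sprintf("targets_db%d.txt", i))
    write_gene_list(sort(db_sets[[i]]), target_paths[i])
  }

  ## interaction edge list ----------------------------------------------
  # the dense zone covers the genes that will end up in the shared set
  candidate_shared <- intersect(sort(unique(unlist(db_sets))), deg_union)
  zone <- withr::with_seed(seed + 20L, {
    extra <- setdiff(genes, candidate_shared)
    c(candidate_shared, sample(extra, max(0L, zone_size - length(candidate_shared))))
  })
  cliques <- withr::with_seed(seed + 21L, {
    pool <- sample(candidate_shared)
    list(pool[1:8], pool[9:15], pool[16:21])
  })
  edges <- withr::with_seed(seed + 22L, {
    backbone <- gen_scale_free(n_genes, 2L, seed = seed + 23L)
    be <- igraph::as_edgelist(backbone, names = FALSE)
    d <- data.frame(a = genes[be[, 1L]], b = genes[be[, 2L]],
                    conf = stats::runif(nrow(be), 0.85, 1),
                    stringsAsFactors = FALSE)
    zg <- igraph::sample_gnp(length(zone), zone_p, directed = FALSE)
    ze <- igraph::as_edgelist(zg, names = FALSE)
    d <- rbind(d, data.frame(a = zone[ze[, 1L]], b = zone[ze[, 2L]],
                             conf = stats::runif(nrow(ze), 0.9, 1)))
    for (cl in cliques) {
      pairs <- utils::combn(cl, 2L)
      d <- rbind(d, data.frame(a = pairs[1L, ], b = pairs[2L, ],
                               conf = stats::runif(ncol(pairs), 0.95, 1)))
    }
    d
  })
  edges_path <- file.path(out_dir, "edges.tsv")
  utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(cliques, file.path(out_dir, "truth", "cliques.json"))

  ## GMT collection -----------------------------------------------------
  gmt <- gen_gmt(genes, n_terms = 60L, size_range = c(10L, 40L),
                 planted = cliques, seed = seed + 30L)
  gmt_path <- file.path(out_dir, "sets.gmt")
  write_gmt(gmt$collection, gmt_path)
  jsonlite::write_json(gmt$truth, file.path(out_dir, "truth", "gmt_terms.json"))

  ## config ------------------------------------------------------------
  config <- list(
    profiles = profiles,
    targets = as.list(target_paths),
    edges = edges_path,
    edges_header = FALSE,
    min_confidence = 0.9,
    scale = "unit",
    gmt = gmt_path,
    out_dir = file.path(out_dir, "results")
  )
  config_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(config = config_path,
                 truth = list(de = truth_de, cliques = cliques,
                              gmt_terms = gmt$truth)))
}
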