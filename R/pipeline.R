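# Abort with the stage name so a failed run names the offending step.
pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# Small deterministic polynomial hash of the serialized config (no
# cryptographic intent; just a run fingerprint for the manifest).
config_hash <- function(cfg) {
  s <- as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%010d", h)
}

default_config <- function() {
  list(
    profiles = list(),
    targets = character(0),
    edges = NULL,
    edges_header = FALSE,
    min_confidence = 0.9,
    scale = "unit",
    deg = list(p_cut = 0.05, lfc_cut = 0.5, variance_floor = 1e-8),
    filter = list(passes = 2L, lcc_only = TRUE),
    hubs = list(k = 10L),
    mcode = list(degree_cutoff = 2L, node_score_cutoff = 0.2,
                 kcore_filter = 2L, haircut = TRUE, fluff = FALSE,
                 min_score = 5),
    enrich = list(adj_p_cut = 0.05, q_cut = 0.05, top_n = 10L),
    gmt = NULL,
    out_dir = "netmod_out"
  )
}

merge_config <- function(cfg) {
  base <- default_config()
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) && is.list(cfg[[nm]])) {
      for (sub in names(cfg[[nm]])) base[[nm]][[sub]] <- cfg[[nm]][[sub]]
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base
}

#' Run the full network-module analysis pipeline
#'
#' Orchestrates every stage from one configuration: per-profile DEG
#' screening (quantile normalization, optional probe collapse, Welch
#' testing, thresholding), target/disease set integration, construction of
#' the interaction network from a confidence-thresholded edge list,
#' topology characterisation (summary metrics, degree distribution and
#' power-law fit, path-length distribution), two-pass median-centrality
#' filtering into the critical network, triple-centrality hub selection,
#' MCODE module detection, and per-module over-representation analysis.
#' Every intermediate artifact is written under `out_dir` along with a
#' `manifest.json` recording per-stage counts, so the run can be audited
#' or resumed from any midpoint. The pipeline itself is deterministic:
#' identical config and inputs give an identical manifest.
#'
#' @param config Either a named list or the path of a JSON file. Fields
#'   (all optional except `edges` plus either `profiles` or pre-screened
#'   disease lists in `disease_lists`): `profiles` — list of
#'   `list(expr=, groups=, probe_map=)` paths; `targets` — herb-target
#'   list files; `disease_lists` — gene-list files used instead of
#'   screening; `edges`, `edges_header`, `min_confidence`, `scale`;
#'   `deg`, `filter`, `hubs`, `mcode`, `enrich` parameter blocks;
#'   `gmt`; `out_dir`.
#' @return The manifest, invisibly, as a named list.
#' @seealso [simulate_bundle()] for a self-contained synthetic input set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  cfg <- merge_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "netmod",
    version = as.character(utils::packageVersion("netmod")),
    config_hash = config_hash(cfg)
  )

  ## 1. screening -----------------------------------------------------
  disease_sets <- list()
  screen_counts <- list()
  if (length(cfg$profiles)) {
    disease_sets <- pipeline_stage("screening", {
      lapply(seq_along(cfg$profiles), function(i) {
        pr <- cfg$profiles[[i]]
        m <- read_expression(pr$expr)
        grp <- read_groups(pr$groups)
        if (!all(colnames(m) %in% names(grp)))
          stop("profile ", i, ": samples missing from groups file")
        grp <- grp[colnames(m)]
        m <- quantile_normalize(m)
        if (!is.null(pr$probe_map))
          m <- collapse_probes(m, read_probe_map(pr$probe_map))
        deg <- differential_expression(m, grp,
                                       p_cut = cfg$deg$p_cut,
                                       lfc_cut = cfg$deg$lfc_cut,
                                       variance_floor = cfg$deg$variance_floor)
        utils::write.table(deg, file.path(out, sprintf("degs_profile%d.tsv", i)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        sets <- filter_degs(deg, cfg$deg$p_cut, cfg$deg$lfc_cut)
        screen_counts[[i]] <<- list(n_genes = nrow(deg),
                                    n_up = length(sets$up),
                                    n_down = length(sets$down))
        gene_set(c(sets$up, sets$down), label = sprintf("PROFILE%d", i))
      })
    })
  }
  if (!is.null(cfg$disease_lists)) {
    disease_sets <- c(disease_sets, pipeline_stage("screening", {
      lapply(cfg$disease_lists, function(p)
        gene_set(read_gene_list(p), label = basename(p)))
    }))
  }
  manifest$screening <- screen_counts

  ## 2. integration ---------------------------------------------------
  shared <- pipeline_stage("integration", {
    if (length(cfg$targets) == 0L) stop("no target list configured")
    if (length(disease_sets) == 0L) stop("no disease gene source configured")
    target_sets <- lapply(cfg$targets, function(p)
      gene_set(read_gene_list(p), label = basename(p)))
    t_union <- union_sets(target_sets)
    d_union <- union_sets(disease_sets)
    shared <- intersect_sets(t_union, d_union)
    write_gene_list(shared$members, file.path(out, "shared_genes.txt"))
    utils::write.table(membership_table(c(target_sets, disease_sets)),
                       file.path(out, "set_membership.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$integration <- list(
      per_target_set = lapply(target_sets, function(s)
        list(label = s$label, size = length(s$members))),
      per_disease_set = lapply(disease_sets, function(s)
        list(label = s$label, size = length(s$members))),
      target_union = length(t_union$members),
      disease_union = length(d_union$members),
      shared = length(shared$members))
    shared
  })

  ## 3. interaction network -------------------------------------------
  pin <- pipeline_stage("pin", {
    if (is.null(cfg$edges)) stop("no edge list configured")
    bg <- read_edge_list(cfg$edges, min_confidence = cfg$min_confidence,
                         scale = cfg$scale, header = cfg$edges_header)
    pin <- suppressWarnings(induce_network(bg, shared$members, lcc_only = TRUE))
    write_edge_list(pin, file.path(out, "pin_edges.tsv"))
    manifest$pin <- list(background_nodes = igraph::vcount(bg),
                          background_edges = igraph::ecount(bg),
                          n_nodes = igraph::vcount(pin),
                          n_edges = igraph::ecount(pin))
    pin
  })

  ## 4. topology ------------------------------------------------------
  pipeline_stage("topology", {
    ts <- suppressWarnings(topology_summary(pin))
    write_topology_summary(ts, file.path(out, "pin_summary.tsv"))
    dd <- degree_distribution(pin)
    utils::write.table(dd, file.path(out, "pin_degree_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fit <- tryCatch(fit_power_law(dd), error = function(e) NULL)
    pld <- suppressWarnings(path_length_distribution(pin))
    utils::write.table(pld, file.path(out, "pin_path_lengths.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$topology <- list(
      summary = unclass(ts),
      power_law = if (is.null(fit)) "not fitted (too few degree classes)"
                  else unclass(fit))
  })

  ## 5. critical network ----------------------------------------------
  critical <- pipeline_stage("critical_pin", {
    res <- withCallingHandlers(
      build_critical_pin(pin, passes = cfg$filter$passes,
                         lcc_only = cfg$filter$lcc_only),
      warning = function(w) invokeRestart("muffleWarning"))
    write_edge_list(res$graph, file.path(out, "critical_edges.tsv"))
    utils::write.table(res$report, file.path(out, "critical_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cts <- suppressWarnings(topology_summary(res$graph))
    write_topology_summary(cts, file.path(out, "critical_summary.tsv"))
    manifest$critical_pin <- list(
      n_nodes = igraph::vcount(res$graph),
      n_edges = igraph::ecount(res$graph),
      passes_completed = nrow(res$report),
      summary = unclass(cts))
    res$graph
  })

  ## 6. hubs ----------------------------------------------------------
  hubs <- pipeline_stage("hubs", {
    k <- min(cfg$hubs$k, igraph::vcount(critical))
    hubs <- suppressMessages(select_hubs(critical, k = k))
    write_gene_list(hubs, file.path(out, "hub_genes.txt"))
    manifest$hubs <- list(k = k, hubs = hubs)
    hubs
  })

  ## 7. modules -------------------------------------------------------
  modules <- pipeline_stage("mcode", {
    mods <- mcode(critical,
                  degree_cutoff = cfg$mcode$degree_cutoff,
                  node_score_cutoff = cfg$mcode$node_score_cutoff,
                  kcore_filter = cfg$mcode$kcore_filter,
                  haircut = cfg$mcode$haircut,
                  fluff = cfg$mcode$fluff,
                  min_score = cfg$mcode$min_score)
    utils::write.table(module_table(mods), file.path(out, "modules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (m in mods)
      write_gene_list(m$members,
                      file.path(out, sprintf("module_%d_genes.txt", m$rank)))
    manifest$mcode <- list(
      n_modules = length(mods),
      modules = lapply(mods, function(m)
        list(rank = m$rank, score = m$score, n = m$n, seed = m$seed)))
    mods
  })

  ## 8. enrichment ----------------------------------------------------
  if (!is.null(cfg$gmt) && length(modules)) {
    pipeline_stage("enrichment", {
      collection <- read_gmt(cfg$gmt)
      enr <- lapply(modules, function(m) {
        tab <- tryCatch(
          ora(m$members, collection,
              adj_p_cut = cfg$enrich$adj_p_cut, q_cut = cfg$enrich$q_cut,
              top_n = cfg$enrich$top_n),
          error = function(e) {
            message("module ", m$rank, ": ", conditionMessage(e))
            NULL
          })
        if (!is.null(tab))
          utils::write.table(tab,
                             file.path(out, sprintf("enrichment_module_%d.tsv", m$rank)),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        list(rank = m$rank,
             n_terms_passing = if (is.null(tab)) 0L else nrow(tab),
             top_term = if (!is.null(tab) && nrow(tab)) tab$term_id[1L] else NA)
      })
      manifest$enrichment <- enr
    })
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
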