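k_named <- function(n, prefix) {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}

test_that("vertex weights match hand computations on cliques and stars", {
  w <- mcode_vertex_weights(k_named(5, "v"))
  expect_equal(unname(w), rep(4, 5)) # closed neighborhood K5: core 4, density 1

  star <- named_graph(c("C", "L1", "C", "L2", "C", "L3", "C", "L4"))
  w <- mcode_vertex_weights(star)
  expect_equal(w[["C"]], 0.4) # 1-core is the whole star, density 4/10
  expect_equal(unname(w[paste0("L", 1:4)]), rep(0, 4)) # degree 1 < cutoff 2
})

test_that("vertex weights equal the prune-based k-core oracle on small graphs", {
  for (seed in 1:8) {
    g <- random_named_graph(sample(5:9, 1), stats::runif(1, 0.3, 0.7), seed = 100 + seed)
    A <- adj_matrix(g)
    expect_equal(mcode_vertex_weights(g), oracle_mcode_weights(A),
                 tolerance = 1e-12)
    # igraph coreness itself vs repeated pruning
    expect_equal(unname(igraph::coreness(g)), unname(oracle_coreness(A)))
  }
})

test_that("complex prediction grows from the densest seeds", {
  k5 <- k_named(5, "v")
  w <- mcode_vertex_weights(k5)
  cx <- mcode_find_complexes(k5, w)
  expect_length(cx, 1L)
  expect_setequal(cx[[1]]$members, paste0("v", 1:5))
  expect_equal(cx[[1]]$score, 5) # density 1 x 5 nodes

  # Two 5-cliques joined by one edge: every vertex's closed neighbourhood
  # still contains its full 4-core, so both bridge endpoints keep weight
  # 4.0 and the greedy expansion walks across the bridge — the two
  # cliques merge into a single complex. (Post-processing, not
  # prediction, is what trims such bridges.)
  g <- igraph::disjoint_union(k_named(5, "a"), k_named(5, "b"))
  g <- igraph::add_edges(g, c("a1", "b1"))
  w <- mcode_vertex_weights(g)
  expect_equal(unname(w), rep(4, 10))
  cx <- mcode_find_complexes(g, w)
  expect_length(cx, 1L)
  expect_setequal(cx[[1]]$members, c(paste0("a", 1:5), paste0("b", 1:5)))
})

test_that("complex prediction matches an independent greedy reference trace", {
  for (seed in 1:6) {
    g <- random_named_graph(sample(6:9, 1), 0.45, seed = 200 + seed)
    A <- adj_matrix(g)
    # once with real weights, once with arbitrary distinct weights
    for (w in list(mcode_vertex_weights(g),
                   withr::with_seed(seed, setNames(sample(seq_len(nrow(A))), rownames(A))))) {
      got <- lapply(mcode_find_complexes(g, w), `[[`, "members")
      expect_identical(got, oracle_mcode_complexes(A, w))
    }
  }
})

test_that("post-processing discards coreless complexes and trims pendants", {
  # 4-clique with a pendant: haircut removes the pendant
  g <- igraph::add_edges(k_named(4, "v") + igraph::vertices("p"), c("v1", "p"))
  mod <- list(list(seed = "v1", members = sort(igraph::V(g)$name), n = 5,
                   density = 7 / 10, score = 3.5))
  out <- mcode_postprocess(mod, g, haircut = TRUE)
  expect_setequal(out[[1]]$members, paste0("v", 1:4))
  expect_equal(out[[1]]$density, 1)
  expect_equal(out[[1]]$score, 4)

  # a tree has no 2-core: discarded
  tree <- named_graph(c("A", "B", "B", "C", "B", "D"))
  modt <- list(list(seed = "B", members = c("A", "B", "C", "D"), n = 4,
                    density = 0.5, score = 2))
  expect_length(mcode_postprocess(modt, tree), 0L)

  # haircut is a fixed point on a 2-core module
  k4 <- k_named(4, "v")
  mod4 <- list(list(seed = "v1", members = paste0("v", 1:4), n = 4,
                    density = 1, score = 4))
  out4 <- mcode_postprocess(mod4, k4)
  expect_setequal(out4[[1]]$members, paste0("v", 1:4))
})

test_that("ranking keeps strictly-above-threshold scores in score order", {
  mods <- list(
    list(seed = "a", members = paste0("a", 1:5), n = 5, density = 1, score = 5),
    list(seed = "b", members = paste0("b", 1:6), n = 6, density = 1, score = 6))
  kept <- mcode_rank_and_filter(mods, min_score = 5)
  expect_length(kept, 1L) # score 5.0 fails strict > 5
  expect_identical(kept[[1]]$seed, "b")
  expect_equal(kept[[1]]$rank, 1L)
})

test_that("modules are disjoint, connected, 2-cored, with self-consistent scores", {
  g <- gen_planted_modules(seed = 8)$graph
  mods <- mcode(g, min_score = 0)
  all_members <- unlist(lapply(mods, `[[`, "members"))
  expect_identical(anyDuplicated(all_members), 0L)
  for (m in mods) {
    sub <- igraph::induced_subgraph(g, m$members)
    expect_true(igraph::is_connected(sub))
    expect_gte(max(igraph::coreness(sub)), 2)
    # score recomputed independently from the member edge list
    dens <- 2 * igraph::ecount(sub) / (m$n * (m$n - 1))
    expect_equal(m$score, dens * m$n, tolerance = 1e-12)
  }
})

test_that("lowering the node score cutoff never grows a complex", {
  g <- gen_planted_modules(seed = 5)$graph
  w <- mcode_vertex_weights(g)
  hi <- mcode_find_complexes(g, w, node_score_cutoff = 0.2)
  lo <- mcode_find_complexes(g, w, node_score_cutoff = 0.05)
  seeds_hi <- vapply(hi, `[[`, "", "seed")
  shared <- vapply(lo, `[[`, "", "seed")
  shared <- shared[shared %in% seeds_hi]
  expect_gt(length(shared), 0)
  for (cx in lo) {
    i <- match(cx$seed, seeds_hi)
    if (!is.na(i)) expect_lte(cx$n, hi[[i]]$n)
  }
})

test_that("module detection is equivariant under node relabeling", {
  for (seed in c(3, 12)) {
    g <- random_named_graph(9, 0.5, seed = 300 + seed)
    mods <- mcode(g, min_score = 0)
    perm <- withr::with_seed(seed, sample(igraph::vcount(g)))
    relabel <- setNames(sprintf("w%02d", perm), igraph::V(g)$name)
    g2 <- g
    igraph::V(g2)$name <- unname(relabel[igraph::V(g)$name])
    mods2 <- mcode(g2, min_score = 0)
    canon <- function(ms, map = NULL) {
      sets <- lapply(ms, function(m) {
        mem <- m$members
        if (!is.null(map)) mem <- unname(map[mem])
        sort(mem)
      })
      sets[order(vapply(sets, paste, "", collapse = ","))]
    }
    expect_identical(canon(mods2), canon(mods, relabel))
  }
})
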