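test_that("read_edge_list applies threshold, self-loop, scaling and dedup rules", {
  f <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("A\tB\t0.95", "B\tC\t0.85", "C\tC\t0.99"), f)
  g <- read_edge_list(f, min_confidence = 0.9)
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_equal(igraph::ecount(g), 1L)

  writeLines("A\tB\t950", f)
  g <- read_edge_list(f, min_confidence = 0.9, scale = "string1000")
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$confidence, 0.95)

  # duplicate pair in either orientation keeps the max confidence
  writeLines(c("A\tB\t0.91", "B\tA\t0.93"), f)
  g <- read_edge_list(f, min_confidence = 0.9)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$confidence, 0.93)

  # two-column files keep everything
  writeLines(c("A\tB", "B\tC"), f)
  expect_equal(igraph::ecount(read_edge_list(f)), 2L)
})

test_that("read_edge_list rejects malformed input with the line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.95", "B\tC"), f)
  expect_error(read_edge_list(f), "line 2")
  writeLines(c("A\tB\t0.95", "B\tC\t1.7"), f)
  expect_error(read_edge_list(f), "line 2.*outside")
  writeLines("A\tB\tsure", f)
  expect_error(read_edge_list(f), "non-numeric")
  expect_error(read_edge_list(tempfile()), "not found")
})

test_that("write_edge_list / read_edge_list round-trips the edge set", {
  g <- gen_scale_free(40, 2, seed = 5)
  igraph::E(g)$confidence <- withr::with_seed(5, stats::runif(igraph::ecount(g), 0.9, 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, f)
  g2 <- read_edge_list(f, min_confidence = 0)
  key <- function(gr) {
    e <- igraph::as_edgelist(gr)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(key(g2), key(g))
  expect_equal(sort(igraph::E(g2)$confidence), sort(igraph::E(g)$confidence))
})

test_that("induce_network restricts to kept symbols and the LCC on request", {
  p3 <- named_graph(c("A", "B", "B", "C"))
  s <- induce_network(p3, c("A", "C"))
  expect_setequal(igraph::V(s)$name, c("A", "C"))
  expect_equal(igraph::ecount(s), 0L)
  s <- induce_network(p3, c("A", "C"), lcc_only = TRUE)
  expect_identical(igraph::V(s)$name, "A") # tie broken lexicographically

  tri <- named_graph(c("A", "B", "B", "C", "A", "C"))
  expect_warning(s <- induce_network(tri, c("A", "B", "C", "Z")), "Z")
  expect_equal(igraph::ecount(s), 3L)

  # two triangles bridged by C-D, drop D
  g <- named_graph(c("A", "B", "B", "C", "A", "C", "D", "E", "E", "F", "D", "F", "C", "D"))
  s <- induce_network(g, setdiff(igraph::V(g)$name, "D"))
  expect_equal(igraph::vcount(s), 5L)
  expect_equal(igraph::ecount(s), 4L) # triangle ABC + edge E-F
  s <- induce_network(g, setdiff(igraph::V(g)$name, "D"), lcc_only = TRUE)
  expect_setequal(igraph::V(s)$name, c("A", "B", "C"))

  expect_error(suppressWarnings(induce_network(tri, "NOPE")), "degenerate")
})

test_that("centralities match hand values on star and complete graphs", {
  star <- named_graph(c("C", "L1", "C", "L2", "C", "L3", "C", "L4"))
  ct <- centrality_table(star)
  hub <- ct[ct$node == "C", ]
  expect_equal(hub$degree, 4L)
  expect_equal(hub$betweenness, 1)
  expect_equal(hub$closeness, 1)
  leaves <- ct[ct$node != "C", ]
  expect_true(all(leaves$degree == 1L))
  expect_true(all(leaves$betweenness == 0))
  expect_equal(leaves$closeness, rep(4 / 7, 4)) # distances 1,2,2,2

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- LETTERS[1:4]
  ct <- centrality_table(k4)
  expect_true(all(ct$betweenness == 0))
  expect_true(all(ct$closeness == 1))
})

test_that("centralities equal the exhaustive shortest-path oracle on small graphs", {
  for (seed in 1:10) {
    g <- random_named_graph(sample(4:8, 1), stats::runif(1, 0.2, 0.7), seed = seed)
    A <- adj_matrix(g)
    ct <- centrality_table(g)
    expect_equal(ct$degree, unname(rowSums(A)))
    expect_equal(ct$closeness, unname(oracle_closeness(A)), tolerance = 1e-12)
    expect_lt(max(abs(ct$betweenness - oracle_betweenness(A))), 1e-9)
  }
})

test_that("topology summary matches closed forms on canonical graphs", {
  tri <- named_graph(c("A", "B", "B", "C", "A", "C"))
  ts <- topology_summary(tri)
  expect_equal(ts$clustering_coefficient, 1)
  expect_equal(ts$diameter, 1L)
  expect_equal(ts$radius, 1L)
  expect_equal(ts$shortest_path_count, 6)
  expect_equal(ts$characteristic_path_length, 1)
  expect_equal(ts$heterogeneity, 0)

  s6 <- igraph::make_star(6, mode = "undirected")
  igraph::V(s6)$name <- paste0("n", 1:6)
  expect_equal(topology_summary(s6)$centralization, 1) # (6/4)*(1 - 2/6)

  # connected => ordered finite pairs n(n-1), path length >= 1
  g <- gen_scale_free(120, 2, seed = 9)
  ts <- topology_summary(g)
  expect_equal(ts$shortest_path_count, 120 * 119)
  expect_gte(ts$characteristic_path_length, 1)
  expect_gte(ts$radius, 1L)
  expect_lte(ts$radius, ts$diameter)

  expect_warning(topology_summary(named_graph(c("A", "B"))), "centralization")
})

test_that("degree histogram matches direct per-node counting", {
  expect_equal(degree_distribution(named_graph(c("A", "B", "B", "C"))),
               data.frame(k = c(1L, 2L), count = c(2L, 1L)))
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- LETTERS[1:4]
  expect_equal(degree_distribution(k4), data.frame(k = 3L, count = 4L))

  g <- random_named_graph(100, 0.05, seed = 3)
  d <- degree_distribution(g)
  deg <- rowSums(adj_matrix(g))
  for (i in seq_len(nrow(d)))
    expect_equal(d$count[i], sum(deg == d$k[i]))
  expect_equal(sum(d$count), sum(deg >= 1))
  expect_true(all(diff(d$k) > 0))

  iso <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(iso)$name <- c("A", "B", "C")
  expect_error(degree_distribution(iso), "isolated")
})

test_that("power-law fit recovers exact log-linear data and is scale-equivariant", {
  d <- data.frame(k = 1:10, count = 100 * (1:10)^-2)
  fit <- fit_power_law(d)
  expect_equal(fit$a, 100, tolerance = 1e-9)
  expect_equal(fit$gamma, 2, tolerance = 1e-9)
  expect_equal(fit$r2_log, 1, tolerance = 1e-9)

  flat <- fit_power_law(data.frame(k = 1:5, count = rep(50, 5)))
  expect_equal(flat$gamma, 0, tolerance = 1e-12)

  # scaling all counts leaves gamma unchanged, scales a
  d2 <- transform(d, count = count * 7)
  fit2 <- fit_power_law(d2)
  expect_equal(fit2$gamma, fit$gamma, tolerance = 1e-9)
  expect_equal(fit2$a, 7 * fit$a, tolerance = 1e-6)

  expect_error(fit_power_law(data.frame(k = 1:2, count = c(3, 1))), ">= 3")
})

test_that("path-length distribution matches BFS enumeration and the summary count", {
  tri <- named_graph(c("A", "B", "B", "C", "A", "C"))
  expect_equal(path_length_distribution(tri),
               data.frame(distance = 1L, count = 6L))

  p4 <- named_graph(c("A", "B", "B", "C", "C", "D"))
  expect_equal(path_length_distribution(p4),
               data.frame(distance = 1:3, count = c(6L, 4L, 2L)))

  for (seed in 11:16) {
    g <- random_named_graph(sample(5:8, 1), 0.5, seed = seed)
    g <- largest_comp_for_test(g)
    D <- oracle_distances(adj_matrix(g))
    finite <- D[is.finite(D) & D > 0]
    pld <- path_length_distribution(g)
    expect_equal(sum(pld$count), length(finite))
    for (i in seq_len(nrow(pld)))
      expect_equal(pld$count[i], sum(finite == pld$distance[i]))
    expect_equal(sum(pld$count), topology_summary(g)$shortest_path_count)
  }
})
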