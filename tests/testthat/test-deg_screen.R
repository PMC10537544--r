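test_that("quantile normalization maps columns onto the rank-mean distribution", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))

  # identical columns are unchanged
  m2 <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(m2), m2)

  # columns share the sorted vector afterwards, and the map is idempotent
  m3 <- withr::with_seed(1, matrix(rnorm(60), 10, 6,
                                   dimnames = list(paste0("g", 1:10), paste0("s", 1:6))))
  out3 <- quantile_normalize(m3)
  sorted <- apply(out3, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_equal(quantile_normalize(out3), out3, tolerance = 1e-12)

  expect_warning(quantile_normalize(m3[, 1, drop = FALSE]), "single-sample")
})

test_that("probe collapse drops ambiguous probes and keeps the strongest per gene", {
  m <- rbind(p1 = c(5, 5, 5, 5), p2 = c(7, 7, 7, 7), p3 = c(9, 9, 9, 9))
  colnames(m) <- paste0("s", 1:4)
  pm <- list(p1 = "A", p2 = "A", p3 = c("A", "B"))
  out <- collapse_probes(m, pm)
  expect_identical(rownames(out), "A")
  expect_equal(unname(out["A", ]), rep(7, 4)) # p2 wins; multi-gene p3 dropped

  # ties go to the lexicographically smallest probe
  m2 <- rbind(pa = c(5, 5), pb = c(5, 5))
  colnames(m2) <- c("s1", "s2")
  out2 <- collapse_probes(m2, list(pb = "G", pa = "G"))
  expect_equal(unname(out2["G", ]), c(5, 5))

  # single-probe genes pass through; unmapped probes are dropped
  out3 <- collapse_probes(m, list(p1 = "A", p2 = "B", p3 = character(0)))
  expect_setequal(rownames(out3), c("A", "B"))

  expect_error(collapse_probes(m, list(p1 = character(0))), "no probe")
})

test_that("Welch test with variance floor reproduces the closed form", {
  m <- rbind(g1 = c(1, 2, 3, 3, 4, 5))
  colnames(m) <- paste0("s", 1:6)
  grp <- c("tumor", "tumor", "tumor", "normal", "normal", "normal")
  res <- differential_expression(m, grp)
  expect_equal(res$logFC, -2)
  expect_equal(res$t, -sqrt(6), tolerance = 1e-12) # -2 / sqrt(1/3 + 1/3)
  expect_equal(res$df, 4, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-sqrt(6), 4), tolerance = 1e-12)
  expect_equal(res$p, 0.0705, tolerance = 1e-3)

  # identical groups: zero variance hits the floor, p = 1
  m0 <- rbind(gz = rep(4, 6))
  colnames(m0) <- paste0("s", 1:6)
  res0 <- differential_expression(m0, grp)
  expect_equal(res0$logFC, 0)
  expect_equal(res0$p, 1)
  expect_identical(res0$direction, "ns")

  expect_error(differential_expression(m, c("a", "a", "a", "a", "a", "b")),
               ">= 2 samples")
})

test_that("BH adjustment within the DEG table behaves as the step-up procedure", {
  sim <- gen_expression(n_genes = 300, seed = 13)
  res <- differential_expression(sim$exprs, sim$groups)
  expect_equal(res$adj_p, p.adjust(res$p, "BH"))
  expect_true(all(res$adj_p >= res$p))
  # known hand value of the step-up rule
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
})

test_that("threshold rule splits DEGs into disjoint up and down sets", {
  deg <- data.frame(
    gene = c("U", "D", "WEAK", "FLAT"),
    logFC = c(0.6, -0.6, 0.4, 0.0),
    adj_p = c(0.01, 0.01, 0.001, 0.9))
  sets <- filter_degs(deg)
  expect_identical(sets$up, "U")
  expect_identical(sets$down, "D")
  expect_length(intersect(sets$up, sets$down), 0)

  sim <- gen_expression(n_genes = 500, seed = 21)
  res <- differential_expression(sim$exprs, sim$groups)
  sets <- filter_degs(res)
  expect_length(intersect(sets$up, sets$down), 0)
  expect_setequal(c(sets$up, sets$down), res$gene[res$direction != "ns"])
})

test_that("expression, groups and probe-map files round-trip", {
  sim <- gen_expression(n_genes = 20, n1 = 3, n2 = 3, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(sim$exprs, f)
  expect_equal(read_expression(f), sim$exprs, tolerance = 1e-12)

  gf <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(sample = names(sim$groups), group = sim$groups),
                     gf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_groups(gf), sim$groups)

  pf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\tA", "p2\tA,B"), pf)
  expect_equal(read_probe_map(pf), list(p1 = "A", p2 = c("A", "B")))
})
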