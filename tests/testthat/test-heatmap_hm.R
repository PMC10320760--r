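test_that("heatmap cells average the 20-member context groups", {
  # constant EF: every cell equals the constant
  efc <- ef_table(enumerate_cxxx(), rep(2.5, 8000))
  hm <- build_heatmap(efc, "a1a2")
  expect_equal(range(hm$cells), c(2.5, 2.5))
  # planted a2 = K depression shows up in the a2 rows/columns
  ef <- ef_table(enumerate_cxxx(), ifelse(substr(enumerate_cxxx(), 3, 3) == "K",
                                          0.1, 2.0))
  h12 <- build_heatmap(ef, "a1a2")
  k <- match("K", AA_ALPHABET20)
  expect_equal(unname(h12$cells[, k]), rep(0.1, 20))
  expect_true(all(h12$cells[, -k] == 2.0))
  h2x <- build_heatmap(ef, "a2x")
  expect_equal(unname(h2x$cells[k, ]), rep(0.1, 20))
  # direct group-averaging oracle on a heterogeneous table
  efr <- random_ef_table(21)
  h <- build_heatmap(efr, "a1x")
  for (cell in list(c("A", "Q"), c("K", "K"), c("W", "C"))) {
    keep <- efr$a1 == cell[1] & efr$x == cell[2]
    expect_equal(h$cells[match(cell[1], AA_ALPHABET20),
                         match(cell[2], AA_ALPHABET20)],
                 mean(efr$ef[keep]))
    expect_equal(sum(keep), 20L)
  }
})

test_that("an incomplete EF table is rejected with the missing motif named", {
  ef <- random_ef_table(22)
  sub <- ef[ef$motif != "CAAA", ]
  class(sub) <- class(ef)
  expect_error(build_heatmap(sub, "a1a2"), "CAAA")
})

test_that("each heatmap partitions the space: 400-cell mean = grand mean", {
  ef <- random_ef_table(23)
  hms <- build_heatmaps(ef)
  for (p in names(hms)) {
    expect_lt(abs(mean(hms[[p]]$cells) - mean(ef$ef)), 1e-9)
    expect_equal(dim(hms[[p]]$cells), c(20L, 20L))
  }
})

test_that("pattern detection is silent on flat and null heatmaps", {
  efc <- ef_table(enumerate_cxxx(), rep(1.7, 8000))
  hm <- build_heatmap(efc, "a2x")
  expect_equal(nrow(detect_patterns(hm)), 0L)
  expect_equal(nrow(detect_patterns(hm, cutoff_type = "sd")), 0L)
})

test_that("a strongly depressed residue row is called restrictive", {
  # a1 = D motifs far below everything else: flagged under both cutoff modes
  ef <- ef_table(enumerate_cxxx(), ifelse(substr(enumerate_cxxx(), 2, 2) == "D",
                                          0.05, 1.0))
  hm <- build_heatmap(ef, "a1x")
  for (ct in c("ci_mean", "sd")) {
    pat <- detect_patterns(hm, cutoff_type = ct)
    restrictive <- pat[pat$direction == "restrictive" & pat$axis == "row", ]
    expect_identical(restrictive$residue, "D")
    expect_identical(restrictive$position, "a1")
    expect_equal(restrictive$n_beyond_cutoff, 20L)
  }
})

test_that("cells exactly at a cutoff do not count toward the 18-of-20 rule", {
  ef <- random_ef_table(24)
  hm <- build_heatmap(ef, "a1a2")
  # degenerate interval of width zero: cells equal to the grand mean (none
  # strictly beyond) must not be counted
  pat <- detect_patterns(hm, z = 0)
  expect_true(all(pat$n_beyond_cutoff <= 20L))
  flat <- ef_table(enumerate_cxxx(), rep(3, 8000))
  expect_equal(nrow(detect_patterns(build_heatmap(flat, "a1a2"), z = 0)), 0L)
})

test_that("hm score sums the three context cells (brute-force oracle)", {
  efc <- ef_table(enumerate_cxxx(), rep(1.2, 8000))
  hc <- build_heatmaps(efc)
  expect_equal(unname(hm_score(c("CASQ", "CVIA"), hc)), c(3.6, 3.6))
  ef <- random_ef_table(25)
  hms <- build_heatmaps(ef)
  probe <- withr::with_seed(26, sample(ef$motif, 100))
  mine <- hm_score(probe, hms)
  oracle <- vapply(probe, oracle_hm_score, 1.0, ef = ef)
  expect_equal(unname(mine), unname(oracle), tolerance = 1e-9)
})

test_that("hm_score_all covers the space and matches the per-motif path", {
  ef <- random_ef_table(27)
  tab <- hm_score_all(ef)
  expect_equal(nrow(tab), 8000L)
  expect_identical(tab$motif, enumerate_cxxx())
  hms <- build_heatmaps(ef)
  idx <- withr::with_seed(28, sample(8000, 50))
  expect_equal(tab$hm_score[idx], unname(hm_score(tab$motif[idx], hms)))
  expect_equal(tab$hm_score, tab$hm_a1a2 + tab$hm_a1x + tab$hm_a2x)
})

test_that("raising one motif's EF by delta raises its hm score by 3*delta/20", {
  ef <- random_ef_table(29)
  delta <- 0.8
  ef2 <- ef
  i <- match("CKQS", ef2$motif)
  ef2$ef[i] <- ef2$ef[i] + delta
  class(ef2) <- class(ef)
  s1 <- hm_score("CKQS", build_heatmaps(ef))
  s2 <- hm_score("CKQS", build_heatmaps(ef2))
  expect_equal(unname(s2 - s1), 3 * delta / 20, tolerance = 1e-9)
})
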