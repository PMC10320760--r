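mk_rep <- function(counts, id = "r1", cond = "25C") {
  replicate_counts(counts, id, cond, n_reads_total = sum(counts))
}

test_that("replicate pooling sums per-motif counts within one condition", {
  p <- pool_replicates(list(mk_rep(c(CASQ = 3L)),
                            mk_rep(c(CASQ = 5L, CVIA = 2L), "r2")))
  expect_identical(p$counts[c("CASQ", "CVIA")], c(CASQ = 8L, CVIA = 2L))
  expect_equal(p$total, 10L)
  one <- mk_rep(c(CKQQ = 4L, CASQ = 1L))
  expect_identical(pool_replicates(list(one))$counts[names(one$counts)],
                   one$counts)
  expect_error(pool_replicates(list(mk_rep(c(CASQ = 1L)),
                                    mk_rep(c(CASQ = 1L), "r2", "37C"))),
               "mixed conditions")
})

test_that("pooling eight simulated replicates matches an element-wise oracle", {
  motifs <- enumerate_cxxx()[1:50]
  reps <- withr::with_seed(3, lapply(1:8, function(i) {
    cnt <- rpois(50, 20)
    names(cnt) <- motifs
    mk_rep(cnt[cnt > 0], paste0("r", i))
  }))
  p <- pool_replicates(reps)
  oracle <- Reduce(`+`, lapply(reps, function(r) {
    full <- setNames(integer(50), motifs)
    full[names(r$counts)] <- r$counts
    full
  }))
  expect_identical(p$counts[motifs[oracle > 0]], oracle[oracle > 0])
})

test_that("EF follows the +1-corrected frequency ratio on each scale", {
  motifs <- enumerate_cxxx()
  c25 <- setNames(rep(10L, 8000), motifs)
  c37 <- c25
  c25["CVFF"] <- 0L   # absent at 25C
  c37["CVFF"] <- 5L
  p25 <- pool_replicates(list(mk_rep(c25[c25 > 0])))
  p37 <- pool_replicates(list(mk_rep(c37, "r1", "37C")))
  ef_raw <- compute_ef(p25, p37, scale = "raw_count")
  expect_equal(ef_raw$ef[ef_raw$motif == "CVFF"], 6 / 1)
  expect_true(all(ef_raw$ef > 0))
  # frequencies sum to 1 before the pseudocount
  expect_equal(sum(ef_raw$freq25), 1)
  expect_equal(sum(ef_raw$freq37), 1)
  # identical pooled counts give EF 1 everywhere, on any scale
  for (sc in c("cpm", "raw_count", "fraction")) {
    ef_id <- compute_ef(p37, p37, scale = sc)
    expect_equal(range(ef_id$ef), c(1, 1))
  }
  # motifs absent from both conditions get EF exactly 1
  c25b <- c(CASQ = 50L); c37b <- c(CASQ = 60L, CKQQ = 10L)
  efb <- compute_ef(pool_replicates(list(mk_rep(c25b))),
                    pool_replicates(list(mk_rep(c37b, "r", "37C"))))
  expect_equal(efb$ef[efb$motif == "CAAA"], 1)
  expect_equal(nrow(efb), 8000L)
  expect_error(compute_ef(p25, pool_replicates(list(mk_rep(c(CASQ = 0L),
                                                           "z", "37C")))),
               "zero total")
})

test_that("motifs absent at 25C but present at 37C stay finite and above 1", {
  absent9 <- c("CFFM", "CIFF", "CILF", "CIYM", "CNWC", "CTFA", "CVFF",
               "CVLW", "CWIA")
  motifs <- enumerate_cxxx()
  c25 <- setNames(rep(100L, 8000), motifs)
  c37 <- c25
  c25[absent9] <- 0L
  c37[absent9] <- 150L
  ef <- compute_ef(pool_replicates(list(mk_rep(c25[c25 > 0]))),
                   pool_replicates(list(mk_rep(c37, "r", "37C"))))
  sel <- ef$ef[match(absent9, ef$motif)]
  expect_true(all(is.finite(sel)))
  expect_true(all(sel > 1))
})

test_that("cpm-scale EFs are invariant to overall sequencing depth", {
  motifs <- enumerate_cxxx()
  cnt <- withr::with_seed(5, setNames(rpois(8000, 50) + 1L, motifs))
  cnt37 <- withr::with_seed(6, setNames(rpois(8000, 50) + 1L, motifs))
  ef1 <- compute_ef(pool_replicates(list(mk_rep(cnt))),
                    pool_replicates(list(mk_rep(cnt37, "r", "37C"))))
  ef2 <- compute_ef(pool_replicates(list(mk_rep(cnt * 7L))),
                    pool_replicates(list(mk_rep(cnt37 * 7L, "r", "37C"))))
  expect_equal(ef1$ef, ef2$ef, tolerance = 1e-12)
})

test_that("quartile assignment matches a full-sort oracle", {
  ef <- random_ef_table(11)
  q <- assign_quartiles(ef)
  expect_identical(as.integer(table(q)), c(2000L, 2000L, 2000L, 2000L))
  expect_equal(unname(q[ef$motif[which.max(ef$ef)]]), 4L)
  ord <- order(ef$ef, ef$motif)
  oracle <- integer(8000)
  oracle[ord] <- rep(1:4, each = 2000)
  expect_identical(unname(q[ef$motif]), oracle)
})

test_that("subgroup restriction reproduces the canonical group sizes", {
  ef <- random_ef_table(12)
  aliphatic <- c("I", "L", "V")
  caalfmi <- subgroup_mean_ef(ef, aliphatic, aliphatic, c("L", "F", "M", "I"))
  expect_equal(caalfmi$n, 36L)
  cxxlfmi <- subgroup_mean_ef(ef, x_set = c("L", "F", "M", "I"))
  expect_equal(cxxlfmi$n, 1600L)
  full <- subgroup_mean_ef(ef)
  expect_equal(full$n, 8000L)
  expect_equal(full$mean, mean(ef$ef))
  # empty intersection is flagged, not an error
  sub <- ef[ef$a1 == "A", ]
  class(sub) <- class(ef)
  res <- subgroup_mean_ef(sub, a1_set = "W")
  expect_true(res$empty)
  expect_equal(res$n, 0L)
})

test_that("EF tables round-trip through their TSV representation", {
  ef <- random_ef_table(13)
  path <- tempfile(fileext = ".tsv")
  write_ef_table(ef, path)
  back <- read_ef_table(path)
  expect_equal(back$ef, ef$ef, tolerance = 1e-12)
  expect_identical(back$motif, ef$motif)
  expect_identical(attr(back, "scale"), attr(ef, "scale"))
})
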