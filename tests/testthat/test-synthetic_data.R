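test_that("ground-truth rules encode the planted specificity determinants", {
  params <- truth_params_default(noise_sd = 0)
  p <- ground_truth_rules(params = params)
  expect_lte(p[["CAKA"]], 0.05)   # a2 = K abolishes
  expect_lte(p[["CADA"]], 0.05)
  expect_gte(p[["CVIR"]], 0.9)    # a2 = I rescues X = R
  expect_gte(p[["CASQ"]], 0.9)    # noncanonical but proficient
  expect_lte(p[["CAAP"]], 0.2)    # X = P unrescued
  expect_gte(p[["CASQ"]], p[["CASA"]])  # Q-at-X bonus
  expect_true(all(p >= 0 & p <= 1))
  # deterministic given seed, including noise
  pn1 <- ground_truth_rules(seed = 9)
  pn2 <- ground_truth_rules(seed = 9)
  expect_identical(pn1, pn2)
})

test_that("library simulation is normalized, seeded, and imbalance-scaled", {
  cfg0 <- simulation_config(library_sigma = 0)
  expect_equal(unname(simulate_library(cfg0)), rep(1 / 8000, 8000))
  for (seed in c(61, 62, 63)) {
    f <- simulate_library(simulation_config(seed = seed))
    expect_equal(sum(f), 1)
    ratio <- unname(quantile(f, 0.995) / quantile(f, 0.005))
    expect_gte(ratio, 5)
    expect_lte(ratio, 20)
  }
  expect_identical(simulate_library(simulation_config(seed = 64)),
                   simulate_library(simulation_config(seed = 64)))
})

test_that("selection follows the closed-form multiplicative growth model", {
  cfg <- simulation_config(s = 0.5, generations = 8L)
  naive <- c(m1 = 0.5, m2 = 0.5)
  truth <- c(m1 = 1, m2 = 0)
  post <- simulate_selection(naive, truth, cfg, "37C")
  expect_equal(post[["m1"]] / post[["m2"]], 1.5^8, tolerance = 1e-12)
  expect_equal(sum(post), 1)
  # permissive condition is neutral regardless of s
  expect_identical(simulate_selection(naive, truth, cfg, "25C"), naive)
  expect_identical(simulate_selection(naive, truth,
                                      simulation_config(s = 0), "37C"), naive)
})

test_that("read sampling conserves totals and records the exact draw", {
  cfg <- simulation_config(n_reads = 5000, junk_fraction = 0.02, seed = 65)
  f <- simulate_library(cfg)
  sr <- sample_reads(f, cfg, "25C", n_replicates = 3L)
  expect_length(sr$truth, 3L)
  n_clean <- 5000 - round(0.02 * 5000)
  for (tr in sr$truth) expect_equal(sum(tr), n_clean)
  # zero reads -> empty draws
  cfg0 <- simulation_config(n_reads = 0, seed = 65)
  sr0 <- sample_reads(f, cfg0, "25C", n_replicates = 1L)
  expect_equal(sum(sr0$truth[[1]]), 0)
})

test_that("identical seeds reproduce the simulation byte for byte", {
  cfg <- simulation_config(n_reads = 3000, replicates_25c = 1L,
                           replicates_37c = 1L, seed = 66, emit_fastq = TRUE)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  s1 <- simulate_screen(cfg, d1)
  s2 <- simulate_screen(cfg, d2)
  expect_identical(s1$truth, s2$truth)
  expect_identical(lapply(s1$replicates, `[[`, "counts"),
                   lapply(s2$replicates, `[[`, "counts"))
  md5 <- function(d) unname(tools::md5sum(sort(list.files(d, full.names = TRUE))))
  expect_identical(md5(d1), md5(d2))
  # and counts are the same whether or not FASTQ is emitted
  s3 <- simulate_screen(simulation_config(n_reads = 3000, replicates_25c = 1L,
                                          replicates_37c = 1L, seed = 66))
  expect_identical(lapply(s1$replicates, `[[`, "counts"),
                   lapply(s3$replicates, `[[`, "counts"))
})

test_that("downstream EF is monotone in planted propensity", {
  cfg <- simulation_config(n_reads = 2e5, seed = 67,
                           truth_params = truth_params_default(noise_sd = 0))
  sim <- simulate_screen(cfg)
  ef <- sim_ef_table(sim)
  stopifnot(identical(names(sim$truth), ef$motif))
  groups <- split(ef$ef, round(sim$truth, 2))
  means <- vapply(groups, mean, 1.0)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
})
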