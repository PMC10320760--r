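test_that("feature enumeration matches the closed-form count", {
  expect_length(enumerate_features(1), 60L)
  expect_length(enumerate_features(2), 630L)
  expect_length(enumerate_features(5), 65097L)
  for (s in 1:6) {
    expect_length(enumerate_features(s), 3 * sum(choose(20, 1:s)))
  }
  labs <- attr(enumerate_features(3), "labels")
  expect_equal(anyDuplicated(labs), 0L)
})

test_that("encoding is set membership, with one-hot block row sums of 3", {
  specs1 <- enumerate_features(1)
  X <- encode("CASQ", specs1)
  expect_equal(sum(X), 3L)
  on <- colnames(X)[X[1, ] == 1]
  expect_setequal(on, c("a1 in {A}", "a2 in {S}", "x in {Q}"))
  spec_dekr <- list(list(position = "a2", residues = c("D", "E", "K", "R")))
  expect_equal(unname(encode(c("CASQ", "CAKA"), spec_dekr)[, 1]), c(0L, 1L))
  # brute-force oracle on random motifs and random set features
  motifs <- withr::with_seed(31, sample(enumerate_cxxx(), 40))
  specs <- withr::with_seed(32, lapply(1:25, function(i)
    list(position = sample(c("a1", "a2", "x"), 1),
         residues = sample(AA_ALPHABET20, sample(1:5, 1)))))
  X2 <- encode(motifs, specs)
  pos_of <- c(a1 = 2L, a2 = 3L, x = 4L)
  for (i in seq_along(motifs)) {
    for (j in seq_along(specs)) {
      res <- substr(motifs[i], pos_of[specs[[j]]$position],
                    pos_of[specs[[j]]$position])
      expect_identical(X2[i, j], as.integer(res %in% specs[[j]]$residues))
    }
  }
})

test_that("label binarization thresholds EF as documented", {
  ef <- random_ef_table(33)
  expect_true(all(binarize_labels(ef, min(ef$ef) - 1)$label == 1L))
  expect_true(all(binarize_labels(ef, Inf)$label == 0L))
  lb <- binarize_labels(ef, 1.0)
  expect_identical(lb$label, as.integer(ef$ef > 1.0))
  expect_equal(lb$threshold, 1.0)
})

test_that("a perfectly separable feature yields a depth-1 pure tree", {
  motifs <- enumerate_cxxx()
  y <- as.integer(!(substr(motifs, 3, 3) %in% c("D", "E", "K", "R")))
  tr <- fit_caax_tree(list(motifs = motifs, label = y))
  expect_false(tr$root$leaf)
  expect_identical(tr$feature_labels[tr$root$feature], "a2 in {D,E,K,R}")
  expect_true(tr$root$left$leaf && tr$root$right$leaf)
  pred <- predict(tr, motifs)
  expect_identical(pred, ifelse(y == 1L, "positive", "negative"))
})

test_that("the root split agrees with an exhaustive-search oracle", {
  for (seed in c(41, 42, 43)) {
    dat <- withr::with_seed(seed, {
      X <- matrix(rbinom(180 * 80, 1, 0.4), nrow = 180)
      w <- rnorm(80)
      y <- as.integer(X %*% w + rnorm(180) > 0)
      list(X = X, y = y)
    })
    tr <- fit_tree(dat$X, dat$y, max_depth = 1L, min_samples = 20L)
    oracle <- oracle_root_split(dat$X, dat$y, 20L)
    if (is.null(oracle$feature)) {
      expect_true(tr$root$leaf)
    } else {
      expect_equal(tr$root$feature, oracle$feature)
      expect_equal(tr$root$gain, oracle$gain, tolerance = 1e-9)
    }
  }
})

test_that("depth and node-size constraints hold in every fitted node", {
  ef <- random_ef_table(44)
  tr <- fit_caax_tree(binarize_labels(ef), max_set_size = 2L)
  check <- function(node) {
    expect_lte(node$depth, 3L)
    expect_gte(node$n, 50L)
    if (!node$leaf) {
      check(node$left)
      check(node$right)
    }
  }
  check(tr$root)
  # degenerate single-class input collapses to one leaf
  flat <- fit_caax_tree(list(motifs = ef$motif, label = rep(1L, 8000)),
                        max_set_size = 1L)
  expect_true(flat$root$leaf)
  expect_identical(flat$root$class, "positive")
})

test_that("predictions are invariant to feature order on tie-free data", {
  dat <- withr::with_seed(45, {
    X <- matrix(rbinom(300 * 40, 1, 0.5), nrow = 300)
    y <- as.integer(X[, 7] == 1 | (X[, 20] == 1 & X[, 33] == 0))
    list(X = X, y = y)
  })
  tr1 <- fit_tree(dat$X, dat$y, min_samples = 10L)
  perm <- withr::with_seed(46, sample(ncol(dat$X)))
  tr2 <- fit_tree(dat$X[, perm], dat$y, min_samples = 10L)
  p1 <- predict_matrix_tree(tr1, dat$X)
  p2 <- predict_matrix_tree(tr2, dat$X[, perm])
  expect_identical(p1, p2)
})

test_that("the implicit full-space fit equals the explicit matrix fit", {
  ef <- random_ef_table(47)
  labels <- binarize_labels(ef)
  tr_implicit <- fit_caax_tree(labels, max_set_size = 1L)
  X <- encode(ef$motif, enumerate_features(1))
  tr_explicit <- fit_tree(X, labels$label, specs = enumerate_features(1))
  same_shape <- function(a, b) {
    expect_equal(a$leaf, b$leaf)
    expect_equal(a$n, b$n)
    expect_equal(a$n_pos, b$n_pos)
    if (!a$leaf) {
      expect_equal(a$feature, b$feature)
      same_shape(a$left, b$left)
      same_shape(a$right, b$right)
    }
  }
  same_shape(tr_implicit$root, tr_explicit$root)
})

test_that("extracted rules cover each leaf exactly once", {
  motifs <- enumerate_cxxx()
  y <- as.integer(!(substr(motifs, 3, 3) %in% c("D", "E", "K", "R")))
  tr <- fit_caax_tree(list(motifs = motifs, label = y))
  rules <- extract_rules(tr)
  n_leaves <- function(node) if (node$leaf) 1L else
    n_leaves(node$left) + n_leaves(node$right)
  expect_length(rules, n_leaves(tr$root))
  expect_match(rules[length(rules)], "a2 in \\{D,E,K,R\\}.*negative")
  tab <- attr(rules, "table")
  expect_equal(sum(tab$n), 8000L)
})
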