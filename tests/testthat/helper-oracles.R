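# Independent brute-force oracles used across tests. These deliberately take
# the slow, obvious path so they share no code with the implementation.

# Mean EF of the 20 motifs sharing two fixed residues, recomputed by explicit
# filtering; hm score = sum of the three such averages.
oracle_hm_score <- function(motif, ef) {
  a1 <- substr(motif, 2, 2); a2 <- substr(motif, 3, 3); x <- substr(motif, 4, 4)
  g <- function(keep) mean(ef$ef[keep])
  g(substr(ef$motif, 2, 2) == a1 & substr(ef$motif, 3, 3) == a2) +
    g(substr(ef$motif, 2, 2) == a1 & substr(ef$motif, 4, 4) == x) +
    g(substr(ef$motif, 3, 3) == a2 & substr(ef$motif, 4, 4) == x)
}

# Exhaustive information-gain search for the best root split of a binary
# feature matrix (entropy in bits), honouring the child-size floor.
oracle_root_split <- function(X, y, min_samples) {
  H <- function(v) {
    if (!length(v)) return(0)
    p <- mean(v)
    if (p == 0 || p == 1) return(0)
    -p * log2(p) - (1 - p) * log2(1 - p)
  }
  n <- length(y)
  best <- NULL
  best_gain <- 0
  for (j in seq_len(ncol(X))) {
    on <- X[, j] == 1
    if (sum(on) < min_samples || sum(!on) < min_samples) next
    gain <- H(y) - mean(on) * H(y[on]) - mean(!on) * H(y[!on])
    if (gain > best_gain + 1e-12) {
      best_gain <- gain
      best <- j
    }
  }
  list(feature = best, gain = best_gain)
}

# A deterministic full EF table with heterogeneous values for heatmap tests.
random_ef_table <- function(seed = 1, sdlog = 0.5) {
  motifs <- enumerate_cxxx()
  ef <- withr::with_seed(seed, exp(rnorm(length(motifs), 0, sdlog)))
  ef_table(motifs, ef)
}

# Minimal single-motif FASTQ writer for extraction tests.
write_test_fastq <- function(path, seqs, quals = NULL) {
  if (is.null(quals)) {
    quals <- vapply(nchar(seqs), function(n) strrep("I", n), "")  # Q40
  }
  ids <- sprintf("@read%05d", seq_along(seqs))
  writeLines(paste(ids, seqs, "+", quals, sep = "\n"),
             con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w"))
  close(con)
  path
}

# Read scaffold mirroring the simulator's amplicon layout, assembled here by
# hand so the extraction tests do not depend on the emitter.
ANCHOR <- "GGTGGCGAAGGTGTACAATGT"
make_read <- function(insert9, prefix = "GATTCCGATGAAGAAGAACAA",
                      suffix = "TGATTTTCTTGATAAAAAAAGATCCAGCATATAATCC") {
  paste0(prefix, ANCHOR, insert9, suffix)
}
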