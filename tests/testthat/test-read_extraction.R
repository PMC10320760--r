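test_that("single-read extraction handles the anchor, quality and codon checks", {
  cfg <- extraction_config()
  expect_identical(extract_motif(make_read("GCATCTCAA"))$motif, "CASQ")
  expect_identical(extract_motif("ACGTACGTACGTACGTACGT")$reject, "no_anchor")
  trunc <- paste0("AAAA", "GGTGGCGAAGGTGTACAATGT", "GCATC")
  expect_identical(extract_motif(trunc)$reject, "truncated")
  r <- make_read("GCATCTCAA")
  lowq <- rep(40L, nchar(r)); lowq[43:51] <- 10L
  expect_identical(extract_motif(r, lowq)$reject, "low_quality")
  expect_identical(extract_motif(make_read("TAAGCAGCA"))$reject, "stop_codon")
  expect_identical(extract_motif(make_read("GCNTCTCAA"))$reject, "invalid_base")
  # reverse-complement orientation is recovered
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(make_read("GCATCTCAA"))))
  expect_identical(extract_motif(rc)$motif, "CASQ")
})

test_that("counting a single-species FASTQ yields exactly that species", {
  fq <- tempfile(fileext = ".fastq")
  write_test_fastq(fq, rep(make_read("GCATCTCAA"), 1000))
  rc <- count_replicate(fq)
  expect_identical(rc$counts, c(CASQ = 1000L))
  expect_equal(rc$n_reads_total, 1000L)
  expect_equal(sum(rc$n_rejected_by_reason), 0L)
})

test_that("empty FASTQ gives empty counts with a warning", {
  fq <- tempfile(fileext = ".fastq")
  file.create(fq)
  expect_warning(rc <- count_replicate(fq), "empty")
  expect_equal(rc$n_reads_total, 0L)
  expect_length(rc$counts, 0L)
})

test_that("every read is either assigned or rejected, never dropped", {
  fq <- tempfile(fileext = ".fastq.gz")
  seqs <- c(rep(make_read("GCATCTCAA"), 50),
            rep(make_read("TAAGCAGCA"), 5),          # stop
            rep("ACGTACGTACGTACGTACGTACGTACGT", 7),  # no anchor
            rep(make_read("AAAGGGCCC"), 20))
  quals <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  quals[1:3] <- vapply(nchar(seqs[1:3]), function(n) strrep("+", n), "") # Q10
  write_test_fastq(fq, seqs, quals)
  rc <- count_replicate(fq)
  expect_equal(sum(rc$counts) + sum(rc$n_rejected_by_reason), rc$n_reads_total)
  expect_identical(unname(rc$counts[c("CASQ", "CKGP")]), c(47L, 20L))
  expect_equal(unname(rc$n_rejected_by_reason["stop_codon"]), 5L)
  expect_equal(unname(rc$n_rejected_by_reason["no_anchor"]), 7L)
  expect_equal(unname(rc$n_rejected_by_reason["low_quality"]), 3L)
})

test_that("extraction is position-independent (anchor search, not offset)", {
  motifs9 <- c("GCATCTCAA", "AAAGGGCCC", "TGTTGGTAT")
  base_seqs <- rep(make_read(motifs9), each = 30)
  shifted <- withr::with_seed(7, vapply(base_seqs, function(s) {
    k <- sample(0:20, 1)
    paste0(paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""), s)
  }, "", USE.NAMES = FALSE))
  fq1 <- tempfile(fileext = ".fastq"); fq2 <- tempfile(fileext = ".fastq")
  write_test_fastq(fq1, base_seqs)
  write_test_fastq(fq2, shifted)
  c1 <- count_replicate(fq1); c2 <- count_replicate(fq2)
  expect_identical(c1$counts[sort(names(c1$counts))],
                   c2$counts[sort(names(c2$counts))])
})

test_that("replicate-level Q30 gate retains exactly the passing replicates", {
  mk <- function(id, q30) replicate_counts(c(CASQ = 100L), id, "37C",
                                           n_reads_total = 100L,
                                           q30_fraction = q30)
  reps <- c(lapply(1:7, function(i) mk(paste0("r", i), 0.96)),
            list(mk("r8", 0.40)))
  qc <- qc_replicates(reps, extraction_config(replicate_q30_fraction_min = 0.8))
  expect_length(qc$retained, 7L)
  expect_false(qc$report$retained[8])
  # threshold zero retains everything
  qc0 <- qc_replicates(reps, extraction_config(replicate_q30_fraction_min = 0))
  expect_length(qc0$retained, 8L)
  # k constructed failures -> 8 - k retained
  for (k in c(2L, 5L)) {
    reps_k <- c(lapply(seq_len(8 - k), function(i) mk(paste0("p", i), 0.9)),
                lapply(seq_len(k), function(i) mk(paste0("f", i), 0.5)))
    expect_length(qc_replicates(reps_k, extraction_config())$retained, 8L - k)
  }
  # all failing is a hard error
  allbad <- lapply(1:3, function(i) mk(paste0("b", i), 0.1))
  expect_error(qc_replicates(allbad, extraction_config()), "all replicates")
})

test_that("unreadable FASTQ raises a hard error", {
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), bad)  # missing quality line
  expect_error(count_replicate(bad), "failed to read FASTQ")
})
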