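#' Extraction configuration
#'
#' Settings for turning amplicon reads into CXXX motif counts. The anchor is
#' the fixed sequence directly upstream of the variable codons and ends with
#' the Cys codon TGT, so the 9 nt that follow it are the XXX codons.
#'
#' @param anchor Anchor DNA string (default the 21-nt amplicon anchor ending
#'   in TGT).
#' @param min_insert_quality Minimum mean Phred over the 9-nt insert for a
#'   read to be counted (default 20).
#' @param replicate_q30_fraction_min Minimum fraction of reads with mean Phred
#'   >= 30 for a replicate to be retained by [qc_replicates()] (default 0.8).
#' @param max_mismatch Anchor mismatches tolerated; exact matching (0) by
#'   default, 1 may be enabled.
#' @param search_revcomp Also search the reverse complement when the forward
#'   anchor is absent (default TRUE; read orientation is not guaranteed).
#' @return List of class `extraction_config`.
#' @export
extraction_config <- function(anchor = "GGTGGCGAAGGTGTACAATGT",
                              min_insert_quality = 20,
                              replicate_q30_fraction_min = 0.8,
                              max_mismatch = 0L,
                              search_revcomp = TRUE) {
  stopifnot(nchar(anchor) > 0, max_mismatch %in% c(0L, 1L),
            replicate_q30_fraction_min >= 0, replicate_q30_fraction_min <= 1)
  if (substr(anchor, nchar(anchor) - 2L, nchar(anchor)) != "TGT") {
    stop("anchor must end with the Cys codon TGT")
  }
  structure(list(anchor = anchor,
                 min_insert_quality = min_insert_quality,
                 replicate_q30_fraction_min = replicate_q30_fraction_min,
                 max_mismatch = as.integer(max_mismatch),
                 search_revcomp = isTRUE(search_revcomp)),
            class = "extraction_config")
}

REJECT_REASONS <- c("no_anchor", "truncated", "low_quality",
                    "invalid_base", "stop_codon")

# Structural sanity check of a 4-line-per-record FASTQ; the downstream parser
# does not reliably reject truncated records, so malformed files must be
# caught here with the offending record number.
validate_fastq <- function(fastq) {
  if (!file.exists(fastq)) stop("no such file: ", fastq)
  lines <- readLines(fastq)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("truncated FASTQ record ", n %/% 4L + 1L, " (", n, " lines)")
  }
  if (n == 0L) return(invisible(TRUE))
  hdr <- seq(1L, n, by = 4L)
  bad_at <- which(substr(lines[hdr], 1, 1) != "@" |
                    substr(lines[hdr + 2L], 1, 1) != "+" |
                    nchar(lines[hdr + 1L]) != nchar(lines[hdr + 3L]))
  if (length(bad_at)) {
    stop("malformed FASTQ record ", bad_at[1])
  }
  invisible(TRUE)
}

# Vectorized core: sequences + per-base Phred scores (an IRanges IntegerList,
# parallel to the reads) -> motif or reason per read.
extract_motifs_vec <- function(seqs, qual_int, cfg) {
  n <- length(seqs)
  motif <- rep(NA_character_, n)
  reject <- rep(NA_character_, n)
  dna <- Biostrings::DNAStringSet(seqs)
  hits <- Biostrings::vmatchPattern(cfg$anchor, dna,
                                    max.mismatch = cfg$max_mismatch)
  stidx <- Biostrings::startIndex(hits)
  nhit <- lengths(stidx)
  st <- rep(NA_integer_, n)
  st[nhit > 0L] <- vapply(stidx[nhit > 0L], `[[`, 1L, 1L)
  if (cfg$search_revcomp && anyNA(st)) {
    miss <- which(is.na(st))
    rc <- Biostrings::reverseComplement(dna[miss])
    hits2 <- Biostrings::vmatchPattern(cfg$anchor, rc,
                                       max.mismatch = cfg$max_mismatch)
    stidx2 <- Biostrings::startIndex(hits2)
    nhit2 <- lengths(stidx2)
    found <- which(nhit2 > 0L)
    if (length(found)) {
      # flip read and qualities into anchor orientation
      i <- miss[found]
      seqs[i] <- as.character(rc[found])
      qual_int[i] <- IRanges::revElements(qual_int, i)[i]
      st[i] <- vapply(stidx2[found], `[[`, 1L, 1L)
    }
  }
  reject[is.na(st)] <- "no_anchor"
  ins_start <- st + nchar(cfg$anchor)
  cand <- which(!is.na(st))
  trunc <- cand[ins_start[cand] + 8L > nchar(seqs[cand])]
  reject[trunc] <- "truncated"
  keep <- setdiff(cand, trunc)
  if (length(keep)) {
    uq <- unlist(qual_int, use.names = FALSE)
    off <- cumsum(c(0L, lengths(qual_int)))[seq_len(n)]
    abs_start <- off[keep] + ins_start[keep]
    qsum <- numeric(length(keep))
    for (k in 0:8) qsum <- qsum + uq[abs_start + k]
    meanq <- qsum / 9
    lowq <- keep[meanq < cfg$min_insert_quality]
    reject[lowq] <- "low_quality"
    keep <- setdiff(keep, lowq)
    if (length(keep)) {
      tr <- translate_insert(substr(seqs[keep], ins_start[keep],
                                    ins_start[keep] + 8L))
      motif[keep] <- tr$motif
      reject[keep] <- tr$reject
    }
  }
  data.frame(motif = motif, reject = reject, stringsAsFactors = FALSE)
}

#' Extract the CXXX motif from a single read
#'
#' Locates the first exact occurrence of the anchor (searching the reverse
#' complement as fallback), checks the mean Phred quality of the 9-nt insert,
#' and translates it. Reads failing any check are reported under a rejection
#' reason, never silently dropped.
#'
#' @param seq Read sequence (character).
#' @param qual Integer vector of per-base Phred scores (same length as `seq`),
#'   or a single quality string in Phred+33 encoding.
#' @param cfg An [extraction_config()].
#' @return List with elements `motif` (NA when rejected) and `reject` (NA or
#'   one of no_anchor, truncated, low_quality, invalid_base, stop_codon).
#' @export
extract_motif <- function(seq, qual = NULL, cfg = extraction_config()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (is.null(qual)) {
    qual <- rep(40L, nchar(seq))
  } else if (is.character(qual)) {
    qual <- utf8ToInt(qual) - 33L
  }
  stopifnot(length(qual) == nchar(seq))
  res <- extract_motifs_vec(seq, IRanges::IntegerList(list(as.integer(qual))), cfg)
  list(motif = res$motif[1], reject = res$reject[1])
}

#' Count CXXX motifs in one FASTQ replicate
#'
#' Reads a FASTQ file (plain or gzip), extracts the motif from every read and
#' tallies counts per motif. Motif identity is defined by translation, not DNA
#' sequence, so synonymous codons merge. The per-read rejection reasons and
#' the replicate-level Q30 fraction (fraction of reads whose mean Phred over
#' the full read is >= 30) are recorded for quality control.
#'
#' @param fastq Path to a FASTQ file.
#' @param cfg An [extraction_config()].
#' @param replicate_id Label for the replicate (default the file name).
#' @param condition Condition label, one of "25C", "37C", "naive_ecoli",
#'   "naive_yeast".
#' @return Object of class `replicate_counts`: list with `replicate_id`,
#'   `condition`, `counts` (named integer vector), `n_reads_total`,
#'   `n_rejected_by_reason`, `q30_fraction`.
#' @export
count_replicate <- function(fastq, cfg = extraction_config(),
                            replicate_id = basename(fastq),
                            condition = "25C") {
  parsed <- tryCatch({
    validate_fastq(fastq)
    reads <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                          with.qualities = TRUE)
    quals <- S4Vectors::mcols(reads)$qualities
    if (length(reads) && !identical(Biostrings::width(quals),
                                    Biostrings::width(reads))) {
      stop("read/quality length mismatch at record ",
           which(Biostrings::width(quals) != Biostrings::width(reads))[1])
    }
    qint <- if (length(reads))
      as(Biostrings::PhredQuality(quals), "IntegerList") else NULL
    list(reads = reads, qint = qint)
  }, error = function(e) stop("failed to read FASTQ '", fastq, "': ",
                              conditionMessage(e), call. = FALSE))
  reads <- parsed$reads
  n <- length(reads)
  if (n == 0L) {
    warning("empty FASTQ: ", fastq)
    return(replicate_counts(integer(0), replicate_id, condition,
                            n_reads_total = 0L,
                            n_rejected_by_reason = setNames(integer(5), REJECT_REASONS),
                            q30_fraction = NA_real_))
  }
  qint <- parsed$qint
  mean_read_q <- sum(qint) / lengths(qint)
  res <- extract_motifs_vec(as.character(reads), qint, cfg)
  counts <- table(res$motif[!is.na(res$motif)])
  counts <- setNames(as.integer(counts), names(counts))
  rej <- table(factor(res$reject, levels = REJECT_REASONS))
  replicate_counts(counts, replicate_id, condition,
                   n_reads_total = n,
                   n_rejected_by_reason = setNames(as.integer(rej), REJECT_REASONS),
                   q30_fraction = mean(mean_read_q >= 30))
}

#' Construct a replicate_counts object
#'
#' @param counts Named integer vector (motif -> count).
#' @param replicate_id,condition Labels.
#' @param n_reads_total Total reads processed (defaults to sum of counts).
#' @param n_rejected_by_reason Named integer vector over rejection reasons.
#' @param q30_fraction Fraction of reads with mean Phred >= 30.
#' @return `replicate_counts` object.
#' @export
replicate_counts <- function(counts, replicate_id, condition,
                             n_reads_total = sum(counts) + sum(n_rejected_by_reason),
                             n_rejected_by_reason = setNames(integer(5), REJECT_REASONS),
                             q30_fraction = 1.0) {
  counts <- setNames(as.integer(counts), names(counts))
  stopifnot(all(counts >= 0L),
            sum(counts) + sum(n_rejected_by_reason) == n_reads_total)
  structure(list(replicate_id = replicate_id, condition = condition,
                 counts = counts, n_reads_total = as.integer(n_reads_total),
                 n_rejected_by_reason = n_rejected_by_reason,
                 q30_fraction = q30_fraction),
            class = "replicate_counts")
}

#' @export
print.replicate_counts <- function(x, ...) {
  cat("replicate_counts:", x$replicate_id, "(", x$condition, ")\n",
      " reads:", x$n_reads_total,
      " assigned:", sum(x$counts),
      " rejected:", sum(x$n_rejected_by_reason),
      " Q30:", round(x$q30_fraction, 3), "\n")
  invisible(x)
}

#' Quality-control filter over replicates
#'
#' Excludes replicates whose fraction of reads at mean Phred >= 30 falls below
#' the configured threshold, mirroring replicate-level sequencing QC.
#'
#' @param replicates List of `replicate_counts`.
#' @param cfg An [extraction_config()]; `replicate_q30_fraction_min` is the
#'   gate.
#' @return List with `retained` (list of replicate_counts), `report`
#'   (data.frame: replicate_id, condition, q30_fraction, retained).
#' @export
qc_replicates <- function(replicates, cfg = extraction_config()) {
  stopifnot(length(replicates) >= 1)
  q30 <- vapply(replicates, function(r) r$q30_fraction, 1.0)
  keep <- is.na(q30) | q30 >= cfg$replicate_q30_fraction_min
  keep[is.na(q30)] <- FALSE
  report <- data.frame(
    replicate_id = vapply(replicates, function(r) r$replicate_id, ""),
    condition = vapply(replicates, function(r) r$condition, ""),
    q30_fraction = q30,
    retained = keep,
    stringsAsFactors = FALSE)
  if (!any(keep)) stop("all replicates excluded by Q30 gate (threshold ",
                       cfg$replicate_q30_fraction_min, ")")
  list(retained = replicates[keep], report = report)
}

#' Write a replicate count table as TSV
#'
#' @param rep A `replicate_counts` object.
#' @param path Output path (columns motif, count).
#' @export
write_replicate_counts <- function(rep, path) {
  df <- data.frame(motif = names(rep$counts), count = unname(rep$counts))
  df <- df[order(df$motif), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a replicate count table written by [write_replicate_counts()]
#'
#' @param path TSV path with columns motif, count.
#' @param replicate_id,condition Labels for the reconstructed object.
#' @param q30_fraction Q30 fraction to attach (counts files do not carry it).
#' @return `replicate_counts` object (rejection tallies zeroed).
#' @export
read_replicate_counts <- function(path, replicate_id = basename(path),
                                  condition = "25C", q30_fraction = 1.0) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("motif", "count") %in% names(df)))
  replicate_counts(setNames(as.integer(df$count), df$motif),
                   replicate_id, condition,
                   n_reads_total = sum(df$count),
                   q30_fraction = q30_fraction)
}
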