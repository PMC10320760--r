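#' Round half away from zero
#'
#' Reporting convention for benchmark percentages: one decimal, halves round
#' up (base `round()` rounds halves to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Threshold classification of scores
#'
#' @param scores Named numeric vector (motif/record -> score).
#' @param cutoff Positive cutoff.
#' @param direction "greater" (strict, default) or "greater_equal". A score
#'   exactly at the cutoff is negative under the default.
#' @return Named character vector, "positive"/"negative".
#' @export
classify <- function(scores, cutoff, direction = c("greater", "greater_equal")) {
  direction <- match.arg(direction)
  pos <- if (direction == "greater") scores > cutoff else scores >= cutoff
  setNames(ifelse(pos, "positive", "negative"), names(scores))
}

#' Confusion summary of predictions against observations
#'
#' Percent false positive uses the predicted-positive count as denominator and
#' percent false negative the predicted-negative count; percent correct uses
#' the total. Raw fractions are kept alongside half-up one-decimal rounded
#' percentages.
#'
#' @param predictions,observed Character vectors ("positive"/"negative") over
#'   the same records (same length and, if named, same names).
#' @return List of class `confusion_summary` with n_total, n_correct,
#'   n_false_positive, n_false_negative, n_predicted_positive,
#'   n_predicted_negative, pct_correct, pct_false_positive,
#'   pct_false_negative and frac_* raw fractions.
#' @export
confusion <- function(predictions, observed) {
  if (length(predictions) != length(observed)) {
    stop("predictions and observations differ in length")
  }
  if (!is.null(names(predictions)) && !is.null(names(observed)) &&
      !identical(names(predictions), names(observed))) {
    stop("predictions and observations have mismatched keys")
  }
  stopifnot(all(predictions %in% c("positive", "negative")),
            all(observed %in% c("positive", "negative")))
  n <- length(predictions)
  fp <- sum(predictions == "positive" & observed == "negative")
  fn <- sum(predictions == "negative" & observed == "positive")
  correct <- n - fp - fn
  npp <- sum(predictions == "positive")
  npn <- n - npp
  frac_fp <- if (npp > 0) fp / npp else NA_real_
  frac_fn <- if (npn > 0) fn / npn else NA_real_
  structure(list(
    n_total = n, n_correct = correct,
    n_false_positive = fp, n_false_negative = fn,
    n_predicted_positive = npp, n_predicted_negative = npn,
    frac_correct = correct / n, frac_false_positive = frac_fp,
    frac_false_negative = frac_fn,
    pct_correct = round_half_up(100 * correct / n),
    pct_false_positive = round_half_up(100 * frac_fp),
    pct_false_negative = round_half_up(100 * frac_fn)),
    class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(
    "confusion: %d/%d correct (%.1f%%), FP %d (%.1f%% of predicted +), FN %d (%.1f%% of predicted -)\n",
    x$n_correct, x$n_total, x$pct_correct, x$n_false_positive,
    x$pct_false_positive, x$n_false_negative, x$pct_false_negative))
  invisible(x)
}

TABLE3_MD5 <- "c6093d0fd8381d04e06df0533059dccf"

#' Load the packaged 48-motif gel-shift benchmark table
#'
#' A 48-row reference set of CXXX motifs with experimentally observed
#' prenylation status (thermotolerance + gel-shift in the Ydj1 reporter
#' context) and four predictor scores: PrePS, a published SVM call, the
#' Ras-reporter screen EF (RRS), and the Ydj1-screen HM score. Three motifs
#' with ambiguous doublet gel patterns (CSGL, CSGK, CKQR) are encoded
#' observed-negative, and CKQH appears twice (two independent gel-shift
#' measurements, 70% and 73%) -- both conventions are required to reproduce
#' the printed summary counts.
#'
#' @param path Optional path to an alternative table in the same format.
#' @return data.frame with columns `protein`, `motif`, `observed`
#'   ("positive"/"negative"), `percent_shift`, `preps_score`, `svm_call`,
#'   `rrs_ef`, `ydj1_hm`.
#' @export
load_table3 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table3_benchmark.tsv",
                        package = "cxxxscreen", mustWork = TRUE)
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, TABLE3_MD5)) {
      stop("packaged benchmark table is corrupted (md5 mismatch)")
    }
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "motif", "observed", "percent_shift", "preps_score",
            "svm_call", "rrs_ef", "ydj1_hm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("malformed benchmark table, missing fields: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(is.na(df[need[-1]])) || nrow(df) != 48L) {
    stop("malformed benchmark table: expected 48 fully populated rows, got ",
         nrow(df))
  }
  stopifnot(all(df$observed %in% c("positive", "negative")),
            all(df$svm_call %in% c(0L, 1L)))
  df
}

#' Benchmark the four prenylation predictors on the reference table
#'
#' Runs all four predictors through the same classify/confusion path with
#' their published positive cutoffs: PrePS > -2, SVM > 0 (calls treated as
#' scores), RRS EF > 3, Ydj1 HM > 3.
#'
#' @param fixture data.frame from [load_table3()] (loaded automatically when
#'   NULL).
#' @return List of class `benchmark_report` with one `confusion_summary` per
#'   predictor (`preps`, `svm`, `rrs`, `hm`) and the cutoffs used.
#' @export
benchmark_table3 <- function(fixture = NULL) {
  if (is.null(fixture)) fixture <- load_table3()
  obs <- fixture$observed
  cutoffs <- c(preps = -2, svm = 0, rrs = 3, hm = 3)
  scores <- list(preps = fixture$preps_score, svm = as.numeric(fixture$svm_call),
                 rrs = fixture$rrs_ef, hm = fixture$ydj1_hm)
  out <- lapply(names(cutoffs), function(p) {
    confusion(classify(scores[[p]], cutoffs[[p]]), obs)
  })
  names(out) <- names(cutoffs)
  structure(c(out, list(cutoffs = cutoffs)), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Predictor benchmark (48-motif gel-shift reference)\n")
  for (p in c("preps", "svm", "rrs", "hm")) {
    s <- x[[p]]
    cat(sprintf(
      " %-5s (> %g): correct %2d (%5.1f%%)  FP %d (%4.1f%%)  FN %2d (%4.1f%%)\n",
      toupper(p), x$cutoffs[[p]], s$n_correct, s$pct_correct,
      s$n_false_positive, s$pct_false_positive,
      s$n_false_negative, s$pct_false_negative))
  }
  invisible(x)
}

#' Serialize a benchmark report to JSON
#'
#' @param report A `benchmark_report`.
#' @param path Output path.
#' @export
write_benchmark_json <- function(report, path) {
  lst <- lapply(report[c("preps", "svm", "rrs", "hm")], unclass)
  lst$cutoffs <- as.list(report$cutoffs)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
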