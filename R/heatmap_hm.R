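HEATMAP_PAIRS <- list(a1a2 = c("a1", "a2"), a1x = c("a1", "x"),
                      a2x = c("a2", "x"))

#' Build a position-pair heatmap of mean EF
#'
#' Groups the 8,000 motifs by their residues at an ordered pair of variable
#' positions; each of the 400 cells is the mean EF of the 20 motifs sharing
#' that residue pair (the third position varies). Rows correspond to the first
#' position of the pair, columns to the second; labels are in fixed
#' alphabetical order. Each heatmap partitions the motif space, so the
#' unweighted mean of the 400 cells equals the grand mean EF.
#'
#' @param ef An `ef_table` covering all 8,000 motifs.
#' @param pair One of "a1a2", "a1x", "a2x".
#' @return Object of class `caax_heatmap`: list with `pair`, `rows`, `cols`
#'   (position labels), `cells` (20 x 20 matrix), `grand_mean`.
#' @export
build_heatmap <- function(ef, pair = c("a1a2", "a1x", "a2x")) {
  pair <- match.arg(pair)
  miss <- setdiff(enumerate_cxxx(), ef$motif)
  if (length(miss)) stop("EF table is missing motif ", miss[1],
                         " (and ", length(miss) - 1L, " more)")
  pos <- HEATMAP_PAIRS[[pair]]
  r <- factor(ef[[pos[1]]], levels = AA_ALPHABET20)
  c_ <- factor(ef[[pos[2]]], levels = AA_ALPHABET20)
  cells <- tapply(ef$ef, list(r, c_), mean)
  structure(list(pair = pair, rows = pos[1], cols = pos[2],
                 cells = unclass(cells), grand_mean = mean(ef$ef)),
            class = "caax_heatmap")
}

#' Build all three position-pair heatmaps
#'
#' @param ef An `ef_table` covering all 8,000 motifs.
#' @return Named list of `caax_heatmap` (a1a2, a1x, a2x).
#' @export
build_heatmaps <- function(ef) {
  lapply(setNames(names(HEATMAP_PAIRS), names(HEATMAP_PAIRS)),
         function(p) build_heatmap(ef, p))
}

#' Detect positive / restrictive residue patterns in a heatmap
#'
#' Row means and column means of the 20x20 cell matrix are computed; the
#' standard deviation over the 20 row means (and, separately, the 20 column
#' means) defines high and low cutoffs around the grand mean. For each row
#' (and column), cells strictly above the high cutoff count toward a positive
#' pattern and cells strictly below the low cutoff toward a restrictive
#' pattern; a pattern is reported when at least `min_members` of the 20 cells
#' lie beyond the cutoff.
#'
#' By default the cutoffs form a 95% confidence interval of the grand mean,
#' `grand_mean +/- z * SD / sqrt(20)` (`cutoff_type = "ci_mean"`). The wider
#' `"sd"` variant (`grand_mean +/- z * SD`) is selectable; note that with a
#' block of uniformly shifted rows the block itself inflates the SD enough
#' that its deviation can never exceed 1.96 SD, so `"sd"` cannot call
#' group-wise restrictions. A t-quantile can replace z via `use_t`.
#'
#' @param hm A `caax_heatmap`.
#' @param z Normal quantile for the interval (default 1.96).
#' @param min_members Minimum cells beyond cutoff (default 18 of 20).
#' @param cutoff_type "ci_mean" (default) or "sd".
#' @param use_t Use `qt(1 - (1-level)/2, df = 19)` instead of z, where the
#'   level is recovered from `z` (default FALSE).
#' @return data.frame with columns `pair`, `axis` ("row"/"col"), `position`,
#'   `residue`, `context_position`, `direction` ("positive"/"restrictive"),
#'   `n_beyond_cutoff`, `mean_value`, plus attributes `cutoffs` describing the
#'   intervals used.
#' @export
detect_patterns <- function(hm, z = 1.96, min_members = 18L,
                            cutoff_type = c("ci_mean", "sd"), use_t = FALSE) {
  cutoff_type <- match.arg(cutoff_type)
  stopifnot(is(hm, "caax_heatmap"))
  M <- hm$cells
  gm <- hm$grand_mean
  crit <- if (use_t) {
    level <- 2 * stats::pnorm(z) - 1
    stats::qt(1 - (1 - level) / 2, df = nrow(M) - 1L)
  } else z
  out <- list()
  cuts <- list()
  for (axis in c("row", "col")) {
    mns <- if (axis == "row") rowMeans(M) else colMeans(M)
    s <- sd(mns)
    half <- if (cutoff_type == "ci_mean") crit * s / sqrt(length(mns)) else crit * s
    hi <- gm + half
    lo <- gm - half
    cuts[[axis]] <- c(low = lo, high = hi)
    pos_lab <- if (axis == "row") hm$rows else hm$cols
    ctx_lab <- if (axis == "row") hm$cols else hm$rows
    for (i in seq_len(nrow(M))) {
      v <- if (axis == "row") M[i, ] else M[, i]
      n_above <- sum(v > hi)
      n_below <- sum(v < lo)
      if (n_above >= min_members) {
        out[[length(out) + 1L]] <- data.frame(
          pair = hm$pair, axis = axis, position = pos_lab,
          residue = AA_ALPHABET20[i], context_position = ctx_lab,
          direction = "positive", n_beyond_cutoff = n_above,
          mean_value = mean(v), stringsAsFactors = FALSE)
      }
      if (n_below >= min_members) {
        out[[length(out) + 1L]] <- data.frame(
          pair = hm$pair, axis = axis, position = pos_lab,
          residue = AA_ALPHABET20[i], context_position = ctx_lab,
          direction = "restrictive", n_beyond_cutoff = n_below,
          mean_value = mean(v), stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(pair = character(), axis = character(), position = character(),
               residue = character(), context_position = character(),
               direction = character(), n_beyond_cutoff = integer(),
               mean_value = numeric(), stringsAsFactors = FALSE)
  attr(res, "cutoffs") <- cuts
  attr(res, "cutoff_type") <- cutoff_type
  attr(res, "z") <- crit
  res
}

#' Detect patterns across all three heatmaps
#'
#' @param heatmaps Named list from [build_heatmaps()].
#' @param ... Passed to [detect_patterns()].
#' @return Combined pattern data.frame.
#' @export
detect_patterns_all <- function(heatmaps, ...) {
  do.call(rbind, lapply(heatmaps, detect_patterns, ...))
}

#' Contextual HM prenylation score of a motif
#'
#' The HM score sums the three heatmap cells indexed by the motif's residue
#' pairs: mean EF over the 20 motifs sharing (a1, a2), plus the mean over the
#' 20 sharing (a1, X), plus the mean over the 20 sharing (a2, X). Averaging
#' over 20-member groups buffers single-motif outliers; the working positive
#' cutoff for predicting prenylation is an HM score > 3.
#'
#' @param motif Character vector of motifs.
#' @param heatmaps Named list from [build_heatmaps()] (all built from one EF
#'   table).
#' @return Numeric vector of HM scores.
#' @export
hm_score <- function(motif, heatmaps) {
  p <- motif_parts(motif)
  i1 <- match(p$a1, AA_ALPHABET20)
  i2 <- match(p$a2, AA_ALPHABET20)
  ix <- match(p$x, AA_ALPHABET20)
  heatmaps$a1a2$cells[cbind(i1, i2)] +
    heatmaps$a1x$cells[cbind(i1, ix)] +
    heatmaps$a2x$cells[cbind(i2, ix)]
}

#' HM scores for the full motif space
#'
#' @param ef An `ef_table` covering all 8,000 motifs.
#' @return data.frame with columns `motif`, `hm_a1a2`, `hm_a1x`, `hm_a2x`,
#'   `hm_score` (8,000 rows, enumeration order).
#' @export
hm_score_all <- function(ef) {
  hms <- build_heatmaps(ef)
  motifs <- enumerate_cxxx()
  p <- motif_parts(motifs)
  i1 <- match(p$a1, AA_ALPHABET20)
  i2 <- match(p$a2, AA_ALPHABET20)
  ix <- match(p$x, AA_ALPHABET20)
  data.frame(motif = motifs,
             hm_a1a2 = hms$a1a2$cells[cbind(i1, i2)],
             hm_a1x = hms$a1x$cells[cbind(i1, ix)],
             hm_a2x = hms$a2x$cells[cbind(i2, ix)],
             hm_score = hm_score(motifs, hms),
             stringsAsFactors = FALSE)
}

#' Export a heatmap as wide and long TSV tables
#'
#' @param hm A `caax_heatmap`.
#' @param path_wide Path for the 20x20 labelled matrix (optional).
#' @param path_long Path for the long format (pos1_res, pos2_res, mean_ef)
#'   (optional).
#' @return Invisibly, the long-format data.frame.
#' @export
write_heatmap <- function(hm, path_wide = NULL, path_long = NULL) {
  M <- hm$cells
  dimnames(M) <- list(AA_ALPHABET20, AA_ALPHABET20)
  if (!is.null(path_wide)) {
    df <- data.frame(residue = rownames(M), M, check.names = FALSE)
    write.table(df, path_wide, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  long <- expand.grid(pos2_res = AA_ALPHABET20, pos1_res = AA_ALPHABET20,
                      stringsAsFactors = FALSE)[, 2:1]
  long$mean_ef <- as.vector(t(M))
  if (!is.null(path_long)) {
    write.table(long, path_long, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(long)
}
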