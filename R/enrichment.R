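#' Pool replicate counts for one condition
#'
#' Sums per-motif counts across replicates of a single condition. Pooling
#' precedes frequency computation: frequencies are taken over the pooled
#' counts, not averaged per replicate.
#'
#' @param replicates List of `replicate_counts`, all sharing one condition.
#' @return Object of class `condition_counts`: list with `condition`, `counts`
#'   (named integer vector), `total`.
#' @export
pool_replicates <- function(replicates) {
  stopifnot(length(replicates) >= 1)
  conds <- unique(vapply(replicates, function(r) r$condition, ""))
  if (length(conds) != 1L) {
    stop("mixed conditions in pool: ", paste(conds, collapse = ", "))
  }
  all_motifs <- sort(unique(unlist(lapply(replicates, function(r) names(r$counts)))))
  pooled <- setNames(integer(length(all_motifs)), all_motifs)
  for (r in replicates) {
    pooled[names(r$counts)] <- pooled[names(r$counts)] + r$counts
  }
  structure(list(condition = conds, counts = pooled, total = sum(pooled)),
            class = "condition_counts")
}

#' Compute per-motif enrichment factors between conditions
#'
#' The enrichment factor of a motif is the ratio of its abundance at the
#' selective temperature (37C) to its abundance at the permissive temperature
#' (25C), with a pseudocount added to both numerator and denominator so that
#' motifs unobserved at 25C remain finite. Abundance is expressed on a
#' configurable scale; the default is counts per million of the pooled
#' condition, under which the pseudocount is small relative to typical motif
#' abundance (1e6/8000 = 125 cpm) and EFs are insensitive to total depth.
#' A literal `fraction` mode (pseudocount added to frequencies in [0,1]) and a
#' `raw_count` mode are selectable; the mode is recorded in the table metadata
#' because it changes the EF scale materially.
#'
#' @param c25,c37 `condition_counts` for the permissive and selective
#'   condition.
#' @param scale One of "cpm", "raw_count", "fraction".
#' @param pseudocount Positive pseudocount (default 1, in units of the scale).
#' @param complete Expand to the full 8,000-motif space, motifs absent from
#'   both conditions getting count 0 and EF = 1 (default TRUE).
#' @return data.frame of class `ef_table` with columns `motif`, `a1`, `a2`,
#'   `x`, `count25`, `count37`, `freq25`, `freq37`, `ef`, and attributes
#'   `scale`, `pseudocount`.
#' @export
compute_ef <- function(c25, c37, scale = c("cpm", "raw_count", "fraction"),
                       pseudocount = 1, complete = TRUE) {
  scale <- match.arg(scale)
  stopifnot(is(c25, "condition_counts"), is(c37, "condition_counts"),
            pseudocount > 0)
  if (c25$total == 0L || c37$total == 0L) {
    stop("zero total count in condition ",
         if (c25$total == 0L) c25$condition else c37$condition)
  }
  motifs <- if (complete) enumerate_cxxx() else
    sort(unique(c(names(c25$counts), names(c37$counts))))
  n25 <- setNames(numeric(length(motifs)), motifs)
  n25[names(c25$counts)[names(c25$counts) %in% motifs]] <-
    c25$counts[names(c25$counts) %in% motifs]
  n37 <- setNames(numeric(length(motifs)), motifs)
  n37[names(c37$counts)[names(c37$counts) %in% motifs]] <-
    c37$counts[names(c37$counts) %in% motifs]
  f25 <- n25 / c25$total
  f37 <- n37 / c37$total
  v25 <- switch(scale, cpm = f25 * 1e6, raw_count = n25, fraction = f25)
  v37 <- switch(scale, cpm = f37 * 1e6, raw_count = n37, fraction = f37)
  ef <- (v37 + pseudocount) / (v25 + pseudocount)
  out <- cbind(motif_parts(motifs),
               data.frame(count25 = as.integer(n25), count37 = as.integer(n37),
                          freq25 = unname(f25), freq37 = unname(f37),
                          ef = unname(ef)))
  rownames(out) <- NULL
  structure(out, scale = scale, pseudocount = pseudocount,
            class = c("ef_table", "data.frame"))
}

#' Build an ef_table directly from an ef vector (for simulations and I/O)
#'
#' @param motifs Character vector of motifs.
#' @param ef Numeric EF values.
#' @param freq25,freq37 Optional frequency columns.
#' @param scale,pseudocount Metadata to attach.
#' @return `ef_table` data.frame.
#' @export
ef_table <- function(motifs, ef, freq25 = NA_real_, freq37 = NA_real_,
                     scale = "cpm", pseudocount = 1) {
  stopifnot(length(motifs) == length(ef), all(ef > 0))
  out <- cbind(motif_parts(motifs),
               data.frame(freq25 = freq25, freq37 = freq37, ef = ef))
  rownames(out) <- NULL
  structure(out, scale = scale, pseudocount = pseudocount,
            class = c("ef_table", "data.frame"))
}

#' Write / read EF tables as TSV with a commented metadata header
#'
#' @param ef An `ef_table`.
#' @param path Output path.
#' @export
write_ef_table <- function(ef, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale=%s pseudocount=%g",
                     attr(ef, "scale"), attr(ef, "pseudocount")), con)
  cols <- intersect(c("motif", "freq25", "freq37", "ef"), names(ef))
  write.table(ef[, cols], con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ef_table
#' @export
read_ef_table <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- list(scale = "cpm", pseudocount = 1)
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("scale=(\\S+) pseudocount=(\\S+)", first))[[1]]
    if (length(m) == 3) meta <- list(scale = m[2], pseudocount = as.numeric(m[3]))
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("motif", "ef") %in% names(df)))
  ef_table(df$motif, df$ef,
           freq25 = if ("freq25" %in% names(df)) df$freq25 else NA_real_,
           freq37 = if ("freq37" %in% names(df)) df$freq37 else NA_real_,
           scale = meta$scale, pseudocount = meta$pseudocount)
}

#' Assign EF quartiles
#'
#' Motifs are ranked by EF (ties broken by motif lexicographic order) and cut
#' into four equal-size groups; quartile 4 holds the top 25%.
#'
#' @param ef An `ef_table`.
#' @return Named integer vector (motif -> quartile 1..4).
#' @export
assign_quartiles <- function(ef) {
  ord <- order(ef$ef, ef$motif)
  n <- nrow(ef)
  q <- integer(n)
  q[ord] <- ceiling(seq_len(n) / (n / 4))
  q <- pmin(q, 4L)
  setNames(as.integer(q), ef$motif)
}

#' Mean EF over a residue-restricted subgroup
#'
#' Restricts the table to motifs whose a1, a2 and X residues fall in the given
#' sets and summarizes the EF. With `a1_set = a2_set = c("I","L","V")` and
#' `x_set = c("L","F","M","I")` this is the classical GGTase-I-leaning
#' CaaL/F/M/I subgroup (n = 36).
#'
#' @param ef An `ef_table`.
#' @param a1_set,a2_set,x_set Nonempty residue sets.
#' @return List with `n`, `mean`, `sd` (population SD; NA with a warning flag
#'   when the intersection is empty).
#' @export
subgroup_mean_ef <- function(ef, a1_set = AA_ALPHABET20,
                             a2_set = AA_ALPHABET20, x_set = AA_ALPHABET20) {
  stopifnot(length(a1_set) > 0, length(a2_set) > 0, length(x_set) > 0)
  sel <- ef$a1 %in% a1_set & ef$a2 %in% a2_set & ef$x %in% x_set
  v <- ef$ef[sel]
  n <- length(v)
  if (n == 0L) {
    return(list(n = 0L, mean = NA_real_, sd = NA_real_, empty = TRUE))
  }
  list(n = n, mean = mean(v),
       sd = sqrt(mean((v - mean(v))^2)), empty = FALSE)
}
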