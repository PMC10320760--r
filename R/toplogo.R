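#' Select the top-enriched fraction of motifs
#'
#' Motifs ranked by EF, descending; ties broken by motif lexicographic order
#' (ascending). The set size is `round(fraction * n)`, so the default 5% of
#' the full space is 400 motifs.
#'
#' @param ef An `ef_table`.
#' @param fraction Fraction in (0, 1] (default 0.05).
#' @return Character vector of motifs.
#' @export
top_fraction <- function(ef, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  k <- round(fraction * nrow(ef))
  ord <- order(-ef$ef, ef$motif)
  ef$motif[ord][seq_len(k)]
}

#' Position frequency matrix of a motif set
#'
#' Counts and relative frequencies of each residue at the three variable
#' positions over a motif set; the frequency form feeds any sequence-logo
#' renderer (the screen's logos are frequency logos, not information-content
#' logos).
#'
#' @param motifs Nonempty character vector of motifs.
#' @return List of class `pfm`: `counts` and `freq` (3 x 20 matrices, rows
#'   a1/a2/x), `n`.
#' @export
pfm <- function(motifs) {
  stopifnot(length(motifs) > 0)
  p <- motif_parts(motifs)
  counts <- rbind(
    a1 = table(factor(p$a1, levels = AA_ALPHABET20)),
    a2 = table(factor(p$a2, levels = AA_ALPHABET20)),
    x  = table(factor(p$x, levels = AA_ALPHABET20)))
  counts <- matrix(as.integer(counts), nrow = 3,
                   dimnames = list(c("a1", "a2", "x"), AA_ALPHABET20))
  structure(list(counts = counts, freq = counts / length(motifs),
                 n = length(motifs)), class = "pfm")
}

#' Residues absent at a position within a motif set
#'
#' Returns the residues that never occur at the given position, optionally
#' restricting first to motifs carrying a given residue at another position
#' (the conditioning used when reading the 3D projections of the enrichment
#' space along one axis).
#'
#' @param motifs Nonempty character vector of motifs.
#' @param position One of "a1", "a2", "x".
#' @param condition_position,condition_residue Optional conditioning: keep
#'   only motifs with `condition_residue` at `condition_position`.
#' @return Character vector of absent residues (possibly empty).
#' @export
absent_residues <- function(motifs, position = c("a1", "a2", "x"),
                            condition_position = NULL,
                            condition_residue = NULL) {
  position <- match.arg(position)
  stopifnot(length(motifs) > 0)
  p <- motif_parts(motifs)
  if (!is.null(condition_position)) {
    stopifnot(condition_position %in% c("a1", "a2", "x"),
              !is.null(condition_residue))
    p <- p[p[[condition_position]] %in% condition_residue, , drop = FALSE]
  }
  setdiff(AA_ALPHABET20, unique(p[[position]]))
}

#' Write logo inputs: PFM tables and the color-group annotation
#'
#' Exports the position frequency matrix (counts and frequencies) as TSV and
#' a JSON color scheme grouping residues as in the screen's custom logo
#' palette (Cys blue; D/R/E/H/K green; N/Q/S/T/Y black; I/L/V red; remainder
#' purple). Rendering is left to external logo tools.
#'
#' @param x A `pfm`.
#' @param prefix Output path prefix; writes `<prefix>_counts.tsv`,
#'   `<prefix>_freq.tsv`, `<prefix>_colors.json`.
#' @return Invisibly, the paths written.
#' @export
write_logo_inputs <- function(x, prefix) {
  stopifnot(is(x, "pfm"))
  paths <- paste0(prefix, c("_counts.tsv", "_freq.tsv", "_colors.json"))
  for (i in 1:2) {
    M <- if (i == 1) x$counts else x$freq
    df <- data.frame(position = rownames(M), M, check.names = FALSE)
    write.table(df, paths[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  scheme <- list(blue = "C",
                 green = c("D", "R", "E", "H", "K"),
                 black = c("N", "Q", "S", "T", "Y"),
                 red = c("I", "L", "V"),
                 purple = c("A", "G", "M", "F", "P", "W"))
  jsonlite::write_json(scheme, paths[3], pretty = TRUE)
  invisible(paths)
}

#' Long-format table of the enrichment space for external 3D/4D plotting
#'
#' @param ef An `ef_table`.
#' @param motifs Optional subset (e.g. from [top_fraction()]).
#' @param path Optional TSV output path.
#' @return data.frame (a1, a2, x, ef).
#' @export
ef_space_table <- function(ef, motifs = NULL, path = NULL) {
  df <- ef[, c("a1", "a2", "x", "ef")]
  if (!is.null(motifs)) df <- df[ef$motif %in% motifs, , drop = FALSE]
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
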