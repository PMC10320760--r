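#' @importFrom methods as is
#' @importFrom stats rnorm rmultinom sd setNames
#' @importFrom utils read.delim write.table combn head
NULL

#' The canonical 20-letter amino acid alphabet
#'
#' One-letter codes in alphabetical order (A < C < D < ... < Y). No ambiguity
#' codes and no stop symbol: the trimer-codon library encodes exactly one codon
#' per amino acid and excludes stops, so the package works end-to-end on this
#' alphabet only.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# One fixed codon per amino acid, mirroring a trimer-phosphoramidite library
# design (single unique codon per residue, no stops). Ala is GCA so that the
# CASQ insert reads GCATCTCAA as on the parent construct.
CODON20 <- c(A = "GCA", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
             G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "TTG",
             M = "ATG", N = "AAT", P = "CCA", Q = "CAA", R = "AGA",
             S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

#' Enumerate the full CXXX motif space
#'
#' Returns all 20^3 = 8,000 four-residue motifs with a fixed N-terminal-of-tail
#' cysteine, in lexicographic order of the variable XXX part (a1 varies
#' slowest, X fastest), so `enumerate_cxxx()[1] == "CAAA"`.
#'
#' @return Character vector of 8,000 motif strings, each 4 characters starting
#'   with "C".
#' @examples
#' length(enumerate_cxxx())
#' head(enumerate_cxxx())
#' @export
enumerate_cxxx <- function() {
  g <- expand.grid(x = AA_ALPHABET20, a2 = AA_ALPHABET20, a1 = AA_ALPHABET20,
                   stringsAsFactors = FALSE)
  paste0("C", g$a1, g$a2, g$x)
}

#' Split motifs into their variable positions
#'
#' @param motifs Character vector of CXXX motif strings.
#' @return data.frame with columns `motif`, `a1`, `a2`, `x`.
#' @export
motif_parts <- function(motifs) {
  stopifnot(is.character(motifs))
  bad <- nchar(motifs) != 4L | substr(motifs, 1, 1) != "C"
  if (any(bad)) {
    stop("not a CXXX motif: ", motifs[which(bad)[1]])
  }
  parts <- data.frame(motif = motifs,
                      a1 = substr(motifs, 2, 2),
                      a2 = substr(motifs, 3, 3),
                      x  = substr(motifs, 4, 4),
                      stringsAsFactors = FALSE)
  ok <- parts$a1 %in% AA_ALPHABET20 & parts$a2 %in% AA_ALPHABET20 &
    parts$x %in% AA_ALPHABET20
  if (!all(ok)) {
    stop("non-standard residue in motif: ", motifs[which(!ok)[1]])
  }
  parts
}

#' Translate a 9-nt library insert into the XXX residues
#'
#' Translates the three codons following the fixed Cys codon under the standard
#' genetic code. Inserts containing a stop codon or a non-ACGT character are
#' rejected (the library design excludes both), as are inputs that are not
#' exactly 9 nt.
#'
#' @param nt9 Character vector of 9-nt uppercase DNA strings.
#' @return data.frame with columns `insert`, `motif` (NA when rejected) and
#'   `reject` (NA, or one of "bad_length", "invalid_base", "stop_codon").
#' @examples
#' translate_insert("GCATCTCAA")  # CASQ
#' translate_insert("TAAGCAGCA")  # stop codon
#' @export
translate_insert <- function(nt9) {
  stopifnot(is.character(nt9))
  n <- length(nt9)
  motif <- rep(NA_character_, n)
  reject <- rep(NA_character_, n)
  badlen <- is.na(nt9) | nchar(nt9) != 9L
  reject[badlen] <- "bad_length"
  idx <- which(!badlen)
  if (length(idx)) {
    code <- Biostrings::GENETIC_CODE
    c1 <- code[substr(nt9[idx], 1, 3)]
    c2 <- code[substr(nt9[idx], 4, 6)]
    c3 <- code[substr(nt9[idx], 7, 9)]
    invalid <- is.na(c1) | is.na(c2) | is.na(c3)
    stopc <- !invalid & (c1 == "*" | c2 == "*" | c3 == "*")
    reject[idx[invalid]] <- "invalid_base"
    reject[idx[stopc]] <- "stop_codon"
    ok <- !invalid & !stopc
    motif[idx[ok]] <- paste0("C", c1[ok], c2[ok], c3[ok])
  }
  data.frame(insert = nt9, motif = motif, reject = reject,
             stringsAsFactors = FALSE)
}

#' Scan protein sequences for a C-terminal CXXX motif
#'
#' Reports the terminal 4 residues of each record when they form a valid CXXX
#' motif (Cys at position -4, standard residues at -3..-1). Records shorter
#' than 4 residues, or with non-standard residues in the tail, yield NA. An
#' optional pattern such as "CKQX" filters the hits ("X" is a wildcard at any
#' variable position).
#'
#' @param fasta Path to a protein FASTA file, or a named character vector of
#'   protein sequences, or a `Biostrings::AAStringSet`.
#' @param pattern Optional motif pattern, 4 characters, "X" as wildcard.
#' @return data.frame with columns `name`, `motif` (NA when absent).
#' @export
scan_cterminal <- function(fasta, pattern = NULL) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    seqs <- Biostrings::readAAStringSet(fasta)
    nm <- names(seqs)
    ss <- as.character(seqs)
  } else if (is(fasta, "AAStringSet")) {
    nm <- names(fasta)
    ss <- as.character(fasta)
  } else {
    stopifnot(is.character(fasta))
    nm <- if (is.null(names(fasta))) as.character(seq_along(fasta)) else names(fasta)
    ss <- unname(fasta)
  }
  if (is.null(nm)) nm <- as.character(seq_along(ss))
  tail4 <- ifelse(nchar(ss) >= 4L, substr(ss, nchar(ss) - 3L, nchar(ss)), NA)
  valid <- !is.na(tail4) & substr(tail4, 1, 1) == "C" &
    substr(tail4, 2, 2) %in% AA_ALPHABET20 &
    substr(tail4, 3, 3) %in% AA_ALPHABET20 &
    substr(tail4, 4, 4) %in% AA_ALPHABET20
  motif <- ifelse(valid, tail4, NA_character_)
  if (!is.null(pattern)) {
    stopifnot(nchar(pattern) == 4L)
    keep <- rep(TRUE, length(motif))
    for (i in 1:4) {
      p <- substr(pattern, i, i)
      if (p != "X") keep <- keep & substr(motif, i, i) == p
    }
    motif[!(keep %in% TRUE)] <- NA_character_
  }
  data.frame(name = nm, motif = motif, stringsAsFactors = FALSE)
}

#' Write a motif list as plain text
#'
#' @param motifs Character vector of motifs.
#' @param path Output path; one motif per line.
#' @export
write_motif_list <- function(motifs, path) {
  writeLines(motifs, path)
  invisible(path)
}
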