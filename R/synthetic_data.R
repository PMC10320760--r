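# Run code under a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulation configuration for the synthetic screen
#'
#' Defaults emulate the study conditions of the competitive-growth screen:
#' all 8,000 motifs in a trimer-codon library with a ~10x abundance imbalance
#' (lognormal, sigma 0.447 puts the 99.5th/0.5th percentile ratio at 10),
#' ~8 generations of growth with temperature-dependent fitness, 8 replicates
#' per temperature condition, and 5e5 reads per replicate. Selection is
#' multiplicative per generation: a motif of prenylation propensity p grows by
#' (1 + s*p) per generation at 37C and is neutral at 25C.
#'
#' @param n_reads Reads per replicate (default 5e5).
#' @param replicates_25c,replicates_37c Replicates per condition (default 8).
#' @param generations Growth generations G (default 8).
#' @param s Selection coefficient per generation at 37C (default 0.3; 0 at
#'   25C always).
#' @param library_sigma Lognormal sigma of the naive library imbalance
#'   (default 0.447).
#' @param junk_fraction Fraction of reads exercising QC paths (half anchor-free,
#'   half low-quality; default 0.02).
#' @param quality_mean,quality_sd Per-read Phred level model: each read gets a
#'   constant quality drawn from N(mean, sd), clipped to [25, 40] for clean
#'   reads (default 37 / 4, giving ~96-97% of reads at Q30+).
#' @param truth_params Rule parameters for [ground_truth_rules()].
#' @param seed Master seed; every random draw in the simulator flows from it.
#' @param emit_fastq Write FASTQ files (default FALSE; count tables are always
#'   produced and identical either way).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_reads = 5e5, replicates_25c = 8L,
                              replicates_37c = 8L, generations = 8L,
                              s = 0.3, library_sigma = 0.447,
                              junk_fraction = 0.02,
                              quality_mean = 37, quality_sd = 4,
                              truth_params = truth_params_default(),
                              seed = 1L, emit_fastq = FALSE) {
  stopifnot(s >= 0, library_sigma >= 0, n_reads >= 0,
            junk_fraction >= 0, junk_fraction < 1)
  structure(list(n_reads = n_reads, replicates_25c = as.integer(replicates_25c),
                 replicates_37c = as.integer(replicates_37c),
                 generations = generations, s = s,
                 library_sigma = library_sigma,
                 junk_fraction = junk_fraction,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 truth_params = truth_params, seed = as.integer(seed),
                 emit_fastq = isTRUE(emit_fastq)),
            class = "simulation_config")
}

#' Default ground-truth rule parameters
#'
#' The rule set plants the screen's headline specificity determinants:
#' charged residues D/K/R at a2 abolish prenylation, E at a2 is milder
#' (matching its weaker, context-dependent restriction), K/P/R at X are
#' strongly unfavourable unless a2 carries a rescuing aliphatic I/L/M/V, Q at
#' X earns a small bonus, and everything else is near-fully prenylated.
#'
#' @param restricted_a2_strong,restricted_a2_mild,restricted_x,rescue_a2
#'   Residue sets.
#' @param p_restricted_strong,p_restricted_mild,p_x_restricted,p_base
#'   Propensities for the respective classes.
#' @param q_bonus Additive bonus for X = Q (capped at 1).
#' @param noise_sd SD of additive Gaussian noise, truncated to keep
#'   propensities in [0, 1].
#' @return List of rule parameters.
#' @export
truth_params_default <- function(restricted_a2_strong = c("D", "K", "R"),
                                 restricted_a2_mild = "E",
                                 restricted_x = c("K", "P", "R"),
                                 rescue_a2 = c("I", "L", "M", "V"),
                                 p_restricted_strong = 0.02,
                                 p_restricted_mild = 0.15,
                                 p_x_restricted = 0.15,
                                 p_base = 0.95, q_bonus = 0.05,
                                 noise_sd = 0.03) {
  list(restricted_a2_strong = restricted_a2_strong,
       restricted_a2_mild = restricted_a2_mild,
       restricted_x = restricted_x, rescue_a2 = rescue_a2,
       p_restricted_strong = p_restricted_strong,
       p_restricted_mild = p_restricted_mild,
       p_x_restricted = p_x_restricted, p_base = p_base,
       q_bonus = q_bonus, noise_sd = noise_sd)
}

#' Rule-based prenylation ground truth
#'
#' Deterministic given motifs, parameters and seed: the rule propensity plus
#' truncated Gaussian noise.
#'
#' @param motifs Character vector (default the full space).
#' @param params From [truth_params_default()].
#' @param seed Seed for the noise draw (no noise when `noise_sd = 0`).
#' @return Named numeric vector of propensities in [0, 1].
#' @export
ground_truth_rules <- function(motifs = enumerate_cxxx(),
                               params = truth_params_default(), seed = 1L) {
  p <- motif_parts(motifs)
  prop <- rep(params$p_base, length(motifs))
  prop[p$x == "Q"] <- pmin(1, params$p_base + params$q_bonus)
  xbad <- p$x %in% params$restricted_x & !(p$a2 %in% params$rescue_a2)
  prop[xbad] <- params$p_x_restricted
  prop[p$a2 %in% params$restricted_a2_mild] <- params$p_restricted_mild
  prop[p$a2 %in% params$restricted_a2_strong] <- params$p_restricted_strong
  if (params$noise_sd > 0) {
    noise <- with_seed(seed, rnorm(length(motifs), 0, params$noise_sd))
    prop <- pmin(1, pmax(0, prop + noise))
  }
  setNames(prop, motifs)
}

#' Simulate the naive library abundance
#'
#' Lognormal weights normalized to frequencies; `sigma = 0` gives the exactly
#' uniform library.
#'
#' @param config A `simulation_config`.
#' @return Named numeric vector of frequencies over the 8,000 motifs (sums to
#'   1).
#' @export
simulate_library <- function(config = simulation_config()) {
  motifs <- enumerate_cxxx()
  w <- if (config$library_sigma == 0) rep(1, length(motifs)) else
    with_seed(config$seed, exp(rnorm(length(motifs), 0, config$library_sigma)))
  setNames(w / sum(w), motifs)
}

#' Apply competitive-growth selection to library frequencies
#'
#' Post-growth frequency of motif m is proportional to
#' `naive(m) * (1 + s * propensity(m))^G` at the selective temperature; at
#' 25C selection is neutral (s treated as 0) and the naive frequencies are
#' returned unchanged.
#'
#' @param naive Named frequency vector from [simulate_library()].
#' @param truth Named propensity vector from [ground_truth_rules()].
#' @param config A `simulation_config`.
#' @param condition "25C" or "37C".
#' @return Named frequency vector (sums to 1).
#' @export
simulate_selection <- function(naive, truth, config = simulation_config(),
                               condition = c("37C", "25C")) {
  condition <- match.arg(condition)
  stopifnot(identical(names(naive), names(truth)))
  s_eff <- if (condition == "37C") config$s else 0
  w <- naive * (1 + s_eff * truth)^config$generations
  w / sum(w)
}

# Fixed read scaffold: 21 nt upstream context + 21 nt anchor (ends with the
# Cys codon TGT) + 9 nt variable insert + stop + downstream context = 100 nt.
READ_UPSTREAM <- "GATTCCGATGAAGAAGAACAAGGTGGCGAAGGTGTACAATGT" # last 21 = anchor
READ_DOWNSTREAM <- "TGATTTTCTTGATAAAAAAAGATCCAGCATATAATCCCTGCTTTAGCGG"

build_reads <- function(motifs) {
  p <- motif_parts(motifs)
  ins <- paste0(CODON20[p$a1], CODON20[p$a2], CODON20[p$x])
  paste0(READ_UPSTREAM, ins, READ_DOWNSTREAM)
}

phred_string <- function(q, len) {
  vapply(q, function(qi) strrep(intToUtf8(qi + 33L), len), "")
}

#' Sample sequencing reads for each replicate
#'
#' For every replicate, clean reads are a multinomial draw from the condition
#' frequencies; the exact draw is returned as the truth table. When FASTQ
#' emission is on, reads embed the anchor, the motif's single fixed codon per
#' amino acid and the downstream stop context in a 100-nt scaffold, with a
#' constant per-read Phred quality drawn from the quality model. A configured
#' fraction of junk reads (half anchor-free random sequence, half low-quality
#' Q10) exercises the extraction QC paths; junk reads are not part of the
#' truth counts.
#'
#' @param frequencies Named frequency vector for one condition.
#' @param config A `simulation_config`.
#' @param condition Condition label used in replicate ids.
#' @param n_replicates Number of replicates to draw.
#' @param outdir Directory for FASTQ files (required when `emit_fastq`).
#' @param seed Seed for this condition's draws.
#' @return List with `truth` (list of named count vectors per replicate) and
#'   `fastq` (character vector of paths, or NULL).
#' @export
sample_reads <- function(frequencies, config = simulation_config(),
                         condition = "25C",
                         n_replicates = config$replicates_25c,
                         outdir = NULL, seed = config$seed) {
  stopifnot(config$n_reads >= 0)
  motifs <- names(frequencies)
  n_junk <- round(config$junk_fraction * config$n_reads)
  n_clean <- config$n_reads - n_junk
  # truth counts are drawn first under their own seed so they are identical
  # whether or not FASTQ emission is enabled
  truth <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      draw <- if (n_clean > 0)
        as.integer(rmultinom(1, n_clean, frequencies)) else
          integer(length(motifs))
      names(draw) <- motifs
      draw[draw > 0L]
    })
  })
  paths <- NULL
  if (config$emit_fastq) {
    stopifnot(!is.null(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- with_seed(seed + 7919L, {
      vapply(seq_len(n_replicates), function(r) {
        path <- file.path(outdir, sprintf("%s_rep%02d.fastq.gz", condition, r))
        emit_fastq_replicate(truth[[r]], n_junk, config, path,
                             sprintf("%s_rep%02d", condition, r))
        path
      }, "")
    })
  }
  list(truth = truth, fastq = paths)
}

emit_fastq_replicate <- function(draw, n_junk, config, path, rep_id) {
  motifs <- rep(names(draw), draw)
  n_clean <- length(motifs)
  seqs <- build_reads(motifs)
  q <- pmin(40L, pmax(25L, round(rnorm(n_clean, config$quality_mean,
                                       config$quality_sd))))
  is_junk <- logical(n_clean)
  if (n_junk > 0) {
    n_noanchor <- ceiling(n_junk / 2)
    n_lowq <- n_junk - n_noanchor
    junk_seq <- vapply(seq_len(n_noanchor), function(i)
      paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = ""),
      "")
    junk_q <- rep(35L, n_noanchor)
    if (n_lowq > 0) {
      lowq_motifs <- names(draw)[sample.int(length(draw), n_lowq, replace = TRUE)]
      junk_seq <- c(junk_seq, build_reads(lowq_motifs))
      junk_q <- c(junk_q, rep(10L, n_lowq))
    }
    seqs <- c(seqs, junk_seq)
    q <- c(q, junk_q)
    is_junk <- c(is_junk, rep(TRUE, n_junk))
  }
  ord <- sample.int(length(seqs))
  seqs <- seqs[ord]
  q <- q[ord]
  qs <- phred_string(q, nchar(seqs[1]))
  ids <- sprintf("@%s_read%07d", rep_id, seq_along(seqs))
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(paste(ids, seqs, "+", qs, sep = "\n"), con)
  invisible(path)
}

#' Simulate the entire screen
#'
#' Library construction, two-temperature competitive growth, and per-replicate
#' read sampling, all driven by one seed. Returns everything downstream
#' stages need: the ground truth, naive and post-selection frequencies, the
#' per-replicate truth count tables (as `replicate_counts` objects), and
#' FASTQ paths when emission is on.
#'
#' @param config A `simulation_config`.
#' @param outdir Output directory for FASTQ files (only used with
#'   `emit_fastq`).
#' @return List of class `screen_simulation` with elements `config`, `truth`
#'   (propensities), `naive`, `freq_25c`, `freq_37c`, `replicates` (list of
#'   `replicate_counts` across both conditions), `fastq` (named list or
#'   NULL).
#' @export
simulate_screen <- function(config = simulation_config(), outdir = NULL) {
  truth <- ground_truth_rules(params = config$truth_params,
                              seed = config$seed + 1L)
  naive <- simulate_library(config)
  f25 <- simulate_selection(naive, truth, config, "25C")
  f37 <- simulate_selection(naive, truth, config, "37C")
  s25 <- sample_reads(f25, config, "25C", config$replicates_25c, outdir,
                      seed = config$seed + 2L)
  s37 <- sample_reads(f37, config, "37C", config$replicates_37c, outdir,
                      seed = config$seed + 3L)
  reps <- c(
    lapply(seq_along(s25$truth), function(r)
      replicate_counts(s25$truth[[r]], sprintf("25C_rep%02d", r), "25C",
                       n_reads_total = sum(s25$truth[[r]]))),
    lapply(seq_along(s37$truth), function(r)
      replicate_counts(s37$truth[[r]], sprintf("37C_rep%02d", r), "37C",
                       n_reads_total = sum(s37$truth[[r]]))))
  structure(list(config = config, truth = truth, naive = naive,
                 freq_25c = f25, freq_37c = f37, replicates = reps,
                 fastq = if (config$emit_fastq)
                   list(`25C` = s25$fastq, `37C` = s37$fastq) else NULL),
            class = "screen_simulation")
}

#' EF table straight from a simulated screen
#'
#' Convenience: pools the simulated truth counts per condition and computes
#' the EF table, bypassing FASTQ round-tripping.
#'
#' @param sim A `screen_simulation`.
#' @param ... Passed to [compute_ef()].
#' @return `ef_table`.
#' @export
sim_ef_table <- function(sim, ...) {
  is25 <- vapply(sim$replicates, function(r) r$condition, "") == "25C"
  compute_ef(pool_replicates(sim$replicates[is25]),
             pool_replicates(sim$replicates[!is25]), ...)
}
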