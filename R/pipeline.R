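#' Default run configuration
#'
#' A plain nested list (serializable as YAML) controlling [run_all()]. The
#' pipeline can start from simulation, from FASTQ files, from count tables,
#' or directly from an EF table; later entry points skip the earlier stages.
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param simulate Simulate the screen as input (default TRUE when no other
#'   input is given).
#' @param sim Arguments forwarded to [simulation_config()] (seed and
#'   `emit_fastq` are taken from the run config).
#' @param emit_fastq Route the simulation through FASTQ files and
#'   [count_replicate()] instead of using the truth counts directly.
#' @param fastq_25c,fastq_37c Paths to FASTQ files per condition (used when
#'   `simulate` is FALSE).
#' @param counts_25c,counts_37c Paths to count TSVs per condition.
#' @param ef_table Path to a pre-made EF table (skips extraction and pooling).
#' @param ef Arguments for [compute_ef()]: `scale`, `pseudocount`.
#' @param extraction Arguments for [extraction_config()].
#' @param patterns Arguments for [detect_patterns()]: `z`, `min_members`,
#'   `cutoff_type`.
#' @param tree Arguments for the tree stage: `label_threshold`,
#'   `max_set_size`, `max_depth`, `min_samples`.
#' @param logo Arguments for the logo stage: `fraction`.
#' @return Nested list of class `run_config`.
#' @export
run_config <- function(outdir = "cxxxscreen_run", seed = 1L, simulate = TRUE,
                       sim = list(), emit_fastq = FALSE,
                       fastq_25c = NULL, fastq_37c = NULL,
                       counts_25c = NULL, counts_37c = NULL,
                       ef_table = NULL,
                       ef = list(scale = "cpm", pseudocount = 1),
                       extraction = list(),
                       patterns = list(z = 1.96, min_members = 18L,
                                       cutoff_type = "ci_mean"),
                       tree = list(label_threshold = 1.0, max_set_size = 5L,
                                   max_depth = 3L, min_samples = 50L),
                       logo = list(fraction = 0.05)) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 simulate = simulate, sim = sim, emit_fastq = emit_fastq,
                 fastq_25c = fastq_25c, fastq_37c = fastq_37c,
                 counts_25c = counts_25c, counts_37c = counts_37c,
                 ef_table = ef_table, ef = ef, extraction = extraction,
                 patterns = patterns, tree = tree, logo = logo),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return `run_config` object.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

pattern_json <- function(patterns, path) {
  jsonlite::write_json(
    list(cutoff_type = attr(patterns, "cutoff_type"),
         critical_value = attr(patterns, "z"),
         patterns = patterns),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- simulate (optional), count, QC, pool, EF,
#' heatmaps + patterns + HM scores, top-fraction logo inputs, decision tree,
#' predictor benchmark -- writing every intermediate as a file under the
#' output directory so any stage can be audited or re-entered, and finishing
#' with a manifest recording parameters and the md5 checksum of every output.
#' The run is a pure function of the config: re-running with the same config
#' and seed reproduces every file byte for byte.
#'
#' @param config A `run_config` (or path to a YAML file).
#' @return Invisibly, a list with the manifest and the main in-memory results
#'   (`ef`, `heatmaps`, `patterns`, `hm_scores`, `tree`, `benchmark`).
#' @export
run_all <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  ecfg <- do.call(extraction_config, config$extraction)
  written <- character(0)
  note <- function(p) { written <<- c(written, p); p }

  ef <- NULL
  qc_report <- NULL
  if (!is.null(config$ef_table)) {
    ef <- stage("ef_load", read_ef_table(config$ef_table))
  } else {
    reps <- NULL
    if (isTRUE(config$simulate)) {
      sim_args <- config$sim
      sim_args$seed <- config$seed
      sim_args$emit_fastq <- isTRUE(config$emit_fastq)
      scfg <- do.call(simulation_config, sim_args)
      sim <- stage("simulate", simulate_screen(scfg, file.path(out, "fastq")))
      stage("simulate_write", {
        write.table(
          data.frame(motif = names(sim$truth), propensity = unname(sim$truth)),
          note(file.path(out, "ground_truth.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        for (r in sim$replicates) {
          write_replicate_counts(
            r, note(file.path(out, sprintf("truth_counts_%s.tsv", r$replicate_id))))
        }
      })
      if (isTRUE(config$emit_fastq)) {
        reps <- stage("count", {
          c(lapply(sim$fastq$`25C`, count_replicate, cfg = ecfg,
                   condition = "25C"),
            lapply(sim$fastq$`37C`, count_replicate, cfg = ecfg,
                   condition = "37C"))
        })
        for (p in unlist(sim$fastq)) note(p)
      } else {
        reps <- sim$replicates
      }
    } else if (!is.null(config$fastq_25c)) {
      reps <- stage("count", {
        c(lapply(config$fastq_25c, count_replicate, cfg = ecfg,
                 condition = "25C"),
          lapply(config$fastq_37c, count_replicate, cfg = ecfg,
                 condition = "37C"))
      })
    } else if (!is.null(config$counts_25c)) {
      reps <- stage("load_counts", {
        c(lapply(config$counts_25c, read_replicate_counts, condition = "25C"),
          lapply(config$counts_37c, read_replicate_counts, condition = "37C"))
      })
    } else {
      stop("stage 'input' failed: no input configured")
    }
    qc <- stage("qc", qc_replicates(reps, ecfg))
    qc_report <- qc$report
    stage("qc_write", {
      jsonlite::write_json(qc$report, note(file.path(out, "qc_report.json")),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      for (r in qc$retained) {
        write_replicate_counts(
          r, note(file.path(out, sprintf("counts_%s.tsv", r$replicate_id))))
      }
    })
    is25 <- vapply(qc$retained, function(r) r$condition, "") == "25C"
    ef <- stage("ef", compute_ef(pool_replicates(qc$retained[is25]),
                                 pool_replicates(qc$retained[!is25]),
                                 scale = config$ef$scale,
                                 pseudocount = config$ef$pseudocount))
    stage("ef_write", write_ef_table(ef, note(file.path(out, "ef_table.tsv"))))
  }

  heatmaps <- stage("heatmap", build_heatmaps(ef))
  stage("heatmap_write", for (p in names(heatmaps)) {
    write_heatmap(heatmaps[[p]],
                  note(file.path(out, sprintf("heatmap_%s.tsv", p))),
                  note(file.path(out, sprintf("heatmap_%s_long.tsv", p))))
  })
  patterns <- stage("patterns",
                    do.call(detect_patterns_all,
                            c(list(heatmaps), config$patterns)))
  stage("patterns_write",
        pattern_json(patterns, note(file.path(out, "patterns.json"))))
  hm <- stage("hmscore", hm_score_all(ef))
  stage("hmscore_write",
        write.table(hm, note(file.path(out, "hm_scores.tsv")), sep = "\t",
                    quote = FALSE, row.names = FALSE))

  top <- stage("logo", top_fraction(ef, config$logo$fraction))
  stage("logo_write", {
    write_motif_list(top, note(file.path(out, "top_motifs.txt")))
    for (p in write_logo_inputs(pfm(top), file.path(out, "top_logo"))) note(p)
    ef_space_table(ef, top, note(file.path(out, "top_ef_space.tsv")))
  })

  tree <- stage("tree", {
    labels <- binarize_labels(ef, config$tree$label_threshold)
    fit_caax_tree(labels, max_set_size = config$tree$max_set_size,
                  max_depth = config$tree$max_depth,
                  min_samples = config$tree$min_samples)
  })
  stage("tree_write", {
    write_tree_json(tree, note(file.path(out, "tree.json")))
    writeLines(extract_rules(tree), note(file.path(out, "tree_rules.txt")))
  })

  bench <- stage("benchmark", benchmark_table3())
  stage("benchmark_write",
        write_benchmark_json(bench, note(file.path(out, "benchmark.json"))))

  manifest <- list(
    package_version = as.character(utils::packageVersion("cxxxscreen")),
    seed = config$seed,
    parameters = unclass(config),
    outputs = lapply(setNames(sort(unique(written)), NULL), function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, ef = ef, heatmaps = heatmaps,
                 patterns = patterns, hm_scores = hm, tree = tree,
                 benchmark = bench, qc = qc_report))
}
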