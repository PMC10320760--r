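#!/usr/bin/env Rscript
# Benchmark the four prenylation predictors on the packaged 48-motif
# gel-shift reference set: PrePS (> -2), the published SVM (> 0), the
# Ras-reporter screen EF (> 3) and the Ydj1-screen HM score (> 3).

library(cxxxscreen)
dir.create("results/benchmark", showWarnings = FALSE, recursive = TRUE)

bench <- benchmark_table3()
print(bench)
write_benchmark_json(bench, "results/benchmark/benchmark.json")

# the same classify/confusion path applied to the HM scores of the current
# simulated screen, against its own ground truth, as a sanity check
if (file.exists("results/heatmaps/hm_scores.tsv") &&
    file.exists("results/sim/ground_truth.tsv")) {
  hm <- read.delim("results/heatmaps/hm_scores.tsv")
  truth <- read.delim("results/sim/ground_truth.tsv")
  obs <- ifelse(truth$propensity[match(hm$motif, truth$motif)] > 0.5,
                "positive", "negative")
  cs <- confusion(classify(setNames(hm$hm_score, hm$motif), 3), obs)
  cat("simulated screen, HM > 3 vs planted truth:\n")
  print(cs)
}
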