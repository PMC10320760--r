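#!/usr/bin/env Rscript
# Simulate the competitive-growth screen at study conditions: all 8,000 CXXX
# motifs, ~10x library imbalance, 8 generations of selection at 37C against a
# neutral 25C arm, 8 replicates per condition, 5e5 reads per replicate. A
# small FASTQ-emitting companion run (2 + 2 replicates) exercises the read
# path used by 02_count_reads.R.

library(cxxxscreen)
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 20230401L)
sim <- simulate_screen(cfg)

write.table(data.frame(motif = names(sim$truth),
                       propensity = unname(sim$truth)),
            "results/sim/ground_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (r in sim$replicates) {
  write_replicate_counts(r, sprintf("results/sim/counts_%s.tsv", r$replicate_id))
}

cat("simulated", length(sim$replicates), "replicates;",
    "reads per replicate:", cfg$n_reads, "\n")
cat("library imbalance (99.5%/0.5% frequency ratio):",
    round(unname(quantile(sim$naive, 0.995) / quantile(sim$naive, 0.005)), 2),
    "\n")

# FASTQ companion run, small enough to keep under version-controlled scale
cfg_fq <- simulation_config(n_reads = 5e4, replicates_25c = 2L,
                            replicates_37c = 2L, seed = 20230402L,
                            emit_fastq = TRUE)
sim_fq <- simulate_screen(cfg_fq, "results/sim/fastq")
for (r in sim_fq$replicates) {
  write_replicate_counts(
    r, sprintf("results/sim/fastq/truth_%s.tsv", r$replicate_id))
}
cat("emitted FASTQ:", length(unlist(sim_fq$fastq)), "files under results/sim/fastq\n")
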