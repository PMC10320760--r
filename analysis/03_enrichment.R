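#!/usr/bin/env Rscript
# Pool the full-scale simulated replicates per temperature, compute the
# pseudocount-corrected enrichment factors on the cpm scale, and summarize
# the EF landscape: range, quartiles, and the GGTase-I-leaning subgroups.

library(cxxxscreen)
stopifnot(dir.exists("results/sim"))
dir.create("results/ef", showWarnings = FALSE)

paths <- list.files("results/sim", pattern = "^counts_", full.names = TRUE)
reps <- lapply(paths, function(p) {
  read_replicate_counts(p, condition = if (grepl("25C", p)) "25C" else "37C")
})
is25 <- vapply(reps, function(r) r$condition, "") == "25C"
ef <- compute_ef(pool_replicates(reps[is25]), pool_replicates(reps[!is25]))
write_ef_table(ef, "results/ef/ef_table.tsv")

cat(sprintf("EF range: %.3f (%s) to %.3f (%s)\n",
            min(ef$ef), ef$motif[which.min(ef$ef)],
            max(ef$ef), ef$motif[which.max(ef$ef)]))
for (m in c("CASQ", "CKQQ", "CVIA", "CVLS")) {
  cat(sprintf("  EF %s = %.3f\n", m, ef$ef[ef$motif == m]))
}

q <- assign_quartiles(ef)
write.table(data.frame(motif = names(q), quartile = unname(q)),
            "results/ef/quartiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

a <- c("I", "L", "V")
caal <- subgroup_mean_ef(ef, a, a, c("L", "F", "M", "I"))
cxxl <- subgroup_mean_ef(ef, x_set = c("L", "F", "M", "I"))
cat(sprintf("CaaL/F/M/I subgroup (n = %d): mean EF %.2f +/- %.2f\n",
            caal$n, caal$mean, caal$sd))
cat(sprintf("CxxL/F/M/I subgroup (n = %d): mean EF %.2f +/- %.2f\n",
            cxxl$n, cxxl$mean, cxxl$sd))
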