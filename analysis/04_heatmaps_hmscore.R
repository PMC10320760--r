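#!/usr/bin/env Rscript
# Build the three position-pair heatmaps of mean EF, call positive and
# restrictive residue patterns (>= 18 of 20 cells beyond the 95% CI of the
# grand mean), and compute the summed HM prenylation score for every motif.

library(cxxxscreen)
stopifnot(file.exists("results/ef/ef_table.tsv"))
dir.create("results/heatmaps", showWarnings = FALSE)

ef <- read_ef_table("results/ef/ef_table.tsv")
hms <- build_heatmaps(ef)
for (p in names(hms)) {
  write_heatmap(hms[[p]], sprintf("results/heatmaps/heatmap_%s.tsv", p),
                sprintf("results/heatmaps/heatmap_%s_long.tsv", p))
}

pat <- detect_patterns_all(hms)
cat("significant patterns:\n")
print(pat[, c("pair", "position", "residue", "context_position", "direction",
              "n_beyond_cutoff")])
jsonlite::write_json(pat, "results/heatmaps/patterns.json",
                     dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)

restr_a2 <- sort(unique(pat$residue[pat$position == "a2" &
                                      pat$direction == "restrictive"]))
cat("restrictive at a2:", restr_a2, "\n")

hm <- hm_score_all(ef)
write.table(hm, "results/heatmaps/hm_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("HM score deciles: %s\n",
            paste(round(quantile(hm$hm_score, 0:10 / 10), 2), collapse = " ")))
cat(sprintf("motifs with HM score > 3 (predicted prenylated): %d of 8000\n",
            sum(hm$hm_score > 3)))
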