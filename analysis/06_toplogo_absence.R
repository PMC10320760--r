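#!/usr/bin/env Rscript
# Characterize the top 5% of enriched motifs: position frequency matrices for
# logo rendering, the long-format EF space table for 3D/4D views, and the
# per-position residue-absence analysis.

library(cxxxscreen)
stopifnot(file.exists("results/ef/ef_table.tsv"))
dir.create("results/logo", showWarnings = FALSE)

ef <- read_ef_table("results/ef/ef_table.tsv")
top <- top_fraction(ef, 0.05)
cat("top 5% =", length(top), "motifs; leaders:", head(top, 8), "\n")
write_motif_list(top, "results/logo/top_motifs.txt")
write_logo_inputs(pfm(top), "results/logo/top5")
invisible(ef_space_table(ef, top, "results/logo/top5_ef_space.tsv"))

for (pos in c("a1", "a2", "x")) {
  cat(sprintf("absent at %-2s in top 5%%: %s\n", pos,
              paste(absent_residues(top, pos), collapse = " ")))
}
# conditioned views along the K axis
for (pos in c("a2", "x")) {
  cat(sprintf("absent at %-2s among top motifs with a1 = K: %s\n", pos,
              paste(absent_residues(top, pos, "a1", "K"), collapse = " ")))
}
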