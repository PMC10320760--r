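#!/usr/bin/env Rscript
# Fit the interpretable entropy decision tree over residue-set features
# (one-hot plus all residue sets up to size 5; 65,097 features) on
# EF-binarized labels and extract the governing rules.

library(cxxxscreen)
stopifnot(file.exists("results/ef/ef_table.tsv"))
dir.create("results/tree", showWarnings = FALSE)

ef <- read_ef_table("results/ef/ef_table.tsv")
labels <- binarize_labels(ef, threshold = 1.0)
cat("labels: ", sum(labels$label), "enriched /", sum(!labels$label),
    "depleted (EF threshold 1.0)\n")

tree <- fit_caax_tree(labels, max_set_size = 5L, max_depth = 3L,
                      min_samples = 50L)
print(tree)
write_tree_json(tree, "results/tree/tree.json")

rules <- extract_rules(tree)
writeLines(rules, "results/tree/rules.txt")
cat(rules, sep = "\n")

pred <- predict(tree, ef$motif)
acc <- mean((pred == "positive") == (labels$label == 1L))
cat(sprintf("training accuracy: %.1f%%\n", 100 * acc))
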