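#!/usr/bin/env Rscript
# Stage 3: damage indices and HRD/HRP classification.
#
# Fits the per-condition count Gaussians, computes DI / RDI / RI per
# model, classifies by PCA with the -0.5 PC1 cutoff and compares the
# calls with the generator's ground-truth labels.

suppressMessages(library(recaplab))
cfg <- recap_config()
foci <- read_foci_csv("results/02_foci.csv")
labels <- read.csv("results/01_truth_labels.csv")

idx <- recap_indices(foci, cfg)
write.csv(idx, "results/03_indices.csv", row.names = FALSE)
cl <- classify_recap(idx, cfg$recap_cutoff)
write.csv(cl, "results/03_classification.csv", row.names = FALSE)
jsonlite::write_json(
  list(loadings = as.data.frame(attr(cl, "loadings"))),
  "results/03_loadings.json", digits = NA)

merged <- merge(cl, labels, by = "model")
message("Indices and PC1 scores:")
print(merge(idx, merged[, c("model", "pc1", "status", "label")], by = "model"))
acc <- mean(merged$status == merged$label)
message(sprintf("Classification accuracy vs ground truth: %d/%d (%.0f%%)",
                sum(merged$status == merged$label), nrow(merged), 100 * acc))
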