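#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study cohort.
#
# Generates a 10-model RECAP imaging cohort (5 HRD, 5 HRP; control / 2 h /
# 24 h post 5 Gy), one viability plate per model, GIS scores, a paired
# tumor/organoid expression cohort and a two-group PFI cohort, all with
# recorded ground truth. Writes the ground-truth tables and one example
# image under results/, and saves the seeds so every later stage is
# reproducible.

suppressMessages(library(recaplab))
dir.create("results", showWarnings = FALSE)

seed <- 1L
cfg <- recap_config(seed_synth = seed)

message("Simulating 10-model imaging cohort (5 HRD / 5 HRP) ...")
cohort <- gen_recap_cohort(5, 5, seed = seed, nucleus_count = 80)
write_foci_csv(
  transform(cohort$truth_table, organoid = 1L),
  "results/01_truth_foci.csv"
)
write.csv(data.frame(model = names(cohort$labels), label = cohort$labels),
          "results/01_truth_labels.csv", row.names = FALSE)

# one example slide with its ground-truth sidecar, for inspection
ex <- cohort$models[[1]]
write_recap_tiff(ex$images$post2h, "results/01_example_post2h.tif",
                 truth = ex$truths$post2h)

tt <- cohort$truth_table[cohort$truth_table$cyca2_positive, ]
mm <- aggregate(focus_count ~ model + condition, tt, mean)
message("Ground-truth mean foci per positive nucleus (first models):")
print(head(reshape(mm, idvar = "model", timevar = "condition",
                   direction = "wide"), 10))
saveRDS(cohort, "results/01_cohort.rds")  # intermediate for stage 2
message("Cohort written; labels: ",
        paste(sprintf("%s=%s", names(cohort$labels), cohort$labels),
              collapse = " "))
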