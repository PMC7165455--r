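#!/usr/bin/env Rscript

# Simulate the study cohort: 10 synthetic femoral heads with the
# human-like (single posterosuperior-medial BV/TV concentration) and 10
# with the ape-like (anterior + posterior superior concentrations)
# phenotype, at the reference geometry (18-mm head radius, 0.3-mm
# voxels).  Volumes and the cohort manifest go to results/cohort/.
#
# Run from the repository root:  Rscript analysis/01_simulate.R [seed]

suppressMessages(library(trabmap))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 424242L
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

specs <- list(human = specimen_spec("human_one_pillar"),
              ape = specimen_spec("ape_two_pillar"))
cat(sprintf("simulating 10 + 10 specimens (master seed %d)...\n", seed))
cohort <- make_cohort(10, specs, master_seed = seed)

rows <- lapply(cohort, function(sp) {
  f <- file.path(out, paste0(sp$id, ".nii.gz"))
  write_volume(sp$volume, f,
               extra = list(seed = sp$seed, pattern = sp$truth$pattern))
  # ground truth: target field summary + blob centres
  jsonlite::write_json(
    list(pattern = sp$truth$pattern,
         blob_centers_mm = sp$truth$blob_centers_mm,
         fill_fraction = mean(sp$volume$voxels[sp$volume$outer_mask])),
    file.path(out, paste0(sp$id, "_truth.json")), auto_unbox = TRUE,
    digits = NA)
  data.frame(id = sp$id, path = f, group = sp$group)
})
manifest <- do.call(rbind, rows)
write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)

fills <- vapply(cohort, function(sp)
  mean(sp$volume$voxels[sp$volume$outer_mask]), numeric(1))
cat(sprintf("done: %d volumes, global fill fraction %.3f-%.3f\n",
            nrow(manifest), min(fills), max(fills)))
cat(sprintf("manifest: %s\n", file.path(out, "manifest.csv")))
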