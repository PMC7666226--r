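#!/usr/bin/env Rscript

# Step 1: simulate a two-line midbrain-organoid cohort and write the
# image stacks to disk as multi-page TIFFs with ground truth alongside.
#
# The H line stands in for healthy controls; the P line emulates the
# PRKN-mutant phenotype: fewer GFAP- and S100B-positive cells around
# the nuclei and fragmented TH-positive neurites. Three organoids per
# line, three 50 um sections per organoid.
#
#   Rscript analysis/01_simulate_cohort.R [seed]

suppressPackageStartupMessages(library(organoidIF))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
out_dir <- "results/cohort"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

base <- scene_spec()  # 24 x 160 x 160 voxels, 20 nuclei, all five channels
specs <- cohort_specs(
  base, c(H = 9L, P = 9L),
  overrides_by_group = list(P = list(
    marker_positive_fraction = c(GFAP = 0.10, S100B = 0.15),
    fragmentation_level = 3L)),
  seed = seed)

cohort <- render_cohort(specs, sections_per_organoid = 3L)

manifest <- do.call(rbind, lapply(cohort, function(x) {
  rec <- x$record
  stem <- sprintf("%s_s%d", rec$organoid_id, rec$section_index)
  tif <- file.path(out_dir, paste0(stem, ".tif"))
  write_stack(rec$stack, tif)
  # ground truth for later validation (not used by the pipeline itself)
  jsonlite::write_json(
    list(n_nuclei = length(x$truth$nucleus_sizes),
         nucleus_voxels = sum(x$truth$nucleus_sizes),
         positive_cells = lapply(x$truth$positive_cells, length),
         fragment_count = x$truth$fragment_count),
    file.path(out_dir, paste0(stem, ".truth.json")),
    auto_unbox = TRUE)
  data.frame(organoid_id = rec$organoid_id, line_id = rec$line_id,
             section_index = rec$section_index, path = tif)
}))
write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)

cat("Rendered", nrow(manifest), "sections for",
    length(unique(manifest$line_id)), "lines into", out_dir, "\n")
cat("Each stack:", paste(dim(cohort[[1]]$record$stack)[1:3], collapse = " x "),
    "voxels,", dim(cohort[[1]]$record$stack)[4], "channels\n")
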