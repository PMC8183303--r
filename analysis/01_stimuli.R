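#!/usr/bin/env Rscript
# Stage 1: simulator geometry and stimulus material.
# Builds the three-screen layout, reports its geometric field-of-view
# coverage, and generates the three videos' feature grids and change-event
# schedules used by the later stages.

suppressPackageStartupMessages(library(pufov))
out <- "results/stimuli"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026L

layout <- screen_layout()
print(layout)
cov <- layout_coverage(layout)
message(sprintf(
  "Geometric coverage of the default layout: %.1f x %.1f deg; %.1f deg half-width.",
  cov["horizontal"], cov["vertical"], max_measurable_eccentricity(layout)))
lay149 <- layout_for_coverage(149)
message(sprintf(
  "Solved eye distance %.2f m gives 149 deg coverage -> max measurable eccentricity %.1f deg.",
  lay149$eye_distance_m, max_measurable_eccentricity(lay149)))

for (v in 1:3) {
  grid <- generate_grid(child_seed(seed, 1, v), layout)
  events <- schedule_events(grid, video_length_s = 300, per_type_count = 140,
                            seed = child_seed(seed, 2, v))
  validate_schedule(events, grid, 300)
  write_tsv(as.data.frame(grid), file.path(out, sprintf("video%d_features.tsv", v)))
  write_tsv(events, file.path(out, sprintf("video%d_events.tsv", v)))
  message(sprintf(
    "video %d: %d features (%d visible), %d events (%s), occupancy %.1f s",
    v, nrow(grid), sum(grid$visible), nrow(events),
    paste(names(table(events$change_type)), table(events$change_type),
          sep = "=", collapse = ", "),
    max(events$offset_s) - min(events$onset_s)))
}
write_occlusion_mask(default_occlusion_mask(), file.path(out, "occlusion_mask.tsv"))
message("stimulus tables written to ", out)
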