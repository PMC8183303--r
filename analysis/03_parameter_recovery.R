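#!/usr/bin/env Rscript
# Stage 3: parameter recovery against the generator's ground truth.
# Re-reads the stage-2 intermediates and quantifies how faithfully the
# analysis chain (alignment -> event matching -> profile fit) recovers the
# detection rates, reaction times and Gaussian perception parameters the
# cohort was simulated with.

suppressPackageStartupMessages(library(pufov))

truth <- read_tsv("results/study/ground_truth.tsv")
outcomes <- read_tsv("results/study/event_outcomes.tsv")
fits <- read_tsv("results/study/profile_fits.tsv")
prof <- participant_profile()   # the generator's study conditions

rows <- lapply(c("color", "shape", "motion"), function(ty) {
  tr <- truth[truth$change_type == ty, ]
  oc <- outcomes[outcomes$change_type == ty, ]
  f <- fits[fits$change_type == ty, ]
  p <- prof$perception[[ty]]
  data.frame(
    change_type = ty,
    true_A = unname(p["A"]), fit_A = f$A,
    true_sigma = unname(p["sigma_e"]), fit_sigma = f$sigma_deg,
    truth_rate = mean(tr$detected), pipeline_rate = mean(oc$detected),
    truth_key_rt = mean((tr$keypress_s - tr$onset_s)[tr$detected]),
    pipeline_key_rt = mean(oc$key_rt_s, na.rm = TRUE),
    truth_gaze_rt = mean((tr$gaze_arrival_s - tr$onset_s)[tr$detected]),
    pipeline_gaze_rt = mean(oc$gaze_rt_s, na.rm = TRUE)
  )
})
rec <- do.call(rbind, rows)
write_tsv(rec, "results/recovery.tsv")
print(rec, row.names = FALSE, digits = 3)

message(sprintf(
  "amplitude recovery: max |A_hat - A*| = %.3f; width recovery: max |sigma_hat/sigma* - 1| = %.1f%%",
  max(abs(rec$fit_A - rec$true_A)),
  100 * max(abs(rec$fit_sigma / rec$true_sigma - 1))))
message(sprintf(
  "detection-rate gap (pipeline - truth): %s pp",
  paste(sprintf("%+.1f", 100 * (rec$pipeline_rate - rec$truth_rate)),
        collapse = ", ")))
message("the motion-type gap concentrates on the side screens, where the ",
        "tracker noise approaches the 200 px feature spacing; see the ",
        "methods vignette.")
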