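#!/usr/bin/env Rscript
# Stage 4: figures.
# Perception-probability curves over eccentricity, recognition-rate bars,
# and reaction-time / saccade-amplitude boxplots from the stage-2 study.

suppressPackageStartupMessages(library(pufov))
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

outcomes <- read_tsv("results/study/event_outcomes.tsv")
summaries <- read_tsv("results/study/participant_summaries.tsv")

fits <- lapply(c(color = "color", shape = "shape", motion = "motion"),
               function(ty) fit_profile(outcomes[outcomes$change_type == ty, ]))

png("results/figures/perception_profiles.png", 900, 600)
plot_profile_fits(fits)
dev.off()

png("results/figures/recognition_rates.png", 700, 500)
rate <- tapply(summaries$rate, summaries$change_type, mean, na.rm = TRUE)
barplot(rate[c("color", "shape", "motion")], ylim = c(0, 1),
        ylab = "recognition rate", col = c("firebrick", "steelblue",
                                           "darkgreen"))
dev.off()

png("results/figures/reaction_times.png", 900, 500)
op <- par(mfrow = c(1, 2))
boxplot(mean_key_rt_s ~ change_type, summaries, ylab = "keypress RT (s)")
boxplot(mean_gaze_rt_s ~ change_type, summaries, ylab = "gaze RT (s)")
par(op)
dev.off()

png("results/figures/saccade_amplitudes.png", 900, 500)
op <- par(mfrow = c(1, 2))
boxplot(mean_amp_deg ~ change_type, summaries,
        ylab = "mean saccade amplitude (deg)")
boxplot(max_amp_deg ~ change_type, summaries,
        ylab = "max saccade amplitude (deg)")
par(op)
dev.off()

message("figures written to results/figures")
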