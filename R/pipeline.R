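#' Study configuration
#'
#' Bundles every stage parameter of the simulated pUFOV study. Defaults are
#' the study conditions: three 5-minute videos, 140 events per change type
#' per video, a 25 x 6 feature grid with 200 px spacing, proximity-mode
#' alignment, 1 s grace, 5 deg profile bins.
#'
#' @param n_participants Cohort size.
#' @param n_videos Videos per participant (each instructed type once when
#'   `n_videos == 3`).
#' @param video_length_s Video duration, seconds.
#' @param per_type_count Change events per type per video.
#' @param layout A [screen_layout()].
#' @param profile A [participant_profile()] shared by the cohort.
#' @param align An [alignment_params()].
#' @param grace_s Detection grace period, seconds.
#' @param bin_width_deg Profile-fit bin width, degrees.
#' @param occlusion Occlusion mask for [generate_grid()].
#' @param calibrate Simulate a 21-point calibration per participant.
#' @param seed Master seed; all stage and participant seeds derive from it
#'   via [child_seed()].
#' @return A `study_config` list.
#' @export
study_config <- function(n_participants = 50L, n_videos = 3L,
                         video_length_s = 300, per_type_count = 140L,
                         layout = screen_layout(),
                         profile = participant_profile(),
                         align = alignment_params(),
                         grace_s = 1, bin_width_deg = 5,
                         occlusion = default_occlusion_mask(),
                         calibrate = TRUE, seed = 1L) {
  structure(list(
    n_participants = as.integer(n_participants),
    n_videos = as.integer(n_videos),
    video_length_s = video_length_s,
    per_type_count = as.integer(per_type_count),
    layout = layout, profile = profile, align = align,
    grace_s = grace_s, bin_width_deg = bin_width_deg,
    occlusion = occlusion, calibrate = calibrate,
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Run one simulated session through alignment and scoring
#'
#' Simulate -> align -> segment saccades -> match events. The building block
#' of [run_study()], exposed so single sessions can be inspected or re-run.
#'
#' @param grid,events One video's stimuli.
#' @param instructed_type Change type to report.
#' @param config A [study_config()].
#' @param seed Session seed.
#' @return List with `session` (simulator output incl. ground truth),
#'   `aligned`, `saccades`, `outcomes`.
#' @export
run_session <- function(grid, events, instructed_type, config, seed) {
  ses <- simulate_participant(grid, events, instructed_type, config$profile,
                              config$layout, seed = seed,
                              video_length_s = config$video_length_s)
  aligned <- align_track(ses$gaze, grid, config$align)
  sacc <- extract_saccades(aligned, config$layout)
  outcomes <- match_events(events, instructed_type, aligned, sacc,
                           ses$keypresses, config$layout, grid,
                           grace = config$grace_s)
  list(session = ses, aligned = aligned, saccades = sacc, outcomes = outcomes)
}

#' Run the full simulated study
#'
#' Executes the whole pipeline: per-video stimulus generation and event
#' scheduling, per-participant session simulation (video order and
#' instructed-type order permuted per participant), gaze alignment, saccade
#' segmentation, event scoring, per-participant and cohort summaries,
#' Gaussian profile fits per change type and the ANOVA comparisons. Fully
#' reproducible from the config's master seed.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, stimulus tables,
#'   per-participant outcome tables, summaries and the report JSON are
#'   written there as delimited text / JSON.
#' @param progress Print per-participant progress.
#' @return A `study_result` list: `report` (a [build_report()] object),
#'   `outcomes` (all event outcomes), `truth` (generator ground truth),
#'   `participants` (per-participant per-type summary rows), `fits`,
#'   `anovas`, `videos` (grids and schedules), `config`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      progress = FALSE) {
  t_start <- Sys.time()
  seed <- config$seed
  videos <- lapply(seq_len(config$n_videos), function(v) {
    grid <- generate_grid(child_seed(seed, 1, v), config$layout,
                          occlusion = config$occlusion)
    events <- schedule_events(grid, config$video_length_s,
                              config$per_type_count,
                              seed = child_seed(seed, 2, v))
    validate_schedule(events, grid, config$video_length_s)
    list(grid = grid, events = events)
  })

  all_outcomes <- list(); all_truth <- list(); part_rows <- list()
  calib_rows <- list()
  for (p in seq_len(config$n_participants)) {
    ord <- with_seed(child_seed(seed, 3, p), list(
      videos = sample(config$n_videos),
      types = sample(CHANGE_TYPES)
    ))
    p_out <- list()
    for (k in seq_len(config$n_videos)) {
      v <- ord$videos[k]
      ty <- ord$types[((k - 1L) %% 3L) + 1L]
      res <- run_session(videos[[v]]$grid, videos[[v]]$events, ty, config,
                         seed = child_seed(seed, 4, p, v))
      oc <- res$outcomes
      oc$participant <- p; oc$video <- v
      tr <- res$session$truth
      tr$participant <- p; tr$video <- v; tr$change_type <- ty
      p_out[[k]] <- oc
      all_truth[[length(all_truth) + 1L]] <- tr
    }
    p_out <- do.call(rbind, p_out)
    all_outcomes[[p]] <- p_out
    calib <- NULL
    if (isTRUE(config$calibrate)) {
      calib <- simulate_calibration(config$layout, config$profile,
                                    seed = child_seed(seed, 5, p))
      ce <- calibration_error(calib, config$layout)
      ce$participant <- p
      calib_rows[[p]] <- ce
    }
    sm <- summarize_participant(p_out, calib = NULL, layout = config$layout)$by_type
    sm$participant <- p
    part_rows[[p]] <- sm
    if (progress) message(sprintf("participant %d/%d done", p,
                                  config$n_participants))
  }
  outcomes <- do.call(rbind, all_outcomes)
  truth <- do.call(rbind, all_truth)
  participants <- do.call(rbind, part_rows)
  calibration <- if (length(calib_rows)) do.call(rbind, calib_rows)

  # cohort pooled summary and per-type Gaussian profile fits
  cohort <- do.call(rbind, lapply(CHANGE_TYPES, function(ty) {
    o <- outcomes[outcomes$change_type == ty, , drop = FALSE]
    det <- o[o$detected, , drop = FALSE]
    data.frame(change_type = ty, n_events = nrow(o), n_detected = nrow(det),
               rate = if (nrow(o)) nrow(det) / nrow(o) else NA_real_,
               mean_gaze_rt_s = if (nrow(det)) mean(det$gaze_rt_s) else NA_real_,
               mean_key_rt_s = if (nrow(det)) mean(det$key_rt_s) else NA_real_,
               mean_amp_deg = if (nrow(det)) mean(det$ecc_detect_deg, na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  fits <- list()
  for (ty in CHANGE_TYPES) {
    o <- outcomes[outcomes$change_type == ty, , drop = FALSE]
    f <- try(fit_profile(o, config$bin_width_deg), silent = TRUE)
    if (!inherits(f, "try-error")) fits[[ty]] <- f
  }
  anovas <- NULL
  if (config$n_participants >= 2L && config$n_videos >= 3L) {
    metrics <- c(rate = "rate", key_rt = "mean_key_rt_s",
                 gaze_rt = "mean_gaze_rt_s", mean_amp_deg = "mean_amp_deg",
                 max_amp_deg = "max_amp_deg", mean_amp_px = "mean_amp_px",
                 max_amp_px = "max_amp_px")
    anovas <- do.call(rbind, lapply(names(metrics), function(m) {
      pp <- data.frame(participant = participants$participant,
                       change_type = participants$change_type,
                       value = participants[[metrics[[m]]]])
      tryCatch(anova_comparisons(pp, metric = m), error = function(e) NULL)
    }))
  }

  meta <- list(seed = seed, n_participants = config$n_participants,
               n_videos = config$n_videos,
               per_type_count = config$per_type_count,
               video_length_s = config$video_length_s,
               align_mode = config$align$mode,
               elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                               units = "secs")))
  report <- build_report(cohort, fits, anovas, meta)
  result <- structure(list(report = report, outcomes = outcomes,
                           truth = truth, participants = participants,
                           calibration = calibration, fits = fits,
                           anovas = anovas, videos = videos,
                           config = config),
                      class = "study_result")
  if (!is.null(out_dir)) write_study(result, out_dir)
  result
}

#' Write study intermediates and the report to a directory
#' @param result A [run_study()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (v in seq_along(result$videos)) {
    write_tsv(as.data.frame(result$videos[[v]]$grid),
              file.path(out_dir, sprintf("video%d_features.tsv", v)))
    write_tsv(result$videos[[v]]$events,
              file.path(out_dir, sprintf("video%d_events.tsv", v)))
  }
  write_tsv(result$outcomes, file.path(out_dir, "event_outcomes.tsv"))
  write_tsv(result$truth, file.path(out_dir, "ground_truth.tsv"))
  write_tsv(result$participants, file.path(out_dir, "participant_summaries.tsv"))
  if (!is.null(result$calibration)) {
    write_tsv(result$calibration, file.path(out_dir, "calibration_errors.tsv"))
  }
  if (!is.null(result$anovas)) {
    write_tsv(result$anovas, file.path(out_dir, "anova_comparisons.tsv"))
  }
  fits_tab <- do.call(rbind, lapply(names(result$fits), function(ty) {
    f <- result$fits[[ty]]
    data.frame(change_type = ty, A = f$A, sigma_deg = f$sigma_deg,
               rss = f$rss, n_bins = f$n_bins_informative)
  }))
  if (!is.null(fits_tab)) write_tsv(fits_tab, file.path(out_dir, "profile_fits.tsv"))
  write_report(result$report, file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Simulated pUFOV study: %d participants x %d videos, %d events/type/video\n",
              x$config$n_participants, x$config$n_videos,
              x$config$per_type_count))
  print(x$report$cohort, row.names = FALSE)
  for (ty in names(x$fits)) {
    cat(sprintf("  %s: ", ty)); print(x$fits[[ty]])
  }
  invisible(x)
}

#' Plot fitted perception profiles
#'
#' Base-graphics visualization of the per-bin detection probabilities and
#' the fitted Gaussian curves, one color per change type.
#'
#' @param fits Named list of [fit_profile()] objects.
#' @param max_e_deg Right edge of the eccentricity axis.
#' @export
plot_profile_fits <- function(fits, max_e_deg = 80) {
  cols <- c(color = "firebrick", shape = "steelblue", motion = "darkgreen")
  plot(NULL, xlim = c(0, max_e_deg), ylim = c(0, 1),
       xlab = "eccentricity (deg)", ylab = "detection probability",
       main = "Perception probability vs. eccentricity")
  e <- seq(0, max_e_deg, length.out = 200)
  for (ty in names(fits)) {
    f <- fits[[ty]]
    points(f$bins$mid_deg, f$bins$p, col = cols[[ty]], pch = 16,
           cex = 0.3 + sqrt(f$bins$n_total) / 20)
    lines(e, f$A * exp(-e^2 / (2 * f$sigma_deg^2)), col = cols[[ty]], lwd = 2)
  }
  legend("topright", legend = names(fits), col = cols[names(fits)], lwd = 2,
         bty = "n")
}
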