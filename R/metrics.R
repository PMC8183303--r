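#' Match change events to gaze visits and keypresses
#'
#' Operationalizes a "correctly acknowledged" change: an event of the
#' instructed type counts as detected iff (a) the aligned track visits the
#' event's feature within \[onset, offset + grace\] and (b) a keypress
#' occurs after that visit (allowing for the estimator lag, see
#' `visit_lag_tol`) and within the same window. Each keypress is consumed
#' by at most one event; if several events qualify for one keypress, the
#' event whose feature the aligned track dwelt on longest between its onset
#' and the keypress wins (strongest gaze evidence), ties broken by the
#' nearest preceding visit.
#'
#' For every event (detected or not) the eccentricity at onset is computed
#' from the aligned gaze position around onset to the changing feature, so
#' the per-bin detection probabilities of the profile fit have both
#' numerator and denominator. The position is averaged over the aligned
#' samples in \[onset - ecc_window_s, onset\]: the resting gaze is
#' stationary, so the pre-onset average estimates it with far less
#' alignment noise than a single sample, and never touches the response
#' saccade.
#'
#' @param events Schedule from [schedule_events()].
#' @param instructed_type Change type the participant was told to report.
#' @param aligned [align_track()] output for the session.
#' @param saccades [extract_saccades()] output for the session.
#' @param keypresses Data frame with `t_s` (or numeric vector of times).
#' @param layout A [screen_layout()].
#' @param grid The feature grid.
#' @param grace Seconds after event offset during which a visit/keypress
#'   still counts (default 1).
#' @param min_visit_s Minimum duration the aligned fixation must rest on the
#'   feature for a "look at it" to count (default 0: any aligned sample).
#' @param visit_lag_tol The aligned visit time is an estimate that lags the
#'   true look by the state-update smoothing and sampling quantization; a
#'   keypress up to this many seconds before the estimated visit still
#'   counts as confirming it (default 0.25 s).
#' @param max_key_delay A keypress confirms a look that just happened: the
#'   last aligned visit of a candidate event's feature must lie within this
#'   many seconds before the keypress (default 1 s, the upper tail of
#'   plausible press latencies).
#' @param ecc_window_s Length of the pre-onset window over which the
#'   aligned position is averaged for the onset eccentricity (default
#'   0.25 s).
#' @param require_visit If FALSE, a keypress inside the window alone counts
#'   as detection (gaze metrics are then NA unless a visit also occurred).
#' @return Data frame of per-event outcomes: `event_id`, `change_type`,
#'   `feature_id`, `onset_s`, `detected`, `gaze_rt_s`, `key_rt_s`,
#'   `ecc_onset_deg`, `ecc_detect_deg` (amplitude of the saccade that
#'   reached the target), `max_amp_deg`, `max_amp_px`.
#' @export
match_events <- function(events, instructed_type, aligned, saccades,
                         keypresses, layout = screen_layout(), grid,
                         grace = 1, min_visit_s = 0, visit_lag_tol = 0.25,
                         max_key_delay = 1, ecc_window_s = 0.25,
                         require_visit = TRUE) {
  if (is.data.frame(keypresses)) keypresses <- keypresses$t_s
  keypresses <- sort(keypresses)
  ev <- events[events$change_type == instructed_type, , drop = FALSE]
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  n <- nrow(ev)

  # aligned gaze position around each event onset: mean of the aligned
  # positions over [onset - ecc_window_s, onset] (fallback: last sample)
  j_all <- match(aligned$feature_id, grid$feature_id)
  agx <- grid$gx[j_all]; agy <- grid$gy[j_all]
  cgx <- c(0, cumsum(agx)); cgy <- c(0, cumsum(agy))
  lo <- findInterval(ev$onset_s - ecc_window_s, aligned$t_s) + 1L
  hi <- findInterval(ev$onset_s, aligned$t_s)
  lo <- pmax(lo, 1L); hi <- pmax(hi, 1L); lo <- pmin(lo, hi)
  cnt <- hi - lo + 1L
  mx <- (cgx[hi + 1L] - cgx[lo]) / cnt
  my <- (cgy[hi + 1L] - cgy[lo]) / cnt
  j_ev <- match(ev$feature_id, grid$feature_id)
  ecc_onset <- angular_distance_global(layout, mx, my,
                                       grid$gx[j_ev], grid$gy[j_ev])

  # aligned fixation runs: feature, start/end sample times, duration
  r <- rle(aligned$feature_id)
  rends <- cumsum(r$lengths)
  rstarts <- c(1L, rends[-length(rends)] + 1L)
  dt <- if (nrow(aligned) > 1L) stats::median(diff(aligned$t_s)) else 0
  runs <- data.frame(feature_id = r$values,
                     t0 = aligned$t_s[rstarts], t1 = aligned$t_s[rends])
  # run duration counts the sample period of the last sample
  runs <- runs[runs$t1 - runs$t0 + dt >= min_visit_s - 1e-9, , drop = FALSE]

  # first qualifying visit per event: a sufficiently long aligned fixation
  # on the event's feature overlapping [onset, offset + grace]
  first_visit <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    hit <- runs$feature_id == ev$feature_id[i] &
      runs$t1 >= ev$onset_s[i] & runs$t0 <= ev$offset_s[i] + grace
    if (any(hit)) {
      first_visit[i] <- max(runs$t0[which(hit)[1]], ev$onset_s[i])
    }
  }

  # per event: sorted times of aligned samples on its feature inside its
  # window, for dwell-occupancy evidence when assigning keypresses
  on_feat_times <- lapply(seq_len(n), function(i) {
    aligned$t_s[aligned$feature_id == ev$feature_id[i] &
                  aligned$t_s >= ev$onset_s[i] &
                  aligned$t_s <= ev$offset_s[i] + grace]
  })

  detected <- logical(n)
  key_time <- rep(NA_real_, n)
  if (require_visit) {
    # keypress-centric greedy assignment: a press confirms a recent look,
    # so candidates must have an aligned visit within max_key_delay before
    # the keypress; among candidates the event with the most aligned dwell
    # on its feature wins (strongest gaze evidence). visit_lag_tol absorbs
    # the positive lag of the aligned visit-time estimate (state-update
    # smoothing plus sampling quantization).
    for (kp in keypresses) {
      cand <- which(!detected & !is.na(first_visit) &
                      first_visit - visit_lag_tol <= kp &
                      kp <= ev$offset_s + grace & kp >= ev$onset_s)
      if (length(cand)) {
        last_visit <- vapply(cand, function(i) {
          tt <- on_feat_times[[i]]
          tt <- tt[tt <= kp + visit_lag_tol]
          if (length(tt)) tt[length(tt)] else -Inf
        }, numeric(1))
        cand <- cand[kp - last_visit <= max_key_delay]
        if (length(cand)) {
          occ <- vapply(cand, function(i) {
            sum(on_feat_times[[i]] <= kp + visit_lag_tol)
          }, integer(1))
          best <- cand[occ == max(occ)]
          pick <- best[which.max(first_visit[best])]
          detected[pick] <- TRUE
          key_time[pick] <- kp
        }
      }
    }
  } else {
    for (kp in keypresses) {
      cand <- which(!detected & kp >= ev$onset_s & kp <= ev$offset_s + grace)
      if (length(cand)) {
        # nearest onset preceding the keypress
        pick <- cand[which.max(ev$onset_s[cand])]
        detected[pick] <- TRUE
        key_time[pick] <- kp
      }
    }
  }

  # saccade amplitudes toward the event feature within the event window
  ecc_detect <- rep(NA_real_, n)
  max_amp_deg <- rep(NA_real_, n); max_amp_px <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    win_end <- if (detected[i]) min(key_time[i], ev$offset_s[i] + grace) else
      ev$offset_s[i] + grace
    s <- saccades[saccades$to_feature == ev$feature_id[i] &
                    saccades$t_end >= ev$onset_s[i] &
                    saccades$t_end <= win_end, , drop = FALSE]
    if (nrow(s)) {
      ecc_detect[i] <- s$amplitude_deg[1]
      max_amp_deg[i] <- max(s$amplitude_deg)
      max_amp_px[i] <- max(s$amplitude_px)
    } else if (detected[i]) {
      # gaze was already on the feature: zero-amplitude acquisition
      ecc_detect[i] <- 0; max_amp_deg[i] <- 0; max_amp_px[i] <- 0
    }
  }

  # the look precedes the press; if the visit-time estimate lags past the
  # keypress (within visit_lag_tol), truncate it to the press time
  gaze_rt <- ifelse(detected, pmin(first_visit, key_time) - ev$onset_s,
                    NA_real_)
  data.frame(
    event_id = ev$event_id, change_type = instructed_type,
    feature_id = ev$feature_id, onset_s = ev$onset_s,
    detected = detected,
    gaze_rt_s = gaze_rt,
    key_rt_s = ifelse(detected, key_time - ev$onset_s, NA_real_),
    ecc_onset_deg = ecc_onset,
    ecc_detect_deg = ecc_detect,
    max_amp_deg = max_amp_deg, max_amp_px = max_amp_px
  )
}

#' Calibration error from a simulated (or recorded) calibration run
#'
#' Mean absolute deviation of reported gaze from the reference points, per
#' axis, per screen and pooled, in pixels and degrees.
#'
#' @param calib [simulate_calibration()] output.
#' @param layout A [screen_layout()].
#' @return Data frame with rows per screen plus a pooled row: `screen`,
#'   `err_x_px`, `err_y_px`, `err_x_deg`, `err_y_deg`, `n`.
#' @export
calibration_error <- function(calib, layout = screen_layout()) {
  one <- function(d, label) {
    ppd <- if (label == "all") {
      rowMeans(vapply(0:2, function(s) px_per_degree(layout, s), numeric(2)))
    } else px_per_degree(layout, as.integer(label))
    ex <- mean(abs(d$x_px - d$ref_x_px))
    ey <- mean(abs(d$y_px - d$ref_y_px))
    data.frame(screen = label, err_x_px = ex, err_y_px = ey,
               err_x_deg = ex / ppd[1], err_y_deg = ey / ppd[2],
               n = nrow(d), stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, lapply(sort(unique(calib$screen_id)), function(s) {
    one(calib[calib$screen_id == s, , drop = FALSE], as.character(s))
  }))
  rbind(per, one(calib, "all"))
}

#' Summarize one participant's outcomes
#'
#' Detection rate, mean reaction times and mean/max saccade amplitudes per
#' change type, plus the calibration error. Types with no events get NA
#' (explicitly undefined), never zero. Means ignore undetected events.
#'
#' @param outcomes Row-bound [match_events()] outcomes across the
#'   participant's sessions.
#' @param calib Optional calibration records for the participant.
#' @param layout A [screen_layout()].
#' @return A list with `by_type` (data frame per change type) and
#'   `calibration` (or NULL).
#' @export
summarize_participant <- function(outcomes, calib = NULL,
                                  layout = screen_layout()) {
  if (nrow(outcomes) == 0L) stop("no outcomes to summarize", call. = FALSE)
  by_type <- do.call(rbind, lapply(CHANGE_TYPES, function(type) {
    o <- outcomes[outcomes$change_type == type, , drop = FALSE]
    if (nrow(o) == 0L) {
      return(data.frame(change_type = type, n_events = 0L, n_detected = 0L,
                        rate = NA_real_, mean_gaze_rt_s = NA_real_,
                        mean_key_rt_s = NA_real_, mean_amp_deg = NA_real_,
                        max_amp_deg = NA_real_, mean_amp_px = NA_real_,
                        max_amp_px = NA_real_, stringsAsFactors = FALSE))
    }
    det <- o[o$detected, , drop = FALSE]
    data.frame(
      change_type = type, n_events = nrow(o), n_detected = nrow(det),
      rate = nrow(det) / nrow(o),
      mean_gaze_rt_s = if (nrow(det)) mean(det$gaze_rt_s) else NA_real_,
      mean_key_rt_s = if (nrow(det)) mean(det$key_rt_s) else NA_real_,
      mean_amp_deg = if (nrow(det)) mean(det$ecc_detect_deg, na.rm = TRUE) else NA_real_,
      max_amp_deg = if (nrow(det)) suppressWarnings(max(det$max_amp_deg, na.rm = TRUE)) else NA_real_,
      mean_amp_px = if (nrow(det)) mean(det$max_amp_px, na.rm = TRUE) else NA_real_,
      max_amp_px = if (nrow(det)) suppressWarnings(max(det$max_amp_px, na.rm = TRUE)) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(by_type) <- NULL
  list(by_type = by_type,
       calibration = if (!is.null(calib)) calibration_error(calib, layout))
}
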