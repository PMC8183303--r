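#' Synthetic participant profile
#'
#' Bundles everything that characterizes a simulated observer: the
#' eccentricity-dependent detection probability per change type (a Gaussian
#' p(e) = A * exp(-e^2 / (2 sigma_e^2)) centered on the current gaze), the
#' gaze- and keypress-latency distributions (shifted log-normals), per-screen
#' anisotropic tracker noise, fixational jitter, target dwell time and the
#' gaze sampling rate.
#'
#' Default detection profiles follow the qualitative ordering of peripheral
#' sensitivity (color < shape < motion): narrow for color, intermediate for
#' shape, wide for motion. Default tracker noise reproduces a pooled mean
#' absolute error of about 3.9 deg horizontally and 3.4 deg vertically
#' (sigma = mean / sqrt(2/pi) for a centered normal), split per screen as
#' 0.7 / 1.0 / 1.3 of the pooled sigma for center / right / left, matching
#' the camera-visibility ordering of the tracking rig. Default latencies put
#' the mean keypress reaction near 0.75 s.
#'
#' @param perception Named list per change type, each `c(A=, sigma_e=)`:
#'   A in \[0,1\], sigma_e in degrees.
#' @param gaze_latency `c(shift=, meanlog=, sdlog=)` of the shifted
#'   log-normal gaze latency, seconds.
#' @param key_latency Same family: extra latency from gaze arrival to the
#'   keypress.
#' @param noise_sd_deg 3 x 2 matrix (rows: screens 0..2; cols: horizontal,
#'   vertical) of tracker noise standard deviations in degrees.
#' @param jitter_sd_deg Fixational jitter standard deviation, degrees.
#' @param dwell_s Dwell time on an acquired target before returning to
#'   center, seconds.
#' @param sampling_rate_hz Gaze sampling rate, Hz.
#' @param dropout_p Probability that a sample is invalid (blink/dropout).
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(
    perception = list(color = c(A = 0.90, sigma_e = 12),
                      shape = c(A = 0.95, sigma_e = 18),
                      motion = c(A = 0.95, sigma_e = 50)),
    gaze_latency = c(shift = 0.20, meanlog = log(0.22), sdlog = 0.35),
    key_latency = c(shift = 0.15, meanlog = log(0.14), sdlog = 0.35),
    noise_sd_deg = default_noise_sd(),
    jitter_sd_deg = 0.3,
    dwell_s = 0.4,
    sampling_rate_hz = 60,
    dropout_p = 0) {
  for (p in perception) {
    if (p["A"] < 0 || p["A"] > 1) stop("A must lie in [0, 1]", call. = FALSE)
    if (p["sigma_e"] <= 0) stop("sigma_e must be positive", call. = FALSE)
  }
  if (sampling_rate_hz <= 0) stop("sampling rate must be positive", call. = FALSE)
  if (any(gaze_latency["shift"] < 0, key_latency["shift"] < 0)) {
    stop("latency shifts must be non-negative", call. = FALSE)
  }
  structure(list(
    perception = perception, gaze_latency = gaze_latency,
    key_latency = key_latency,
    noise_sd_deg = noise_sd_deg, jitter_sd_deg = jitter_sd_deg,
    dwell_s = dwell_s, sampling_rate_hz = sampling_rate_hz,
    dropout_p = dropout_p
  ), class = "participant_profile")
}

#' Default per-screen tracker noise
#'
#' Pooled mean absolute errors of 3.9 deg (horizontal) and 3.4 deg
#' (vertical) converted to normal standard deviations via the half-normal
#' mean E|X| = sigma * sqrt(2/pi), then split 1.3 / 0.7 / 1.0 for screens
#' left / center / right.
#'
#' @return 3 x 2 matrix of standard deviations in degrees.
#' @export
default_noise_sd <- function() {
  pooled <- c(h = 3.9, v = 3.4) / sqrt(2 / pi)
  split <- c(1.3, 0.7, 1.0)  # left, center, right
  m <- outer(split, pooled)
  dimnames(m) <- list(screen = 0:2, axis = c("h", "v"))
  m
}

#' Zero-noise profile helper (exact-geometry testing)
#' @param ... Overrides passed to [participant_profile()].
#' @return A `participant_profile` with no tracker noise or jitter.
#' @export
noiseless_profile <- function(...) {
  participant_profile(noise_sd_deg = matrix(0, 3, 2), jitter_sd_deg = 0, ...)
}

rshifted_lnorm <- function(n, par) {
  par["shift"] + stats::rlnorm(n, par["meanlog"], par["sdlog"])
}

#' Detection probability of the Gaussian perception model
#' @param e Eccentricity, degrees.
#' @param A Amplitude (probability at 0 deg).
#' @param sigma_e Width, degrees.
#' @return Probability.
#' @export
perception_prob <- function(e, A, sigma_e) A * exp(-e^2 / (2 * sigma_e^2))

#' Simulate one participant watching one video
#'
#' The simulated observer rests at the center of the center screen. At each
#' event onset of the instructed change type, detection is a Bernoulli draw
#' with probability `perception_prob(e, A, sigma_e)` where `e` is the
#' angular distance between the *current* gaze position (the observer may
#' still be handling a previous event) and the changing feature. On
#' detection the gaze jumps to the feature after the gaze latency, dwells,
#' a keypress fires after the extra key latency, and gaze returns to center.
#' Saccades are instantaneous between samples; flight time is absorbed by
#' the latency. Events of non-instructed types never trigger a response.
#' Reported gaze samples carry fixational jitter plus per-screen tracker
#' noise.
#'
#' @param grid A [generate_grid()] result.
#' @param events Schedule from [schedule_events()].
#' @param instructed_type One of `"color"`, `"shape"`, `"motion"`.
#' @param profile A [participant_profile()].
#' @param layout A [screen_layout()].
#' @param seed Integer seed.
#' @param video_length_s Video duration, seconds.
#' @param emit_gaze If FALSE, skip building the sampled gaze log (ground
#'   truth and keypresses only); used for fast Monte-Carlo checks.
#' @return A list of class `session` with elements `gaze` (data frame `t_s`,
#'   `screen_id`, `x_px`, `y_px`, `gx`, `gy`, `valid`), `keypresses`
#'   (data frame `t_s`), `truth` (per instructed event: `event_id`,
#'   `feature_id`, `ecc_onset_deg`, `detected`, `gaze_arrival_s`,
#'   `keypress_s`), and the session metadata.
#' @export
simulate_participant <- function(grid, events, instructed_type, profile,
                                 layout = screen_layout(), seed = 1L,
                                 video_length_s = 300, emit_gaze = TRUE) {
  if (!instructed_type %in% CHANGE_TYPES) {
    stop("instructed_type must be one of ", paste(CHANGE_TYPES, collapse = ", "),
         call. = FALSE)
  }
  vis <- grid$visible[match(events$feature_id, grid$feature_id)]
  if (any(!vis)) stop("event references an occluded feature", call. = FALSE)

  cx <- (layout$screen_px[1] - 1) / 2
  cy <- (layout$screen_px[2] - 1) / 2
  center <- c(gx = layout$screen_px[1] + cx, gy = cy)  # center screen, global

  ev <- events[events$change_type == instructed_type, , drop = FALSE]
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  par_per <- profile$perception[[instructed_type]]

  with_seed(seed, {
    n_ev <- nrow(ev)
    detected <- logical(n_ev); ecc <- numeric(n_ev)
    arrival <- rep(NA_real_, n_ev); keypress <- rep(NA_real_, n_ev)
    # dwell segments built so far: feature gaze intervals [start, end] at (gx, gy)
    seg_start <- numeric(0); seg_end <- numeric(0)
    seg_gx <- numeric(0); seg_gy <- numeric(0)
    busy_until <- 0
    for (i in seq_len(n_ev)) {
      fi <- match(ev$feature_id[i], grid$feature_id)
      t0 <- ev$onset_s[i]
      # current true gaze position at onset: a feature if inside a dwell
      # segment, the center reference otherwise
      pos <- center
      if (length(seg_start)) {
        k <- which(seg_start <= t0 & seg_end > t0)
        if (length(k)) pos <- c(gx = seg_gx[k[1]], gy = seg_gy[k[1]])
      }
      e <- angular_distance_global(layout, pos["gx"], pos["gy"],
                                   grid$gx[fi], grid$gy[fi])
      ecc[i] <- e
      p <- perception_prob(e, par_per["A"], par_per["sigma_e"])
      if (stats::runif(1) < p) {
        detected[i] <- TRUE
        lat <- rshifted_lnorm(1, profile$gaze_latency)
        t_arr <- max(t0, busy_until) + lat
        t_key <- t_arr + rshifted_lnorm(1, profile$key_latency)
        t_leave <- t_arr + profile$dwell_s
        arrival[i] <- t_arr; keypress[i] <- t_key
        busy_until <- t_leave
        seg_start <- c(seg_start, t_arr); seg_end <- c(seg_end, t_leave)
        seg_gx <- c(seg_gx, grid$gx[fi]); seg_gy <- c(seg_gy, grid$gy[fi])
      }
    }
    truth <- data.frame(
      event_id = ev$event_id, feature_id = ev$feature_id,
      onset_s = ev$onset_s, offset_s = ev$offset_s,
      ecc_onset_deg = ecc, detected = detected,
      gaze_arrival_s = arrival, keypress_s = keypress
    )
    keypresses <- data.frame(t_s = sort(keypress[detected]))

    gaze <- NULL
    if (emit_gaze) {
      dt <- 1 / profile$sampling_rate_hz
      t <- seq(0, video_length_s, by = dt)
      t <- t[t < video_length_s]
      ngz <- length(t)
      gx <- rep(center["gx"], ngz); gy <- rep(center["gy"], ngz)
      for (k in seq_along(seg_start)) {
        inseg <- t >= seg_start[k] & t < seg_end[k]
        gx[inseg] <- seg_gx[k]; gy[inseg] <- seg_gy[k]
      }
      # fixational jitter (isotropic, degrees) + per-screen tracker noise
      scr <- global_to_screen(layout, gx, gy)$screen
      ppd <- vapply(0:2, function(s) px_per_degree(layout, s), numeric(2))
      jit <- profile$jitter_sd_deg
      if (jit > 0) {
        gx <- gx + stats::rnorm(ngz, 0, jit) * ppd[1, scr + 1L]
        gy <- gy + stats::rnorm(ngz, 0, jit) * ppd[2, scr + 1L]
      }
      sdh <- profile$noise_sd_deg[scr + 1L, 1]
      sdv <- profile$noise_sd_deg[scr + 1L, 2]
      if (any(sdh > 0)) gx <- gx + stats::rnorm(ngz, 0, sdh) * ppd[1, scr + 1L]
      if (any(sdv > 0)) gy <- gy + stats::rnorm(ngz, 0, sdv) * ppd[2, scr + 1L]
      gx <- pmin(pmax(gx, -0.5), 3 * layout$screen_px[1] - 0.5)
      gy <- pmin(pmax(gy, -0.5), layout$screen_px[2] - 0.5)
      valid <- stats::runif(ngz) >= profile$dropout_p
      sc2 <- global_to_screen(layout, gx, gy)
      gaze <- data.frame(t_s = t, screen_id = sc2$screen,
                         x_px = gx - sc2$screen * layout$screen_px[1],
                         y_px = gy, gx = gx, gy = gy, valid = valid)
      gaze$gx[!valid] <- NA_real_; gaze$gy[!valid] <- NA_real_
      gaze$x_px[!valid] <- NA_real_; gaze$y_px[!valid] <- NA_real_
    }
    structure(list(gaze = gaze, keypresses = keypresses, truth = truth,
                   instructed_type = instructed_type, seed = seed,
                   video_length_s = video_length_s),
              class = "session")
  })
}

#' Default 21-point calibration pattern
#'
#' Seven reference points per screen (a 3 x 2 outer grid plus the screen
#' center), kept away from the occluded lower center region.
#'
#' @param layout A [screen_layout()].
#' @return Data frame `screen_id`, `x_px`, `y_px`.
#' @export
default_calibration_points <- function(layout = screen_layout()) {
  w <- layout$screen_px[1]; h <- layout$screen_px[2]
  xs <- c(0.2, 0.5, 0.8) * (w - 1)
  ys <- c(0.25, 0.7) * (h - 1)
  pts <- expand.grid(x_px = xs, y_px = ys)
  pts <- rbind(pts, data.frame(x_px = 0.5 * (w - 1), y_px = 0.475 * (h - 1)))
  out <- do.call(rbind, lapply(0:2, function(s) cbind(screen_id = s, pts)))
  rownames(out) <- NULL
  out
}

#' Simulate a gaze calibration run
#'
#' For each reference point the simulated tracker reports `n_samples` gaze
#' samples centered on the point with the profile's per-screen noise.
#'
#' @param layout A [screen_layout()].
#' @param profile A [participant_profile()].
#' @param reference_points Data frame `screen_id`, `x_px`, `y_px`; default
#'   the 21-point pattern of [default_calibration_points()].
#' @param seed Integer seed.
#' @param n_samples Samples recorded per reference point.
#' @return Data frame `point_id`, `screen_id`, `ref_x_px`, `ref_y_px`,
#'   `x_px`, `y_px` (one row per sample).
#' @export
simulate_calibration <- function(layout = screen_layout(),
                                 profile = participant_profile(),
                                 reference_points = default_calibration_points(layout),
                                 seed = 1L, n_samples = 30L) {
  if (is.null(reference_points) || nrow(reference_points) == 0L) {
    stop("reference_points must be non-empty", call. = FALSE)
  }
  check_pixels(layout, reference_points$screen_id,
               reference_points$x_px, reference_points$y_px)
  with_seed(seed, {
    recs <- lapply(seq_len(nrow(reference_points)), function(i) {
      s <- reference_points$screen_id[i]
      ppd <- px_per_degree(layout, s)
      sd_px <- profile$noise_sd_deg[s + 1L, ] * ppd
      data.frame(
        point_id = i - 1L, screen_id = s,
        ref_x_px = reference_points$x_px[i],
        ref_y_px = reference_points$y_px[i],
        x_px = reference_points$x_px[i] + stats::rnorm(n_samples, 0, sd_px[1]),
        y_px = reference_points$y_px[i] + stats::rnorm(n_samples, 0, sd_px[2])
      )
    })
    do.call(rbind, recs)
  })
}
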