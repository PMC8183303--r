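#' Randomized stimulus feature grid
#'
#' Generates the 150 stimulus objects arranged as a 25 x 6 matrix across the
#' three unrolled canvases, 200 px apart, each object 40 x 40 px. Shape
#' (square/triangle), color (red/green) and orientation (0/45 deg) are drawn
#' independently and uniformly per object so that no grouping by position,
#' shape or color arises. Visibility comes from an occlusion mask (regions
#' hidden by the vehicle chassis); change events are only ever placed on
#' visible objects.
#'
#' @param seed Integer seed; the grid is deterministic given the seed.
#' @param layout A [screen_layout()]; used to split global coordinates into
#'   per-screen coordinates and to check the object footprint.
#' @param occlusion 25 x 6 logical matrix (columns x rows), TRUE = visible.
#'   Default: [default_occlusion_mask()].
#' @param n_cols,n_rows Grid dimensions (defaults 25 x 6).
#' @param spacing_px Center-to-center spacing (default 200).
#' @return A `feature_grid`: data frame with one row per feature
#'   (`feature_id`, `screen_id`, `x`, `y`, `gx`, `gy`, `col`, `row`, `shape`,
#'   `color`, `orientation`, `visible`) plus attributes `seed` and `mask`.
#' @export
generate_grid <- function(seed, layout = screen_layout(),
                          occlusion = default_occlusion_mask(n_cols, n_rows),
                          n_cols = 25L, n_rows = 6L, spacing_px = 200) {
  occlusion <- as.matrix(occlusion)
  if (!identical(dim(occlusion), c(as.integer(n_cols), as.integer(n_rows)))) {
    stop("occlusion mask must be ", n_cols, " x ", n_rows, call. = FALSE)
  }
  total_w <- 3 * layout$screen_px[1]
  total_h <- layout$screen_px[2]
  x0 <- (total_w - (n_cols - 1) * spacing_px) / 2
  y0 <- (total_h - (n_rows - 1) * spacing_px) / 2
  idx <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  gx <- x0 + idx$col * spacing_px
  gy <- y0 + idx$row * spacing_px
  sc <- global_to_screen(layout, gx, gy)
  n <- nrow(idx)
  draws <- with_seed(seed, list(
    shape = sample(c("square", "triangle"), n, replace = TRUE),
    color = sample(c("red", "green"), n, replace = TRUE),
    orientation = sample(c(0, 45), n, replace = TRUE)
  ))
  grid <- data.frame(
    feature_id = seq_len(n) - 1L,
    screen_id = sc$screen, x = sc$x, y = sc$y,
    gx = gx, gy = gy,
    col = idx$col, row = idx$row,
    shape = draws$shape, color = draws$color, orientation = draws$orientation,
    visible = occlusion[cbind(idx$col + 1L, idx$row + 1L)],
    stringsAsFactors = FALSE
  )
  structure(grid, seed = seed, mask = occlusion,
            class = c("feature_grid", "data.frame"))
}

#' Default occlusion mask
#'
#' Approximates the vehicle-chassis occlusion: the lower rows of the center
#' screen (dashboard and hood region) are hidden; everything else is visible.
#'
#' @param n_cols,n_rows Grid dimensions.
#' @return Logical matrix (columns x rows), TRUE = visible.
#' @export
default_occlusion_mask <- function(n_cols = 25L, n_rows = 6L) {
  m <- matrix(TRUE, n_cols, n_rows)
  center_cols <- which(seq_len(n_cols) - 1L >= 8 & seq_len(n_cols) - 1L <= 16)
  occluded_rows <- which(seq_len(n_rows) - 1L >= n_rows - 2L)
  m[center_cols, occluded_rows] <- FALSE
  m
}

#' Read / write an occlusion mask as a delimited 0/1 grid
#' @param path File path. Rows of the file are grid rows (top first).
#' @return `read_occlusion_mask()`: logical columns x rows matrix.
#' @export
read_occlusion_mask <- function(path) {
  m <- as.matrix(utils::read.table(path))
  t(m == 1)
}

#' @rdname read_occlusion_mask
#' @param mask Logical columns x rows matrix.
#' @export
write_occlusion_mask <- function(mask, path) {
  utils::write.table(t(mask * 1L), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

CHANGE_TYPES <- c("color", "shape", "motion")

#' Schedule feature-change events for one video
#'
#' Draws the constrained schedule of change events: for each of the three
#' change types, `per_type_count` events with durations uniform in
#' \[`min_duration`, `max_duration`\] seconds and gaps between consecutive
#' same-type events uniform in (0, `max_gap`\] seconds. Events of the same
#' type never overlap; events of different types may overlap in time but
#' never target the same feature simultaneously. Targets are drawn uniformly
#' from visible features. If a drawn schedule overruns the video it is
#' rejected and resampled (the expected occupancy for 140 events,
#' ~279.5 s, fits a 300 s video with high probability).
#'
#' @param grid A [generate_grid()] result.
#' @param video_length_s Video duration, seconds (default 300).
#' @param per_type_count Events per change type (default 140).
#' @param seed Integer seed.
#' @param min_duration,max_duration Event visibility bounds, s (1 and 2).
#' @param max_gap Maximum same-type inter-event pause, s (1).
#' @param max_tries Resampling attempts before giving up.
#' @return Data frame of `event_id`, `change_type`, `feature_id`, `onset_s`,
#'   `offset_s`, sorted by onset.
#' @export
schedule_events <- function(grid, video_length_s = 300, per_type_count = 140,
                            seed = 1L, min_duration = 1, max_duration = 2,
                            max_gap = 1, max_tries = 100L) {
  if (per_type_count < 0) stop("per_type_count must be >= 0", call. = FALSE)
  if (per_type_count * min_duration > video_length_s) {
    stop("infeasible schedule: per_type_count * min_duration exceeds video length",
         call. = FALSE)
  }
  visible_ids <- grid$feature_id[grid$visible]
  if (per_type_count > 0 && length(visible_ids) == 0L) {
    stop("no visible features to schedule on", call. = FALSE)
  }
  if (per_type_count == 0L) {
    return(data.frame(event_id = integer(), change_type = character(),
                      feature_id = integer(), onset_s = numeric(),
                      offset_s = numeric(), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    per_type <- lapply(CHANGE_TYPES, function(type) {
      for (try in seq_len(max_tries)) {
        durations <- stats::runif(per_type_count, min_duration, max_duration)
        gaps <- max_gap - stats::runif(per_type_count, 0, max_gap) # (0, max_gap]
        onsets <- cumsum(gaps + c(0, durations[-per_type_count]))
        offsets <- onsets + durations
        if (offsets[per_type_count] < video_length_s) {
          return(data.frame(change_type = type, onset_s = onsets,
                            offset_s = offsets, stringsAsFactors = FALSE))
        }
      }
      stop("could not draw a feasible schedule for type ", type, call. = FALSE)
    })
    ev <- do.call(rbind, per_type)
    ev <- ev[order(ev$onset_s), , drop = FALSE]
    # assign target features: uniform over visible, resampling any draw that
    # would put two temporally overlapping events on one feature
    n <- nrow(ev)
    feat <- integer(n)
    for (i in seq_len(n)) {
      repeat {
        f <- visible_ids[sample.int(length(visible_ids), 1L)]
        clash <- FALSE
        if (i > 1L) {
          prev <- seq_len(i - 1L)
          clash <- any(feat[prev] == f & ev$offset_s[prev] > ev$onset_s[i])
        }
        if (!clash) break
      }
      feat[i] <- f
    }
    ev$feature_id <- feat
    ev$event_id <- seq_len(n) - 1L
    rownames(ev) <- NULL
    ev[, c("event_id", "change_type", "feature_id", "onset_s", "offset_s")]
  })
}

#' Validate a change-event schedule
#'
#' Checks every schedule invariant: durations within bounds, no same-type
#' temporal overlap, same-type gaps positive and at most `max_gap`, no two
#' temporally overlapping events on one feature, all events inside the
#' video, and targets visible.
#'
#' @param events Schedule from [schedule_events()].
#' @param grid The grid it was scheduled on.
#' @inheritParams schedule_events
#' @return TRUE invisibly, or an error describing the first violation.
#' @export
validate_schedule <- function(events, grid, video_length_s = 300,
                              min_duration = 1, max_duration = 2,
                              max_gap = 1) {
  if (nrow(events) == 0L) return(invisible(TRUE))
  dur <- events$offset_s - events$onset_s
  if (any(dur < min_duration - 1e-9 | dur > max_duration + 1e-9)) {
    stop("event duration outside [min_duration, max_duration]", call. = FALSE)
  }
  if (any(events$onset_s < 0) || any(events$offset_s > video_length_s)) {
    stop("event outside video", call. = FALSE)
  }
  vis <- grid$visible[match(events$feature_id, grid$feature_id)]
  if (any(!vis)) stop("event targets an occluded feature", call. = FALSE)
  for (type in unique(events$change_type)) {
    e <- events[events$change_type == type, , drop = FALSE]
    e <- e[order(e$onset_s), , drop = FALSE]
    if (nrow(e) > 1L) {
      gaps <- e$onset_s[-1] - e$offset_s[-nrow(e)]
      if (any(gaps <= 0)) stop("same-type events overlap", call. = FALSE)
      if (any(gaps > max_gap + 1e-9)) {
        stop("same-type gap exceeds max_gap", call. = FALSE)
      }
    }
  }
  e <- events[order(events$onset_s), , drop = FALSE]
  for (i in seq_len(nrow(e))[-1]) {
    prev <- seq_len(i - 1L)
    if (any(e$feature_id[prev] == e$feature_id[i] &
            e$offset_s[prev] > e$onset_s[i])) {
      stop("two overlapping events share a feature", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Instantaneous stimulus state at a time point
#'
#' Returns the per-feature state at time `t`: the LAB color (only the a
#' channel moves during a color change, keeping lightness constant), the
#' shape-morph parameter (0 = base shape, 1 = the other shape) and the
#' wiggle angle (45 * sin(2 pi f t') degrees around the base orientation
#' during a motion event).
#'
#' @param grid A [generate_grid()] result.
#' @param events Schedule from [schedule_events()].
#' @param t Time, seconds.
#' @param f_wiggle Wiggle frequency, Hz (default 2).
#' @param lab_red,lab_green LAB endpoints for the two colors; equal L and b
#'   so only the a channel moves.
#' @return Data frame: `feature_id`, `L`, `a`, `b`, `morph`, `wiggle_deg`.
#' @export
state_at <- function(grid, events, t, f_wiggle = 2,
                     lab_red = c(L = 60, a = 60, b = 45),
                     lab_green = c(L = 60, a = -60, b = 45)) {
  base_a <- ifelse(grid$color == "red", lab_red["a"], lab_green["a"])
  st <- data.frame(
    feature_id = grid$feature_id,
    L = unname(lab_red["L"]), a = as.numeric(base_a), b = unname(lab_red["b"]),
    morph = 0, wiggle_deg = 0
  )
  act <- events[events$onset_s <= t & events$offset_s > t, , drop = FALSE]
  for (i in seq_len(nrow(act))) {
    j <- match(act$feature_id[i], st$feature_id)
    frac <- (t - act$onset_s[i]) / (act$offset_s[i] - act$onset_s[i])
    if (act$change_type[i] == "color") {
      target_a <- if (grid$color[j] == "red") lab_green["a"] else lab_red["a"]
      st$a[j] <- st$a[j] + frac * (target_a - st$a[j])
    } else if (act$change_type[i] == "shape") {
      st$morph[j] <- frac
    } else {
      st$wiggle_deg[j] <- 45 * sin(2 * pi * f_wiggle * (t - act$onset_s[i]))
    }
  }
  st
}
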