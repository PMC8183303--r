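#' Alignment parameters
#'
#' Controls the Markov random-walk assignment of gaze samples to features.
#'
#' `sigma_t_px` is the pixel distance scale of the transition weights. The
#' default, 150 px, is the horizontal tracker error expressed in pixels.
#'
#' Two update modes are provided:
#' \describe{
#'   \item{`"literal"`}{the transition-matrix random walk: per sample the
#'     matrix T with entries `T[i, j] = exp(-d_i) - exp(-d_j)` (distances in
#'     units of `sigma_t_px`) is rebuilt from the current gaze point and one
#'     update `v_t = T v_{t-1}` is performed under the row convention
#'     `(v_t)_i = sum_j T[i, j] (v_{t-1})_j`; negative entries are clipped to
#'     zero and the vector renormalized. Algebraically
#'     `(v_t)_i = exp(-d_i) - C` with `C` independent of i, so the argmax is
#'     always the nearest visible feature: literal mode has no hysteresis.}
#'   \item{`"proximity"`}{an explicitly sticky variant,
#'     `v_t = lambda v_{t-1} + (1 - lambda) w` with `w_i` proportional to
#'     `exp(-d_i)`; `lambda` in \[0, 1) sets how much noise excursion is
#'     needed before the aligned feature switches. Default for noisy data.}
#' }
#' Ties in the argmax go to the lowest `feature_id`.
#'
#' @param sigma_t_px Distance scale, pixels (> 0).
#' @param mode `"proximity"` (default) or `"literal"`.
#' @param lambda Stickiness in \[0, 1), proximity mode only.
#' @return An `alignment_params` object.
#' @export
alignment_params <- function(sigma_t_px = 150, mode = c("proximity", "literal"),
                             lambda = 0.5) {
  mode <- match.arg(mode)
  if (sigma_t_px <= 0) stop("sigma_t_px must be positive", call. = FALSE)
  if (lambda < 0 || lambda >= 1) stop("lambda must lie in [0, 1)", call. = FALSE)
  structure(list(sigma_t_px = sigma_t_px, mode = mode, lambda = lambda),
            class = "alignment_params")
}

#' Transition weight between two features given a gaze point
#'
#' The random-walk transition weight from feature i to feature j for gaze
#' point g: `(1 - exp(-|g - f_j| / sigma)) - (1 - exp(-|g - f_i| / sigma))`,
#' i.e. `exp(-d_i) - exp(-d_j)` with distances on the unrolled pixel canvas
#' in units of `sigma_t_px`. Antisymmetric in (i, j).
#'
#' @param g Gaze point, `c(gx, gy)` global pixels.
#' @param f_i,f_j Feature positions, `c(gx, gy)` global pixels.
#' @param sigma_t_px Distance scale, pixels.
#' @return Scalar weight in \[-1, 1\].
#' @export
transition_weight <- function(g, f_i, f_j, sigma_t_px = 150) {
  if (sigma_t_px <= 0) stop("sigma_t_px must be positive", call. = FALSE)
  di <- sqrt(sum((g - f_i)^2)) / sigma_t_px
  dj <- sqrt(sum((g - f_j)^2)) / sigma_t_px
  exp(-di) - exp(-dj)
}

#' Align a gaze track to the feature grid
#'
#' Runs the Markov random walk over the gaze samples: per sample the
#' transition structure is rebuilt from the current gaze point and one state
#' update is performed (see [alignment_params()] for the two modes); the
#' aligned feature is the argmax of the state vector, ties to the lowest
#' feature id. The initial state is uniform over visible features. Invalid
#' samples (blinks/dropouts) hold the previous state and aligned feature.
#'
#' @param gaze Gaze data frame with `t_s`, `gx`, `gy`, `valid` (as produced
#'   by [simulate_participant()]).
#' @param grid A [generate_grid()] result; only visible features are states.
#' @param params An [alignment_params()].
#' @return Data frame `t_s`, `feature_id`, `v_max` (the winning state
#'   weight), with attribute `features` (the visible-feature table used).
#' @export
align_track <- function(gaze, grid, params = alignment_params()) {
  if (is.null(gaze) || nrow(gaze) == 0L) stop("empty gaze track", call. = FALSE)
  feats <- grid[grid$visible, , drop = FALSE]
  if (nrow(feats) == 0L) stop("no visible features", call. = FALSE)
  nf <- nrow(feats)
  nt <- nrow(gaze)

  valid <- gaze$valid & !is.na(gaze$gx) & !is.na(gaze$gy)
  vidx <- which(valid)
  if (length(vidx) == 0L) stop("gaze track has no valid samples", call. = FALSE)
  gx <- gaze$gx[vidx]; gy <- gaze$gy[vidx]
  nv <- length(vidx)

  # pixel distances on the unrolled canvas, in units of sigma_T
  D <- sqrt(outer(gx, feats$gx, "-")^2 + outer(gy, feats$gy, "-")^2) /
    params$sigma_t_px
  E <- exp(-D)

  if (params$mode == "literal") {
    v <- rep(1 / nf, nf)
    win <- integer(nv); vmax <- numeric(nv)
    for (t in seq_len(nv)) {
      e <- E[t, ]
      # (v_t)_i = sum_j (e_i - e_j) v_j = e_i * sum(v) - sum(e * v)
      vnew <- pmax(e * sum(v) - sum(e * v), 0)
      s <- sum(vnew)
      if (s <= 0) {
        # degenerate: v was a point mass on the nearest feature already
        vnew <- as.numeric(e == max(e))
        s <- sum(vnew)
      }
      v <- vnew / s
      win[t] <- which.max(v)   # first max = lowest feature_id (rows id-sorted)
      vmax[t] <- v[win[t]]
    }
  } else {
    lam <- params$lambda
    W <- E / rowSums(E)
    # v_t = lam * v_{t-1} + (1 - lam) * w_t is a recursive (AR1) filter per
    # feature column; rowsums stay 1 because each w_t row sums to 1
    V <- vapply(seq_len(nf), function(j) {
      as.numeric(stats::filter((1 - lam) * W[, j], lam,
                               method = "recursive", init = 1 / nf))
    }, numeric(nv))
    if (nv == 1L) V <- matrix(V, nrow = 1L)
    win <- max.col(V, ties.method = "first")
    vmax <- V[cbind(seq_len(nv), win)]
  }

  # map back to the full track: invalid samples hold the previous state;
  # leading invalid samples take the uniform-state argmax (lowest id)
  last_valid <- cumsum(valid)
  full_win <- ifelse(last_valid == 0L, 1L, win[pmax(last_valid, 1L)])
  full_vmax <- ifelse(last_valid == 0L, 1 / nf, vmax[pmax(last_valid, 1L)])
  structure(
    data.frame(t_s = gaze$t_s, feature_id = feats$feature_id[full_win],
               v_max = full_vmax),
    features = feats, class = c("aligned_track", "data.frame"))
}

#' Segment an aligned track into saccades
#'
#' Every change of the aligned feature yields a saccade from the old to the
#' new feature. Consecutive saccades whose directions (on the unrolled
#' canvas) differ by less than `merge_angle_deg` and whose intervening dwell
#' is shorter than `merge_gap_s` are merged into one: a string of saccades
#' in a similar direction counts as a single saccade, with the amplitude
#' recomputed end to end.
#'
#' @param aligned An [align_track()] result (attribute `features` required,
#'   or pass `grid`).
#' @param layout A [screen_layout()] for angular amplitudes.
#' @param merge_angle_deg Direction-similarity threshold (default 45).
#' @param merge_gap_s Maximum intervening dwell to merge (default 0.1 s).
#' @param grid Optional grid to resolve feature positions.
#' @return Data frame `from_feature`, `to_feature`, `t_start`, `t_end`,
#'   `amplitude_px`, `amplitude_deg`, `direction_deg`.
#' @export
extract_saccades <- function(aligned, layout = screen_layout(),
                             merge_angle_deg = 45, merge_gap_s = 0.1,
                             grid = NULL) {
  if (nrow(aligned) == 0L) stop("empty aligned track", call. = FALSE)
  feats <- grid %||% attr(aligned, "features")
  empty <- data.frame(from_feature = integer(), to_feature = integer(),
                      t_start = numeric(), t_end = numeric(),
                      amplitude_px = numeric(), amplitude_deg = numeric(),
                      direction_deg = numeric())
  r <- rle(aligned$feature_id)
  if (length(r$values) < 2L) return(empty)
  ends <- cumsum(r$lengths)           # last sample index of each fixation
  starts <- c(1L, ends[-length(ends)] + 1L)
  sac <- data.frame(
    from_feature = r$values[-length(r$values)],
    to_feature = r$values[-1],
    t_start = aligned$t_s[ends[-length(ends)]],
    t_end = aligned$t_s[starts[-1]]
  )

  jf <- match(sac$from_feature, feats$feature_id)
  jt <- match(sac$to_feature, feats$feature_id)
  fgx <- feats$gx; fgy <- feats$gy
  dir_of <- function(jf, jt) {
    # screen y grows downward; negate for conventional math angles
    rad2deg(atan2(-(fgy[jt] - fgy[jf]), fgx[jt] - fgx[jf]))
  }
  dirs <- dir_of(jf, jt)

  # merge strings of similar-direction saccades separated by short dwells,
  # in place on preallocated vectors (the merged direction is recomputed
  # end-to-end before comparing with the next saccade)
  n <- nrow(sac)
  m_from <- integer(n); m_to <- integer(n)
  m_t0 <- numeric(n); m_t1 <- numeric(n); m_dir <- numeric(n)
  k <- 1L
  m_from[1] <- jf[1]; m_to[1] <- jt[1]
  m_t0[1] <- sac$t_start[1]; m_t1[1] <- sac$t_end[1]; m_dir[1] <- dirs[1]
  for (i in seq_len(n)[-1]) {
    ddir <- abs(((dirs[i] - m_dir[k] + 180) %% 360) - 180)
    if (ddir < merge_angle_deg && sac$t_start[i] - m_t1[k] < merge_gap_s) {
      m_to[k] <- jt[i]
      m_t1[k] <- sac$t_end[i]
      m_dir[k] <- dir_of(m_from[k], m_to[k])
    } else {
      k <- k + 1L
      m_from[k] <- jf[i]; m_to[k] <- jt[i]
      m_t0[k] <- sac$t_start[i]; m_t1[k] <- sac$t_end[i]; m_dir[k] <- dirs[i]
    }
  }
  idx <- seq_len(k)
  jf <- m_from[idx]; jt <- m_to[idx]
  data.frame(
    from_feature = feats$feature_id[jf],
    to_feature = feats$feature_id[jt],
    t_start = m_t0[idx], t_end = m_t1[idx],
    amplitude_px = sqrt((fgx[jt] - fgx[jf])^2 + (fgy[jt] - fgy[jf])^2),
    amplitude_deg = angular_distance_global(layout, fgx[jf], fgy[jf],
                                            fgx[jt], fgy[jt]),
    direction_deg = m_dir[idx]
  )
}
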