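#' Fit a Gaussian perception-probability profile over eccentricity
#'
#' Bins event eccentricities (every event of the type, detected or not) into
#' `bin_width_deg` bins, forms per-bin detection probabilities
#' detected / total, and fits p(e) = A * exp(-e^2 / (2 sigma^2)) centered at
#' 0 deg by weighted least squares with weights equal to the per-bin totals.
#' A is box-constrained to \[0, 1\] and sigma to \[0.5, 1e4\] degrees.
#'
#' @param outcomes Data frame with `ecc_onset_deg` and `detected` (cohort
#'   event outcomes for one change type).
#' @param bin_width_deg Bin width in degrees (default 5).
#' @param free_center If TRUE, also fit a center offset mu (default FALSE:
#'   the profile is symmetric around the gaze direction).
#' @return A `profile_fit` list: `A`, `sigma_deg`, (`mu_deg`,) `rss`,
#'   `bins` (data frame of `mid_deg`, `n_total`, `n_detected`, `p`,
#'   `p_fit`), `n_bins_informative`, `converged`.
#' @export
fit_profile <- function(outcomes, bin_width_deg = 5, free_center = FALSE) {
  stopifnot(bin_width_deg > 0)
  e <- outcomes$ecc_onset_deg
  det <- outcomes$detected
  keep <- !is.na(e)
  e <- e[keep]; det <- det[keep]
  if (!length(e)) stop("no events with eccentricities", call. = FALSE)
  edges <- seq(0, max(e) + bin_width_deg, by = bin_width_deg)
  bin <- findInterval(e, edges, rightmost.closed = TRUE)
  tab <- data.frame(
    mid_deg = (edges[-length(edges)] + edges[-1]) / 2,
    n_total = tabulate(bin, nbins = length(edges) - 1L),
    n_detected = vapply(seq_len(length(edges) - 1L),
                        function(b) sum(det[bin == b]), integer(1))
  )
  tab <- tab[tab$n_total > 0L, , drop = FALSE]
  tab$p <- tab$n_detected / tab$n_total
  if (nrow(tab) < 3L) stop("fewer than 3 informative bins", call. = FALSE)
  if (all(tab$n_detected == 0L)) stop("no detections: no profile to fit", call. = FALSE)

  w <- tab$n_total
  obj <- function(par) {
    mu <- if (free_center) par[3] else 0
    sum(w * (tab$p - par[1] * exp(-(tab$mid_deg - mu)^2 / (2 * par[2]^2)))^2)
  }
  init <- c(A = min(1, max(tab$p)),
            sigma = max(bin_width_deg, max(tab$mid_deg[tab$p > max(tab$p) / 2])))
  lower <- c(0, 0.5); upper <- c(1, 1e4)
  if (free_center) {
    init <- c(init, mu = 0); lower <- c(lower, -90); upper <- c(upper, 90)
  }
  ft <- stats::optim(init, obj, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 500))
  mu <- if (free_center) ft$par[3] else 0
  tab$p_fit <- ft$par[1] * exp(-(tab$mid_deg - mu)^2 / (2 * ft$par[2]^2))
  out <- list(A = unname(ft$par[1]), sigma_deg = unname(ft$par[2]),
              rss = ft$value, bins = tab,
              n_bins_informative = nrow(tab),
              bin_width_deg = bin_width_deg,
              converged = ft$convergence == 0)
  if (free_center) out$mu_deg <- unname(mu)
  structure(out, class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("Gaussian perception profile: A = %.3f, sigma = %.2f deg (rss %.4f, %d bins)\n",
              x$A, x$sigma_deg, x$rss, x$n_bins_informative))
  invisible(x)
}

#' One-way fixed-effects ANOVA between change types
#'
#' Classical one-way F test on per-participant means (one value per
#' participant per group), with the conventional alpha = 0.05 two-sided
#' decision rule. The degenerate case of zero variance everywhere with equal
#' means yields F = 0, p = 1.
#'
#' @param groups Named list of numeric vectors (one per group).
#' @param label Comparison label, e.g. `"C-S"` or `"C-S-M"`.
#' @return A data frame row: `comparison`, `F`, `p`, `df1`, `df2`,
#'   `group_sizes`.
#' @export
anova_oneway <- function(groups, label = paste(names(groups), collapse = "-")) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L || any(vapply(groups, length, 1L) < 2L)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  df1 <- length(groups) - 1L
  df2 <- length(x) - length(groups)
  if (all(vapply(groups, stats::var, 1) == 0)) {
    means <- vapply(groups, mean, 1)
    if (max(means) - min(means) == 0) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  } else {
    ow <- stats::oneway.test(x ~ g, var.equal = TRUE)
    f <- unname(ow$statistic); p <- unname(ow$p.value)
  }
  data.frame(comparison = label, F = f, p = p, df1 = df1, df2 = df2,
             group_sizes = paste(vapply(groups, length, 1L), collapse = ","),
             stringsAsFactors = FALSE)
}

#' All pairwise and omnibus change-type comparisons for one metric
#'
#' Runs the C-S, S-M, C-M and C-S-M one-way ANOVAs used to compare
#' reaction times, detection ratios and saccade amplitudes between change
#' types.
#'
#' @param per_participant Data frame with columns `participant`,
#'   `change_type` and the metric column `value`.
#' @param metric Name recorded in the output.
#' @return Data frame of [anova_oneway()] rows.
#' @export
anova_comparisons <- function(per_participant, metric = "value") {
  lab <- c(color = "C", shape = "S", motion = "M")
  grp <- lapply(CHANGE_TYPES, function(ty) {
    per_participant$value[per_participant$change_type == ty]
  })
  names(grp) <- lab[CHANGE_TYPES]
  pairs <- list(c("C", "S"), c("S", "M"), c("C", "M"))
  rows <- lapply(pairs, function(p) anova_oneway(grp[p]))
  rows <- c(rows, list(anova_oneway(grp, label = "C-S-M")))
  out <- do.call(rbind, rows)
  out$metric <- metric
  out
}

#' Assemble and serialize a study report
#'
#' Collects the cohort summary, Gaussian profile fits and ANOVA tables into
#' one JSON-serializable report.
#'
#' @param cohort_by_type Data frame of per-type cohort summaries (pooled
#'   rates, mean RTs, amplitudes).
#' @param fits Named list of [fit_profile()] results per change type (may be
#'   empty).
#' @param anovas Data frame of [anova_comparisons()] rows (may be NULL).
#' @param meta List of provenance fields (seed, n participants, timings...).
#' @return A `study_report` list.
#' @export
build_report <- function(cohort_by_type = NULL, fits = list(), anovas = NULL,
                         meta = list()) {
  structure(list(
    meta = meta,
    cohort = cohort_by_type,
    profile_fits = lapply(fits, function(f) {
      f <- unclass(f)
      f$bins <- as.data.frame(f$bins)
      f
    }),
    anova = anovas
  ), class = "study_report")
}

#' @rdname build_report
#' @param report A `study_report`.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname build_report
#' @export
read_report <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(r, class = "study_report")
}
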