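#' Estimate the maximal growth rate from the exponential phase
#'
#' Scans all contiguous windows of at least `min_window_points` points,
#' fits a log-linear regression in each, and returns the maximal slope among
#' windows whose r-squared meets `r2_threshold` (falling back to the best-r2
#' window when none qualifies). Growth rates are per hour.
#'
#' On dense grids (e.g. 10-minute OD reads) very short windows make the
#' max-slope statistic noise-sensitive; raise `min_window_points` so windows
#' span at least ~1 h of data in that case (see the methods vignette).
#'
#' @param times Time points, hours.
#' @param values Positive measurements (CFU counts or OD). Non-positive
#'   values are dropped before the log transform (plating can yield zeros);
#'   losing more than half the points this way raises a warning.
#' @param min_window_points Minimal window length (default 4).
#' @param r2_threshold Admissibility threshold on the window r-squared.
#' @return A list of class `rate_estimate`: `rate` (1/h), `window`
#'   (t_start, t_end), `r2`, `ci95`, `n_points`, `admissible` (whether any
#'   window met the threshold).
#' @examples
#' t <- 0:8
#' estimate_max_growth_rate(t, exp(0.9 * t))$rate  # 0.9
#' @export
estimate_max_growth_rate <- function(times, values, min_window_points = 4,
                                     r2_threshold = 0.98) {
  keep <- is.finite(values) & values > 0
  if (sum(keep) < length(values) / 2)
    warning("more than half the points are non-positive and were dropped",
            call. = FALSE)
  times <- times[keep]; values <- values[keep]
  n <- length(times)
  if (n < min_window_points)
    stop("need at least ", min_window_points, " positive points", call. = FALSE)
  y <- log(values)
  if (sd(y) == 0) {
    return(structure(list(rate = 0, window = range(times), r2 = NA_real_,
                          ci95 = c(0, 0), n_points = n, admissible = FALSE),
                     class = "rate_estimate"))
  }
  best <- window_scan(times, y, min_window_points, r2_threshold,
                      pick = "max_slope")
  structure(c(best, list(admissible = best$met_threshold)),
            class = "rate_estimate")
}

#' Estimate the death rate from the post-peak exponential decline
#'
#' The death phase starts at the global argmax of the median-smoothed curve
#' (ties broken to the earliest time). Because the per-capita rate only
#' approaches `-d` once the growth factors have vanished, the near-flat
#' early-stationary plateau must not dilute the fit: the rate is the
#' steepest log-linear decline over contiguous post-peak windows of at
#' least `min_window_points` points (r-squared admissibility
#' `r2_threshold`, falling back to the full post-peak segment), reported as
#' a positive number (larger = faster death).
#'
#' @inheritParams estimate_max_growth_rate
#' @param min_window_points Minimal decline-window length.
#' @param r2_threshold Window admissibility threshold; lower than for
#'   growth because the decline signal is shallow relative to the
#'   scale-proportional counting noise.
#' @return A `rate_estimate` list (rate in 1/h, positive for decline).
#' @examples
#' t <- c(0, 8, 16, 24, 32, 40)
#' v <- c(1, 50, 100, 100 * exp(-0.05 * 8), 100 * exp(-0.05 * 16), 100 * exp(-0.05 * 24))
#' estimate_death_rate(t, v)$rate  # 0.05
#' @export
estimate_death_rate <- function(times, values, min_window_points = 4,
                                r2_threshold = 0.8) {
  keep <- is.finite(values) & values > 0
  if (sum(keep) < length(values) / 2)
    warning("more than half the points are non-positive and were dropped",
            call. = FALSE)
  times <- times[keep]; values <- values[keep]
  n <- length(times)
  if (n < 4L) stop("need at least 4 positive points", call. = FALSE)
  sm <- stats::runmed(values, 3)
  peak <- which.max(sm)  # which.max returns the earliest tie
  if (n - peak < 2L)
    stop("no death phase: curve ends at (or just after) its maximum",
         call. = FALSE)
  idx <- peak:n
  tt <- times[idx]; yy <- log(values[idx])
  m <- length(idx)
  if (m >= min_window_points) {
    # steepest decline = maximal slope of the negated log curve
    best <- window_scan(tt, -yy, min(min_window_points, m), r2_threshold)
    est <- list(rate = best$rate, window = best$window, r2 = best$r2,
                ci95 = sort(best$ci95), n_points = best$n_points,
                admissible = best$met_threshold)
  } else {
    fit <- lm(yy ~ tt)
    sl <- unname(coef(fit)[2])
    se <- summary(fit)$coefficients[2, 2]
    ci <- -sl + c(-1, 1) * qt(0.975, m - 2) * se
    est <- list(rate = -sl, window = range(tt),
                r2 = summary(fit)$r.squared, ci95 = sort(ci),
                n_points = m, admissible = TRUE)
  }
  if (est$rate <= 0)
    stop("no death phase: post-peak segment is not declining", call. = FALSE)
  structure(est, class = "rate_estimate")
}

# Sliding-window log-linear scan over all contiguous windows of >= min_len
# points (O(1) per window via prefix sums). y is already on the log scale.
window_scan <- function(times, y, min_len, r2_threshold, pick = "max_slope") {
  n <- length(times)
  ct <- cumsum(c(0, times)); cy <- cumsum(c(0, y))
  ctt <- cumsum(c(0, times^2)); cty <- cumsum(c(0, times * y))
  cyy <- cumsum(c(0, y^2))
  best_adm <- NULL; best_any <- NULL
  for (i in seq_len(n - min_len + 1L)) {
    for (j in (i + min_len - 1L):n) {
      m <- j - i + 1L
      st <- ct[j + 1] - ct[i]; sy <- cy[j + 1] - cy[i]
      stt <- ctt[j + 1] - ctt[i]; sty <- cty[j + 1] - cty[i]
      syy <- cyy[j + 1] - cyy[i]
      sxx <- stt - st^2 / m
      if (sxx <= 0) next
      sxy <- sty - st * sy / m
      sst <- syy - sy^2 / m
      sl <- sxy / sxx
      sse <- max(sst - sl * sxy, 0)
      r2 <- if (sst > 0) 1 - sse / sst else NA_real_
      se <- if (m > 2) sqrt(sse / (m - 2) / sxx) else NA_real_
      cand <- list(rate = sl, window = c(times[i], times[j]), r2 = r2,
                   ci95 = sl + c(-1, 1) * qt(0.975, max(m - 2, 1)) * se,
                   n_points = m)
      if (!is.na(r2) && r2 >= r2_threshold) {
        if (is.null(best_adm) || cand$rate > best_adm$rate) best_adm <- cand
      }
      if (is.null(best_any) || (!is.na(r2) && (is.na(best_any$r2) || r2 > best_any$r2)))
        best_any <- cand
    }
  }
  if (!is.null(best_adm)) c(best_adm, list(met_threshold = TRUE))
  else c(best_any, list(met_threshold = FALSE))
}

#' Per-replicate growth/death rate table for a long-format dataset
#'
#' Applies [estimate_max_growth_rate()] (on OD rows when present, else CFU)
#' and [estimate_death_rate()] (on CFU rows) per strain and replicate.
#'
#' @param data Long data frame with columns `strain`, `replicate`, `time_h`,
#'   `value`, `modality`.
#' @param od_min_window_points Window floor used for dense OD grids.
#' @return Data frame: `strain`, `replicate`, `which` ("growth"/"death"),
#'   `rate`, `t_start`, `t_end`, `r2`, `ci_low`, `ci_high`.
#' @export
rate_table <- function(data, od_min_window_points = 7) {
  stopifnot(all(c("strain", "replicate", "time_h", "value", "modality") %in% names(data)))
  out <- list()
  for (s in unique(data$strain)) {
    ds <- data[data$strain == s, ]
    growth_mod <- if ("OD" %in% ds$modality) "OD" else "CFU"
    for (r in unique(ds$replicate[ds$modality == growth_mod])) {
      d1 <- ds[ds$modality == growth_mod & ds$replicate == r, ]
      mw <- if (growth_mod == "OD") od_min_window_points else 4
      est <- try(estimate_max_growth_rate(d1$time_h, d1$value,
                                          min_window_points = mw), silent = TRUE)
      if (!inherits(est, "try-error"))
        out[[length(out) + 1L]] <- data.frame(
          strain = s, replicate = r, which = "growth", rate = est$rate,
          t_start = est$window[1], t_end = est$window[2], r2 = est$r2,
          ci_low = est$ci95[1], ci_high = est$ci95[2])
    }
    for (r in unique(ds$replicate[ds$modality == "CFU"])) {
      d1 <- ds[ds$modality == "CFU" & ds$replicate == r, ]
      est <- try(estimate_death_rate(d1$time_h, d1$value), silent = TRUE)
      if (!inherits(est, "try-error"))
        out[[length(out) + 1L]] <- data.frame(
          strain = s, replicate = r, which = "death", rate = est$rate,
          t_start = est$window[1], t_end = est$window[2], r2 = est$r2,
          ci_low = est$ci95[1], ci_high = est$ci95[2])
    }
  }
  do.call(rbind, out)
}
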