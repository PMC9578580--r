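#' Parameter-range presets for feasibility mapping
#'
#' `fig3b`: lambda 0.8-1.5, B 1e-4..1e-3, K_r 0..1, K_qs 1e2..1e3 (density
#' model only). `s4fig` (Hill study): B down to 1e-5, K_qs up to 1e5, Hill
#' exponent 0.25-20. Neither source states a death-rate range; `d` spans
#' 0.01-0.3 1/h (the order of the observed death rates; see the methods
#' vignette).
#'
#' @param preset `"fig3b"` or `"s4fig"`.
#' @return Named list of `(low, high)` ranges with a `log` attribute naming
#'   the log-uniformly sampled parameters.
#' @export
feasibility_ranges <- function(preset = c("fig3b", "s4fig")) {
  preset <- match.arg(preset)
  rg <- switch(preset,
    fig3b = list(lambda_max = c(0.8, 1.5), d = c(0.01, 0.3),
                 B = c(1e-4, 1e-3), K_r = c(0, 1), K_qs = c(1e2, 1e3),
                 H = c(1, 1)),
    s4fig = list(lambda_max = c(0.8, 1.5), d = c(0.01, 0.3),
                 B = c(1e-5, 1e-3), K_r = c(0, 1), K_qs = c(1e2, 1e5),
                 H = c(0.25, 20))
  )
  attr(rg, "log") <- c("d", "B", "K_qs")
  rg
}

#' Sample the attainable (time-to-max-FC, max-FC) phase space of a model
#'
#' Draws parameter sets (log-uniform for `d`, `B`, `K_qs`; uniform for
#' `lambda_max`, `K_r`, `H`), simulates each to `horizon` hours and records
#' the trajectory summary. Simulation failures are recorded, not fatal.
#'
#' @param ranges Named list of `(low, high)` per parameter, as from
#'   [feasibility_ranges()].
#' @param n_samples Number of parameter draws.
#' @param model `"R"` or `"RQ"`.
#' @param horizon Simulation horizon, h (the experiments ran 56 h).
#' @param dt Output grid step for peak location, h.
#' @param seed Integer seed.
#' @param obs_grid Optional observation schedule (times in h). When given,
#'   each trajectory is summarized on that sparse grid without peak
#'   refinement, yielding the region of grid-observable summaries — the
#'   right reference when testing grid-limited observations for membership.
#' @return Data frame of class `qsg_region_points` with columns `t_max_fc`,
#'   `max_fc` and the drawn parameters; attribute `failure_fraction`.
#' @export
sample_phase_space <- function(ranges, n_samples = 1e4, model = c("RQ", "R"),
                               horizon = 56, dt = 0.25, seed = 1,
                               obs_grid = NULL) {
  model <- match.arg(model)
  stopifnot(n_samples >= 1)
  logpars <- attr(ranges, "log")
  if (is.null(logpars)) logpars <- c("d", "B", "K_qs")
  set.seed(seed)
  draws <- lapply(names(ranges), function(nm) {
    draw_param(ranges[[nm]], n_samples, nm %in% logpars && all(ranges[[nm]] > 0))
  })
  names(draws) <- names(ranges)
  if (is.null(draws$H)) draws$H <- rep(1, n_samples)
  times <- if (is.null(obs_grid)) seq(0, horizon, by = dt) else as.numeric(obs_grid)
  refine <- is.null(obs_grid)
  t_max <- max_fc <- rep(NA_real_, n_samples)
  fail <- 0L
  for (i in seq_len(n_samples)) {
    p <- kinetic_params(draws$lambda_max[i], draws$d[i], draws$B[i],
                        draws$K_r[i],
                        if (model == "RQ" && !is.null(draws$K_qs)) draws$K_qs[i] else Inf,
                        draws$H[i])
    sim <- try(simulate_growth(p, model, times), silent = TRUE)
    if (inherits(sim, "try-error")) { fail <- fail + 1L; next }
    sm <- trajectory_summary(sim$time, sim$N, refine = refine)
    t_max[i] <- sm$t_max_fc; max_fc[i] <- sm$max_fc
  }
  out <- data.frame(t_max_fc = t_max, max_fc = max_fc,
                    as.data.frame(draws))
  out <- out[!is.na(out$t_max_fc), ]
  structure(out, failure_fraction = fail / n_samples, model = model,
            horizon = horizon, ranges = ranges,
            class = c("qsg_region_points", "data.frame"))
}

#' Envelope of a sampled feasibility region
#'
#' Bins the points by log10 maximal fold change and records the min/max
#' time-to-max per bin, giving lower and upper boundary polylines of the
#' attainable set (the region is visibly non-convex, so a per-bin envelope
#' is used rather than a convex hull).
#'
#' @param points Data frame with `t_max_fc`, `max_fc` (e.g. from
#'   [sample_phase_space()]).
#' @param n_bins Number of log10(max FC) bins.
#' @return A list of class `qsg_region`: `bins` (data frame with bin edges,
#'   `t_min`, `t_max`, `n`), `fc_span`, `model_id`.
#' @export
region_boundary <- function(points, n_bins = 50) {
  stopifnot(nrow(points) >= 3)
  lf <- log10(points$max_fc)
  tm <- points$t_max_fc
  if (diff(range(lf)) < 1e-9 || diff(range(tm)) < 1e-9 ||
      abs(stats::cor(lf, tm)) > 1 - 1e-12)
    stop("degenerate (collinear or zero-spread) point cloud", call. = FALSE)
  edges <- seq(min(lf), max(lf), length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(lf, edges, rightmost.closed = TRUE), 1L), n_bins)
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- idx == b
    if (!any(sel)) return(NULL)
    data.frame(bin = b, fc_lo = 10^edges[b], fc_hi = 10^edges[b + 1],
               t_min = min(tm[sel]), t_max = max(tm[sel]), n = sum(sel))
  }))
  structure(list(bins = bins, fc_span = range(points$max_fc),
                 model_id = attr(points, "model"), n_bins = n_bins),
            class = "qsg_region")
}

#' Test whether an observation lies inside a feasibility region
#'
#' Looks up the observation's fold-change bin and compares its
#' time-to-max-FC against the bin's `[t_min, t_max]` envelope. The margin is
#' a signed distance in hours: positive outside (beyond the nearer
#' boundary), negative inside. Observed peak times from sparse schedules are
#' grid-limited, so margins should be judged against the sampling interval
#' (8 h for the coarse schedule).
#'
#' @param t_max_fc,max_fc The observation.
#' @param region A `qsg_region` from [region_boundary()].
#' @return List: `inside`, `margin_h`, `fc_in_span`.
#' @export
point_in_region <- function(t_max_fc, max_fc, region) {
  stopifnot(inherits(region, "qsg_region"))
  bins <- region$bins
  in_span <- max_fc >= region$fc_span[1] && max_fc <= region$fc_span[2]
  b <- bins[bins$fc_lo <= max_fc & max_fc <= bins$fc_hi, ]
  if (nrow(b) == 0) {
    # out-of-span or empty interior bin: judge against the nearest populated
    # bin so the time-margin stays informative
    mid <- sqrt(bins$fc_lo * bins$fc_hi)
    b <- bins[which.min(abs(log10(mid) - log10(max_fc))), ]
  }
  b <- b[1, ]
  if (!in_span || t_max_fc < b$t_min || t_max_fc > b$t_max) {
    margin <- max(b$t_min - t_max_fc, t_max_fc - b$t_max, 0)
    list(inside = FALSE, margin_h = margin, fc_in_span = in_span)
  } else {
    list(inside = TRUE, margin_h = -min(t_max_fc - b$t_min, b$t_max - t_max_fc),
         fc_in_span = TRUE)
  }
}

#' Export a feasibility region (points + envelope) as JSON
#'
#' @param points A `qsg_region_points` data frame.
#' @param region A `qsg_region` envelope.
#' @param path Output file path.
#' @export
write_region_json <- function(points, region, path) {
  obj <- list(model = attr(points, "model"),
              ranges = attr(points, "ranges"),
              failure_fraction = attr(points, "failure_fraction"),
              points = points[, c("t_max_fc", "max_fc")],
              envelope = region$bins)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
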