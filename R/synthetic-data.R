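#' Standard sampling schedules
#'
#' The CFU time courses use either a coarse 9-point schedule (t = 0, 3, 8 h,
#' then every 8 h to 56 h) or a finer 11-point schedule (t = 0, 1, 2 h, then
#' every 3 h); OD is read every 10 minutes for 16 h.
#'
#' @param kind One of `"coarse9"`, `"fine11"`, `"od10min"`, `"custom"`.
#' @param times Required when `kind = "custom"`: strictly increasing times
#'   from 0, hours.
#' @return Numeric vector of times (hours) with attribute `kind`.
#' @examples
#' sampling_schedule("coarse9")
#' @export
sampling_schedule <- function(kind = c("coarse9", "fine11", "od10min", "custom"),
                              times = NULL) {
  kind <- match.arg(kind)
  t <- switch(kind,
    coarse9 = c(0, 3, 8, 16, 24, 32, 40, 48, 56),
    fine11  = c(0, 1, 2, 5, 8, 11, 14, 17, 20, 23, 26),
    od10min = seq(0, 16, by = 1 / 6),
    custom  = times
  )
  if (is.null(t) || length(t) < 2L || t[1] != 0 || any(diff(t) <= 0))
    stop("schedule times must be strictly increasing from 0", call. = FALSE)
  structure(t, kind = kind)
}

#' Archetype specifications for synthetic strain panels
#'
#' Three dynamic classes mirror the study's phenotype clusters:
#' * `blue` — inefficient growers / strong communicators: low `K_qs`
#'   (slowdown at low density), low efficiency `1/B`, low death rate;
#' * `red` — highly efficient but rapidly dying: high `1/B`, high `d`,
#'   intermediate-to-high `K_qs`;
#' * `green` — efficient growers / poor communicators: highest `K_qs`,
#'   high `1/B` (slightly below red), low-to-intermediate `d`.
#'
#' Sub-ranges are chosen so the classes show the distinct dynamics the
#' clusters are defined by (low maximal fold change and slow death for
#' blue; intermediate fold change with rapid decline for red; the highest
#' fold change for green), anchored to the broad ranges lambda 0.8-1.5 1/h,
#' K_r 0..1, K_qs 1e2..1e3.
#'
#' @param name `"blue"`, `"red"` or `"green"`, or `"all"` for the list of
#'   all three.
#' @param n_strains Number of strains drawn from the class.
#' @param replicates_range Inclusive range the per-strain replicate count is
#'   drawn from (the study's panels are unbalanced, 3-7 replicates).
#' @return A list of class `archetype_spec` (or list of three).
#' @export
archetype_spec <- function(name = c("blue", "red", "green", "all"),
                           n_strains = 4, replicates_range = c(3, 7)) {
  name <- match.arg(name)
  if (name == "all") {
    return(lapply(c("blue", "red", "green"), archetype_spec,
                  n_strains = n_strains, replicates_range = replicates_range))
  }
  ranges <- switch(name,
    blue = list(
      lambda_max = c(0.8, 1.0), d = c(0.02, 0.04),
      B = c(2.5e-3, 4e-3),         # 1/B 250..400 (inefficient; low peak)
      K_r = c(0.1, 0.4), K_qs = c(0.8e2, 1.3e2)
    ),
    red = list(
      lambda_max = c(1.2, 1.35), d = c(0.25, 0.29),
      B = c(1.25e-4, 1.54e-4),     # 1/B 6500..8000 (most efficient)
      K_r = c(0.1, 0.4), K_qs = c(5.2e2, 5.8e2)
    ),
    green = list(
      lambda_max = c(1.0, 1.3), d = c(0.05, 0.08),
      B = c(1.67e-4, 2.2e-4),      # 1/B 4500..6000 (slightly below red)
      K_r = c(0.1, 0.4), K_qs = c(6.5e2, 9.5e2)
    )
  )
  structure(list(name = name, param_ranges = ranges, n_strains = n_strains,
                 replicates_range = replicates_range),
            class = "archetype_spec")
}

# draw one value per (low, high) range; log-uniform for scale parameters
draw_param <- function(range, n, log_scale) {
  if (length(range) != 2L || range[1] > range[2] || any(range <= 0 & log_scale))
    stop("invalid parameter range", call. = FALSE)
  if (range[1] == range[2]) return(rep(range[1], n))
  if (log_scale) exp(runif(n, log(range[1]), log(range[2])))
  else runif(n, range[1], range[2])
}

#' Draw strain-level kinetic parameters from an archetype
#'
#' `B` and `K_qs` are drawn log-uniformly (they span decades); `lambda_max`,
#' `d` and `K_r` uniformly. Deterministic given `seed`.
#'
#' @param spec An [archetype_spec()].
#' @param seed Integer seed.
#' @return List of [kinetic_params()], length `spec$n_strains`.
#' @export
generate_strain_params <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "archetype_spec"))
  set.seed(seed)
  n <- spec$n_strains
  rg <- spec$param_ranges
  lam <- draw_param(rg$lambda_max, n, FALSE)
  d   <- draw_param(rg$d, n, FALSE)
  B   <- draw_param(rg$B, n, TRUE)
  Kr  <- draw_param(rg$K_r, n, FALSE)
  Kqs <- draw_param(rg$K_qs, n, TRUE)
  lapply(seq_len(n), function(i)
    kinetic_params(lam[i], d[i], B[i], Kr[i], Kqs[i]))
}

#' Generate a replicated CFU time course from known kinetics
#'
#' Simulates the density-dependent model and overlays multiplicative
#' lognormal noise with unit median and coefficient of variation `noise_cv`
#' (CFU counts span several decades, so the residual spread is roughly
#' scale-proportional). Counts start from `N0_cells` cells.
#'
#' @param p [kinetic_params()].
#' @param schedule A [sampling_schedule()] (or numeric times from 0).
#' @param n_replicates Number of replicates.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param N0_cells Inoculum size (cells); the study used 1e6 per well.
#' @param seed Integer seed (deterministic output).
#' @param model `"RQ"` (default) or `"R"`.
#' @return A long data frame: `strain`, `replicate`, `time_h`, `value`,
#'   `modality = "CFU"`, with attribute `params`.
#' @export
generate_cfu_dataset <- function(p, schedule = sampling_schedule("coarse9"),
                                 n_replicates = 5, noise_cv = 0.1,
                                 N0_cells = 1e6, seed = 1, model = "RQ",
                                 strain = "synthetic") {
  stopifnot(noise_cv >= 0)
  sim <- simulate_growth(as_kinetic_params(p), model, times = as.numeric(schedule))
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))     # lognormal with unit median, CV = noise_cv
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(rep_i) {
    eps <- if (noise_cv == 0) 1 else rlnorm(nrow(sim), meanlog = 0, sdlog = sdlog)
    data.frame(strain = strain, replicate = rep_i, time_h = sim$time,
               value = N0_cells * sim$N * eps, modality = "CFU")
  }))
  attr(out, "params") <- as_kinetic_params(p)
  out
}

#' Generate a replicated OD time course from known kinetics
#'
#' OD proxies total (live + dead) biomass: dead cells keep scattering light.
#' The simulated OD is `od0 * (1 + cumulative gross births)`, which is
#' non-decreasing even while the live count declines, plus additive Gaussian
#' reader noise.
#'
#' @inheritParams generate_cfu_dataset
#' @param noise_sd Additive Gaussian noise standard deviation (OD units).
#' @param od0 Initial optical density (the study inoculated at OD 0.05).
#' @return A long data frame with `modality = "OD"`.
#' @export
generate_od_dataset <- function(p, schedule = sampling_schedule("od10min"),
                                n_replicates = 3, noise_sd = 0.003,
                                od0 = 0.05, seed = 1, model = "RQ",
                                strain = "synthetic") {
  stopifnot(noise_sd >= 0)
  sim <- simulate_growth(as_kinetic_params(p), model, times = as.numeric(schedule))
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(rep_i) {
    eps <- if (noise_sd == 0) 0 else rnorm(nrow(sim), 0, noise_sd)
    data.frame(strain = strain, replicate = rep_i, time_h = sim$time,
               value = od0 * (1 + sim$births) + eps, modality = "OD")
  }))
  attr(out, "params") <- as_kinetic_params(p)
  out
}

#' Generate a full multi-strain, multi-archetype panel
#'
#' Draws strains from the three archetype classes, simulates replicated CFU
#' (and optionally OD) time courses for each, and returns the long table plus
#' the generating truth.
#'
#' @param specs List of [archetype_spec()]s (default: the three standard
#'   classes, 4 strains each).
#' @param schedule CFU sampling schedule.
#' @param noise_cv CFU noise level.
#' @param with_od Also generate OD datasets per strain.
#' @param od_noise_sd OD noise level.
#' @param seed Integer seed.
#' @return A list with `data` (long CFU table; plus `od` if requested),
#'   `truth` (data frame of strain, class, generating parameters).
#' @export
generate_archetype_panel <- function(specs = archetype_spec("all"),
                                     schedule = sampling_schedule("coarse9"),
                                     noise_cv = 0.15, with_od = FALSE,
                                     od_noise_sd = 0.003, seed = 1) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 3 * sum(vapply(specs, function(s) as.integer(s$n_strains), 1L)) + 3)
  si <- 0L
  rows <- list(); od_rows <- list(); truth <- list()
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    si <- si + 1L
    params <- generate_strain_params(spec, seed = seeds[si])
    for (j in seq_along(params)) {
      si <- si + 1L
      id <- sprintf("%s_%02d", spec$name, j)
      n_rep <- sample(seq(spec$replicates_range[1], spec$replicates_range[2]), 1)
      rows[[id]] <- generate_cfu_dataset(params[[j]], schedule, n_rep,
                                         noise_cv, seed = seeds[si], strain = id)
      if (with_od) {
        si <- si + 1L
        od_rows[[id]] <- generate_od_dataset(params[[j]], n_replicates = 3,
                                             noise_sd = od_noise_sd,
                                             seed = seeds[si], strain = id)
      }
      truth[[id]] <- data.frame(strain = id, class = spec$name,
                                t(unlist(unclass(params[[j]]))))
    }
  }
  out <- list(data = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  if (with_od) out$od <- do.call(rbind, c(od_rows, list(make.row.names = FALSE)))
  out
}
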