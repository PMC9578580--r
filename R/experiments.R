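#' Draw kinetic parameters from the broad study ranges
#'
#' lambda uniform 0.8-1.5 1/h; B log-uniform 1e-4..1e-3; K_r uniform 0-1;
#' K_qs log-uniform 1e2..1e3 (density model); d log-uniform over `d_range`
#' (defaults to 0.05-0.25 1/h, the order of the observed death rates).
#'
#' @param n Number of parameter sets.
#' @param model `"RQ"` or `"R"` (`K_qs = Inf`).
#' @param d_range Death-rate range, 1/h.
#' @param seed Integer seed.
#' @return List of [kinetic_params()].
#' @export
draw_study_params <- function(n, model = c("RQ", "R"),
                              d_range = c(0.05, 0.25), seed = 1) {
  model <- match.arg(model)
  set.seed(seed)
  lam <- runif(n, 0.8, 1.5)
  d <- exp(runif(n, log(d_range[1]), log(d_range[2])))
  B <- exp(runif(n, log(1e-4), log(1e-3)))
  Kr <- runif(n, 0, 1)
  Kqs <- if (model == "RQ") exp(runif(n, log(1e2), log(1e3))) else rep(Inf, n)
  lapply(seq_len(n), function(i) kinetic_params(lam[i], d[i], B[i], Kr[i], Kqs[i]))
}

#' Parameter-recovery study (two-stage protocol)
#'
#' For each of `n_datasets` seeded draws from the study ranges, generates a
#' fine-schedule CFU dataset (5 replicates, multiplicative noise) plus the
#' paired stage-one measurements the study design prescribes: an OD time
#' course for the maximal growth rate and a 56-hour coarse-schedule CFU
#' time course for the death rate (the fine schedule's 26-hour horizon
#' truncates the death phase for much of the parameter space). `B`, `K_r`,
#' `K_qs` are then fit per fine-schedule replicate with lambda and d fixed,
#' the per-dataset median of the fitted parameters is taken, and relative
#' errors against the generating truth are reported.
#'
#' @param n_datasets Number of independent datasets.
#' @param n_replicates CFU replicates per dataset.
#' @param noise_cv CFU noise level.
#' @param od_noise_sd OD noise level.
#' @param n_starts Multi-start count passed to [fit_model()].
#' @param seed Integer seed.
#' @return List: `per_dataset` (data frame of truth, estimates and relative
#'   errors) and `median_rel_err` (named vector over K_qs, B, lambda_max, d).
#' @export
recovery_study <- function(n_datasets = 20, n_replicates = 5, noise_cv = 0.1,
                           od_noise_sd = 0.003, n_starts = 8, seed = 1) {
  set.seed(seed)
  dseeds <- sample.int(1e9, 4 * n_datasets)
  truth <- draw_study_params(n_datasets, "RQ", seed = dseeds[1])
  sched <- sampling_schedule("fine11")
  coarse <- sampling_schedule("coarse9")
  rows <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    p <- truth[[i]]
    cfu <- generate_cfu_dataset(p, sched, n_replicates, noise_cv,
                                seed = dseeds[n_datasets + i])
    od <- generate_od_dataset(p, n_replicates = 3, noise_sd = od_noise_sd,
                              seed = dseeds[2 * n_datasets + i])
    cfu56 <- generate_cfu_dataset(p, coarse, 3, noise_cv,
                                  seed = dseeds[3 * n_datasets + i])
    lam_hat <- median(vapply(split(od, od$replicate), function(d1)
      estimate_max_growth_rate(d1$time_h, d1$value, min_window_points = 7)$rate, 1.0))
    d_hats <- vapply(split(cfu56, cfu56$replicate), function(d1) {
      est <- try(estimate_death_rate(d1$time_h, d1$value), silent = TRUE)
      if (inherits(est, "try-error")) NA_real_ else est$rate
    }, 1.0)
    d_hat <- median(d_hats, na.rm = TRUE)
    if (!is.finite(d_hat)) d_hat <- 0.1
    fc <- normalize_fold_change(cfu)
    est <- vapply(split(fc, fc$replicate), function(tr) {
      f <- try(two_stage_fit(tr$time_h, tr$value, lam_hat, d_hat,
                             model = "RQ", n_starts = n_starts, seed = dseeds[i]),
               silent = TRUE)
      if (inherits(f, "try-error")) return(c(B = NA, K_r = NA, K_qs = NA))
      c(B = f$params$B, K_r = f$params$K_r, K_qs = f$params$K_qs)
    }, c(B = 1.0, K_r = 1.0, K_qs = 1.0))
    B_hat <- median(est["B", ], na.rm = TRUE)
    Kqs_hat <- median(est["K_qs", ], na.rm = TRUE)
    rows[[i]] <- data.frame(
      dataset = i,
      lambda_true = p$lambda_max, d_true = p$d, B_true = p$B, K_qs_true = p$K_qs,
      lambda_hat = lam_hat, d_hat = d_hat, B_hat = B_hat, K_qs_hat = Kqs_hat,
      rel_err_lambda = abs(lam_hat - p$lambda_max) / p$lambda_max,
      rel_err_d = abs(d_hat - p$d) / p$d,
      rel_err_B = abs(B_hat - p$B) / p$B,
      rel_err_K_qs = abs(Kqs_hat - p$K_qs) / p$K_qs)
  }
  per <- do.call(rbind, rows)
  list(per_dataset = per,
       median_rel_err = c(
         K_qs = median(per$rel_err_K_qs, na.rm = TRUE),
         B = median(per$rel_err_B, na.rm = TRUE),
         lambda_max = median(per$rel_err_lambda, na.rm = TRUE),
         d = median(per$rel_err_d, na.rm = TRUE)))
}

#' Model-falsification study (feasibility re-enactment)
#'
#' Re-enacts the resource-only model's falsification: most density-limited
#' dynamics show (time-to-max-FC, max-FC) pairs the resource-only model
#' cannot produce. The resource-only region is sampled over the broad
#' ranges with the death rate held at a small representative value
#' (`region_d`; death is negligible for peak placement and is not among the
#' varied region parameters), and is built from summaries taken on the same
#' coarse 9-point observation grid as the observations, so grid resolution
#' cannot manufacture outsideness. Observations are noiseless trajectories
#' summarized on that grid: density-model draws (K_qs in 1e2..1e3) carry
#' the natural death-rate spread; the resource-only null draws come from
#' the region's own ensemble, so their inside fraction checks the
#' machinery.
#'
#' @param n_obs Observations per generating model.
#' @param n_region Parameter draws for the region.
#' @param region_d Death rate (1/h) the region is computed at.
#' @param d_range Death-rate range of the density-model observations.
#' @param seed Integer seed.
#' @return List: `frac_outside_RQ`, `frac_outside_R`, `margins_RQ`,
#'   `margins_R` (hours; negative = inside), `region`.
#' @export
falsification_study <- function(n_obs = 20, n_region = 1e4, region_d = 0.05,
                                d_range = c(0.01, 0.3), seed = 1) {
  set.seed(seed)
  seeds <- sample.int(1e9, 3)
  sched <- sampling_schedule("coarse9")
  rg <- feasibility_ranges("fig3b")
  rg$d <- c(region_d, region_d)
  pts <- sample_phase_space(rg, n_samples = n_region, model = "R",
                            seed = seeds[1], obs_grid = sched)
  region <- region_boundary(pts)

  observe <- function(params) {
    vapply(params, function(p) {
      sim <- simulate_growth(p, if (is.finite(p$K_qs)) "RQ" else "R",
                             times = as.numeric(sched))
      sm <- trajectory_summary(sim$time, sim$N, refine = FALSE)
      pr <- point_in_region(sm$t_max_fc, sm$max_fc, region)
      c(outside = as.numeric(!pr$inside),
        margin = if (pr$inside) -pr$margin_h else pr$margin_h)
    }, c(outside = 1.0, margin = 1.0))
  }
  obs_RQ <- observe(draw_study_params(n_obs, "RQ", d_range = d_range,
                                      seed = seeds[2]))
  obs_R <- observe(draw_study_params(n_obs, "R",
                                     d_range = c(region_d, region_d),
                                     seed = seeds[3]))
  list(frac_outside_RQ = mean(obs_RQ["outside", ]),
       frac_outside_R = mean(obs_R["outside", ]),
       margins_RQ = obs_RQ["margin", ], margins_R = obs_R["margin", ],
       region = region)
}

#' Model-selection study (AIC/BIC on synthetic curves)
#'
#' Generates noisy single-replicate fold-change curves from a chosen model
#' and compares the resource-only and density-dependent fits under the
#' canonical two-stage protocol: lambda from a paired OD time course, d
#' from a paired 56-hour coarse-schedule curve, then `B`, `K_r` (and
#' `K_qs`) fit to the fold-change curve. Both models share the stage-one
#' estimates, so the information criteria compare the dynamics terms on
#' equal footing while charging the density model for its extra parameter.
#'
#' @param n_curves Number of curves.
#' @param generator `"RQ"` or `"R"` (the data-generating model).
#' @param noise_cv Multiplicative noise level.
#' @param n_starts Multi-start count.
#' @param seed Integer seed.
#' @return List: `summary` (from [compare_models_dataset()]),
#'   `frac_spearman_high` (fraction of density-model fits with Spearman rho
#'   above 0.85), `fits_R`, `fits_RQ`.
#' @export
model_selection_study <- function(n_curves = 30, generator = c("RQ", "R"),
                                  noise_cv = 0.1, n_starts = 8, seed = 1) {
  generator <- match.arg(generator)
  set.seed(seed)
  seeds <- sample.int(1e9, 3 * n_curves + 1)
  truth <- draw_study_params(n_curves, generator, seed = seeds[3 * n_curves + 1])
  sched <- sampling_schedule("fine11")
  fits_R <- fits_RQ <- vector("list", n_curves)
  for (i in seq_len(n_curves)) {
    p <- truth[[i]]
    cfu <- generate_cfu_dataset(p, sched, n_replicates = 1,
                                noise_cv = noise_cv, seed = seeds[i],
                                model = generator)
    od <- generate_od_dataset(p, n_replicates = 1, noise_sd = 0.003,
                              seed = seeds[n_curves + i], model = generator)
    cfu56 <- generate_cfu_dataset(p, sampling_schedule("coarse9"), 1, noise_cv,
                                  seed = seeds[2 * n_curves + i],
                                  model = generator)
    lam_hat <- estimate_max_growth_rate(od$time_h, od$value,
                                        min_window_points = 7)$rate
    d_est <- try(estimate_death_rate(cfu56$time_h, cfu56$value), silent = TRUE)
    d_hat <- if (inherits(d_est, "try-error")) 0.1 else d_est$rate
    fc <- normalize_fold_change(cfu)
    fits_R[[i]] <- two_stage_fit(fc$time_h, fc$value, lam_hat, d_hat,
                                 model = "R", n_starts = n_starts, seed = seeds[i])
    fits_RQ[[i]] <- two_stage_fit(fc$time_h, fc$value, lam_hat, d_hat,
                                  model = "RQ", n_starts = n_starts, seed = seeds[i])
  }
  rho <- vapply(fits_RQ, `[[`, 1.0, "spearman_rho")
  list(summary = compare_models_dataset(fits_R, fits_RQ),
       frac_spearman_high = mean(rho > 0.85),
       fits_R = fits_R, fits_RQ = fits_RQ)
}

#' Archetype-clustering study
#'
#' Generates three-archetype panels (4 strains per class) and checks that
#' time-series clustering of the median trajectories recovers the
#' generating classes, scored by the adjusted Rand index.
#'
#' @param seeds Integer vector of panel seeds.
#' @param noise_cv CFU noise level.
#' @return List: `ari` (per seed), `median_ari`.
#' @export
clustering_study <- function(seeds = 1:10, noise_cv = 0.15) {
  ari <- vapply(seeds, function(s) {
    panel <- generate_archetype_panel(noise_cv = noise_cv, seed = s)
    mt <- median_trajectories(panel$data)
    cl <- cluster_timeseries(mt, k = 3)
    truth <- panel$truth$class[match(rownames(mt), panel$truth$strain)]
    mclust::adjustedRandIndex(cl$labels, truth)
  }, 1.0)
  list(ari = ari, median_ari = median(ari))
}
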