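PARAM_NAMES <- c("lambda_max", "d", "B", "K_r", "K_qs")

#' Default fitting bounds
#'
#' The broad feasibility ranges (lambda 0.8-1.5, B 1e-4..1e-3, K_r 0..1,
#' K_qs 1e2..1e3) widened by a factor of 10 on each side; the death-rate
#' bounds span well past the rates seen in practice.
#'
#' @param model `"RQ"` or `"R"` (the latter has no `K_qs` row).
#' @return A 2-column matrix (`lower`, `upper`) with parameter row names.
#' @export
default_fit_bounds <- function(model = "RQ") {
  b <- rbind(
    lambda_max = c(0.08, 15),
    d          = c(1e-3, 3),
    B          = c(1e-5, 1e-2),
    K_r        = c(1e-4, 10),
    K_qs       = c(10, 1e4)
  )
  colnames(b) <- c("lower", "upper")
  if (model == "R") b <- b[PARAM_NAMES[1:4], , drop = FALSE]
  b
}

#' Fit the growth/death model to a fold-change trajectory
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, `minpack.lm`) on
#' log10-transformed parameters, minimizing the sum of squared fold-change
#' residuals at the observation times. Because the objective is multi-modal,
#' the fit is restarted from `n_starts` log-uniformly drawn initial points
#' (the heuristic/supplied init is always the first start) and the best final
#' residual sum of squares wins. Deterministic given `seed`.
#'
#' @param times Observation times (h), starting at 0.
#' @param values Fold-change observations, normalized so `values[1] == 1`.
#' @param model `"RQ"` or `"R"` (`K_qs` held at `Inf`).
#' @param init Optional [kinetic_params()] used as the first start and as the
#'   source of values for `fixed` parameters.
#' @param bounds Parameter bounds matrix as from [default_fit_bounds()].
#' @param fixed Character vector of parameter names held at their `init`
#'   values (the two-stage protocol fixes `lambda_max` and `d` from the
#'   exponential phases and fits only `B`, `K_r`, `K_qs`).
#' @param n_starts Number of multi-start initializations.
#' @param seed Integer seed for the start draws.
#' @param residual_scale `"linear"` (fold change; default, the scale the
#'   study fit on) or `"log"` (log fold change).
#' @param rtol,atol ODE solver tolerances used inside the objective.
#' @return A list of class `qsg_fit`: `model_id`, `params`
#'   ([kinetic_params()]), `fixed_mask`, `rss`, `n_points`, `n_free_params`,
#'   `aic`, `bic`, `aicc`, `ci95` (per free parameter),
#'   `non_identifiable` (free parameters whose linearized CI spans the whole
#'   bound interval), `n_iterations`, `converged`, `spearman_rho`,
#'   `spearman_p`, `fitted`, `data`, `starts` (per-start diagnostics).
#' @export
fit_model <- function(times, values, model = c("RQ", "R"), init = NULL,
                      bounds = NULL, fixed = character(), n_starts = 8,
                      seed = 1, residual_scale = c("linear", "log"),
                      rtol = 1e-10, atol = 1e-12) {
  model <- match.arg(model)
  residual_scale <- match.arg(residual_scale)
  stopifnot(length(times) == length(values), times[1] == 0)
  if (abs(values[1] - 1) > 1e-6)
    stop("curve must be normalized to fold change (value 1 at t = 0)", call. = FALSE)
  if (is.null(bounds)) bounds <- default_fit_bounds(model)
  pnames <- rownames(bounds)
  if (!all(fixed %in% pnames)) stop("unknown parameter in `fixed`", call. = FALSE)
  free <- setdiff(pnames, fixed)
  n <- length(times)
  k <- length(free)
  if (n <= k + 1)
    stop("underdetermined: ", n, " points for ", k, " free parameters", call. = FALSE)

  if (is.null(init)) {
    mfc <- max(values)
    init <- kinetic_params(
      lambda_max = 1, d = 0.05, B = min(max(1 / max(mfc, 2), 1e-5), 1e-2),
      K_r = 0.3, K_qs = if (model == "RQ") max(mfc / 3, 20) else Inf)
  }
  init <- as_kinetic_params(init)
  full0 <- unlist(unclass(init))[PARAM_NAMES]
  if (model == "R") full0["K_qs"] <- Inf

  lo <- log10(bounds[free, "lower"]); hi <- log10(bounds[free, "upper"])
  obs <- values

  make_params <- function(par_log10) {
    full <- full0
    full[free] <- 10^par_log10
    full
  }
  residual_fn <- function(par_log10) {
    full <- make_params(par_log10)
    sim <- try(simulate_growth(
      kinetic_params(full["lambda_max"], full["d"], full["B"],
                     full["K_r"], full["K_qs"]),
      model = model, times = times, rtol = rtol, atol = atol), silent = TRUE)
    if (inherits(sim, "try-error") || any(!is.finite(sim$N)))
      return(rep(1e4, n))
    if (residual_scale == "log") log(pmax(sim$N, 1e-12)) - log(pmax(obs, 1e-12))
    else sim$N - obs
  }

  # multi-start: supplied/heuristic init first; for the density model also a
  # start with K_qs at its upper bound (the resource-only limit), so the
  # nested model is always reachable; then seeded log-uniform draws
  start0 <- pmin(pmax(log10(full0[free]), lo), hi)
  starts <- rbind(start0)
  if ("K_qs" %in% free) {
    startR <- start0
    startR["K_qs"] <- hi[match("K_qs", free)]
    starts <- rbind(starts, startR)
  }
  n_rand <- max(n_starts - nrow(starts), 0)
  set.seed(seed)
  if (n_rand > 0)
    starts <- rbind(starts,
                    matrix(runif(n_rand * k, rep(lo, each = n_rand),
                                 rep(hi, each = n_rand)),
                           ncol = k, dimnames = list(NULL, free)))
  colnames(starts) <- free

  runs <- vector("list", nrow(starts))
  for (s in seq_len(nrow(starts))) {
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = starts[s, ], lower = lo, upper = hi, fn = residual_fn,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-13,
                                           ptol = 1e-13, epsfcn = 1e-8))),
      silent = TRUE)
    if (inherits(fit, "try-error")) {
      runs[[s]] <- list(ok = FALSE, msg = as.character(fit))
    } else {
      runs[[s]] <- list(ok = TRUE, par = fit$par, rss = fit$deviance,
                        niter = fit$niter, info = fit$info,
                        converged = fit$info %in% 1:3)
    }
  }
  ok <- vapply(runs, function(x) isTRUE(x$ok), TRUE)
  if (!any(ok)) {
    stop("all ", nrow(starts), " starts failed: ",
         paste(unique(unlist(lapply(runs, `[[`, "msg"))), collapse = "; "),
         call. = FALSE)
  }
  rss_all <- vapply(runs, function(x) if (isTRUE(x$ok)) x$rss else Inf, 1.0)
  best <- runs[[which.min(rss_all)]]
  par_hat <- best$par
  full_hat <- make_params(par_hat)
  p_hat <- kinetic_params(full_hat["lambda_max"], full_hat["d"], full_hat["B"],
                          full_hat["K_r"], full_hat["K_qs"])

  sim_hat <- simulate_growth(p_hat, model = model, times = times,
                             rtol = rtol, atol = atol)
  pred <- sim_hat$N

  ic <- information_criteria(best$rss, n, k)
  ci <- fit_ci95(residual_fn, par_hat, best$rss, n, k)
  ci_nat <- 10^ci
  rownames(ci_nat) <- free
  non_id <- free[ci_nat[, 1] <= bounds[free, "lower"] &
                 ci_nat[, 2] >= bounds[free, "upper"]]

  sp <- suppressWarnings(cor.test(pred, obs, method = "spearman", exact = FALSE))

  structure(list(
    model_id = model, params = p_hat,
    fixed_mask = setNames(PARAM_NAMES %in% fixed, PARAM_NAMES),
    rss = best$rss, n_points = n, n_free_params = k,
    aic = ic$aic, bic = ic$bic, aicc = ic$aicc,
    ci95 = ci_nat, non_identifiable = non_id,
    n_iterations = best$niter, converged = best$converged,
    spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
    fitted = pred, data = list(times = times, values = values),
    residual_scale = residual_scale,
    starts = data.frame(rss = rss_all,
                        converged = vapply(runs, function(x) isTRUE(x$converged), TRUE))
  ), class = "qsg_fit")
}

# 95% CI from the linearized covariance sigma^2 (J'J)^-1 at the optimum,
# on the log10 parameter scale (J by central differences).
fit_ci95 <- function(residual_fn, par, rss, n, k) {
  if (k == 0) return(matrix(numeric(0), ncol = 2))
  h <- 1e-5
  r0 <- residual_fn(par)
  J <- matrix(0, length(r0), k)
  for (j in seq_len(k)) {
    pp <- par; pm <- par
    pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
    J[, j] <- (residual_fn(pp) - residual_fn(pm)) / (2 * h)
  }
  sigma2 <- rss / max(n - k, 1)
  cov <- try(solve(crossprod(J)) * sigma2, silent = TRUE)
  if (inherits(cov, "try-error")) {
    se <- rep(Inf, k)
  } else {
    se <- sqrt(pmax(diag(cov), 0))
  }
  cbind(par - qt(0.975, max(n - k, 1)) * se,
        par + qt(0.975, max(n - k, 1)) * se)
}

#' Two-stage fit: rates from the exponential phases, then the full dynamics
#'
#' Convenience wrapper implementing the study's protocol: `lambda_max` and
#' `d` are held at their stage-one estimates and only `B`, `K_r` (and `K_qs`
#' for the density-dependent model) are fit to the full fold-change curve.
#'
#' @inheritParams fit_model
#' @param lambda_hat,d_hat Stage-one estimates (1/h).
#' @param ... Passed to [fit_model()].
#' @return A `qsg_fit` object.
#' @export
two_stage_fit <- function(times, values, lambda_hat, d_hat,
                          model = c("RQ", "R"), ...) {
  model <- match.arg(model)
  bounds <- default_fit_bounds(model)
  lambda_hat <- min(max(lambda_hat, bounds["lambda_max", 1]), bounds["lambda_max", 2])
  d_hat <- min(max(d_hat, bounds["d", 1]), bounds["d", 2])
  mfc <- max(values)
  init <- kinetic_params(lambda_hat, d_hat,
                         B = min(max(1 / max(mfc, 2), 1e-5), 1e-2),
                         K_r = 0.3,
                         K_qs = if (model == "RQ") max(mfc / 3, 20) else Inf)
  fit_model(times, values, model = model, init = init,
            fixed = c("lambda_max", "d"), ...)
}

#' Least-squares information criteria
#'
#' Gaussian concentrated-likelihood forms:
#' `AIC = n log(rss/n) + 2k`, `BIC = n log(rss/n) + k log(n)`, plus the
#' small-sample `AICc = AIC + 2k(k+1)/(n-k-1)`.
#'
#' @param rss Residual sum of squares (> 0; 0 returns `-Inf` with attribute
#'   `zero_rss = TRUE`).
#' @param n_points,n_free_params Sample size and free-parameter count.
#' @return List with `aic`, `bic`, `aicc`.
#' @examples
#' information_criteria(0.9, 9, 4)$aic  # 9*log(0.1) + 8
#' @export
information_criteria <- function(rss, n_points, n_free_params) {
  stopifnot(n_points > n_free_params, rss >= 0)
  n <- n_points; k <- n_free_params
  if (rss == 0) {
    out <- list(aic = -Inf, bic = -Inf, aicc = -Inf)
    attr(out, "zero_rss") <- TRUE
    return(out)
  }
  aic <- n * log(rss / n) + 2 * k
  list(aic = aic,
       bic = n * log(rss / n) + k * log(n),
       aicc = aic + 2 * k * (k + 1) / max(n - k - 1, 1))
}

#' Compare the resource-only and density-dependent fits of one curve
#'
#' `delta = criterion(RQ) - criterion(R)`; negative values prefer the
#' density-dependent model.
#'
#' @param fit_R,fit_RQ `qsg_fit` objects for the same curve.
#' @return List: `delta_aic`, `delta_bic`, `preferred_aic`, `preferred_bic`.
#' @export
compare_models <- function(fit_R, fit_RQ) {
  stopifnot(inherits(fit_R, "qsg_fit"), inherits(fit_RQ, "qsg_fit"))
  if (fit_R$n_points != fit_RQ$n_points ||
      !isTRUE(all.equal(fit_R$data, fit_RQ$data)))
    stop("fits are not of the same curve", call. = FALSE)
  da <- fit_RQ$aic - fit_R$aic
  db <- fit_RQ$bic - fit_R$bic
  list(delta_aic = da, delta_bic = db,
       preferred_aic = if (da < 0) "RQ" else "R",
       preferred_bic = if (db < 0) "RQ" else "R")
}

#' Dataset-level model comparison summary
#'
#' Summarizes per-curve criterion differences across a dataset (mean and sd
#' of `delta`), the fraction of curves preferring the density-dependent
#' model, and a two-sample Kolmogorov-Smirnov test between the two models'
#' criterion values.
#'
#' @param fits_R,fits_RQ Lists of `qsg_fit` objects, pairwise over the same
#'   curves.
#' @return A list with per-criterion summaries.
#' @export
compare_models_dataset <- function(fits_R, fits_RQ) {
  stopifnot(length(fits_R) == length(fits_RQ))
  cmp <- Map(compare_models, fits_R, fits_RQ)
  da <- vapply(cmp, `[[`, 1.0, "delta_aic")
  db <- vapply(cmp, `[[`, 1.0, "delta_bic")
  aR <- vapply(fits_R, `[[`, 1.0, "aic"); aQ <- vapply(fits_RQ, `[[`, 1.0, "aic")
  bR <- vapply(fits_R, `[[`, 1.0, "bic"); bQ <- vapply(fits_RQ, `[[`, 1.0, "bic")
  ks_a <- suppressWarnings(ks.test(aR, aQ))
  ks_b <- suppressWarnings(ks.test(bR, bQ))
  list(
    n = length(da),
    aic = list(mean_delta = mean(da), sd_delta = sd(da),
               frac_prefer_RQ = mean(da < 0), ks_p = ks_a$p.value),
    bic = list(mean_delta = mean(db), sd_delta = sd(db),
               frac_prefer_RQ = mean(db < 0), ks_p = ks_b$p.value)
  )
}

#' Fit quality: rank agreement between model and data
#'
#' Spearman rank correlation between the fitted trajectory and the
#' observations at the data times.
#'
#' @param fit A `qsg_fit` object.
#' @return List with `spearman_rho` and `p_value` (`NA` with a flag when the
#'   predictions are constant).
#' @export
fit_quality <- function(fit) {
  stopifnot(inherits(fit, "qsg_fit"))
  if (sd(fit$fitted) == 0)
    return(list(spearman_rho = NA_real_, p_value = NA_real_, constant = TRUE))
  sp <- suppressWarnings(cor.test(fit$fitted, fit$data$values,
                                  method = "spearman", exact = FALSE))
  list(spearman_rho = unname(sp$estimate), p_value = sp$p.value,
       constant = FALSE)
}

#' @export
print.qsg_fit <- function(x, ...) {
  cat(sprintf("Model %s fit: rss = %.4g (n = %d, k = %d), AIC = %.2f, BIC = %.2f\n",
              x$model_id, x$rss, x$n_points, x$n_free_params, x$aic, x$bic))
  cat(sprintf("  converged: %s in %d iterations; Spearman rho = %.3f\n",
              x$converged, x$n_iterations, x$spearman_rho))
  print(x$params)
  invisible(x)
}
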