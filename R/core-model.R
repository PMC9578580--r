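#' @useDynLib qsgrowth
#' @importFrom stats median coef lm cor.test ks.test cutree hclust dist
#'   prcomp qt quantile runif rnorm rlnorm sd setNames complete.cases
NULL

#' Per-capita gross growth rate under resource and density modulation
#'
#' Evaluates the growth-rate law of the model: the maximal rate `lambda_max`
#' multiplied by a Monod/Hill resource factor (normalized to equal 1 at the
#' initial resource level `r0`) and, for the density-dependent model, by the factor
#' `K_qs / (N + K_qs)`. Death is not subtracted.
#'
#' @param r Resource level(s), normalized units (`r0 = 1` initially).
#' @param N Population density(ies), fold-change units.
#' @param p A [kinetic_params()] object.
#' @param model `"RQ"` (resource + density-dependent) or `"R"`
#'   (resource-only; ignores `K_qs`).
#' @param r0 Initial resource level the Monod factor is normalized to.
#' @return Per-capita gross growth rate(s), 1/h.
#' @examples
#' p <- kinetic_params(1, 0.02, 1e-3, K_r = 1, K_qs = 100)
#' growth_modulation(r = 0.5, N = 100, p, model = "RQ")  # 1/3
#' @export
growth_modulation <- function(r, N, p, model = c("RQ", "R"), r0 = 1) {
  model <- match.arg(model)
  p <- as_kinetic_params(p)
  if (any(r < 0) || any(N < 0)) stop("r and N must be non-negative", call. = FALSE)
  res <- resource_factor(r, p$K_r, p$H, r0)
  dens <- if (model == "R" || !is.finite(p$K_qs)) 1 else p$K_qs / (N + p$K_qs)
  p$lambda_max * res * dens
}

# Monod/Hill resource factor, normalized so it equals 1 at r = r0.
resource_factor <- function(r, K_r, H = 1, r0 = 1) {
  rh <- r^H
  krh <- K_r^H
  r0h <- r0^H
  out <- ((r0h + krh) / r0h) * (rh / (rh + krh))
  # r = 0 (and K_r = 0, giving 0/0) means no resource: factor 0
  out[r <= 0] <- 0
  out
}

#' Simulate the growth/death model
#'
#' Integrates the coupled ODEs for population `N` (fold-change units),
#' resource `r` (normalized units) and cumulative gross births `c` with an
#' adaptive solver (compiled right-hand side, `deSolve::ode`). The
#' resource-only model is the `K_qs = Inf` special case of the
#' density-dependent model, so both share one right-hand side.
#'
#' @param p A [kinetic_params()] object.
#' @param model `"RQ"` or `"R"`.
#' @param times Strictly increasing time grid in hours, starting at 0.
#' @param N0,r0 Initial population (fold change) and resource; both default
#'   to 1 (normalized units).
#' @param rtol,atol Solver relative/absolute tolerances.
#' @param method `deSolve` integration method.
#' @return A data frame of class `qsg_sim` with columns `time`, `N`, `r`,
#'   `births` (cumulative gross births), and attributes `params`, `model`.
#' @examples
#' p <- kinetic_params(1.1, 0.05, 5e-4, 0.3, 400)
#' sim <- simulate_growth(p, "RQ", times = seq(0, 56, by = 0.5))
#' @export
simulate_growth <- function(p, model = c("RQ", "R"), times,
                            N0 = 1, r0 = 1,
                            rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  model <- match.arg(model)
  p <- as_kinetic_params(p)
  if (length(times) < 2L || any(diff(times) <= 0) || times[1] != 0)
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  K_qs <- if (model == "R") Inf else p$K_qs
  parms <- c(p$lambda_max, p$d, p$B, p$K_r, K_qs, p$H, r0)
  out <- deSolve::ode(
    y = c(N = N0, r = r0, births = 0), times = times,
    func = "qsgrowth_derivs", parms = parms,
    dllname = "qsgrowth", initfunc = "qsgrowth_initmod",
    rtol = rtol, atol = atol, method = method
  )
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(out, "istate")[1], ")",
         call. = FALSE)
  df <- as.data.frame(out)
  df$r <- pmax(df$r, 0)
  df$N <- pmax(df$N, 0)
  structure(df, params = p, model = model, N0 = N0, r0 = r0,
            class = c("qsg_sim", "data.frame"))
}

#' Summarize a trajectory by its maximal fold change and the time it occurs
#'
#' @param times Time points, hours.
#' @param values Population values (fold change or raw counts; the maximum is
#'   normalized by the value at `times[1]`).
#' @param refine For densely simulated trajectories, refine the peak location
#'   by a local quadratic fit (in log value) around the grid maximum. Leave
#'   `FALSE` for sparse observed data, where the grid argmax is reported.
#' @return A list with `max_fc` and `t_max_fc` (hours).
#' @examples
#' trajectory_summary(c(0, 8, 16, 24), c(1, 4, 9, 4))  # max_fc 9 at 16 h
#' @export
trajectory_summary <- function(times, values, refine = FALSE) {
  if (inherits(times, "qsg_sim")) {
    sim <- times
    return(trajectory_summary(sim$time, sim$N, refine = TRUE))
  }
  stopifnot(length(times) == length(values))
  if (length(times) < 2L) stop("need at least 2 points", call. = FALSE)
  fc <- values / values[1]
  i <- which.max(fc)
  t_max <- times[i]
  max_fc <- fc[i]
  if (refine && i > 1L && i < length(times) && all(fc[(i - 1):(i + 1)] > 0)) {
    # vertex of the parabola through the three log-FC points around the max
    tt <- times[(i - 1):(i + 1)]
    yy <- log(fc[(i - 1):(i + 1)])
    d21 <- (yy[2] - yy[1]) / (tt[2] - tt[1])
    d32 <- (yy[3] - yy[2]) / (tt[3] - tt[2])
    curv <- (d32 - d21) / (tt[3] - tt[1])
    if (curv < 0) {
      tv <- (tt[1] + tt[2]) / 2 - d21 / (2 * curv)
      if (tv >= tt[1] && tv <= tt[3]) {
        t_max <- tv
        # evaluate the interpolating parabola at its vertex (Newton form)
        yv <- yy[1] + d21 * (tv - tt[1]) + curv * (tv - tt[1]) * (tv - tt[2])
        max_fc <- exp(yv)
      }
    }
  }
  list(max_fc = max_fc, t_max_fc = t_max)
}

#' Decompose the realized per-capita growth rate into its modulating factors
#'
#' For a density-dependent simulation, returns the time courses of the
#' density factor `K_qs / (N + K_qs)`, the (normalized) resource factor and
#' the death rate, so that `lambda_max * resource_factor * density_factor - d`
#' equals the realized per-capita rate at every time point.
#'
#' @param sim A `qsg_sim` data frame from [simulate_growth()].
#' @param p Optional [kinetic_params()]; defaults to the simulation's own.
#' @return A data frame with columns `time`, `resource_factor`,
#'   `density_factor`, `death_rate`, `per_capita_rate`.
#' @export
decompose_growth_terms <- function(sim, p = NULL) {
  stopifnot(inherits(sim, "qsg_sim"))
  if (is.null(p)) p <- attr(sim, "params")
  p <- as_kinetic_params(p)
  r0 <- attr(sim, "r0")
  if (is.null(r0)) r0 <- 1
  res <- resource_factor(sim$r, p$K_r, p$H, r0)
  dens <- if (is.finite(p$K_qs)) p$K_qs / (sim$N + p$K_qs) else rep(1, nrow(sim))
  data.frame(
    time = sim$time,
    resource_factor = res,
    density_factor = dens,
    death_rate = p$d,
    per_capita_rate = p$lambda_max * res * dens - p$d
  )
}
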