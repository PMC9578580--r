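# Independent fixed-step RK4 integrator of the growth/resource ODEs, written
# against the model equations directly (no shared code with the package's
# solver path). Used as the brute-force oracle for solver checks.

oracle_rhs <- function(y, p, Kqs) {
  N <- max(y[1], 0); r <- max(y[2], 0)
  res <- if (r <= 0) 0 else ((1 + p$K_r) / 1) * (r / (r + p$K_r))
  dens <- if (is.finite(Kqs)) Kqs / (N + Kqs) else 1
  g <- p$lambda_max * res * dens
  c(y[1] * (g - p$d), -p$B * g * N)
}

oracle_rk4 <- function(p, model = "RQ", t_end, dt = 1e-3, out_times = NULL) {
  Kqs <- if (model == "R") Inf else p$K_qs
  n_steps <- ceiling(t_end / dt)
  y <- c(1, 1)
  ts <- 0
  if (is.null(out_times)) out_times <- seq(0, t_end, length.out = 201)
  out <- matrix(NA_real_, length(out_times), 3)
  out[1, ] <- c(0, y)
  oi <- 2L
  for (s in seq_len(n_steps)) {
    h <- min(dt, t_end - ts)
    k1 <- oracle_rhs(y, p, Kqs)
    k2 <- oracle_rhs(y + h / 2 * k1, p, Kqs)
    k3 <- oracle_rhs(y + h / 2 * k2, p, Kqs)
    k4 <- oracle_rhs(y + h * k3, p, Kqs)
    y_new <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t_new <- ts + h
    # linear interpolation onto requested output times
    while (oi <= length(out_times) && out_times[oi] <= t_new + 1e-12) {
      w <- if (t_new > ts) (out_times[oi] - ts) / (t_new - ts) else 1
      out[oi, ] <- c(out_times[oi], (1 - w) * y + w * y_new)
      oi <- oi + 1L
    }
    y <- y_new; ts <- t_new
    if (oi > length(out_times)) break
  }
  while (oi <= length(out_times)) {  # guard against float drift at t_end
    out[oi, ] <- c(out_times[oi], y)
    oi <- oi + 1L
  }
  data.frame(time = out[, 1], N = out[, 2], r = out[, 3])
}

# deterministic parameter draws from the broad ranges, for property loops
random_params <- function(n, seed, model = "RQ") {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kinetic_params(
      lambda_max = runif(1, 0.8, 1.5),
      d = exp(runif(1, log(0.01), log(0.3))),
      B = exp(runif(1, log(1e-4), log(1e-3))),
      K_r = runif(1, 0.01, 1),
      K_qs = if (model == "RQ") exp(runif(1, log(1e2), log(1e3))) else Inf
    )
  })
}
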