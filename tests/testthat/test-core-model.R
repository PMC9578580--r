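test_that("growth modulation matches the rate law at hand-checked points", {
  p <- kinetic_params(1.0, 0.02, 1e-3, K_r = 0.5, K_qs = 1000)
  # normalization forces the factor to 1 at r = r(0), N = 0
  expect_equal(growth_modulation(1, 0, p, "RQ"), 1.0, tolerance = 1e-12)
  # resource factor vanishes with the resource
  expect_equal(growth_modulation(0, 5, p, "RQ"), 0)
  # hand evaluation: 1 * (2/1) * (0.5/1.5) * (100/200) = 1/3
  p2 <- kinetic_params(1, 0.02, 1e-3, K_r = 1, K_qs = 100)
  expect_equal(growth_modulation(0.5, 100, p2, "RQ"), 1 / 3, tolerance = 1e-12)
  # model R ignores the density factor
  expect_equal(growth_modulation(0.5, 100, p2, "R"), 2 * 0.5 / 1.5, tolerance = 1e-12)
  expect_error(growth_modulation(-0.1, 1, p), "non-negative")
  expect_error(growth_modulation(1, -1, p), "non-negative")
})

test_that("Hill variant reduces to Monod at H = 1 and normalizes to 1 at r0", {
  for (H in c(0.5, 1, 2, 8)) {
    p <- kinetic_params(1.2, 0.05, 5e-4, K_r = 0.4, K_qs = Inf, H = H)
    expect_equal(growth_modulation(1, 0, p, "R"), 1.2, tolerance = 1e-12)
  }
  pH1 <- kinetic_params(1, 0.05, 5e-4, K_r = 0.4, K_qs = 300, H = 1)
  pM <- kinetic_params(1, 0.05, 5e-4, K_r = 0.4, K_qs = 300)
  r <- seq(0, 1, by = 0.1)
  expect_equal(growth_modulation(r, 50, pH1, "RQ"),
               growth_modulation(r, 50, pM, "RQ"), tolerance = 1e-12)
})

test_that("pure exponential growth and decay limits match closed forms", {
  pg <- kinetic_params(1, 1e-12, 1e-12, 1e-12, Inf)
  sim <- simulate_growth(pg, "RQ", times = c(0, log(2)))
  expect_equal(sim$N[2], 2, tolerance = 1e-6)
  pd <- suppressWarnings(kinetic_params(1e-12, 0.1, 1e-12, 1e-12, Inf))
  sim2 <- simulate_growth(pd, "RQ", times = c(0, 5, 10))
  expect_equal(sim2$N, exp(-0.1 * c(0, 5, 10)), tolerance = 1e-6)
})

test_that("adaptive solver agrees with a fixed-step RK4 oracle", {
  p <- kinetic_params(1, 0.02, 1e-3, 0.1, 500)
  out_t <- seq(0, 56, by = 2)
  orc <- oracle_rk4(p, "RQ", 56, dt = 1e-3, out_times = out_t)
  sim <- simulate_growth(p, "RQ", times = out_t)
  expect_lt(max(abs(sim$N - orc$N) / pmax(orc$N, 1)), 1e-4)
  expect_lt(max(abs(sim$r - orc$r)), 1e-4)
})

test_that("solver matches the oracle across random parameter sets", {
  out_t <- seq(0, 40, by = 4)
  for (p in random_params(8, seed = 11)) {
    orc <- oracle_rk4(p, "RQ", 40, dt = 5e-3, out_times = out_t)
    sim <- simulate_growth(p, "RQ", times = out_t)
    expect_lt(max(abs(sim$N - orc$N) / pmax(orc$N, 1e-6)), 1e-3)
  }
})

test_that("trajectory summaries report the peak and its time", {
  # boundary maximum on a monotone curve
  s <- trajectory_summary(c(0, 4, 8), c(1, 3, 9))
  expect_equal(s$t_max_fc, 8)
  expect_equal(s$max_fc, 9)
  # grid argmax on sparse observed data
  s2 <- trajectory_summary(c(0, 8, 16, 24), c(1, 4, 9, 4))
  expect_equal(s2$max_fc, 9)
  expect_equal(s2$t_max_fc, 16)
  expect_error(trajectory_summary(0, 1), "at least 2")
})

test_that("refined peak agrees with a fine-grid oracle", {
  p <- kinetic_params(1, 0.05, 1e-3, 0.2, 300)
  sim <- simulate_growth(p, "RQ", times = seq(0, 56, by = 0.5))
  sm <- trajectory_summary(sim)
  fine <- simulate_growth(p, "RQ", times = seq(0, 56, by = 1e-3))
  i <- which.max(fine$N)
  expect_lt(abs(sm$t_max_fc - fine$time[i]), 0.1)
  expect_lt(abs(sm$max_fc - fine$N[i]) / fine$N[i], 0.005)
})

test_that("growth-term decomposition recovers the realized per-capita rate", {
  p <- kinetic_params(1, 0.03, 1e-3, 0.3, 200)
  sim <- simulate_growth(p, "RQ", times = seq(0, 40, by = 0.25))
  dec <- decompose_growth_terms(sim)
  # initial-condition algebra
  expect_equal(dec$resource_factor[1], 1, tolerance = 1e-9)
  expect_equal(dec$density_factor[1], 200 / 201, tolerance = 1e-9)
  expect_true(all(dec$resource_factor >= 0 & dec$resource_factor <= 1))
  expect_true(all(dec$density_factor >= 0 & dec$density_factor <= 1))
  # density factor acts first (falls below 0.9 before the resource factor)
  t_dens <- dec$time[which(dec$density_factor < 0.9)[1]]
  t_res <- dec$time[which(dec$resource_factor < 0.9)[1]]
  expect_lt(t_dens, t_res)
  # disabled density term
  pI <- kinetic_params(1, 0.03, 1e-3, 0.3, Inf)
  simI <- simulate_growth(pI, "RQ", times = seq(0, 40, by = 1))
  decI <- decompose_growth_terms(simI)
  expect_true(all(decI$density_factor == 1))
})

test_that("resource conservation and the yield bound hold along simulations", {
  # fine grid: the trapezoidal quadrature of the death integral must be
  # well below the 1e-5 conservation tolerance being checked
  for (p in random_params(6, seed = 5)) {
    sim <- simulate_growth(p, "RQ", times = seq(0, 56, by = 0.05))
    # r(0) - r(t) = B * (N - N0 + d * integral of N), trapezoidal quadrature
    intN <- cumsum(c(0, (head(sim$N, -1) + tail(sim$N, -1)) / 2 * diff(sim$time)))
    lhs <- 1 - sim$r
    rhs <- p$B * (sim$N - 1 + p$d * intN)
    expect_lt(max(abs(lhs - rhs)) / max(lhs[length(lhs)], 1e-6), 1e-5)
    expect_lte(max(sim$N), 1 + 1 / p$B + 1e-6)
  }
})

test_that("density model converges to the resource-only model as K_qs grows", {
  base <- list(lambda_max = 1.1, d = 0.05, B = 5e-4, K_r = 0.3)
  times <- seq(0, 56, by = 1)
  simR <- simulate_growth(kinetic_params(1.1, 0.05, 5e-4, 0.3, Inf), "R", times)
  sup <- sapply(c(1e3, 1e5, 1e7), function(kqs) {
    simQ <- simulate_growth(kinetic_params(1.1, 0.05, 5e-4, 0.3, kqs), "RQ", times)
    max(abs(simQ$N - simR$N) / pmax(simR$N, 1))
  })
  expect_true(all(diff(sup) < 0))
  expect_lt(sup[3], 5e-4)
})

test_that("larger Hill exponents sharpen the exponential-to-stationary transition", {
  times <- seq(0, 56, by = 0.1)
  frac_time_mid <- sapply(c(1, 4, 12), function(H) {
    p <- kinetic_params(1.1, 0.05, 5e-4, 0.4, Inf, H = H)
    sim <- simulate_growth(p, "R", times)
    dec <- decompose_growth_terms(sim, p)
    mean(dec$resource_factor > 0.1 & dec$resource_factor < 0.9)
  })
  expect_true(all(diff(frac_time_mid) < 0))
})

test_that("initial per-capita rate matches the closed form", {
  p <- kinetic_params(1.2, 0.07, 5e-4, 0.3, 250)
  dec <- decompose_growth_terms(simulate_growth(p, "RQ", c(0, 1, 2)), p)
  expect_equal(dec$per_capita_rate[1], 1.2 * 250 / 251 - 0.07, tolerance = 1e-9)
  pR <- kinetic_params(1.2, 0.07, 5e-4, 0.3, Inf)
  decR <- decompose_growth_terms(simulate_growth(pR, "RQ", c(0, 1, 2)), pR)
  expect_equal(decR$per_capita_rate[1], 1.2 - 0.07, tolerance = 1e-9)
})

test_that("parameter validation and JSON round trip behave", {
  expect_error(kinetic_params(-1, 0.1, 1e-3, 0.1), "lambda_max")
  expect_error(kinetic_params(1, 0.1, 1e-3, 0.1, K_qs = -5), "K_qs")
  expect_warning(kinetic_params(0.05, 0.1, 1e-3, 0.1), "never grows")
  p <- kinetic_params(1.1, 0.05, 5e-4, 0.3, 400, H = 2)
  q <- params_from_json(params_to_json(p))
  expect_equal(unclass(q), unclass(p))
  pinf <- kinetic_params(1.1, 0.05, 5e-4, 0.3, Inf)
  qinf <- params_from_json(params_to_json(pinf))
  expect_identical(qinf$K_qs, Inf)
})
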