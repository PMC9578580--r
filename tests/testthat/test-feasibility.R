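test_that("degenerate ranges collapse the phase space to a single point", {
  rg <- list(lambda_max = c(1, 1), d = c(0.05, 0.05), B = c(5e-4, 5e-4),
             K_r = c(0.3, 0.3), K_qs = c(300, 300))
  pts <- sample_phase_space(rg, n_samples = 5, model = "RQ", seed = 1)
  expect_equal(nrow(unique(round(pts[, c("t_max_fc", "max_fc")], 8))), 1)
})

test_that("with tiny K_r the resource-only peak time matches the exponential argument", {
  rg <- list(lambda_max = c(0.9, 1.4), d = c(0.02, 0.02), B = c(1e-4, 1e-3),
             K_r = c(1e-6, 1e-6))
  pts <- sample_phase_space(rg, n_samples = 30, model = "R", seed = 3)
  pred <- log(pts$max_fc) / (pts$lambda_max - pts$d)
  expect_lt(median(abs(pts$t_max_fc - pred) / pred), 0.10)
})

test_that("the density term only delays the peak at matched fold change", {
  rg <- feasibility_ranges("fig3b")
  ptsR <- sample_phase_space(rg, 1500, "R", seed = 4)
  ptsQ <- sample_phase_space(rg, 1500, "RQ", seed = 4)
  bR <- region_boundary(ptsR, n_bins = 12)
  bQ <- region_boundary(ptsQ, n_bins = 12)
  shared <- intersect(bR$bins$bin, bQ$bins$bin)
  tR <- bR$bins$t_max[match(shared, bR$bins$bin)]
  tQ <- bQ$bins$t_max[match(shared, bQ$bins$bin)]
  # upper attainable time of the density model dominates in most shared bins
  expect_gte(mean(tQ >= tR - 0.5), 0.8)
})

test_that("region envelope handles rectangles and rejects degenerate clouds", {
  set.seed(9)
  pts <- data.frame(
    t_max_fc = c(1, 1, 5, 5, runif(50, 1, 5)),
    max_fc = c(10, 1000, 10, 1000, 10^runif(50, 1, 3)))
  rb <- region_boundary(pts, n_bins = 4)
  expect_equal(min(rb$bins$t_min), 1)
  expect_equal(max(rb$bins$t_max), 5)
  coll <- data.frame(t_max_fc = 1:10, max_fc = 10^(1:10 / 5))
  expect_error(region_boundary(coll), "degenerate")
})

test_that("membership tests distinguish interior, exterior and out-of-span points", {
  rg <- feasibility_ranges("fig3b")
  pts <- sample_phase_space(rg, 1000, "R", seed = 6)
  region <- region_boundary(pts)
  # a sampled point is inside its own region
  pr <- point_in_region(pts$t_max_fc[1], pts$max_fc[1], region)
  expect_true(pr$inside)
  expect_lte(pr$margin_h, 0)
  # beyond the upper time boundary at the same fold change
  b <- region$bins[3, ]
  fc_mid <- sqrt(b$fc_lo * b$fc_hi)
  out <- point_in_region(b$t_max + 10, fc_mid, region)
  expect_false(out$inside)
  expect_gte(out$margin_h, 10 - 1e-9)
  far <- point_in_region(30, region$fc_span[2] * 100, region)
  expect_false(far$inside)
  expect_false(far$fc_in_span)
})

test_that("envelope area is stable across sampling seeds", {
  rg <- feasibility_ranges("fig3b")
  area <- function(seed) {
    region <- region_boundary(sample_phase_space(rg, 1e4, "R", seed = seed))
    with(region$bins, sum((t_max - t_min) * (log10(fc_hi) - log10(fc_lo))))
  }
  a1 <- area(1); a2 <- area(2)
  expect_lt(abs(a1 - a2) / a1, 0.05)
})

test_that("yield ceiling bounds every sampled fold change", {
  rg <- feasibility_ranges("fig3b")
  pts <- sample_phase_space(rg, 500, "RQ", seed = 8)
  expect_lte(max(pts$max_fc), 1 + 1 / 1e-4)
})

test_that("Hill-sharpened resource limitation extends times but does not cover density delays", {
  # the attainable upper time (maximized over K_r) grows when H > 1 is allowed
  t_up <- function(H) {
    max(sapply(c(0.3, 0.8, 0.997), function(Kr) {
      p <- kinetic_params(0.9, 0.05, 3e-4, Kr, Inf, H = H)
      trajectory_summary(simulate_growth(p, "R", seq(0, 56, 0.25)))$t_max_fc
    }))
  }
  expect_gt(t_up(5), t_up(1))
  expect_gt(t_up(20), t_up(1))
  # yet strongly density-delayed observations stay uncovered at H <= 20
  rgH <- feasibility_ranges("s4fig")
  ptsH <- sample_phase_space(rgH, 4000, "R", seed = 10,
                             obs_grid = sampling_schedule("coarse9"))
  regH <- region_boundary(ptsH)
  obs <- draw_study_params(20, "RQ", d_range = c(0.01, 0.3), seed = 12)
  outside <- sapply(obs, function(p) {
    sim <- simulate_growth(p, "RQ", as.numeric(sampling_schedule("coarse9")))
    sm <- trajectory_summary(sim$time, sim$N, refine = FALSE)
    !point_in_region(sm$t_max_fc, sm$max_fc, regH)$inside
  })
  expect_gt(mean(outside), 0)
})

test_that("falsification studies keep the resource-only null inside its own region", {
  fs <- falsification_study(n_obs = 10, n_region = 2000, seed = 3)
  expect_equal(fs$frac_outside_R, 0)
  expect_gt(fs$frac_outside_RQ, 0)
  expect_true(all(fs$margins_R <= 0))
})
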