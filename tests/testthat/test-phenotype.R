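test_that("median trajectories aggregate replicates and enforce shared grids", {
  d <- data.frame(
    strain = rep("s1", 9), replicate = rep(1:3, each = 3),
    time_h = rep(c(0, 4, 8), 3),
    value = c(1, 1, 1, 1, 2, 3, 1, 3, 5))
  mt <- median_trajectories(d, normalize = FALSE)
  expect_equal(unname(mt["s1", ]), c(1, 2, 3))
  single <- d[d$replicate == 1, ]
  expect_equal(unname(median_trajectories(single, normalize = FALSE)["s1", ]),
               c(1, 1, 1))
  bad <- d; bad$time_h[9] <- 9
  expect_error(median_trajectories(bad, normalize = FALSE), "shared time grid")
})

test_that("median curves track the noiseless truth through replicate noise", {
  p <- kinetic_params(1.1, 0.06, 6e-4, 0.3, 350)
  sched <- sampling_schedule("coarse9")
  truthN <- simulate_growth(p, "RQ", as.numeric(sched))$N
  devs <- sapply(1:20, function(s) {
    cfu <- generate_cfu_dataset(p, sched, 5, noise_cv = 0.2, seed = 100 + s)
    mt <- median_trajectories(cfu)
    abs(mt[1, ] - truthN) / truthN
  })
  # per point, the fold-change deviation carries two lognormal factors
  # (eps_t / eps_0), so the median-of-5 curve deviates by about
  # 0.675 * 1.253 * sqrt(2) * 0.2 / sqrt(5) ~ 0.107 at the median; assert
  # the computed bound with sampling margin
  expect_true(all(apply(devs, 1, median) < 0.16))
  expect_lt(mean(apply(devs, 1, median)), 0.11)
})

test_that("time-series clustering separates obvious groups and respects k", {
  mat <- rbind(a1 = c(1, 10, 100), a2 = c(1, 10, 100),
               b1 = c(1, 100, 10000), b2 = c(1, 100, 10000))
  cl <- cluster_timeseries(mat, k = 2)
  expect_equal(cl$labels[["a1"]], cl$labels[["a2"]])
  expect_equal(cl$labels[["b1"]], cl$labels[["b2"]])
  expect_false(cl$labels[["a1"]] == cl$labels[["b1"]])
  expect_equal(unique(cluster_timeseries(mat, k = 1)$labels), 1L)
  expect_error(cluster_timeseries(mat, k = 9), "exceeds")
  # log10 transform makes labels invariant to uniform rescaling
  cl2 <- cluster_timeseries(mat * 1e3, k = 2)
  expect_equal(unname(cl2$labels), unname(cl$labels))
})

test_that("archetype panels are recovered by clustering (seeded example)", {
  panel <- generate_archetype_panel(noise_cv = 0.15, seed = 5)
  mt <- median_trajectories(panel$data)
  cl <- cluster_timeseries(mt, k = 3)
  truth <- panel$truth$class[match(rownames(mt), panel$truth$strain)]
  expect_gte(mclust::adjustedRandIndex(cl$labels, truth), 0.9)
})

test_that("clustering agreement scores match hand-computed confusion matrices", {
  a <- clustering_agreement(c(1, 2, 1, 2), c(1, 2, 1, 2))
  b <- clustering_agreement(c(1, 2, 1, 2), c(2, 1, 2, 1))
  expect_equal(a$macro_accuracy, b$macro_accuracy)
  expect_equal(a$macro_f1, b$macro_f1)
  perfect <- clustering_agreement(c("x", "x", "y"), c("y", "y", "x"))
  expect_equal(perfect$macro_accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  hand <- clustering_agreement(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(hand$macro_f1, (2 / 3 + 4 / 5) / 2, tolerance = 1e-12)
  expect_equal(hand$macro_accuracy, 0.75)
  # random labels: macro accuracy concentrates near 1/k
  set.seed(42)
  acc <- replicate(30, {
    truth <- rep(1:3, each = 60)
    clustering_agreement(truth, sample(1:3, 180, replace = TRUE))$macro_accuracy
  })
  expect_lt(abs(mean(acc) - 1 / 3), 0.05)
})

test_that("phenotype tables bracket medians with 34/66 percentiles", {
  samples <- data.frame(strain = rep(c("a", "b"), each = 5),
                        max_fc = c(1:5 * 100, 1:5 * 1000),
                        d = runif(10, 0.05, 0.1))
  tab <- phenotype_table(samples)
  expect_true(all(tab$p34$max_fc <= tab$median$max_fc))
  expect_true(all(tab$p66$max_fc >= tab$median$max_fc))
  expect_equal(tab$median["a", "max_fc"], 300)
})

test_that("parameter PCA matches eigen-decomposition and flags constants", {
  m <- matrix(c(1, 2, 3, 2, 4, 6, 3, 6, 9, 4, 8, 12), 4, 3, byrow = TRUE)
  expect_equal(parameter_pca(m, "none")$variance_pct[1], 100, tolerance = 1e-9)
  set.seed(2)
  x <- matrix(rnorm(55), 11, 5)
  vp <- parameter_pca(x, "none")$variance_pct
  ev <- eigen(cov(x))$values
  expect_equal(vp, 100 * ev / sum(ev), tolerance = 1e-10)
  expect_equal(sum(vp), 100, tolerance = 1e-9)
  expect_true(all(diff(vp) <= 1e-12))
  # permutation invariance over row order
  vp2 <- parameter_pca(x[sample(11), ], "none")$variance_pct
  expect_equal(vp, vp2, tolerance = 1e-9)
  xc <- cbind(x[, 1:2], const = 1)
  colnames(xc) <- c("a", "b", "cst")
  expect_error(parameter_pca(xc, "z"), "cst")
})

test_that("plane deviation measures distance from the first two axes", {
  set.seed(8)
  sc <- matrix(rnorm(30), 10, 3)
  pc <- parameter_pca(sc, "none")
  manual <- abs(pc$scores[, 3])
  expect_equal(unname(pc$plane_deviation), unname(manual), tolerance = 1e-9)
})

test_that("correlation utility reproduces hand-computed values", {
  x <- c(1, 2, 3)
  expect_equal(correlate(x, 2 * x + 1)$rho, 1, tolerance = 1e-12)
  expect_equal(correlate(x, c(1, 3, 2))$rho, 0.5, tolerance = 1e-12)
  expect_equal(correlate(x, -x)$rho, -1, tolerance = 1e-12)
  expect_error(correlate(x, c(2, 2, 2)), "zero variance")
})

test_that("phenotypic distances z-score per parameter and flag separators", {
  tab <- data.frame(
    d = c(0.05, 0.05, 0.15, 0.25),
    K_qs = rep(300, 4), inv_B = rep(2000, 4),
    K_r = rep(0.3, 4), lambda_max = rep(1.1, 4),
    row.names = c("s1", "s2", "s3", "s4"))
  self <- phenotypic_distance(tab, "s1", "s2")
  expect_equal(unname(self$per_parameter), rep(0, 5))
  expect_equal(self$scalar, 0)
  sd_d <- sd(tab$d)
  pd <- phenotypic_distance(tab, "s1", "s4")
  expect_equal(unname(pd$per_parameter["d"]), 0.2 / sd_d, tolerance = 1e-12)
  expect_equal(unname(pd$per_parameter[-1]), rep(0, 4))
  expect_identical(pd$separating, "d")
  expect_error(phenotypic_distance(tab[, -2], "s1", "s4"), "missing")
})

test_that("archetype classes are separated by at least two parameters", {
  panel <- generate_archetype_panel(noise_cv = 0.1, seed = 1)
  tr <- panel$truth
  tab <- data.frame(d = tr$d, K_qs = tr$K_qs, inv_B = 1 / tr$B,
                    K_r = tr$K_r, lambda_max = tr$lambda_max,
                    row.names = tr$strain)
  cm <- do.call(rbind, lapply(split(tab, tr$class), function(d) apply(d, 2, median)))
  full <- rbind(tab, as.data.frame(cm))
  for (pair in list(c("blue", "red"), c("blue", "green"), c("red", "green"))) {
    pd <- phenotypic_distance(full, pair[1], pair[2])
    expect_gte(length(pd$separating), 2)
  }
})

test_that("dispersion statistics match hand oracles", {
  expect_equal(dispersion_stats(rep(4, 5), rep(c("a", "b"), c(3, 2)))$cv_pooled, 0)
  ds <- dispersion_stats(c(1, 2, 3), c("a", "a", "a"))
  expect_equal(ds$cv_pooled, sqrt(2 / 3) / 2, tolerance = 1e-12)  # population sd / mean
  two <- dispersion_stats(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(two$ks_p["a", "b"], 1)
  expect_error(dispersion_stats(c(-1, 1), c("a", "b")), "mean")
})

test_that("the phenotype report runs both preprocessing modes coherently", {
  panel <- generate_archetype_panel(noise_cv = 0.1, seed = 2)
  tr <- panel$truth
  set.seed(1)
  samples <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    n <- 4
    data.frame(strain = tr$strain[i],
               max_fc = (1 / tr$B[i]) * 0.6 * exp(rnorm(n, 0, 0.1)),
               lambda_max = tr$lambda_max[i] * exp(rnorm(n, 0, 0.03)),
               d = tr$d[i] * exp(rnorm(n, 0, 0.1)),
               K_qs = tr$K_qs[i] * exp(rnorm(n, 0, 0.15)),
               inv_B = (1 / tr$B[i]) * exp(rnorm(n, 0, 0.1)),
               K_r = tr$K_r[i] * exp(rnorm(n, 0, 0.1)))
  }))
  rep <- phenotype_report(samples)
  for (m in c("log_z", "z")) {
    expect_equal(sum(rep$pca3[[m]]$variance_pct), 100, tolerance = 1e-9)
    expect_equal(sum(rep$pca5[[m]]$variance_pct), 100, tolerance = 1e-9)
  }
  expect_true(is.finite(rep$correlations$strain$kqs_invB$p_value))
  expect_true(abs(rep$correlations$sample$maxfc_invB$rho) <= 1)
  expect_true(all(sapply(rep$dispersion, function(d) d$cv_pooled) > 0))
})
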