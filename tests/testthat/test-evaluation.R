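test_that("Bland-Altman matches closed forms on a 5-point toy input", {
  gold <- cbind(c(1, 2, 3, 4, 5), c(0, 0, 0, 0, 0), c(10, 20, 30, 40, 50))
  prop <- gold + cbind(c(0.1, -0.2, 0.3, 0, 0.2),
                       c(1, 1, 1, 1, 1),
                       c(0.5, -0.5, 0.1, -0.1, 0))
  ba <- bland_altman(prop, gold)
  for (k in 1:3) {
    d <- prop[, k] - gold[, k]
    m <- (prop[, k] + gold[, k]) / 2
    expect_equal(ba$mean_diff[k], mean(d), tolerance = 1e-12)
    expect_equal(ba$sd_diff[k], sd(d), tolerance = 1e-12)
    expect_equal(ba$loa_low[k], mean(d) - 1.96 * sd(d), tolerance = 1e-12)
    expect_equal(ba$loa_high[k], mean(d) + 1.96 * sd(d), tolerance = 1e-12)
    if (!ba$degenerate[k]) {
      tt <- t.test(d)
      expect_equal(ba$t_stat[k], unname(tt$statistic), tolerance = 1e-12)
      expect_equal(ba$p_fixed[k], tt$p.value, tolerance = 1e-12)
      fit <- summary(lm(d ~ m))$coefficients
      expect_equal(ba$slope[k], fit[2, 1], tolerance = 1e-12)
      expect_equal(ba$p_slope[k], fit[2, 4], tolerance = 1e-12)
    }
  }
})

test_that("identical and constant-offset inputs behave as expected", {
  gold <- matrix(rnorm(30), 10, 3)
  ba0 <- bland_altman(gold, gold)
  expect_equal(ba0$mean_diff, rep(0, 3))
  expect_true(all(ba0$degenerate))
  bac <- bland_altman(gold + matrix(c(2, 2, 2), 10, 3, byrow = TRUE), gold)
  expect_equal(bac$mean_diff, rep(2, 3))
  expect_equal(bac$sd_diff, rep(0, 3), tolerance = 1e-12)
  expect_true(all(bac$degenerate))
  expect_equal(bac$slope, rep(0, 3))
  expect_error(bland_altman(gold[1:2, ], gold[1:2, ]), "at least 3")
  expect_error(bland_altman(gold[1:5, ], gold), "paired")
})

test_that("injected fixed and proportional biases are recovered within CIs", {
  rng <- rgbmocap:::local_rng(21)
  n <- 6000
  gold <- cbind(rng$runif(n, -1000, 1000), rng$runif(n, -1000, 1000),
                rng$runif(n, -1000, 1000))
  b <- -0.4; s <- -4e-4
  prop <- gold + b + s * gold + matrix(rng$rnorm(3 * n, 0, 1.5), n, 3)
  ba <- bland_altman(prop, gold)
  for (k in 1:3) {
    expect_gte(b, ba$ci_low[k]); expect_lte(b, ba$ci_high[k])
    expect_gte(s, ba$slope_ci_low[k]); expect_lte(s, ba$slope_ci_high[k])
    expect_lt(ba$p_fixed[k], 0.01)
    expect_lt(ba$p_slope[k], 0.01)
  }
})

test_that("resultant error statistics match brute force", {
  expect_equal(resultant_error_stats(matrix(0, 5, 3))$mean, 0)
  st <- resultant_error_stats(cbind(3, 4, 0))
  expect_equal(st$mean, 5)
  rng <- rgbmocap:::local_rng(22)
  ev <- matrix(rng$rnorm(3000), 1000, 3)
  st2 <- resultant_error_stats(ev)
  r <- sort(sqrt(rowSums(ev^2)))
  # brute-force linear interpolation percentile
  brute <- function(p) {
    h <- (length(r) - 1) * p + 1
    lo <- floor(h)
    r[lo] + (h - lo) * (r[min(lo + 1, length(r))] - r[lo])
  }
  expect_equal(st2$p95, brute(0.95), tolerance = 1e-12)
  expect_equal(st2$p99, brute(0.99), tolerance = 1e-12)
  expect_lte(st2$p95, st2$p99)
  expect_error(resultant_error_stats(numeric(0)), "no error")
})

robust_points <- function(sc, frames = 1:2) {
  det <- project_scene(sc, frames = frames)
  unlist(reconstruct_sequence(det, sc$cameras)$points, recursive = FALSE)
}

test_that("zero noise-sphere diameter gives zero distances", {
  sc <- small_scene()
  pts <- robust_points(sc, frames = 1)
  rb <- robustness_mc(pts, sc$cameras,
                      robustness_config(noise_sphere_diameter_mm = 0,
                                        iterations = 200, seed = 1))
  expect_lt(max(rb$max_mm), 1e-9)
})

test_that("robustness distances are nonnegative, max >= mean, reproducible", {
  sc <- small_scene()
  pts <- robust_points(sc, frames = 1)
  cfg <- robustness_config(iterations = 1500, seed = 8)
  rb1 <- robustness_mc(pts, sc$cameras, cfg)
  rb2 <- robustness_mc(pts, sc$cameras, cfg)
  expect_identical(rb1, rb2)
  expect_true(all(rb1$mean_mm >= 0))
  expect_true(all(rb1$max_mm >= rb1$mean_mm))
})

test_that("mean perturbation distance scales linearly with the noise diameter", {
  sc <- small_scene()
  pts <- robust_points(sc, frames = 1)
  r1 <- robustness_mc(pts, sc$cameras,
                      robustness_config(noise_sphere_diameter_mm = 6,
                                        iterations = 8000, seed = 5))
  r2 <- robustness_mc(pts, sc$cameras,
                      robustness_config(noise_sphere_diameter_mm = 12,
                                        iterations = 8000, seed = 5))
  expect_lt(abs(r2$mean_mm / r1$mean_mm - 2), 2 * 0.05)
})

test_that("points without stored coordinates are rejected", {
  sc <- small_scene()
  pts <- robust_points(sc, frames = 1)
  pts[[1]]$detections <- NULL
  expect_error(robustness_mc(pts, sc$cameras), "digitized")
})
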