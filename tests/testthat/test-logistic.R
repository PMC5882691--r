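test_that("logistic density honours its closed form", {
  p <- logistic_params(0.05, 0.46, 0.42)
  expect_equal(logistic_density(0, p), 0.05)
  expect_equal(logistic_density(100, p), 0.46, tolerance = 1e-6)
  # fixed point: rho0 = rho_max stays constant
  pc <- logistic_params(0.3, 0.3, 1.7)
  expect_equal(logistic_density(c(0, 1, 8, 40), pc), rep(0.3, 4))
  # algebraic inversion: with (0.1, 0.4, 0.5), rho = 0.2 at t = ln(3)/0.5
  p2 <- logistic_params(0.1, 0.4, 0.5)
  expect_equal(logistic_density(log(3) / 0.5, p2), 0.2)
})

test_that("logistic curve satisfies the logistic ODE", {
  p <- logistic_params(0.07, 0.52, 0.61)
  t <- seq(0.1, 14, length.out = 200)
  h <- 1e-4
  drho <- (logistic_density(t + h, p) - logistic_density(t - h, p)) / (2 * h)
  rho <- logistic_density(t, p)
  expect_lt(max(abs(drho - p$omega * rho * (1 - rho / p$rho_max))), 1e-6)
})

test_that("series generation validates inputs and is seed-deterministic", {
  p <- logistic_params(0.05, 0.46, 0.42)
  t <- seq(0, 15, length.out = 52)
  expect_error(generate_logistic_series(p, c(0, 1, 1, 2)),
               class = "vasculonet_invalid_input")
  expect_error(generate_logistic_series(logistic_params(0.5, 0.4, 1), t),
               class = "vasculonet_invalid_input")
  a <- generate_logistic_series(p, t, noise_sd = 0.02, seed = 9)
  b <- generate_logistic_series(p, t, noise_sd = 0.02, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$values >= 0 & a$values <= 1))
  clean <- generate_logistic_series(p, t, noise_sd = 0)
  expect_equal(clean$values, logistic_density(t, p))
})

test_that("noiseless fits recover parameters near machine precision", {
  truth <- logistic_params(0.05, 0.46, 0.42)
  s <- generate_logistic_series(truth, seq(0, 15, length.out = 52))
  f <- fit_logistic(s)
  expect_equal(f$rho0, truth$rho0, tolerance = 1e-4)
  expect_equal(f$rho_max, truth$rho_max, tolerance = 1e-4)
  expect_equal(f$omega, truth$omega, tolerance = 1e-4)
  expect_lt(f$rss, 1e-10)
})

test_that("fit failures are flagged, not silent", {
  flat <- density_series(1:10, rep(0.3, 10))
  expect_error(fit_logistic(flat), class = "vasculonet_fit_failure")
  expect_error(fit_logistic(density_series(1:3, c(0.1, 0.2, 0.3))),
               class = "vasculonet_invalid_input")
})

test_that("noisy replicates recover parameters within 10% median error", {
  grid <- expand.grid(rho_max = c(0.3, 0.6), omega = c(0.3, 0.7))
  t <- seq(0, 15, length.out = 52)
  for (i in seq_len(nrow(grid))) {
    truth <- logistic_params(0.05, grid$rho_max[i], grid$omega[i])
    err_rm <- err_om <- numeric(40)
    for (r in 1:40) {
      s <- generate_logistic_series(truth, t, noise_sd = 0.02,
                                    seed = 5000 + 100 * i + r)
      f <- fit_logistic(s)
      err_rm[r] <- abs(f$rho_max - truth$rho_max) / truth$rho_max
      err_om[r] <- abs(f$omega - truth$omega) / truth$omega
    }
    expect_lt(median(err_rm), 0.10)
    expect_lt(median(err_om), 0.10)
  }
})

test_that("time-shift changes rho0 but not rho_max or omega", {
  truth <- logistic_params(0.05, 0.46, 0.42)
  t <- seq(0, 15, length.out = 52)
  s <- generate_logistic_series(truth, t, noise_sd = 0.01, seed = 42)
  f0 <- fit_logistic(s)
  shifted <- density_series(t + 3, s$values)
  f1 <- fit_logistic(shifted)
  expect_equal(f1$rho_max, f0$rho_max, tolerance = 1e-3)
  expect_equal(f1$omega, f0$omega, tolerance = 1e-2)
  # shifting back restores rho0
  back <- density_series(t, s$values)
  expect_equal(fit_logistic(back)$rho0, f0$rho0, tolerance = 1e-6)
})

test_that("transition detection brackets a step and orders its thresholds", {
  t <- seq(0, 10, 0.5)
  v <- ifelse(t < 5, 0, 1)
  tr <- detect_transitions(density_series(t, v))
  expect_lt(abs(tr$onset_h - 5), 0.5)
  expect_lt(abs(tr$saturation_h - 5), 0.5)
  expect_lte(tr$onset_h, tr$saturation_h)
  # monotone series: onset <= saturation always
  p <- logistic_params(0.02, 0.5, 0.8)
  s <- generate_logistic_series(p, seq(0, 15, 0.25))
  tr2 <- detect_transitions(s)
  expect_lte(tr2$onset_h, tr2$saturation_h)
})

test_that("transition times match analytic threshold crossings", {
  p <- logistic_params(0.01, 0.3, 1.0)
  t <- seq(0, 15, 0.1)
  s <- generate_logistic_series(p, t)
  tr <- detect_transitions(s)
  # invert the logistic closed form for rho* = theta * plateau
  invert <- function(rho) {
    -log((1 / rho - 1 / p$rho_max) / (1 / p$rho0 - 1 / p$rho_max)) / p$omega
  }
  expect_lt(abs(tr$onset_h - invert(0.1 * tr$plateau_value)), 0.1)
  expect_lt(abs(tr$saturation_h - invert(0.95 * tr$plateau_value)), 0.1)
})

test_that("a series never reaching saturation is flagged", {
  # rising linear ramp: final 10% mean is below the 95% threshold ever crossed
  t <- seq(0, 10, 0.5)
  v <- seq(0, 0.4, length.out = length(t))
  tr <- detect_transitions(density_series(t, v), theta_sat = 1.5)
  expect_false(tr$saturation_defined)
  expect_true(is.na(tr$saturation_h))
})
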