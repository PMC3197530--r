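test_that("disk-model conversions are exact and mutually inverse", {
  expect_identical(cells_from_diameter(0), 0)
  expect_identical(cells_from_diameter(0.02, 20), 1)   # one cell
  expect_identical(cells_from_diameter(6, 20), 90000)  # (6000/20)^2
  expect_identical(area_from_cells(0), 0)
  expect_equal(area_from_cells(90000, 20), 36)
  expect_error(cells_from_diameter(5, 0), "positive")
  expect_error(area_from_cells(-1), "non-negative")
  # round trip within 1e-3 relative error for d >= 1 mm
  d <- seq(1, 25, by = 0.7)
  d2 <- sqrt(area_from_cells(cells_from_diameter(d)))
  expect_true(all(abs(d2 - d) / d < 1e-3))
})

test_that("engrafted tumor load follows the stated loss fraction", {
  expect_identical(seed_initial_tumor(0.5e6, 0.6), 2e5)
  expect_identical(seed_initial_tumor(1e4, 1), 0)
  expect_identical(seed_initial_tumor(1e4, 0), 1e4)
  expect_error(seed_initial_tumor(1e4, 1.2), "0, 1")
})

test_that("forward-Euler newborns match the growth law and clamp at capacity", {
  gp <- gompertz_params(a = 0.14, b = 0.009)
  # carrying capacity is a fixed point
  K <- exp(0.14 / 0.009)
  expect_identical(euler_newborns(K, gp)$w, 0L)
  expect_identical(euler_newborns(K * 1.5, gp)$w, 0L)  # clamped above K
  expect_identical(euler_newborns(0, gp)$w, 0L)        # extinct stays extinct
  # pure exponential limit at b = 0
  gp0 <- gompertz_params(a = 0.02, b = 0)
  en <- euler_newborns(1e5, gp0)
  expect_identical(en$w, 2000L)
  # fractional growth is carried, never lost
  en2 <- euler_newborns(101, gp0)       # 2.02 expected newborns
  expect_identical(en2$w, 2L)
  expect_equal(en2$residual, 0.02, tolerance = 1e-9)
  en3 <- euler_newborns(101, gp0, residual = en2$residual)
  expect_equal(en3$w + en3$residual, 2.04, tolerance = 1e-9)
})

test_that("Euler iteration converges linearly to the closed-form solution", {
  gp <- gompertz_default_params()
  x0 <- 2e5
  horizon <- 30
  euler_path <- function(dt) {
    x <- x0
    for (i in seq_len(horizon / dt)) x <- x + dt * x * (gp$a - gp$b * log(x))
    x
  }
  exact <- gompertz_cells(horizon, gp, x0)
  err <- vapply(c(1, 0.5, 0.1, 0.01), function(dt)
    abs(euler_path(dt) - exact) / exact, 0)
  expect_true(all(diff(err) < 0))            # error shrinks with dt
  expect_equal(err[1] / err[3], 10, tolerance = 3)   # ~linear order
  expect_lt(err[4], 1e-4)
})

test_that("Euler iteration from x0 is sigmoid and bounded near K", {
  gp <- gompertz_default_params()
  x <- 2e5; res <- 0; path <- numeric(600)
  for (i in 1:600) {
    en <- euler_newborns(x, gp, residual = res)
    x <- x + en$w; res <- en$residual
    path[i] <- x
  }
  expect_true(all(diff(path) >= 0))
  expect_lt(max(path), gp$K * (1 + gp$a))   # bounded by one-step overshoot
  expect_gt(path[600], 0.95 * gp$K)
})

test_that("parameter recovery: noise-free series within 1%", {
  gp <- gompertz_default_params()
  series <- generate_growth_fixture(gp, x0 = 2e5, times_days = seq(2, 32, 2),
                                    noise_cv = 0)
  fit <- fit_gompertz(series, x0 = 2e5)
  expect_equal(fit$a, gp$a, tolerance = 0.01)
  expect_equal(fit$b, gp$b, tolerance = 0.01)
  expect_lt(fit$residual_norm, 1e-3)
  expect_s3_class(fit, "gompertz_fit")
  expect_named(coef(fit), c("a", "b", "K"))
  # predictions reproduce the generating curve
  expect_equal(predict(fit, days = 10), gompertz_cells(30, gp, 2e5),
               tolerance = 0.02)
})

test_that("parameter recovery: 5% noise gives <10% median error over 100 seeds", {
  # the study design: one cage of six mice sharing the growth law,
  # measured every 3 days, each diameter the mean of 2 caliper reads
  gp <- gompertz_default_params()
  err <- t(vapply(1:100, function(s) {
    set.seed(s)
    series <- generate_growth_fixture(gp, x0 = 2e5,
                                      times_days = seq(3, 30, 3),
                                      noise_cv = 0.05, n_mice = 6)
    fit <- fit_gompertz(series, x0 = 2e5)
    c(abs(fit$a - gp$a) / gp$a, abs(fit$b - gp$b) / gp$b)
  }, numeric(2)))
  expect_lt(median(err[, 1]), 0.10)
  expect_lt(median(err[, 2]), 0.10)
})

test_that("degenerate series are rejected with a diagnostic", {
  expect_error(fit_gompertz(data.frame(day = 1, diameter_mm = 2)),
               "degenerate|at least 3")
  flat <- data.frame(day = c(1, 2, 3), diameter_mm = c(2, 2, 2))
  expect_error(fit_gompertz(flat), "degenerate")
  single <- generate_growth_fixture(gompertz_default_params(),
                                    times_days = 0, noise_cv = 0)
  expect_error(fit_gompertz(single), "degenerate|at least 3")
  bad <- data.frame(day = c(3, 2, 1), diameter_mm = c(1, 2, 3))
  expect_error(fit_gompertz(bad), "increasing")
})

test_that("growth fixtures are non-negative and fit-compatible", {
  set.seed(9)
  gp <- gompertz_default_params()
  f <- generate_growth_fixture(gp, times_days = seq(3, 30, 3), noise_cv = 0.3)
  expect_true(all(f$diameter_mm >= 0))
  expect_named(f, c("day", "diameter_mm"))
  expect_error(generate_growth_fixture(gp, noise_cv = -1), "non-negative")
})
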