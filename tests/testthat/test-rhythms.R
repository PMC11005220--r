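test_that("linear detrending matches a normal-equations oracle", {
  t <- (0:239) * 18
  # exact line -> all-zero residuals
  expect_equal(detrend_linear(2 * t + 5, 18), rep(0, 240), tolerance = 1e-9)
  # constant -> zero series (degenerate slope)
  expect_equal(detrend_linear(rep(7, 240), 18), rep(0, 240))

  # line + cosine: residuals equal the OLS oracle exactly and track the
  # cosine component
  y <- 0.002 * t + 1 + cos(2 * pi * t / 1440)
  X <- cbind(1, t)
  oracle <- y - X %*% solve(crossprod(X), crossprod(X, y))
  expect_equal(detrend_linear(y, 18), as.numeric(oracle), tolerance = 1e-10)
  expect_gt(stats::cor(detrend_linear(y, 18), cos(2 * pi * t / 1440)), 0.999)
})

test_that("periodogram recovers pure and mixed cosines on the grid", {
  y <- cosine_series(M = 0, A = 1, phi = 0, tau = 1423)
  res <- suppressWarnings(periodogram_top_periods(y))
  expect_equal(res$top_periods[1], 1423)
  # power 1 at the generating period, below 1 elsewhere
  pg <- res$periodogram
  at <- which(pg$period_grid_min == 1423)
  expect_gt(pg$power[at], 1 - 1e-9)
  expect_true(all(pg$power[-at] < pg$power[at]))

  # two components, amplitudes 3 and 1: both peaks found, in amplitude
  # order, each near its generating period (finite-window leakage between
  # the components shifts the maxima by a few minutes); the whole curve
  # and its ranked maxima are cross-checked against an independent lm()
  # grid oracle
  t <- (0:239) * 18
  y2 <- 3 * cos(2 * pi * t / 1423) + 1 * cos(2 * pi * (t - 100) / 720)
  res2 <- suppressWarnings(
    periodogram_top_periods(y2, grid = c(600, 1680, 1), k = 2))
  expect_length(res2$top_periods, 2)
  expect_lt(abs(res2$top_periods[1] - 1423), 10)
  expect_lt(abs(res2$top_periods[2] - 720), 25)

  taus <- seq(600, 1680)
  oracle_power <- vapply(taus, function(tau)
    summary(stats::lm(y2 ~ cos(2 * pi * t / tau) +
                        sin(2 * pi * t / tau)))$r.squared, 0)
  pg2 <- res2$periodogram
  expect_equal(pg2$power, oracle_power, tolerance = 1e-10)
  inner <- 2:(length(taus) - 1)
  omax <- inner[oracle_power[inner] > oracle_power[inner - 1] &
                  oracle_power[inner] > oracle_power[inner + 1]]
  omax <- omax[order(-oracle_power[omax])]
  expect_equal(res2$top_periods, taus[omax[1:2]])
})

test_that("white noise shows no dominant circadian cycle", {
  maxp <- vapply(1:50, function(s) {
    y <- with_seed(s, stats::rnorm(240))
    max(suppressWarnings(periodogram_top_periods(y))$periodogram$power)
  }, 0)
  expect_true(all(maxp < 0.2))
})

test_that("periodogram agrees with the discrete-Fourier oracle on its subgrid", {
  # 1440 min = 3 full cycles of the 72-h window: an exact Fourier frequency
  y <- with_seed(4, stats::rnorm(240, mean = 5))
  pg <- suppressWarnings(periodogram_top_periods(y))$periodogram
  at <- which(pg$period_grid_min == 1440)
  f <- stats::fft(y)
  k <- 3 + 1  # 3 cycles across n = 240 samples (R's index 1 is DC)
  explained <- 2 * Mod(f[k])^2 / 240
  r2_fourier <- explained / sum((y - mean(y))^2)
  expect_equal(pg$power[at], r2_fourier, tolerance = 1e-8)
})

test_that("periodogram enforces coverage and reports scarce maxima", {
  expect_error(periodogram_top_periods(rnorm(100), 18), "coverage error")
  y <- cosine_series(M = 0, A = 1, phi = 0, tau = 1423)
  expect_warning(res <- periodogram_top_periods(y, k = 5), "local maxima")
  expect_true(isTRUE(attr(res$top_periods, "incomplete")))
})

test_that("cosinor fit is exact on clean input and safe on degenerate input", {
  y <- cosine_series(M = 10, A = 3, phi = 300, tau = 1423)
  rp <- cosinor_fit(y, 18, 1423)
  expect_equal(rp$mesor, 10, tolerance = 1e-9)
  expect_equal(rp$amplitude, 3, tolerance = 1e-9)
  expect_equal(rp$adjphase_min, 300, tolerance = 1e-6)

  cst <- cosinor_fit(rep(4.2, 240), 18, 1423)
  expect_equal(cst$amplitude, 0)
  expect_equal(cst$mesor, 4.2)
  expect_equal(cst$rsq, 0)
  expect_equal(cst$adjphase_min, 0)
})

test_that("noisy cosinor estimates are unbiased at the simulation noise level", {
  M <- 10; A <- 3; phi <- 300; tau <- 1423
  clean <- cosine_series(M = M, A = A, phi = phi, tau = tau)
  fits <- lapply(1:200, function(s) {
    y <- clean + with_seed(s, stats::rnorm(240, 0, 0.05 * M))
    cosinor_fit(y, 18, tau)
  })
  amp <- vapply(fits, `[[`, 0, "amplitude")
  expect_lt(abs(mean(amp) / A - 1), 0.02)
  ph <- vapply(fits, `[[`, 0, "adjphase_min")
  ang <- 2 * pi * ph / tau
  circ_mean <- (atan2(mean(sin(ang)), mean(cos(ang))) * tau / (2 * pi)) %% tau
  expect_lt(min(abs(circ_mean - phi), tau - abs(circ_mean - phi)), 10)
})

test_that("rhythm estimates are scale- and time-shift-equivariant", {
  y <- cosine_series(M = 10, A = 3, phi = 300, tau = 1423) +
    with_seed(8, stats::rnorm(240, 0, 0.2))
  a <- cosinor_fit(y, 18, 1423)
  b <- cosinor_fit(2.5 * y, 18, 1423)
  expect_equal(b$amplitude, 2.5 * a$amplitude, tolerance = 1e-9)
  expect_equal(b$mesor, 2.5 * a$mesor, tolerance = 1e-9)
  expect_equal(b$adjphase_min, a$adjphase_min, tolerance = 1e-9)
  ta <- suppressWarnings(periodogram_top_periods(y))$top_periods
  tb <- suppressWarnings(periodogram_top_periods(2.5 * y))$top_periods
  expect_identical(as.numeric(ta), as.numeric(tb))

  # dropping the first k samples advances the series: adjphase shifts by
  # -k*dt modulo tau (clean signal, so the two fits see the same rhythm)
  clean <- cosine_series(M = 10, A = 3, phi = 300, tau = 1423)
  k <- 10
  full <- cosinor_fit(clean, 18, 1423)
  shifted <- cosinor_fit(clean[-(1:k)], 18, 1423)
  expect_equal((full$adjphase_min - shifted$adjphase_min) %% 1423, k * 18,
               tolerance = 1e-6)
})
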