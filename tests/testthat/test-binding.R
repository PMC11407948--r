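test_that("inner-filter correction matches its closed form", {
  expect_equal(correct_inner_filter(100, 0, 0), 100)
  expect_equal(correct_inner_filter(0, 0.3, 0.7), 0)
  expect_equal(correct_inner_filter(100, 0.1, 0.1), 100 * exp(0.1),
               tolerance = 1e-12)
  expect_error(correct_inner_filter(100, -0.1, 0), "absorbances")
  # monotone increasing in A1 + A2
  a <- seq(0, 1, by = 0.1)
  expect_true(all(diff(correct_inner_filter(rep(50, 11), a, rev(a) * 0 + 0.2)) > 0))
})

test_that("applying attenuation then correcting recovers the true signal", {
  set.seed(11)
  for (k in 1:50) {
    f_true <- runif(1, 1, 1e4)
    a1 <- runif(1, 0, 1); a2 <- runif(1, 0, 1)
    f_obs <- f_true * exp(-(a1 + a2) / 2)
    expect_equal(correct_inner_filter(f_obs, a1, a2), f_true,
                 tolerance = 1e-12)
  }
})

test_that("delta_percent computes signed percent changes", {
  expect_equal(delta_percent(100, 100), 0)
  expect_equal(delta_percent(100, 112.82), 12.82, tolerance = 1e-12)
  expect_equal(delta_percent(100, 78.08), -21.92, tolerance = 1e-12)
  expect_error(delta_percent(0, 5), "baseline")
  expect_error(delta_percent(-1, 5), "baseline")
  set.seed(3)
  for (k in 1:50) {
    b <- runif(1, 1e-3, 1e5); p <- runif(1, -99, 200)
    expect_equal(delta_percent(b, b * (1 + p / 100)), p, tolerance = 1e-10)
  }
})

test_that("quench_points extracts monotone quenching from a synthetic series", {
  series <- toy_titration()
  pts <- quench_points(series)
  expect_equal(nrow(pts), 5L)
  expect_true(all(diff(pts$F) < 0))
  expect_true(all(pts$F < pts$F0))
  expect_equal(pts$Q, series$ligand_concs[-1])

  # IFE with all-zero absorbances changes nothing
  cfg0 <- titration_config(ka = 4.15e4, n = 0.91,
                           ife = list(a1 = rep(0, 6), a2 = rep(0, 6)))
  s0 <- simulate_titration(cfg0)
  expect_equal(quench_points(s0, apply_ife = TRUE),
               quench_points(s0, apply_ife = FALSE))

  # single-spectrum series -> no usable points
  one <- titration_series(1e-5, 0, list(gauss_spectrum()))
  expect_equal(nrow(quench_points(one)), 0L)

  expect_error(quench_points(series, apply_ife = TRUE), "ife_absorbances")
  uv <- simulate_uv(titration_config(ka = 1e4, n = 1), 10)
  expect_error(quench_points(uv), "emission")
})

test_that("quench_points warns but retains non-quenching points", {
  sp_hi <- gauss_spectrum(peak = 1100)
  series <- titration_series(1e-5, c(0, 1e-6),
                             list(gauss_spectrum(peak = 1000), sp_hi))
  expect_warning(pts <- quench_points(series), "F >= F0")
  expect_equal(nrow(pts), 1L)
})

test_that("double-log fit recovers identity parameters from two exact points", {
  pts <- data.frame(Q = c(0.1, 1), F0 = 1, F = c(1 / 1.1, 0.5))
  fit <- fit_double_log(pts)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$Ka, 1, tolerance = 1e-12)
  expect_equal(fit$n, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("double-log fit is exact on noiseless generative data", {
  # the generative model F = F0/(1 + Ka Q^n) is exactly log-linear
  set.seed(21)
  for (k in 1:20) {
    ka <- 10^runif(1, 2, 6)
    n <- runif(1, 0.5, 2)
    q <- sort(10^runif(sample(3:8, 1), -6, -3))
    f <- 1000 / (1 + ka * q^n)
    fit <- fit_double_log(data.frame(Q = q, F0 = 1000, F = f))
    # Ka = 10^intercept amplifies the regression's rounding error ~ln(10)*|x|
    expect_equal(fit$Ka, ka, tolerance = 1e-6)
    expect_equal(fit$n, n, tolerance = 1e-8)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("double-log fit drops untransformable points and errors when starved", {
  pts <- data.frame(Q = c(0, 0.1, 1, 2), F0 = 1, F = c(1, 1 / 1.1, 0.5, 1.2))
  expect_message(fit <- fit_double_log(pts), "dropped 2")
  expect_equal(fit$points_used, 2L)
  expect_equal(fit$points_dropped, 2L)
  expect_equal(fit$Ka, 1, tolerance = 1e-12)

  expect_error(fit_double_log(data.frame(Q = 1, F0 = 1, F = 0.5)), ">= 2 usable")
  expect_error(
    suppressMessages(fit_double_log(data.frame(Q = c(1, 2), F0 = 1, F = c(1, 1)))),
    "no quenching signal")
})

test_that("rsfq obeys its algebraic identities", {
  expect_equal(rsfq(100, 100), 0)
  expect_equal(rsfq(100, 0), 1)
  expect_equal(rsfq(100, 41.9), 0.581, tolerance = 1e-12)
  expect_warning(v <- rsfq(100, 110), "enhancement")
  expect_lt(v, 0)
  set.seed(5)
  for (k in 1:30) {
    f0 <- runif(1, 1, 1e4); f <- runif(1, 0, f0)
    r <- rsfq(f0, f)
    expect_gte(r, 0); expect_lte(r, 1)
    expect_equal(r + f / f0, 1, tolerance = 1e-12)
  }
})

test_that("displacement_curve converts marker doses to percent curves", {
  pts <- data.frame(marker_conc = c(1e-6, 2e-6), F1 = c(200, 200),
                    F2 = c(150, 120))
  cur <- displacement_curve(pts, 1e-5)
  expect_equal(cur$ratio, c(0.1, 0.2))
  expect_equal(cur$displacement, c(75, 60))
  flat <- displacement_curve(data.frame(marker_conc = 1e-6, F1 = 5, F2 = 5), 1e-5)
  expect_equal(flat$displacement, 100)
  expect_error(displacement_curve(data.frame(marker_conc = 1, F1 = 0, F2 = 1), 1),
               "F1")
})

test_that("site_assignment follows the marker displacement logic", {
  curve <- function(endpoint) data.frame(ratio = 1, displacement = endpoint)
  expect_equal(site_assignment(curve(70), curve(99), threshold = 10), "Sudlow I")
  expect_equal(site_assignment(curve(99), curve(70), threshold = 10), "Sudlow II")
  expect_equal(site_assignment(curve(100), curve(100)), "neither")
  expect_equal(site_assignment(curve(50), curve(50), threshold = 10), "both")
})
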