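test_that("charge current is the charge-weighted velocity sum", {
  topo <- particle_system(matrix(0, 2, 3), masses = c(1, 1), box_edge = 10,
                          charges = c(2, 0))
  vel <- array(0, c(3, 2, 3)); vel[, 1, 1] <- 1
  tr <- trajectory(topo, c(0, 1, 2) * 1e-3, array(1, c(3, 2, 3)), vel)
  J <- charge_current(tr, 1:2)
  expect_equal(J[, 1], rep(2, 3))
  expect_equal(J[, 2], rep(0, 3))
})

test_that("opposite charges with equal velocities cancel", {
  topo <- particle_system(matrix(0, 2, 3), masses = c(1, 1), box_edge = 10,
                          charges = c(1, -1))
  vel <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  vel[, 2, ] <- vel[, 1, ]
  tr <- trajectory(topo, c(0, 1e-3), array(0, c(2, 2, 3)), vel)
  expect_equal(max(abs(charge_current(tr, 1:2))), 0)
})

test_that("charge current is additive over disjoint groups", {
  set.seed(3)
  topo <- particle_system(matrix(0, 10, 3), masses = rep(1, 10),
                          box_edge = 10, charges = round(rnorm(10), 2))
  vel <- array(rnorm(20 * 10 * 3), c(20, 10, 3))
  tr <- trajectory(topo, seq_len(20) * 1e-3, array(0, c(20, 10, 3)), vel)
  a <- 1:4; b <- 5:10
  expect_equal(charge_current(tr, a) + charge_current(tr, b),
               charge_current(tr, 1:10), tolerance = 1e-12)
})

test_that("missing velocities produce an instructive error", {
  topo <- particle_system(matrix(0, 1, 3), masses = 1, box_edge = 10,
                          charges = 1)
  tr <- trajectory(topo, c(0, 1e-3), array(0, c(2, 1, 3)))
  expect_error(charge_current(tr, 1), "velocities")
})

test_that("Wiener-Khinchin ACF equals the direct lag-sum estimator", {
  set.seed(8)
  x <- rnorm(512)
  max_lag <- 200
  acf_fft <- autocorrelation(x, max_lag)
  acf_direct <- sapply(0:max_lag, function(l)
    sum(x[1:(512 - l)] * x[(1 + l):512]) / 512)
  expect_equal(acf_fft, acf_direct, tolerance = 1e-10)
})

test_that("cosine autocorrelation follows its closed form", {
  dt <- 1e-3; n <- 20000
  x <- cos(2 * pi * 25 * (0:(n - 1)) * dt)
  acf_c <- autocorrelation(x, 1000)
  expect_equal(acf_c[1], 0.5, tolerance = 1e-3)    # <cos^2> = 1/2
  # biased (1/N) estimator of a cosine: 0.5 (1 - tau/N) cos(omega tau)
  lags <- 0:1000
  expected <- 0.5 * (1 - lags / n) * cos(2 * pi * 25 * lags * dt)
  expect_equal(acf_c[lags + 1], expected, tolerance = 1e-3)
})

test_that("white-noise ACF off-lag values vanish statistically", {
  set.seed(12)
  n <- 50000
  acf_c <- autocorrelation(rnorm(n), 100)
  expect_lt(max(abs(acf_c[-1] / acf_c[1])), 3 / sqrt(n))
})

test_that("a single charged cosine yields one dominant spectral peak", {
  tr <- make_analytic_trajectory(
    data.frame(frequency = 34.5, amplitude = 1, axis = "z"),
    dt = 1e-3, duration = 50, charge = 1)
  sp <- absorption_spectrum(tr, "signal")
  expect_equal(sp$resolution, 0.02, tolerance = 1e-4)
  expect_equal(sp$nyquist, 500, tolerance = 1e-9)
  pk <- find_peak(sp)
  expect_equal(unname(pk["frequency"]), 34.5, tolerance = 0.02)
  expect_false(attr(pk, "no_distinct_peak"))
})

test_that("two equal cosines give two peaks of equal height", {
  tr <- make_analytic_trajectory(
    data.frame(frequency = c(10, 40), amplitude = c(1, 1),
               axis = c("z", "z")),
    dt = 1e-3, duration = 20, charge = 1)
  sp <- absorption_spectrum(tr, "signal", normalization = "none")
  h1 <- find_peak(sp, band = c(5, 15))["height"]
  h2 <- find_peak(sp, band = c(35, 45))["height"]
  expect_equal(unname(h1 / h2), 1, tolerance = 0.05)
})

test_that("an all-neutral group has an identically zero spectrum", {
  tr <- make_analytic_trajectory(
    data.frame(frequency = 20, amplitude = 1, axis = "z"),
    dt = 1e-3, duration = 5, charge = 0)
  sp <- absorption_spectrum(tr, "signal", normalization = "none")
  expect_equal(max(sp$absorption), 0)
})

test_that("parabolic interpolation resolves an off-bin frequency", {
  tr <- make_analytic_trajectory(
    data.frame(frequency = 34.51, amplitude = 1, axis = "z"),
    dt = 1e-3, duration = 50, charge = 1)
  sp <- absorption_spectrum(tr, "signal")
  pk <- find_peak(sp, band = c(30, 40))
  expect_equal(unname(pk["frequency"]), 34.51, tolerance = 0.01)
})

test_that("pure noise is flagged as having no distinct peak", {
  tr <- make_analytic_trajectory(
    data.frame(frequency = numeric(), amplitude = numeric(),
               axis = character()),
    noise_sd = 1, dt = 1e-3, duration = 10, charge = 1, seed = 4)
  # heavier ACF truncation smooths the flat noise floor
  sp <- absorption_spectrum(tr, "signal", max_lag = 500)
  pk <- find_peak(sp, band = c(1, 400))
  expect_true(attr(pk, "no_distinct_peak"))
})

test_that("windowed and unwindowed spectra agree on peak location", {
  tr <- make_analytic_trajectory(
    data.frame(frequency = 34.5, amplitude = 1, axis = "z"),
    noise_sd = 0.2, dt = 1e-3, duration = 20, charge = 1, seed = 5)
  p1 <- find_peak(absorption_spectrum(tr, "signal", window = "hann"),
                  band = c(30, 40))
  p2 <- find_peak(absorption_spectrum(tr, "signal", window = "none"),
                  band = c(30, 40))
  expect_lt(abs(p1["frequency"] - p2["frequency"]), 0.05)
})

test_that("non-uniform sampling and empty bands are rejected", {
  topo <- particle_system(matrix(0, 1, 3), masses = 1, box_edge = 10,
                          charges = 1)
  tr <- trajectory(topo, c(0, 1e-3, 3e-3),
                   array(0, c(3, 1, 3)), array(1, c(3, 1, 3)))
  expect_error(absorption_spectrum(tr, 1), "uniform")
  tr2 <- make_analytic_trajectory(
    data.frame(frequency = 10, amplitude = 1, axis = "z"),
    dt = 1e-3, duration = 1)
  sp <- absorption_spectrum(tr2, "signal")
  expect_error(find_peak(sp, band = c(600, 700)), "band")
})
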