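test_that("the default echo scheme reproduces the two-segment 40-echo train", {
  te <- makeEchoTimes()
  expect_length(te, 40)
  expect_equal(te[1], 7.4)
  expect_equal(te[32], 7.4 + 31 * 9)     # 286.4 ms
  expect_equal(te[40], 286.4 + 8 * 50)   # 686.4 ms
  expect_true(all(diff(te) > 0))
})

test_that("a single-segment scheme is uniformly spaced", {
  te <- makeEchoTimes(echoScheme(n1 = 10, te1 = 5, esp1 = 5, n2 = 0))
  expect_equal(te, seq(5, 50, by = 5))
})

test_that("inversion times are log-spaced with fixed endpoints", {
  ti <- makeInversionTimes()
  expect_length(ti, 25)
  expect_equal(ti[1], 0.0035)
  expect_equal(ti[25], 10)
  expect_true(all(diff(ti) > 0))
  # before 0.1 ms rounding, consecutive ratios are constant
  raw <- exp(seq(log(0.0035), log(10), length.out = 25))
  expect_equal(unique(round(diff(log(raw)), 12)),
               round(log((10 / 0.0035)^(1 / 24)), 12))
  expect_equal(makeInversionTimes(2, 0.01, 1), c(0.01, 1))
  expect_error(makeInversionTimes(300, 0.001, 0.0012), "reduce n")
})

test_that("noiseless simulation equals the forward model and is reproducible", {
  sys <- worked_system()
  te <- echo_times_s()
  s0 <- simulateRoiDecay(sys, te, snr = Inf)
  expect_identical(s0, evalDecay(apparentTransverseComponents(sys), te))

  a <- simulateRoiDecay(sys, te, snr = 100, seed = 7)
  b <- simulateRoiDecay(sys, te, snr = 100, seed = 7)
  c <- simulateRoiDecay(sys, te, snr = 100, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("seeded simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(simulateRoiDecay(worked_system(), echo_times_s(), snr = 50,
                             seed = 99))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("the Rician noise floor matches its closed-form mean", {
  # at times where the true signal has fully decayed, the magnitude noise
  # mean is sigma * sqrt(pi / 2)
  sys <- poolSystem(1, t2 = 0.005)
  tt <- c(0.0074, seq(0.3, 0.7, length.out = 9))  # 9 floor samples
  snr <- 500
  sims <- sapply(1:1200, function(i)
    simulateRoiDecay(sys, tt, snr = snr, seed = 10000 + i)[-1])
  expect_lt(abs(mean(sims) / ((1 / snr) * sqrt(pi / 2)) - 1), 0.02)
})

test_that("doubling the SNR halves the residual noise SD", {
  sys <- worked_system()
  te <- echo_times_s()
  s0 <- simulateRoiDecay(sys, te, snr = Inf)
  res_sd <- sapply(c(250, 500), function(snr) {
    r <- sapply(1:300, function(i)
      simulateRoiDecay(sys, te, snr = snr, seed = 2000 + i,
                       noise = "gaussian") - s0)
    sd(r)
  })
  expect_equal(res_sd[1] / res_sd[2], 2, tolerance = 0.1)
})

test_that("SIR series simulation is exact at infinite SNR and respects the pre-delay", {
  skip_if_not_installed("deSolve")
  p <- qmtParams(m0 = 1, psr = 0.12, kmf = 15, r1 = 0.5, sf = -0.95)
  ti <- makeInversionTimes()
  expect_equal(simulateSirSeries(p, ti, snr = Inf), sirRecoverySignal(p, ti))

  # finite pre-delay: both pools recover from saturation for preDelay
  # seconds before the inversion; ODE oracle for the full experiment
  kfm <- 15 * 0.12
  rhs <- function(t, y, parms) {
    list(c(0.5 * (1 - y[1]) + 15 * y[2] - kfm * y[1],
           0.5 * (0.12 - y[2]) + kfm * y[1] - 15 * y[2]))
  }
  pre <- deSolve::lsoda(c(0, 0), times = c(1e-12, 3.5), rhs, parms = NULL,
                        rtol = 1e-12, atol = 1e-14)
  init <- c(-0.95 * pre[2, 2], 0.83 * pre[2, 3])
  sol <- deSolve::lsoda(init, times = c(1e-12, 10), rhs, parms = NULL,
                        rtol = 1e-12, atol = 1e-14)
  got <- simulateSirSeries(p, ti, snr = Inf, preDelay = 3.5)
  expect_equal(got[length(ti)], unname(sol[2, 2]), tolerance = 1e-8)
  # at t = 10 s the pre-delay effect is tiny but nonzero
  full <- simulateSirSeries(p, ti, snr = Inf)
  expect_false(identical(got, full))
})

test_that("histology generator honours a zero lesion density", {
  p <- histologyGenParams(grid = c(200, 150), fov = c(15, 11.25),
                          lesionDensity = 0)
  h <- generateHistologyImage(p, seed = 3)
  expect_equal(h$truth[["ed"]], 0)
  expect_equal(nrow(h$lesions), 0)
  expect_true(all(labelMatrix(h$labelMap) %in% 1:2))
})

test_that("histology generation is a pure function of (params, seed)", {
  p <- histologyGenParams(grid = c(200, 150), fov = c(15, 11.25),
                          lesionDensity = 2000)
  h1 <- generateHistologyImage(p, seed = 5)
  h2 <- generateHistologyImage(p, seed = 5)
  expect_identical(h1$image, h2$image)
  expect_identical(h1$lesions, h2$lesions)
  h3 <- generateHistologyImage(p, seed = 6)
  expect_false(identical(h1$image, h3$image))
  # label-map fractions sum to one over tissue
  expect_equal(sum(h1$truth), 1, tolerance = 1e-12)
})

test_that("placed lesion diameters match the requested distribution", {
  # wide low-resolution field to accumulate a few hundred lesions
  p <- histologyGenParams(grid = c(1600, 1200), fov = c(480, 360),
                          lesionDensity = 1651)
  h <- generateHistologyImage(p, seed = 21)
  expect_gte(nrow(h$lesions), 200)
  expect_equal(mean(h$lesions$diameter_um), 3.1, tolerance = 0.05)
})
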