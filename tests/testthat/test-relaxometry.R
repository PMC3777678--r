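test_that("zero exchange reproduces the intrinsic components exactly", {
  sys <- poolSystem(c(0.75, 0.25), t2 = c(0.05, 0.15))
  cmp <- apparentTransverseComponents(sys)
  expect_equal(apparentT2(cmp), c(0.05, 0.15))
  expect_equal(amplitudes(cmp), c(0.75, 0.25))
})

test_that("the exchanging two-pool system yields two equal components", {
  cmp <- apparentTransverseComponents(worked_system())
  expect_equal(amplitudes(cmp), c(0.5, 0.5), tolerance = 1e-9)
  # apparent time constants shrink relative to the intrinsic values
  expect_lt(apparentT2(cmp)[1], 0.05)
  expect_lt(apparentT2(cmp)[2], 0.15)
})

test_that("apparent components match matrix-exponential propagation", {
  set.seed(42)
  times <- seq(0.001, 0.7, length.out = 25)
  for (rep in 1:100) {
    sys <- random_system(sample(2:3, 1))
    cmp <- apparentTransverseComponents(sys)
    s_eig <- evalDecay(cmp, times)
    s_exp <- propagate_expm(sys, times)
    expect_equal(s_eig, s_exp, tolerance = 1e-6)
    # conservation of initial magnetization
    expect_equal(sum(amplitudes(cmp)), 1, tolerance = 1e-9)
  }
})

test_that("bi-exponential refit of the propagated decay recovers the eigen time constants", {
  sys <- worked_system()
  cmp <- apparentTransverseComponents(sys)
  tt <- seq(0.002, 0.8, length.out = 400)
  s <- propagate_expm(sys, tt)
  fit <- minpack.lm::nlsLM(
    s ~ a1 * exp(-tt / r1) + a2 * exp(-tt / r2),
    start = list(a1 = 0.6, r1 = 0.04, a2 = 0.4, r2 = 0.12),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15))
  est <- coef(fit)
  expect_equal(sort(c(est[["r1"]], est[["r2"]])), apparentT2(cmp),
               tolerance = 1e-6)
  expect_equal(sort(c(est[["a1"]], est[["a2"]])), sort(amplitudes(cmp)),
               tolerance = 1e-6)
})

test_that("amplitudes shift monotonically toward the slow component with exchange", {
  f <- c(0.75, 0.25)
  slow <- fast <- numeric(0)
  for (scale in c(0.25, 0.5, 1, 2, 4)) {
    k <- exchangeFromResidence(f, tau = 0.2 / scale)
    cmp <- apparentTransverseComponents(poolSystem(f, c(0.05, 0.15), k = k))
    fast <- c(fast, amplitudes(cmp)[1])
    slow <- c(slow, amplitudes(cmp)[2])
  }
  expect_true(all(diff(slow) >= -1e-12))
  expect_true(all(diff(fast) <= 1e-12))
})

test_that("fast exchange collapses the spectrum onto the mean relaxation rate", {
  f <- c(0.6, 0.4)
  t2 <- c(0.03, 0.2)
  r_mean <- sum(f / t2)
  gap <- numeric(0)
  for (c in c(10, 100, 1000)) {
    k0 <- exchangeFromResidence(f, tau = 0.1)
    cmp <- apparentTransverseComponents(poolSystem(f, t2, k = c * k0))
    dom <- which.max(abs(amplitudes(cmp)))
    gap <- c(gap, abs(1 / apparentT2(cmp)[dom] - r_mean) / r_mean)
    # dominant amplitude approaches the full signal
    expect_gt(amplitudes(cmp)[dom], 0.9)
  }
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 1e-3)
})

test_that("invalid pool systems are rejected", {
  expect_error(poolSystem(c(0.5, 0.4), c(0.05, 0.15)), "sum to 1")
  expect_error(poolSystem(c(0.5, 0.5), c(-0.05, 0.15)), "positive")
  k <- matrix(c(0, 1, 5, 0), 2, 2)
  expect_error(poolSystem(c(0.5, 0.5), c(0.05, 0.15), k = k),
               "detailed balance")
  sys <- poolSystem(c(0.5, 0.5), c(0.05, 0.15))
  expect_error(apparentTransverseComponents(sys, mInit = c(0, 0)))
})

test_that("degenerate pools merge into a single component", {
  sys <- poolSystem(c(0.5, 0.5), t2 = c(0.08, 0.08))
  cmp <- apparentTransverseComponents(sys)
  expect_length(apparentT2(cmp), 1)
  expect_equal(amplitudes(cmp), 1, tolerance = 1e-9)
})

test_that("SIR recovery matches the single-pool closed form when psr = 0", {
  p <- qmtParams(m0 = 2, psr = 0, kmf = 10, r1 = 1.3, sf = -1)
  tt <- c(0.01, 0.1, 0.5, 2)
  expect_equal(sirRecoverySignal(p, tt), 2 * (1 - 2 * exp(-1.3 * tt)),
               tolerance = 1e-12)
  # null point at ln(2)/r1
  expect_lt(abs(sirRecoverySignal(p, log(2) / 1.3)), 1e-12)
})

test_that("SIR recovery converges to equilibrium and matches an ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- qmtParams(m0 = 1, psr = 0.15, kmf = 10, r1 = 0.6, sf = -0.95,
                 sm = 0.83)
  expect_equal(sirRecoverySignal(p, 50 / 0.6), 1, tolerance = 1e-9)

  kfm <- 10 * 0.15
  rhs <- function(t, y, parms) {
    list(c(0.6 * (1 - y[1]) + 10 * y[2] - kfm * y[1],
           0.6 * (0.15 - y[2]) + kfm * y[1] - 10 * y[2]))
  }
  tt <- c(0.0035, 0.1, 1, 10)
  sol <- deSolve::lsoda(c(-0.95, 0.83 * 0.15), times = c(1e-12, tt), rhs,
                        parms = NULL, rtol = 1e-12, atol = 1e-14)
  expect_equal(sirRecoverySignal(p, tt), sol[-1, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("magnitude flag returns absolute signal values", {
  p <- qmtParams(sf = -1, r1 = 1)
  tt <- c(0.05, 3)
  s <- sirRecoverySignal(p, tt)
  expect_lt(s[1], 0)
  expect_equal(sirRecoverySignal(p, tt, magnitude = TRUE), abs(s))
})

test_that("pool systems and qMT parameters round-trip through list configs", {
  sys <- worked_system()
  sys2 <- poolSystemFromList(poolSystemToList(sys))
  expect_equal(poolFractions(sys2), poolFractions(sys))
  expect_equal(poolT2(sys2), poolT2(sys))
  expect_equal(exchangeRates(sys2), exchangeRates(sys))
  p <- qmtParams(m0 = 2, psr = 0.12, kmf = 8, r1 = 0.7, sf = -0.9, sm = 0.8)
  p2 <- qmtParamsFromList(qmtParamsToList(p))
  expect_equal(qmtParamsToList(p2), qmtParamsToList(p))
})
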