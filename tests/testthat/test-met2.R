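test_that("a noiseless mono-exponential is recovered by the one-component fit", {
  te <- echo_times_s()
  s <- exp(-te / 0.05)
  fit <- fitGaussianComponents(s, te, 1)
  cmp <- componentTable(fit)
  # the fixed 0.04-decade line width keeps a pure exponential just outside
  # the model class; recovery is tight but not exact
  expect_equal(10^cmp$center, 0.05, tolerance = 0.01)
  expect_equal(cmp$amplitude, 1, tolerance = 0.01)
  expect_lt(chi2(fit), 1e-4)
})

test_that("a noiseless two-component decay is recovered to 0.01 absolute", {
  te <- echo_times_s()
  sys <- poolSystem(c(0.25, 0.75), t2 = c(0.015, 0.060))
  s <- simulateRoiDecay(sys, te, snr = Inf)
  # with the line width fitted, discrete exponentials are recovered tightly
  fit <- fitGaussianComponents(s, te, 2, met2Options(fitWidth = TRUE))
  cmp <- componentTable(fit)
  expect_lt(max(abs(cmp$amplitude - c(0.25, 0.75))), 0.01)
  expect_equal(10^cmp$center, c(0.015, 0.060), tolerance = 0.05)
  # the fixed default width carries a small model-class bias
  cmp0 <- componentTable(fitGaussianComponents(s, te, 2))
  expect_lt(max(abs(cmp0$amplitude - c(0.25, 0.75))), 0.02)
})

test_that("chi-square is non-increasing in the number of components", {
  te <- echo_times_s()
  for (seed in 1:3) {
    s <- simulateRoiDecay(three_pool_system(), te, snr = 300, seed = seed)
    chis <- vapply(1:3, function(n)
      chi2(fitGaussianComponents(s, te, n)), numeric(1))
    expect_true(all(diff(chis) <= 1e-10))
  }
})

test_that("model selection keeps the simpler model when fits are equal", {
  te <- echo_times_s()
  s <- exp(-te / 0.05)
  f1 <- fitGaussianComponents(s, te, 1)
  fake <- function(chi, np) new("ComponentFit",
    components = data.frame(center = -1.3, width = 0.04, amplitude = 1),
    chi2 = chi, nParams = np, grid = f1@grid, spectrum = f1@spectrum)
  expect_equal(selectNComponents(list(fake(1, 2), fake(1, 4), fake(1, 6)),
                                 40), 1)
  # a perfect larger fit is adopted directly
  expect_equal(selectNComponents(list(fake(1, 2), fake(0, 4)), 40), 2)
})

test_that("three-component signals are selected and recovered at high SNR", {
  te <- echo_times_s()
  res <- t(sapply(1:25, function(i) {
    sys <- three_pool_system(fed = 0.2)
    s <- simulateRoiDecay(sys, te, snr = 1000, seed = 300 + i,
                          noise = "gaussian")
    fits <- lapply(1:3, function(n) fitGaussianComponents(s, te, n))
    nsel <- selectNComponents(fits, length(te))
    ewf <- NA_real_
    if (nsel == 3) {
      labs <- clusterT2Classes(10^componentTable(fits[[3]])$center, 3)
      ewf <- ewf(computeWaterFractions(fits[[3]], labs))
    }
    c(nsel = nsel, ewf = ewf)
  }))
  expect_gte(mean(res[, "nsel"] == 3), 0.9)
  expect_lt(median(abs(res[, "ewf"] - 0.2), na.rm = TRUE), 0.02)
})

test_that("the F-test ladder is conservative on mono-exponential nulls", {
  te <- echo_times_s()
  nsel <- vapply(1:60, function(i) {
    s <- simulateRoiDecay(poolSystem(1, t2 = 0.08), te, snr = 500,
                          seed = 700 + i, noise = "gaussian")
    fits <- lapply(1:2, function(n) fitGaussianComponents(s, te, n))
    selectNComponents(fits, length(te))
  }, integer(1))
  expect_lte(mean(nsel > 1), 0.07)
})

test_that("T2 classes cluster into short / intermediate / long", {
  t2 <- c(0.015, 0.018, 0.045, 0.05, 0.15, 0.16)
  labs <- clusterT2Classes(t2, 3)
  expect_equal(as.character(labs),
               c("short", "short", "intermediate", "intermediate",
                 "long", "long"))
  # permutation invariance
  perm <- c(5, 1, 6, 3, 2, 4)
  labs2 <- clusterT2Classes(t2[perm], 3)
  expect_equal(as.character(labs2), as.character(labs)[perm])
  # breaks separate the classes
  brk <- attr(labs, "breaks")
  expect_length(brk, 2)
  expect_equal(classifyT2(t2, brk), as.character(labs))
})

test_that("clustering attains the exhaustive optimal 1-D partition", {
  sse_of <- function(x, cut1, cut2) {
    parts <- list(x[seq_len(cut1)],
                  x[seq(cut1 + 1, cut2)],
                  x[seq(cut2 + 1, length(x))])
    sum(vapply(parts, function(p) sum((p - mean(p))^2), numeric(1)))
  }
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    t2 <- sort(10^runif(n, -2, -0.3))
    x <- log10(t2)
    best <- Inf
    for (c1 in 1:(n - 2)) for (c2 in (c1 + 1):(n - 1))
      best <- min(best, sse_of(x, c1, c2))
    labs <- clusterT2Classes(t2, 3)
    got <- sum(vapply(split(x, labs), function(p) sum((p - mean(p))^2),
                      numeric(1)))
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("water fractions normalize the labelled amplitudes", {
  fit <- new("ComponentFit",
             components = data.frame(center = c(-1.8, -1.2, -0.8),
                                     width = 0.04,
                                     amplitude = c(0.25, 0.60, 0.15)),
             chi2 = 0, nParams = 6, grid = seq(-3, 0.4, length.out = 16),
             spectrum = rep(0, 16))
  wf <- computeWaterFractions(fit, c("short", "intermediate", "long"))
  expect_equal(mwf(wf), 0.25)
  expect_equal(ewf(wf), 0.15)
  expect_equal(mwf(wf) + ewf(wf) + wf@intermediate, 1, tolerance = 1e-12)

  # absent class contributes zero
  fit2 <- new("ComponentFit",
              components = data.frame(center = c(-1.8, -1.2), width = 0.04,
                                      amplitude = c(0.3, 0.7)),
              chi2 = 0, nParams = 4, grid = seq(-3, 0.4, length.out = 16),
              spectrum = rep(0, 16))
  wf2 <- computeWaterFractions(fit2, c("short", "intermediate"))
  expect_equal(ewf(wf2), 0)
  expect_error(computeWaterFractions(fit2, c("short")), "one label")
})

test_that("voxelwise SE follows SD / sqrt(N)", {
  te <- echo_times_s()
  sysA <- three_pool_system(fed = 0.4, fmy = 0.2)
  sysB <- three_pool_system(fed = 0.6, fmy = 0.2)
  vox <- cbind(simulateRoiDecay(sysA, te, snr = Inf),
               simulateRoiDecay(sysB, te, snr = Inf))
  vu <- voxelwiseUncertainty(vox, te, 3, breaks = c(0.03, 0.12))
  expect_equal(vu$n, 2)
  expect_equal(vu$ewf_se, sd(vu$values[, "ewf"]) / sqrt(2))
  expect_equal(vu$ewf_se, 0.1, tolerance = 0.02)

  # identical voxels: zero spread
  vox0 <- cbind(vox[, 1], vox[, 1], vox[, 1])
  vu0 <- voxelwiseUncertainty(vox0, te, 3, breaks = c(0.03, 0.12))
  expect_equal(vu0$ewf_se, 0, tolerance = 1e-12)

  expect_error(voxelwiseUncertainty(vox[, 1, drop = FALSE], te, 3),
               "at least 2")
})
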