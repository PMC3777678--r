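# shared fixtures: model systems and schemes used across test files

# the two-pool exchanging system of the worked example: T2 = 50/150 ms,
# 75% of signal in the short pool, long-pool residence time 200 ms
worked_system <- function() {
  f <- c(0.75, 0.25)
  poolSystem(f, t2 = c(0.05, 0.15), k = exchangeFromResidence(f, tau = 0.2))
}

# study-like three-pool system without exchange (myelin / ie / edema)
three_pool_system <- function(fed = 0.2, fmy = 0.12,
                              t2 = c(0.015, 0.06, 0.3)) {
  poolSystem(c(fmy, 1 - fmy - fed, fed), t2 = t2)
}

echo_times_s <- function() makeEchoTimes() / 1e3

# random valid exchanging systems for property tests (detailed balance
# enforced by construction)
random_system <- function(npool) {
  f <- runif(npool, 0.1, 1)
  f <- f / sum(f)
  t2 <- sort(runif(npool, 0.01, 0.4))
  k <- matrix(0, npool, npool)
  for (i in seq_len(npool)) for (j in seq_len(npool)) if (i < j) {
    kij <- runif(1, 0, 10)
    k[i, j] <- kij
    k[j, i] <- kij * f[i] / f[j]
  }
  poolSystem(f, t2, k = k)
}

# matrix-exponential propagation of the transverse Bloch-McConnell system:
# the independent oracle for the eigen route
propagate_expm <- function(system, times, mInit = NULL) {
  f <- poolFractions(system)
  if (is.null(mInit)) mInit <- f
  k <- exchangeRates(system); diag(k) <- 0
  A <- t(k); diag(A) <- -(1 / poolT2(system) + rowSums(k))
  vapply(times, function(t)
    sum(Matrix::expm(A * t) %*% mInit), numeric(1))
}
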