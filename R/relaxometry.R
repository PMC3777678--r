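#' Apparent transverse decay components of an exchanging pool system
#'
#' Computes the observed multi-exponential transverse decay of an n-pool
#' Bloch-McConnell relaxation-exchange system. Transverse magnetization
#' evolves as dM/dt = A M with
#' \code{A[i,i] = -(1/t2[i] + sum_j k[i,j])} and \code{A[i,j] = k[j,i]}
#' (magnetization arriving in pool i from pool j). Eigen-decomposition of A
#' yields apparent time constants \code{-1/lambda_n} and amplitudes
#' \code{a_n = sum(v_n) * (w_n . m_init)} where v_n, w_n are the right and
#' left eigenvectors. The total observed signal is
#' \code{S(t) = sum_n a_n exp(-t / t2app_n)}.
#'
#' With exchange, the amplitude of the slower-relaxing apparent component
#' exceeds the equilibrium fraction of the slow pool: water exchange moves
#' observed signal from fast- to slow-relaxing components. This is the
#' mechanism by which the apparent edema (long-T2) water fraction inflates
#' relative to the true edema volume fraction.
#'
#' Nearly degenerate eigenvalues (relative gap below \code{degenerateTol})
#' are merged by summing their amplitudes; components with negligible
#' amplitude (below \code{1e-12 * sum(m_init)}) are dropped.
#'
#' @param system a valid \linkS4class{PoolSystem}
#' @param mInit per-pool initial transverse magnetization; defaults to the
#'   equilibrium fractions
#' @param degenerateTol relative tolerance below which apparent rates are
#'   considered degenerate and merged
#' @return an \linkS4class{ApparentComponents}, sorted ascending in T2
#' @examples
#' sys <- poolSystem(c(0.75, 0.25), t2 = c(0.05, 0.15),
#'                   k = exchangeFromResidence(c(0.75, 0.25), tau = 0.2))
#' apparentTransverseComponents(sys)
#' @export
apparentTransverseComponents <- function(system, mInit = NULL,
                                         degenerateTol = 1e-10) {
  validObject(system)
  f <- system@fractions
  n <- length(f)
  if (is.null(mInit)) mInit <- f
  if (length(mInit) != n || any(mInit < 0) || all(mInit == 0))
    stop("mInit must be length-n, non-negative and not all zero")

  k <- system@k; diag(k) <- 0
  A <- t(k)                       # A[i,j] = k[j,i], magnetization j -> i
  diag(A) <- -(1 / system@t2 + rowSums(k))

  eg <- eigen(A)
  if (max(abs(Im(eg$values))) > 1e-8 * max(abs(eg$values)))
    stop("complex apparent relaxation rates; system is not a valid exchange system")
  lam <- Re(eg$values)
  V <- Re(eg$vectors)
  amp <- colSums(V) * drop(solve(V, mInit))
  t2app <- -1 / lam

  ord <- order(t2app)
  t2app <- t2app[ord]; amp <- amp[ord]

  # merge near-degenerate components (relative gap in rate)
  keep_t2 <- numeric(0); keep_a <- numeric(0)
  for (i in seq_along(t2app)) {
    if (length(keep_t2) &&
        abs(1 / t2app[i] - 1 / tail(keep_t2, 1)) <=
          degenerateTol * abs(1 / tail(keep_t2, 1))) {
      keep_a[length(keep_a)] <- tail(keep_a, 1) + amp[i]
    } else {
      keep_t2 <- c(keep_t2, t2app[i]); keep_a <- c(keep_a, amp[i])
    }
  }
  sel <- abs(keep_a) >= 1e-12 * sum(mInit)
  new("ApparentComponents", t2app = keep_t2[sel], amplitudes = keep_a[sel])
}

#' Evaluate a multi-exponential decay
#'
#' @param components an \linkS4class{ApparentComponents}
#' @param times times (seconds)
#' @return signal values \code{sum_n a_n exp(-t / t2app_n)}
#' @export
evalDecay <- function(components, times) {
  drop(exp(-outer(times, 1 / components@t2app)) %*% components@amplitudes)
}

#' Selective inversion recovery signal of a coupled two-pool system
#'
#' Forward model for the SIR-qMT experiment: longitudinal magnetization of a
#' free water pool (f) coupled to a macromolecular pool (m) recovers after a
#' selective inversion of the free pool. Both pools share the longitudinal
#' rate \code{r1}; exchange rates are \code{kmf} (m to f) and
#' \code{kfm = kmf * psr} (detailed balance with pool-size ratio psr).
#' Initial conditions are \code{Mzf(0) = sf * m0} and
#' \code{Mzm(0) = sm * psr * m0}. The free-pool signal is bi-exponential in
#' t and converges monotonically to m0.
#'
#' @param params a \linkS4class{QMTParams}
#' @param times inversion times, seconds, ascending and positive
#' @param magnitude if TRUE return |signal| (magnitude images); default
#'   signed
#' @return free-pool signal at each time
#' @examples
#' sirRecoverySignal(qmtParams(psr = 0, sf = -1, r1 = 1), times = log(2))
#' # ~0: the single-pool null point at t = ln 2 / r1
#' @export
sirRecoverySignal <- function(params, times, magnitude = FALSE) {
  validObject(params)
  if (any(times <= 0) || is.unsorted(times, strictly = TRUE))
    stop("times must be positive and strictly ascending")
  p <- params
  init <- c(p@sf * p@m0, p@sm * p@psr * p@m0)
  s <- .twoPoolRecovery(p, times, init)[, 1]
  if (magnitude) abs(s) else s
}

# Longitudinal recovery of the coupled (free, macromolecular) pair from an
# arbitrary initial condition; returns a matrix with columns (Mzf, Mzm).
# Raw-parameter version (no validity checks): used inside optimizers where
# finite-difference perturbations may step just outside the bounds.
.twoPoolRecoveryRaw <- function(m0, psr, kmf, r1, times, init) {
  kfm <- kmf * psr
  B <- matrix(c(-(r1 + kfm), kfm,
                kmf, -(r1 + kmf)), 2, 2)
  m_eq <- c(m0, psr * m0)
  d0 <- init - m_eq
  eg <- eigen(B)
  co <- Re(solve(eg$vectors, d0))
  E <- exp(outer(times, Re(eg$values)))
  V <- Re(eg$vectors)
  cbind(m_eq[1] + E %*% (V[1, ] * co),
        m_eq[2] + E %*% (V[2, ] * co))
}

.twoPoolRecovery <- function(p, times, init) {
  kfm <- p@kmf * p@psr
  # deviation from equilibrium decays as d' = B d
  B <- matrix(c(-(p@r1 + kfm), kfm,
                p@kmf, -(p@r1 + p@kmf)), 2, 2)
  m_eq <- c(p@m0, p@psr * p@m0)
  d0 <- init - m_eq
  eg <- eigen(B)
  co <- Re(solve(eg$vectors, d0))
  E <- exp(outer(times, Re(eg$values)))
  V <- Re(eg$vectors)
  cbind(m_eq[1] + E %*% (V[1, ] * co),
        m_eq[2] + E %*% (V[2, ] * co))
}

#' Serialize / deserialize model objects to plain-list configuration
#'
#' Converts a \linkS4class{PoolSystem} or \linkS4class{QMTParams} to and
#' from the list form used in JSON run configurations (keys:
#' \code{fractions}, \code{t2_ms}, \code{t1_s}, \code{k_per_s} for pool
#' systems; \code{m0}, \code{psr}, \code{kmf}, \code{r1}, \code{sf},
#' \code{sm} for qMT parameters).
#'
#' @param x object to serialize
#' @return a plain list (\code{...ToList}) or the reconstructed object
#'   (\code{...FromList})
#' @export
poolSystemToList <- function(x) {
  out <- list(fractions = x@fractions, t2_ms = x@t2 * 1e3,
              k_per_s = x@k)
  if (length(x@t1)) out$t1_s <- x@t1
  out
}

#' @rdname poolSystemToList
#' @param cfg a list as produced by \code{poolSystemToList}
#' @export
poolSystemFromList <- function(cfg) {
  k <- cfg$k_per_s
  if (!is.null(k) && !is.matrix(k)) k <- matrix(unlist(k), length(cfg$fractions))
  poolSystem(unlist(cfg$fractions), unlist(cfg$t2_ms) / 1e3,
             t1 = if (is.null(cfg$t1_s)) numeric() else unlist(cfg$t1_s),
             k = k)
}

#' @rdname poolSystemToList
#' @export
qmtParamsToList <- function(x) {
  list(m0 = x@m0, psr = x@psr, kmf = x@kmf, r1 = x@r1, sf = x@sf, sm = x@sm)
}

#' @rdname poolSystemToList
#' @export
qmtParamsFromList <- function(cfg) {
  cfg <- cfg[intersect(c("m0", "psr", "kmf", "r1", "sf", "sm"), names(cfg))]
  do.call(qmtParams, lapply(cfg, as.numeric))
}
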