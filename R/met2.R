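# Multi-exponential T2 analysis: Gaussian spectral components fitted by
# variable projection (outer search over component centers on the log-T2
# axis, inner non-negative least squares for amplitudes), nested F-test
# model selection, exact 1-D clustering of component T2s into
# short/intermediate/long classes, and MWF/EWF computation.

#' Default MET2 fitting options
#'
#' @param nGrid number of log-T2 grid points
#' @param t2Range T2 grid range in seconds
#' @param width common Gaussian component width, decades of log10(T2)
#' @param fitWidth if TRUE the common width is fitted within widthBounds
#' @param widthBounds bounds for the fitted width (decades)
#' @param candSpacing spacing (decades) of the global candidate-center
#'   grid enumerated before local refinement; one value per model order
#'   (1, 2, 3 components)
#' @param nRefine number of top candidate center sets polished by the
#'   local bounded search
#' @param nJitterStarts extra seeded jittered starts around the best
#'   candidate set
#' @param jitterSd SD (decades) of the start jitter
#' @param seed seed for the jittered starts
#' @return list of options for \code{\link{fitGaussianComponents}}
#' @export
met2Options <- function(nGrid = 256, t2Range = c(0.001, 3), width = 0.04,
                        fitWidth = FALSE, widthBounds = c(0.01, 0.2),
                        candSpacing = c(0.02, 0.02, 0.04), nRefine = 2,
                        nJitterStarts = 2, jitterSd = 0.08, seed = 0) {
  list(nGrid = nGrid, t2Range = t2Range, width = width, fitWidth = fitWidth,
       widthBounds = widthBounds, candSpacing = candSpacing,
       nRefine = nRefine, nJitterStarts = nJitterStarts,
       jitterSd = jitterSd, seed = seed)
}

# model matrix column for one Gaussian spectral component: the Gaussian
# line (center, width in log10 s) integrated over the log-T2 grid against
# exponential decay kernels. E is exp(-t / T2_grid), nt x nGrid.
.component_kernel <- function(E, grid, centers, width) {
  G <- vapply(centers, function(ct) {
    g <- exp(-0.5 * ((grid - ct) / width)^2)
    g / sum(g)
  }, numeric(length(grid)))
  E %*% G
}

# exact non-negative least squares for up to 3 columns by support
# enumeration: the NNLS optimum equals the unconstrained solution on the
# best feasible support subset
.nnls_small <- function(K, signal) {
  m <- ncol(K)
  if (m > 3) {
    a <- pracma::lsqnonneg(K, signal)$x
    return(a)
  }
  G <- crossprod(K); b <- drop(crossprod(K, signal))
  best_a <- rep(0, m); best_q <- 0   # empty support: chi2 = ss, q = a.b = 0
  for (sz in seq_len(m)) {
    for (sub in utils::combn(m, sz, simplify = FALSE)) {
      a_s <- tryCatch(solve(G[sub, sub, drop = FALSE], b[sub]),
                      error = function(e) NULL)
      if (is.null(a_s) || any(a_s < 0)) next
      q <- sum(a_s * b[sub])
      if (q > best_q) {
        best_q <- q
        best_a <- rep(0, m); best_a[sub] <- a_s
      }
    }
  }
  best_a
}

.met2_objective <- function(centers, width, E, grid, signal) {
  K <- .component_kernel(E, grid, centers, width)
  a <- .nnls_small(K, signal)
  r <- signal - drop(K %*% a)
  list(chi2 = sum(r * r), a = a)
}

# Exact global search over an m-point candidate grid for the best 1-, 2-
# or 3-subset of component centers under the non-negative least squares
# objective. For a fixed support the NNLS optimum is the unconstrained
# least squares solution when feasible; otherwise the best feasible
# sub-support applies, so enumerating subsets with closed-form solves
# yields the exact discrete optimum. Returns the nTop best center sets.
.met2_global <- function(E, grid, signal, cand, width, nComp, nTop) {
  K <- .component_kernel(E, grid, cand, width)
  Gm <- crossprod(K)
  b <- drop(crossprod(K, signal))
  ss <- sum(signal^2)
  m <- length(cand)
  d <- diag(Gm)

  pick <- function(chi, feas, sets) {
    # best feasible (interior) candidate sets, plus the best overall
    ordf <- order(chi + ifelse(feas, 0, Inf))
    top <- ordf[seq_len(min(nTop, sum(feas)))]
    best <- which.min(chi)
    idx <- unique(c(top, best))
    lapply(idx, function(t) sets(t))
  }

  a1 <- pmax(b / d, 0)
  chi1 <- ss - (2 * a1 * b - a1^2 * d)
  if (nComp == 1) {
    ord <- order(chi1)[seq_len(min(nTop, m))]
    return(lapply(ord, function(i) cand[i]))
  }

  pr <- utils::combn(m, 2)
  i <- pr[1, ]; j <- pr[2, ]
  g11 <- d[i]; g22 <- d[j]; g12 <- Gm[cbind(i, j)]
  det2 <- g11 * g22 - g12^2
  p1 <- (g22 * b[i] - g12 * b[j]) / det2
  p2 <- (g11 * b[j] - g12 * b[i]) / det2
  feas2 <- det2 > 0 & p1 >= 0 & p2 >= 0
  chi2p <- ss - (p1 * b[i] + p2 * b[j])
  chi2p[!feas2] <- pmin(chi1[i], chi1[j])[!feas2]
  if (nComp == 2)
    return(pick(chi2p, feas2, function(t) cand[c(i[t], j[t])]))

  # triples: closed-form 3x3 solve via the adjugate, vectorized
  pairIdx <- matrix(0L, m, m)
  pairIdx[cbind(i, j)] <- seq_along(i)
  tr <- utils::combn(m, 3)
  t1 <- tr[1, ]; t2 <- tr[2, ]; t3 <- tr[3, ]
  A11 <- d[t1]; A22 <- d[t2]; A33 <- d[t3]
  A12 <- Gm[cbind(t1, t2)]; A13 <- Gm[cbind(t1, t3)]; A23 <- Gm[cbind(t2, t3)]
  det3 <- A11 * (A22 * A33 - A23^2) - A12 * (A12 * A33 - A23 * A13) +
    A13 * (A12 * A23 - A22 * A13)
  b1 <- b[t1]; b2 <- b[t2]; b3 <- b[t3]
  x1 <- ((A22 * A33 - A23^2) * b1 + (A13 * A23 - A12 * A33) * b2 +
           (A12 * A23 - A13 * A22) * b3) / det3
  x2 <- ((A13 * A23 - A12 * A33) * b1 + (A11 * A33 - A13^2) * b2 +
           (A12 * A13 - A11 * A23) * b3) / det3
  x3 <- ((A12 * A23 - A13 * A22) * b1 + (A12 * A13 - A11 * A23) * b2 +
           (A11 * A22 - A12^2) * b3) / det3
  chi3 <- ss - (x1 * b1 + x2 * b2 + x3 * b3)
  feas3 <- det3 > 0 & x1 >= 0 & x2 >= 0 & x3 >= 0
  sub <- pmin(chi2p[pairIdx[cbind(t1, t2)]],
              chi2p[pairIdx[cbind(t1, t3)]],
              chi2p[pairIdx[cbind(t2, t3)]])
  chi3[!feas3] <- sub[!feas3]
  pick(chi3, feas3, function(t) cand[c(t1[t], t2[t], t3[t])])
}

#' Fit Gaussian-shaped T2 spectral components to a decay
#'
#' Fits the decay to a sum of \code{nComponents} (1-3) decaying
#' exponential families, each with a Gaussian spectrum of log-spaced time
#' constants and a non-negative amplitude. The fit is a variable
#' projection: the component centers are searched on the log-T2 axis and
#' the amplitudes are obtained at each step by non-negative least squares
#' against the model matrix formed by integrating each Gaussian line over
#' the log-T2 grid. The center search is global then local: an exact
#' enumeration of center subsets on a coarse candidate grid (closed-form
#' subset least squares), followed by bounded quasi-Newton refinement of
#' the best candidate sets plus seeded jittered restarts. The best
#' chi-square wins, ties going to the solution with fewer effective
#' components.
#'
#' @param signal decay values, length >= nParams + 2 (noisy signed data
#'   are accepted; non-negativity is enforced on the spectrum, not the
#'   data)
#' @param times sampling times, seconds
#' @param nComponents 1, 2 or 3
#' @param options see \code{\link{met2Options}}
#' @return a \linkS4class{ComponentFit}
#' @examples
#' te <- makeEchoTimes() / 1e3
#' s <- exp(-te / 0.05)
#' fitGaussianComponents(s, te, 1)
#' @export
fitGaussianComponents <- function(signal, times, nComponents,
                                  options = met2Options()) {
  nComponents <- as.integer(nComponents)
  if (!nComponents %in% 1:3) stop("nComponents must be 1, 2 or 3")
  nPar <- 2L * nComponents + if (isTRUE(options$fitWidth)) 1L else 0L
  if (length(signal) != length(times)) stop("signal/times length mismatch")
  if (length(signal) < nPar + 2) stop("too few samples for this model")
  if (all(signal == 0)) stop("signal is identically zero")

  grid <- seq(log10(options$t2Range[1]), log10(options$t2Range[2]),
              length.out = options$nGrid)
  E <- exp(-outer(times, 10^(-grid)))
  lo <- grid[1] + 2 * options$width
  hi <- grid[length(grid)] - 2 * options$width
  m <- nComponents

  spacing <- rep(options$candSpacing, length.out = 3)[m]
  cand <- seq(lo, hi, by = spacing)
  tops <- .met2_global(E, grid, signal, cand, options$width, m,
                       options$nRefine)
  starts <- tops
  if (options$nJitterStarts > 0) {
    jitters <- .with_seed(options$seed,
      matrix(rnorm(options$nJitterStarts * m, 0, options$jitterSd),
             options$nJitterStarts, m))
    for (s in seq_len(options$nJitterStarts))
      starts[[length(starts) + 1]] <-
        pmin(pmax(tops[[1]] + jitters[s, ], lo), hi)
  }

  fitWidth <- isTRUE(options$fitWidth)
  obj <- function(par) {
    if (fitWidth) {
      w <- par[m + 1]; ctr <- par[seq_len(m)]
    } else {
      w <- options$width; ctr <- par
    }
    .met2_objective(ctr, w, E, grid, signal)$chi2
  }

  best <- NULL
  for (st in starts) {
    par0 <- if (fitWidth) c(st, options$width) else st
    lower <- c(rep(lo, m), if (fitWidth) options$widthBounds[1])
    upper <- c(rep(hi, m), if (fitWidth) options$widthBounds[2])
    res <- tryCatch(
      optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    width <- if (fitWidth) res$par[m + 1] else options$width
    ctr <- sort(res$par[seq_len(m)])
    ev <- .met2_objective(ctr, width, E, grid, signal)
    nEff <- sum(ev$a > 1e-12 * max(ev$a))
    cand_fit <- list(centers = ctr, width = width, a = ev$a, chi2 = ev$chi2,
                     nEff = nEff, converged = res$convergence == 0)
    if (is.null(best) || cand_fit$chi2 < best$chi2 * (1 - 1e-10) ||
        (abs(cand_fit$chi2 - best$chi2) <= 1e-10 * max(best$chi2, 1e-300) &&
         cand_fit$nEff < best$nEff))
      best <- cand_fit
  }
  if (is.null(best) || !is.finite(best$chi2))
    stop("Gaussian component fit failed to converge from all starts")

  # merge components whose centers collapsed onto each other
  ctr <- best$centers; a <- best$a; w <- best$width
  keep_c <- numeric(0); keep_a <- numeric(0)
  for (i in seq_along(ctr)) {
    if (length(keep_c) && abs(ctr[i] - tail(keep_c, 1)) < 1e-6) {
      keep_a[length(keep_a)] <- tail(keep_a, 1) + a[i]
    } else {
      keep_c <- c(keep_c, ctr[i]); keep_a <- c(keep_a, a[i])
    }
  }
  comp <- data.frame(center = keep_c, width = w, amplitude = keep_a)
  gw <- vapply(seq_len(nrow(comp)), function(i) {
    g <- exp(-0.5 * ((grid - comp$center[i]) / w)^2)
    comp$amplitude[i] * g / sum(g)
  }, numeric(length(grid)))
  new("ComponentFit", components = comp, chi2 = best$chi2,
      nParams = nPar, grid = grid, spectrum = rowSums(gw))
}

#' F-test selection of the number of T2 components
#'
#' Sequential nested F-tests between the 1-, 2- and 3-component fits of
#' the same signal: the larger model is adopted iff
#' \code{F = ((chi2_r - chi2_f)/dp) / (chi2_f/(n - p_f))} has P < alpha.
#' A perfect larger fit (chi2 = 0 against chi2 > 0) is adopted directly.
#'
#' @param fits list of \linkS4class{ComponentFit} indexed by component
#'   count (1, 2, 3); a leading subset is allowed
#' @param nData number of data points fitted
#' @param alpha significance level (default 0.05)
#' @param ladder \code{"sequential"} (stop at the first non-significant
#'   step) or \code{"exhaustive"} (test every nested pair against the
#'   current choice)
#' @return the selected number of components
#' @export
selectNComponents <- function(fits, nData, alpha = 0.05,
                              ladder = c("sequential", "exhaustive")) {
  ladder <- match.arg(ladder)
  ns <- seq_along(fits)
  if (nData <= fits[[length(fits)]]@nParams)
    stop("nData must exceed the largest model's parameter count")
  adopt <- function(r, f) {
    c2r <- fits[[r]]@chi2; c2f <- fits[[f]]@chi2
    pf_ <- fits[[f]]@nParams; dp <- pf_ - fits[[r]]@nParams
    if (c2f <= 0) return(c2r > 0)
    Fv <- ((c2r - c2f) / dp) / (c2f / (nData - pf_))
    if (!is.finite(Fv) || Fv <= 0) return(FALSE)
    pf(Fv, dp, nData - pf_, lower.tail = FALSE) < alpha
  }
  sel <- 1L
  if (ladder == "sequential") {
    for (f in ns[-1]) {
      if (adopt(sel, f)) sel <- f else break
    }
  } else {
    for (f in ns[-1]) if (adopt(sel, f)) sel <- f
  }
  sel
}

#' Cluster component T2 values into short/intermediate/long classes
#'
#' Partitions T2 component values (clustered on the log10 scale, the
#' k-means objective) into k classes. In one dimension the optimal
#' k-means partition is contiguous in sorted order, so the within-class
#' sum of squares is minimized exactly by dynamic programming over
#' contiguous partitions: the result is deterministic, invariant to input
#' order, and globally optimal. Classes are ordered by center; for k = 3
#' they are labelled short, intermediate and long.
#'
#' @param t2 component T2 values, seconds
#' @param k number of classes (default 3)
#' @return character vector of class labels, one per input value, with
#'   attribute \code{"breaks"}: k - 1 boundary T2 values (geometric
#'   midpoints between adjacent class extremes, seconds) usable to
#'   classify new component values
#' @examples
#' clusterT2Classes(c(0.015, 0.018, 0.045, 0.05, 0.15, 0.16))
#' @export
clusterT2Classes <- function(t2, k = 3) {
  if (any(t2 <= 0)) stop("T2 values must be positive")
  x <- log10(t2)
  if (length(unique(x)) < k)
    stop("need at least k distinct T2 values")
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cs <- c(0, cumsum(xs)); cs2 <- c(0, cumsum(xs^2))
  sse <- function(i, j) { # segment cost for xs[i..j]
    m <- j - i + 1
    (cs2[j + 1] - cs2[i]) - (cs[j + 1] - cs[i])^2 / m
  }
  # dp[c][j]: best cost of splitting xs[1..j] into c segments
  dp <- matrix(Inf, k, n); arg <- matrix(0L, k, n)
  for (j in seq_len(n)) dp[1, j] <- sse(1, j)
  if (k > 1) for (c in 2:k) for (j in c:n) {
    for (i in c:j) {
      v <- dp[c - 1, i - 1] + sse(i, j)
      if (v < dp[c, j]) { dp[c, j] <- v; arg[c, j] <- i }
    }
  }
  bounds <- integer(k + 1); bounds[k + 1] <- n
  j <- n
  if (k > 1) for (c in k:2) { bounds[c] <- arg[c, j] - 1L; j <- bounds[c] }
  bounds[1] <- 0L
  seg <- rep(seq_len(k), diff(bounds))
  lab_sorted <- seg
  labels_k <- .t2_class_labels(k)
  out <- character(n)
  out[ord] <- labels_k[lab_sorted]
  brk <- vapply(seq_len(k - 1), function(c) {
    10^((xs[bounds[c + 1]] + xs[bounds[c + 1] + 1]) / 2)
  }, numeric(1))
  attr(out, "breaks") <- brk
  out
}

# class naming convention: 2 classes = short/intermediate (normal white
# matter), 3 classes add the long (edema) class
.t2_class_labels <- function(k) {
  if (k == 3) c("short", "intermediate", "long")
  else if (k == 2) c("short", "intermediate")
  else paste0("class", seq_len(k))
}

#' Classify component T2 values with precomputed class breaks
#'
#' @param t2 T2 values, seconds
#' @param breaks boundary T2 values as returned in the \code{"breaks"}
#'   attribute of \code{\link{clusterT2Classes}}
#' @return character labels (short/intermediate/long for 2 breaks)
#' @export
classifyT2 <- function(t2, breaks) {
  k <- length(breaks) + 1
  .t2_class_labels(k)[findInterval(t2, breaks) + 1]
}

#' Myelin and edema water fractions from a labelled component fit
#'
#' MWF is the short-class signal fraction, EWF the long-class signal
#' fraction; a class absent from the fit contributes 0.
#'
#' @param fit a \linkS4class{ComponentFit}
#' @param labels character class label per component
#'   (short/intermediate/long)
#' @return a \linkS4class{WaterFractions}
#' @export
computeWaterFractions <- function(fit, labels) {
  cmp <- fit@components
  if (length(labels) != nrow(cmp))
    stop("one label per component required")
  if (!all(labels %in% c("short", "intermediate", "long")))
    stop("labels must be short/intermediate/long")
  tot <- sum(cmp$amplitude)
  if (tot <= 0) stop("total component amplitude is zero")
  frac <- vapply(c("short", "intermediate", "long"),
                 function(cl) sum(cmp$amplitude[labels == cl]) / tot,
                 numeric(1))
  new("WaterFractions", mwf = frac[["short"]], ewf = frac[["long"]],
      intermediate = frac[["intermediate"]], total = tot)
}

#' Fit a decay and report water fractions in one call
#'
#' Convenience wrapper: fits 1..3 components, selects the count by F-test,
#' labels the selected components and returns the fractions plus the fit.
#'
#' @param signal,times decay data (times in seconds)
#' @param breaks class boundaries (seconds); if NULL the selected fit's
#'   own components are clustered when 3 are present, otherwise short/
#'   intermediate labels are assigned in T2 order
#' @param alpha F-test level
#' @param options \code{\link{met2Options}}
#' @return list(fractions, fit, nSelected)
#' @export
analyzeDecay <- function(signal, times, breaks = NULL, alpha = 0.05,
                         options = met2Options()) {
  fits <- lapply(1:3, function(n)
    fitGaussianComponents(signal, times, n, options))
  nSel <- selectNComponents(fits, length(signal), alpha)
  fit <- fits[[nSel]]
  t2c <- 10^fit@components$center
  labels <- if (!is.null(breaks)) classifyT2(t2c, breaks)
  else if (nrow(fit@components) >= 3)
    as.character(clusterT2Classes(t2c, 3))
  else c("short", "intermediate", "long")[seq_len(nrow(fit@components))]
  list(fractions = computeWaterFractions(fit, labels), fit = fit,
       nSelected = nSel, labels = labels)
}

#' Intra-ROI standard error of MWF/EWF by voxelwise analysis
#'
#' Fits every voxel decay with the component count fixed to the ROI-level
#' selection, labels components with the supplied class breaks, and
#' reports the standard error of the mean fraction,
#' \code{SE = SD(voxel values) / sqrt(N)}.
#'
#' @param voxelSignals matrix, one column per voxel (rows = echoes)
#' @param times echo times, seconds
#' @param nComponents ROI-level component count (fixed for every voxel)
#' @param breaks class boundary T2s (seconds), see
#'   \code{\link{clusterT2Classes}}
#' @param options \code{\link{met2Options}}
#' @param maxFailFraction error if more than this fraction of voxel fits
#'   fail (default 0.5)
#' @return list with mwf/ewf voxel means, SDs, SEs and the voxel values
#' @export
voxelwiseUncertainty <- function(voxelSignals, times, nComponents,
                                 breaks = c(0.025, 0.1),
                                 options = met2Options(),
                                 maxFailFraction = 0.5) {
  voxelSignals <- as.matrix(voxelSignals)
  nv <- ncol(voxelSignals)
  if (nv < 2) stop("need at least 2 voxels")
  vals <- matrix(NA_real_, nv, 2, dimnames = list(NULL, c("mwf", "ewf")))
  for (v in seq_len(nv)) {
    fit <- tryCatch(
      fitGaussianComponents(pmax(voxelSignals[, v], 0), times, nComponents,
                            options),
      error = function(e) NULL)
    if (is.null(fit)) next
    labels <- classifyT2(10^fit@components$center, breaks)
    wf <- tryCatch(computeWaterFractions(fit, labels),
                   error = function(e) NULL)
    if (is.null(wf)) next
    vals[v, ] <- c(wf@mwf, wf@ewf)
  }
  ok <- !is.na(vals[, 1])
  if (mean(!ok) > maxFailFraction)
    stop("more than half of the voxel fits failed")
  n <- sum(ok)
  list(mwf = mean(vals[ok, "mwf"]), ewf = mean(vals[ok, "ewf"]),
       mwf_sd = sd(vals[ok, "mwf"]), ewf_sd = sd(vals[ok, "ewf"]),
       mwf_se = sd(vals[ok, "mwf"]) / sqrt(n),
       ewf_se = sd(vals[ok, "ewf"]) / sqrt(n),
       n = n, values = vals[ok, , drop = FALSE])
}
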