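#' @import methods
#' @importFrom stats coef kmeans lm mad median optim pf pt qt quantile rnorm rpois
#'   runif sd setNames var
#' @importFrom utils head read.csv tail write.csv
#' @useDynLib imerelax, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.rel_tol <- 1e-9

#' PoolSystem: an n-compartment relaxation-exchange system
#'
#' Describes a system of exchanging water compartments ("pools") by their
#' equilibrium signal fractions, intrinsic relaxation time constants and
#' first-order magnetization exchange rates. \code{k[i, j]} is the rate
#' (1/s) at which magnetization leaves pool \code{i} for pool \code{j};
#' diagonal entries are ignored. At equilibrium the rates must satisfy
#' detailed balance, \code{fractions[i] * k[i, j] == fractions[j] * k[j, i]}.
#'
#' @slot fractions numeric, equilibrium signal fraction per pool (sums to 1)
#' @slot t2 numeric, intrinsic T2 per pool (seconds)
#' @slot t1 numeric, intrinsic T1 per pool (seconds); may be empty
#' @slot k matrix, first-order exchange rates (1/s)
#' @export
setClass("PoolSystem",
  representation(fractions = "numeric", t2 = "numeric",
                 t1 = "numeric", k = "matrix"))

setValidity("PoolSystem", function(object) {
  n <- length(object@fractions)
  msg <- character()
  if (length(object@t2) != n)
    msg <- c(msg, "t2 must have one entry per pool")
  if (any(object@fractions < 0))
    msg <- c(msg, "fractions must be non-negative")
  if (abs(sum(object@fractions) - 1) > .rel_tol)
    msg <- c(msg, "fractions must sum to 1")
  if (any(object@t2 <= 0))
    msg <- c(msg, "all t2 must be positive")
  if (length(object@t1) && (length(object@t1) != n || any(object@t1 <= 0)))
    msg <- c(msg, "t1, when given, must be positive with one entry per pool")
  if (!all(dim(object@k) == c(n, n)))
    msg <- c(msg, "k must be an n x n matrix")
  else {
    koff <- object@k; diag(koff) <- 0
    if (any(koff < 0))
      msg <- c(msg, "off-diagonal exchange rates must be non-negative")
    # detailed balance: f_i k_ij = f_j k_ji (relative tolerance)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
      a <- object@fractions[i] * koff[i, j]
      b <- object@fractions[j] * koff[j, i]
      if (abs(a - b) > .rel_tol * max(1, abs(a), abs(b)))
        msg <- c(msg, sprintf("detailed balance violated between pools %d and %d", i, j))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PoolSystem
#'
#' @param fractions equilibrium signal fractions (will be checked to sum to 1)
#' @param t2 intrinsic T2 values, seconds
#' @param t1 optional intrinsic T1 values, seconds
#' @param k exchange-rate matrix (1/s); defaults to no exchange
#' @return a validated \linkS4class{PoolSystem}
#' @examples
#' sys <- poolSystem(c(0.75, 0.25), t2 = c(0.05, 0.15))
#' @export
poolSystem <- function(fractions, t2, t1 = numeric(), k = NULL) {
  n <- length(fractions)
  if (is.null(k)) k <- matrix(0, n, n)
  new("PoolSystem", fractions = as.numeric(fractions), t2 = as.numeric(t2),
      t1 = as.numeric(t1), k = k)
}

#' Exchange-rate matrix for two pools from a residence time
#'
#' Builds the 2 x 2 exchange matrix in which pool \code{pool} has mean
#' residence time \code{tau} (seconds); the reverse rate follows from
#' detailed balance with the given equilibrium fractions.
#'
#' @param fractions length-2 equilibrium fractions
#' @param tau residence time (s) of pool \code{pool}
#' @param pool which pool the residence time refers to (default 2, the slow pool)
#' @return 2 x 2 exchange-rate matrix (1/s)
#' @export
exchangeFromResidence <- function(fractions, tau, pool = 2L) {
  stopifnot(length(fractions) == 2, tau > 0, pool %in% c(1L, 2L))
  k <- matrix(0, 2, 2)
  other <- 3L - pool
  k[pool, other] <- 1 / tau
  k[other, pool] <- k[pool, other] * fractions[pool] / fractions[other]
  k
}

setMethod("show", "PoolSystem", function(object) {
  n <- length(object@fractions)
  cat(sprintf("PoolSystem with %d pool(s)\n", n))
  cat("  fractions:", paste(signif(object@fractions, 4), collapse = ", "), "\n")
  cat("  T2 (ms):  ", paste(signif(object@t2 * 1e3, 4), collapse = ", "), "\n")
  if (length(object@t1))
    cat("  T1 (s):   ", paste(signif(object@t1, 4), collapse = ", "), "\n")
  koff <- object@k; diag(koff) <- 0
  if (any(koff > 0)) cat("  exchange rates present (1/s); max", signif(max(koff), 4), "\n")
  else cat("  no exchange\n")
})

#' @rdname poolSystem
#' @param object,x a PoolSystem
#' @export
setGeneric("poolFractions", function(x) standardGeneric("poolFractions"))
#' @rdname poolSystem
#' @export
setMethod("poolFractions", "PoolSystem", function(x) x@fractions)
#' @rdname poolSystem
#' @export
setGeneric("poolT2", function(x) standardGeneric("poolT2"))
#' @rdname poolSystem
#' @export
setMethod("poolT2", "PoolSystem", function(x) x@t2)
#' @rdname poolSystem
#' @export
setGeneric("exchangeRates", function(x) standardGeneric("exchangeRates"))
#' @rdname poolSystem
#' @export
setMethod("exchangeRates", "PoolSystem", function(x) x@k)

#' ApparentComponents: observed multi-exponential decay components
#'
#' The apparent (observed) time constants and amplitudes of the
#' multi-exponential transverse decay of an exchanging pool system. The
#' amplitudes sum to the total initial magnetization.
#'
#' @slot t2app apparent time constants, seconds, ascending
#' @slot amplitudes signal amplitudes, same length
#' @export
setClass("ApparentComponents",
  representation(t2app = "numeric", amplitudes = "numeric"))

setValidity("ApparentComponents", function(object) {
  msg <- character()
  if (length(object@t2app) != length(object@amplitudes))
    msg <- c(msg, "t2app and amplitudes must have equal length")
  if (any(object@t2app <= 0))
    msg <- c(msg, "apparent T2 values must be positive")
  if (is.unsorted(object@t2app, strictly = TRUE))
    msg <- c(msg, "t2app must be strictly ascending")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ApparentComponents", function(object) {
  cat("ApparentComponents\n")
  print(data.frame(t2_ms = object@t2app * 1e3, amplitude = object@amplitudes))
})

#' @rdname apparentTransverseComponents
#' @export
setGeneric("apparentT2", function(x) standardGeneric("apparentT2"))
#' @rdname apparentTransverseComponents
#' @export
setMethod("apparentT2", "ApparentComponents", function(x) x@t2app)
#' @rdname apparentTransverseComponents
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))
#' @rdname apparentTransverseComponents
#' @export
setMethod("amplitudes", "ApparentComponents", function(x) x@amplitudes)

#' QMTParams: coupled two-pool longitudinal relaxation parameters
#'
#' The five fitted parameters of the selective inversion recovery (SIR)
#' quantitative magnetization transfer signal model, plus the fixed
#' macromolecular saturation factor \code{sm}. \code{psr} is the
#' macromolecular-to-free pool-size ratio; \code{kmf} the
#' macromolecular-to-free exchange rate (the free-to-macromolecular rate is
#' \code{kmf * psr} by detailed balance); \code{r1} the shared longitudinal
#' rate 1/T1; \code{sf} the free-pool inversion efficiency.
#'
#' @slot m0 equilibrium free-pool signal (> 0)
#' @slot psr pool-size ratio (>= 0)
#' @slot kmf macromolecular-to-free exchange rate, 1/s (>= 0)
#' @slot r1 longitudinal relaxation rate, 1/s (> 0)
#' @slot sf free-pool inversion efficiency, in [-1, 1]
#' @slot sm macromolecular-pool saturation factor (fixed, not fitted)
#' @export
setClass("QMTParams",
  representation(m0 = "numeric", psr = "numeric", kmf = "numeric",
                 r1 = "numeric", sf = "numeric", sm = "numeric"))

setValidity("QMTParams", function(object) {
  msg <- character()
  if (object@m0 <= 0) msg <- c(msg, "m0 must be positive")
  if (object@psr < 0) msg <- c(msg, "psr must be non-negative")
  if (object@kmf < 0) msg <- c(msg, "kmf must be non-negative")
  if (object@r1 <= 0) msg <- c(msg, "r1 must be positive")
  if (object@sf < -1 || object@sf > 1) msg <- c(msg, "sf must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct QMTParams
#'
#' @param m0 equilibrium free-pool signal
#' @param psr pool-size ratio
#' @param kmf macromolecular-to-free exchange rate (1/s)
#' @param r1 longitudinal rate (1/s)
#' @param sf free-pool inversion efficiency
#' @param sm macromolecular saturation factor (default 0.83, appropriate for
#'   a short hard inversion pulse)
#' @return a validated \linkS4class{QMTParams}
#' @export
qmtParams <- function(m0 = 1, psr = 0.15, kmf = 10, r1 = 0.6,
                      sf = -0.95, sm = 0.83) {
  new("QMTParams", m0 = m0, psr = psr, kmf = kmf, r1 = r1, sf = sf, sm = sm)
}

setMethod("show", "QMTParams", function(object) {
  cat("QMTParams: ",
      sprintf("m0 = %.4g, PSR = %.4g, kmf = %.4g 1/s, R1 = %.4g 1/s (T1 = %.4g s), sf = %.4g, sm = %.4g\n",
              object@m0, object@psr, object@kmf, object@r1, 1 / object@r1,
              object@sf, object@sm))
})

#' @rdname qmtParams
#' @param x a QMTParams
#' @export
setGeneric("psr", function(x) standardGeneric("psr"))
#' @rdname qmtParams
#' @export
setMethod("psr", "QMTParams", function(x) x@psr)
#' @rdname qmtParams
#' @export
setGeneric("kmf", function(x) standardGeneric("kmf"))
#' @rdname qmtParams
#' @export
setMethod("kmf", "QMTParams", function(x) x@kmf)

#' ComponentFit: a Gaussian-component T2 spectrum fit
#'
#' Result of fitting a decay to 1-3 spectral components, each a Gaussian
#' line on the log10(T2) axis with a common width. \code{components} holds
#' one row per component (center in log10 seconds, width in decades,
#' non-negative amplitude), ordered by center.
#'
#' @slot components data.frame with columns center, width, amplitude
#' @slot chi2 sum of squared residuals
#' @slot nParams number of fitted parameters
#' @slot grid log10(T2/s) grid on which the spectrum is tabulated
#' @slot spectrum spectral amplitude at each grid point (non-negative)
#' @export
setClass("ComponentFit",
  representation(components = "data.frame", chi2 = "numeric",
                 nParams = "numeric", grid = "numeric", spectrum = "numeric"))

setValidity("ComponentFit", function(object) {
  msg <- character()
  cmp <- object@components
  if (!all(c("center", "width", "amplitude") %in% names(cmp)))
    msg <- c(msg, "components needs columns center, width, amplitude")
  else {
    if (any(cmp$amplitude < 0)) msg <- c(msg, "amplitudes must be non-negative")
    if (nrow(cmp) > 1 && is.unsorted(cmp$center, strictly = TRUE))
      msg <- c(msg, "component centers must be strictly ordered")
  }
  if (object@chi2 < 0) msg <- c(msg, "chi2 must be non-negative")
  if (any(object@spectrum < -1e-12)) msg <- c(msg, "spectrum must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ComponentFit", function(object) {
  cat(sprintf("ComponentFit: %d component(s), chi2 = %.4g\n",
              nrow(object@components), object@chi2))
  cmp <- object@components
  print(data.frame(T2_ms = 10^cmp$center * 1e3, width_decades = cmp$width,
                   amplitude = cmp$amplitude))
})

#' @rdname fitGaussianComponents
#' @export
setGeneric("componentTable", function(x) standardGeneric("componentTable"))
#' @rdname fitGaussianComponents
#' @export
setMethod("componentTable", "ComponentFit", function(x) x@components)
#' @rdname fitGaussianComponents
#' @export
setGeneric("chi2", function(x) standardGeneric("chi2"))
#' @rdname fitGaussianComponents
#' @export
setMethod("chi2", "ComponentFit", function(x) x@chi2)

#' WaterFractions: short/intermediate/long T2 signal fractions
#'
#' @slot mwf myelin water fraction (short-T2 class signal fraction)
#' @slot ewf edema water fraction (long-T2 class signal fraction)
#' @slot intermediate intermediate-class signal fraction
#' @slot total total signal amplitude
#' @export
setClass("WaterFractions",
  representation(mwf = "numeric", ewf = "numeric",
                 intermediate = "numeric", total = "numeric"))

setValidity("WaterFractions", function(object) {
  fr <- c(object@mwf, object@intermediate, object@ewf)
  msg <- character()
  if (any(fr < -1e-12) || any(fr > 1 + 1e-12))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > .rel_tol)
    msg <- c(msg, "fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WaterFractions", function(object) {
  cat(sprintf("WaterFractions: MWF = %.4f, intermediate = %.4f, EWF = %.4f (total signal %.4g)\n",
              object@mwf, object@intermediate, object@ewf, object@total))
})

#' @rdname computeWaterFractions
#' @export
setGeneric("mwf", function(x) standardGeneric("mwf"))
#' @rdname computeWaterFractions
#' @export
setMethod("mwf", "WaterFractions", function(x) x@mwf)
#' @rdname computeWaterFractions
#' @export
setGeneric("ewf", function(x) standardGeneric("ewf"))
#' @rdname computeWaterFractions
#' @export
setMethod("ewf", "WaterFractions", function(x) x@ewf)

#' QMTFitResult: fitted SIR-qMT model with uncertainties
#'
#' @slot params the fitted \linkS4class{QMTParams}
#' @slot covariance 5 x 5 covariance matrix of (m0, psr, kmf, r1, sf)
#' @slot chi2 residual sum of squares
#' @slot se named standard errors
#' @slot diagnostics list: convergence info, bound flags, start used
#' @export
setClass("QMTFitResult",
  representation(params = "QMTParams", covariance = "matrix",
                 chi2 = "numeric", se = "numeric", diagnostics = "list"))

setValidity("QMTFitResult", function(object) {
  msg <- character()
  if (object@chi2 < 0) msg <- c(msg, "chi2 must be non-negative")
  if (any(object@se < 0, na.rm = TRUE)) msg <- c(msg, "standard errors must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "QMTFitResult", function(object) {
  p <- object@params
  cat("QMTFitResult (5-parameter coupled two-pool SIR fit)\n")
  est <- c(m0 = p@m0, psr = p@psr, kmf = p@kmf, r1 = p@r1, sf = p@sf)
  print(data.frame(estimate = est, se = object@se[names(est)]))
  cat(sprintf("  chi2 = %.4g, converged = %s\n", object@chi2,
              isTRUE(object@diagnostics$converged)))
})

#' @rdname fitSir
#' @export
setMethod("chi2", "QMTFitResult", function(x) x@chi2)

#' @rdname fitSir
#' @export
setGeneric("qmtEstimates", function(x) standardGeneric("qmtEstimates"))
#' @rdname fitSir
#' @export
setMethod("qmtEstimates", "QMTFitResult", function(x) {
  p <- x@params
  c(m0 = p@m0, psr = p@psr, kmf = p@kmf, r1 = p@r1, sf = p@sf)
})
#' @rdname fitSir
#' @export
setGeneric("qmtSE", function(x) standardGeneric("qmtSE"))
#' @rdname fitSir
#' @export
setMethod("qmtSE", "QMTFitResult", function(x) x@se)

# Histology label codes: 0 background, 1 myelin, 2 intra/extra-axonal, 3 edema
.lab_bg <- 0L; .lab_my <- 1L; .lab_ie <- 2L; .lab_ed <- 3L

#' HistologyLabelMap: per-pixel tissue class labels
#'
#' Integer label matrix with codes 0 = background (non-tissue), 1 = myelin,
#' 2 = intra/extra-axonal space, 3 = edema, plus the isotropic pixel size in
#' micrometers.
#'
#' @slot labels integer matrix of class codes
#' @slot pixelSize micrometers per pixel (> 0)
#' @export
setClass("HistologyLabelMap",
  representation(labels = "matrix", pixelSize = "numeric"))

setValidity("HistologyLabelMap", function(object) {
  msg <- character()
  if (!all(object@labels %in% 0:3))
    msg <- c(msg, "labels must be integer codes 0..3")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a HistologyLabelMap
#' @param labels integer matrix (0 background, 1 myelin, 2 intra/extra-axonal, 3 edema)
#' @param pixelSize micrometers per pixel
#' @export
histologyLabelMap <- function(labels, pixelSize) {
  storage.mode(labels) <- "integer"
  new("HistologyLabelMap", labels = labels, pixelSize = pixelSize)
}

setMethod("show", "HistologyLabelMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("HistologyLabelMap %d x %d px at %.4g um/px\n", d[1], d[2],
              object@pixelSize))
  tab <- table(factor(object@labels, levels = 0:3,
                      labels = c("background", "myelin", "ie", "edema")))
  print(tab)
})

#' @rdname segmentRegions
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname segmentRegions
#' @export
setMethod("labelMatrix", "HistologyLabelMap", function(x) x@labels)
#' @rdname segmentRegions
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname segmentRegions
#' @export
setMethod("pixelSize", "HistologyLabelMap", function(x) x@pixelSize)

#' WaterContent: compartment volume fractions and water-content fractions
#'
#' Stores the compartment volume fractions V (myelin, intra/extra-axonal,
#' edema), the relative water densities rho, the total water content
#' fraction W = sum(V * rho), and the compartment water fractions
#' Wx = V * rho / W (which sum to 1).
#'
#' @slot v named volume fractions (my, ie, ed), summing to 1
#' @slot rho named relative water densities
#' @slot w total water content fraction
#' @slot wx named compartment water-content fractions
#' @export
setClass("WaterContent",
  representation(v = "numeric", rho = "numeric", w = "numeric", wx = "numeric"))

setValidity("WaterContent", function(object) {
  msg <- character()
  if (any(object@v < 0)) msg <- c(msg, "volume fractions must be non-negative")
  if (abs(sum(object@v) - 1) > .rel_tol) msg <- c(msg, "volume fractions must sum to 1")
  if (abs(object@w - sum(object@v * object@rho)) > .rel_tol)
    msg <- c(msg, "w must equal sum(v * rho)")
  if (abs(sum(object@wx) - 1) > .rel_tol)
    msg <- c(msg, "compartment water fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WaterContent", function(object) {
  cat(sprintf("WaterContent: W = %.4f\n", object@w))
  print(data.frame(V = object@v, rho = object@rho, Wx = object@wx))
})
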