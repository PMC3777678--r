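# Seeded synthetic-data generators: multi-echo decays, selective inversion
# recovery series, and toluidine-blue-like histology fields with known
# ground truth. All generators are pure functions of (parameters, seed):
# the RNG state of the calling session is saved and restored.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Multi-echo acquisition scheme
#'
#' A two-segment echo train: \code{n1} early echoes starting at \code{te1}
#' with spacing \code{esp1}, followed by \code{n2} late echoes continuing
#' with spacing \code{esp2}. The default reproduces a 40-echo acquisition
#' with a 7.4 ms first echo, 32 echoes at 9 ms spacing and 8 final echoes
#' at 50 ms spacing. All times in milliseconds.
#'
#' @param n1,te1,esp1 early-segment echo count, first echo time and spacing (ms)
#' @param n2,esp2 late-segment echo count and spacing (ms)
#' @return a list of class \code{"echoScheme"}
#' @export
echoScheme <- function(n1 = 32, te1 = 7.4, esp1 = 9, n2 = 8, esp2 = 50) {
  if (n1 < 1 || te1 <= 0 || esp1 <= 0 || n2 < 0 || (n2 > 0 && esp2 <= 0))
    stop("echo scheme entries must be positive (n2 may be 0)")
  structure(list(n1 = n1, te1 = te1, esp1 = esp1, n2 = n2, esp2 = esp2),
            class = "echoScheme")
}

#' Echo times of a two-segment multi-echo scheme
#'
#' @param scheme an \code{\link{echoScheme}}
#' @return echo times in milliseconds, strictly ascending
#' @examples
#' te <- makeEchoTimes()   # 40 echoes, first at 7.4 ms, last at 686.4 ms
#' @export
makeEchoTimes <- function(scheme = echoScheme()) {
  early <- scheme$te1 + scheme$esp1 * seq(0, scheme$n1 - 1)
  late <- if (scheme$n2 > 0)
    tail(early, 1) + scheme$esp2 * seq_len(scheme$n2) else numeric()
  times <- c(early, late)
  if (is.unsorted(times, strictly = TRUE)) stop("echo times must increase")
  times
}

#' Pseudo-logarithmically spaced inversion times
#'
#' \code{n} log-spaced times from \code{tmin} to \code{tmax} inclusive,
#' rounded to 0.1 ms. The default emulates 25 inversion times between
#' 3.5 ms and 10 s.
#'
#' @param n number of times (>= 2)
#' @param tmin,tmax range in seconds, 0 < tmin < tmax
#' @return inversion times in seconds, strictly ascending
#' @export
makeInversionTimes <- function(n = 25, tmin = 0.0035, tmax = 10) {
  if (n < 2 || tmin <= 0 || tmin >= tmax)
    stop("need n >= 2 and 0 < tmin < tmax")
  t <- exp(seq(log(tmin), log(tmax), length.out = n))
  t <- round(t, 4)                 # 0.1 ms rounding
  if (is.unsorted(t, strictly = TRUE))
    stop("0.1 ms rounding collapsed adjacent inversion times; reduce n")
  t
}

.add_noise <- function(s, snr, nAvg = 1, noise = c("rician", "gaussian")) {
  noise <- match.arg(noise)
  if (!is.finite(snr)) return(s)
  sd0 <- s[1] / snr / sqrt(nAvg)
  # reference amplitude is the t = 0 signal for decays; for series whose
  # first sample is not the largest, callers pass ref via attr
  ref <- attr(s, "noise_ref")
  if (!is.null(ref)) sd0 <- ref / snr / sqrt(nAvg)
  if (noise == "gaussian") {
    s + rnorm(length(s), 0, sd0)
  } else {
    sqrt((s + rnorm(length(s), 0, sd0))^2 + rnorm(length(s), 0, sd0)^2)
  }
}

#' Simulate a noisy ROI decay curve
#'
#' Evaluates the multi-exponential forward model of a
#' \linkS4class{PoolSystem} at the given times and adds seeded noise.
#' Rician noise (default) is the magnitude of a complex Gaussian
#' perturbation with per-channel SD \code{S(0) / snr / sqrt(nAvg)};
#' Gaussian noise adds a single real channel, appropriate for ROI-mean
#' signals where averaging makes the noise near-normal.
#'
#' @param system a \linkS4class{PoolSystem}
#' @param times sampling times, seconds, ascending
#' @param snr signal-to-noise ratio at t = 0; \code{Inf} for noiseless
#' @param seed integer seed (RNG state is restored on exit)
#' @param nAvg number of signal averages
#' @param noise \code{"rician"} or \code{"gaussian"}
#' @param mInit initial per-pool magnetization (default equilibrium fractions)
#' @return numeric decay vector
#' @export
simulateRoiDecay <- function(system, times, snr = Inf, seed = NULL,
                             nAvg = 1, noise = c("rician", "gaussian"),
                             mInit = NULL) {
  noise <- match.arg(noise)
  if (is.unsorted(times, strictly = TRUE) || any(times < 0))
    stop("times must be non-negative and ascending")
  if (snr <= 0) stop("snr must be positive")
  cmp <- apparentTransverseComponents(system, mInit = mInit)
  s <- evalDecay(cmp, times)
  attr(s, "noise_ref") <- sum(cmp@amplitudes)   # S(0)
  out <- .with_seed(seed, .add_noise(s, snr, nAvg, noise))
  attributes(out) <- NULL
  out
}

#' Simulate a noisy selective inversion recovery series
#'
#' Wraps \code{\link{sirRecoverySignal}} with seeded noise. With a finite
#' \code{preDelay}, the pools are assumed saturated by the readout and
#' recover for \code{preDelay} seconds before the inversion, which scales
#' the effective initial condition.
#'
#' @param params a \linkS4class{QMTParams}
#' @param times inversion times, seconds
#' @param snr signal-to-noise ratio relative to m0; \code{Inf} noiseless
#' @param seed integer seed
#' @param nAvg number of averages
#' @param noise \code{"rician"} or \code{"gaussian"}; Gaussian keeps the
#'   signal signed, Rician returns magnitudes
#' @param preDelay repetition pre-delay in seconds (\code{Inf} = full
#'   recovery before inversion)
#' @return numeric signal vector
#' @export
simulateSirSeries <- function(params, times, snr = Inf, seed = NULL,
                              nAvg = 1, noise = c("gaussian", "rician"),
                              preDelay = Inf) {
  noise <- match.arg(noise)
  validObject(params)
  if (any(times <= 0) || is.unsorted(times, strictly = TRUE))
    stop("times must be positive and strictly ascending")
  p <- params
  if (is.finite(preDelay)) {
    pre <- .twoPoolRecovery(p, preDelay, c(0, 0))
    init <- c(p@sf * pre[1, 1], p@sm * pre[1, 2])
  } else {
    init <- c(p@sf * p@m0, p@sm * p@psr * p@m0)
  }
  s <- .twoPoolRecovery(p, times, init)[, 1]
  attr(s, "noise_ref") <- p@m0
  out <- .with_seed(seed, .add_noise(s, snr, nAvg, noise))
  attributes(out) <- NULL
  out
}

#' Histology generator parameters
#'
#' Defaults emulate a toluidine-blue stained 1 um section of spinal white
#' matter digitized into a 1600 x 1200 grid over a 120 x 90 um^2 field of
#' view (0.075 um/px). Axons are packed disks with a myelin annulus
#' (inner/outer radius ratio \code{gRatio}); intramyelinic edema lesions
#' are circles with Normal(mean, sd) diameters placed with centres on
#' myelin. Rendering uses the dark-stain convention: myelin dark (0.20),
#' intra/extra-axonal mid (0.55), edema bright (0.90), plus a linear
#' illumination gradient and Gaussian noise.
#'
#' @param grid image dimensions, pixels (width, height)
#' @param fov field of view, micrometers (width, height)
#' @param lesionDensity lesions per mm^2 of tissue
#' @param lesionDiameterMean,lesionDiameterSd lesion diameter (um)
#' @param axonPacking target areal packing fraction of axon disks
#' @param axonRadiusMean,axonRadiusSd outer axon (fibre) radius (um)
#' @param gRatio inner/outer radius ratio of the myelin annulus
#' @param intensities named mean intensities for my, ie, ed in [0, 1]
#' @param noiseSd Gaussian intensity noise SD
#' @param illumAmplitude peak-to-centre amplitude of the linear
#'   illumination gradient
#' @return a list of class \code{"histologyGenParams"}
#' @export
histologyGenParams <- function(grid = c(1600, 1200), fov = c(120, 90),
                               lesionDensity = 600,
                               lesionDiameterMean = 3.1,
                               lesionDiameterSd = 0.4,
                               axonPacking = 0.52,
                               axonRadiusMean = 1.7, axonRadiusSd = 0.45,
                               gRatio = 0.68,
                               intensities = c(my = 0.20, ie = 0.55, ed = 0.90),
                               noiseSd = 0.05, illumAmplitude = 0.05) {
  stopifnot(all(grid > 0), all(fov > 0), lesionDensity >= 0,
            lesionDiameterMean > 0, lesionDiameterSd >= 0,
            axonPacking > 0, axonPacking < 0.9,
            gRatio > 0, gRatio < 1,
            all(intensities >= 0), all(intensities <= 1))
  structure(list(grid = grid, fov = fov, lesionDensity = lesionDensity,
                 lesionDiameterMean = lesionDiameterMean,
                 lesionDiameterSd = lesionDiameterSd,
                 axonPacking = axonPacking,
                 axonRadiusMean = axonRadiusMean, axonRadiusSd = axonRadiusSd,
                 gRatio = gRatio, intensities = intensities,
                 noiseSd = noiseSd, illumAmplitude = illumAmplitude),
            class = "histologyGenParams")
}

#' Named lesion-density presets (lesions per mm^2)
#'
#' Per-tract mean lesion densities for the two intoxication severities,
#' usable as \code{lesionDensity} values in
#' \code{\link{histologyGenParams}}: e.g. \code{lesionDensityPresets()[["dCST-HCP600"]]}.
#' @return named numeric vector
#' @export
lesionDensityPresets <- function() {
  c("dCST-HCP600" = 1651, "FG-HCP600" = 1291, "RST-HCP600" = 545,
    "VST-HCP600" = 497,
    "dCST-HCP300" = 776, "FG-HCP300" = 469, "RST-HCP300" = 344,
    "VST-HCP300" = 142)
}

# rasterize one filled circle / annulus into an integer label matrix
# (cx, cy, radii in pixel units, matrix indexed [row, col] = [y, x])
.paint_circle <- function(lab, cx, cy, rin, rout, value) {
  nr <- nrow(lab); nc <- ncol(lab)
  i0 <- max(1L, floor(cy - rout)); i1 <- min(nr, ceiling(cy + rout))
  j0 <- max(1L, floor(cx - rout)); j1 <- min(nc, ceiling(cx + rout))
  if (i0 > i1 || j0 > j1) return(lab)
  ii <- i0:i1; jj <- j0:j1
  d2 <- outer((ii - cy)^2, (jj - cx)^2, "+")
  sel <- d2 <= rout^2 & d2 > rin^2
  block <- lab[ii, jj, drop = FALSE]
  block[sel] <- value
  lab[ii, jj] <- block
  lab
}

#' Generate a synthetic histology field with known ground truth
#'
#' Packs myelinated axons (random sequential adsorption of non-overlapping
#' disks), paints myelin annuli, places non-overlapping circular edema
#' lesions with centres on myelin by rejection sampling, and renders class
#' intensities plus illumination gradient and noise. The returned truth is
#' computed from the label map itself.
#'
#' @param p a \code{\link{histologyGenParams}}
#' @param seed integer seed
#' @param maxLesionAttempts rejection-sampling cap per lesion
#' @return list with \code{image} (matrix in [0,1], rows = y),
#'   \code{labelMap} (\linkS4class{HistologyLabelMap}),
#'   \code{truth} (named volume fractions my/ie/ed) and
#'   \code{lesions} (data.frame x_um, y_um, diameter_um)
#' @export
generateHistologyImage <- function(p = histologyGenParams(), seed = NULL,
                                   maxLesionAttempts = 1e5) {
  .with_seed(seed, {
    px <- p$fov[1] / p$grid[1]            # um per pixel
    if (abs(px - p$fov[2] / p$grid[2]) > 1e-9 * px)
      stop("grid and fov must give isotropic pixels")
    nr <- p$grid[2]; nc <- p$grid[1]      # rows = y, cols = x
    lab <- matrix(.lab_ie, nr, nc)

    # axons: lognormal outer radii, packed to the target fraction
    cv <- p$axonRadiusSd / p$axonRadiusMean
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(p$axonRadiusMean) - sdlog^2 / 2
    disks <- .rsa_disks(p$fov[1], p$fov[2], meanlog, sdlog,
                        p$axonPacking, as.integer(2e5), 0.99)
    for (a in seq_len(nrow(disks))) {
      rout <- disks[a, 3] / px
      rin <- rout * p$gRatio
      lab <- .paint_circle(lab, disks[a, 1] / px, disks[a, 2] / px,
                           rin, rout, .lab_my)
    }

    # lesions: centres on myelin, non-overlapping circles
    area_mm2 <- prod(p$fov) * 1e-6
    n_les <- round(p$lesionDensity * area_mm2)
    myel_idx <- which(lab == .lab_my)
    les <- matrix(numeric(0), 0, 3)       # x_px, y_px, r_px
    for (l in seq_len(n_les)) {
      placed <- FALSE
      for (att in seq_len(maxLesionAttempts)) {
        d_um <- rnorm(1, p$lesionDiameterMean, p$lesionDiameterSd)
        if (d_um <= 0) next
        idx <- myel_idx[sample.int(length(myel_idx), 1)]
        cy <- (idx - 1) %% nr + 1; cx <- (idx - 1) %/% nr + 1
        r <- d_um / 2 / px
        if (cx - r < 1 || cx + r > nc || cy - r < 1 || cy + r > nr) next
        if (nrow(les)) {
          if (any((les[, 1] - cx)^2 + (les[, 2] - cy)^2 < (les[, 3] + r)^2))
            next
        }
        les <- rbind(les, c(cx, cy, r))
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(
          "could not place lesion %d of %d (achieved density %.1f / mm^2)",
          l, n_les, nrow(les) / area_mm2))
    }
    for (l in seq_len(nrow(les)))
      lab <- .paint_circle(lab, les[l, 1], les[l, 2], -1, les[l, 3], .lab_ed)

    # render
    means <- c(p$intensities[["my"]], p$intensities[["ie"]],
               p$intensities[["ed"]])
    img <- matrix(means[lab], nr, nc)
    illum <- p$illumAmplitude *
      (matrix(seq_len(nc), nr, nc, byrow = TRUE) / nc - 0.5)
    img <- img + illum + matrix(rnorm(nr * nc, 0, p$noiseSd), nr, nc)
    img <- pmin(pmax(img, 0), 1)

    lm <- histologyLabelMap(lab, px)
    counts <- tabulate(lab, nbins = 3)
    truth <- setNames(counts / sum(counts), c("my", "ie", "ed"))
    lesions <- if (nrow(les))
      data.frame(x_um = les[, 1] * px, y_um = les[, 2] * px,
                 diameter_um = 2 * les[, 3] * px)
    else data.frame(x_um = numeric(), y_um = numeric(),
                    diameter_um = numeric())
    list(image = img, labelMap = lm, truth = truth, lesions = lesions)
  })
}
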