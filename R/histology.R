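# Quantitative histology: edge-preserving smoothing + CLAHE, seeded region
# growing into myelin / intra-extra-axonal / edema classes, compartment
# volume fractions, water-content fractions, and lesion morphometry.

#' Preprocess a histology image
#'
#' Perona-Malik anisotropic diffusion (exponential conductance) followed by
#' contrast-limited adaptive histogram equalization. The diffusion smooths
#' within homogeneous regions while preserving edges (conductance decays
#' with the squared gradient); CLAHE normalizes local contrast, which also
#' flattens slowly varying illumination. Output is rescaled to [0, 1].
#'
#' @param image 2-D numeric matrix, values in [0, 1]
#' @param kappa gradient scale of the conductance (intensity units)
#' @param lambda update step (<= 0.25 for stability)
#' @param iterations number of diffusion iterations
#' @param claheTiles CLAHE tile grid (tiles per side)
#' @param claheLimit CLAHE contrast limit (EBImage convention; higher
#'   allows more enhancement)
#' @param clahe set FALSE to skip the equalization step
#' @return preprocessed matrix in [0, 1]
#' @export
preprocessImage <- function(image, kappa = 0.1, lambda = 0.15,
                            iterations = 20, claheTiles = 8,
                            claheLimit = 2, clahe = TRUE) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2-D numeric matrix")
  if (lambda <= 0 || lambda > 0.25)
    stop("lambda must be in (0, 0.25] for a stable explicit scheme")
  out <- .pm_diffuse(image, kappa, lambda, as.integer(iterations))
  if (clahe) {
    # tile counts must divide the image dimensions exactly
    div_near <- function(n, want) {
      for (k in want:1) if (n %% k == 0) return(k)
      1L
    }
    nx <- div_near(nrow(out), claheTiles)
    ny <- div_near(ncol(out), claheTiles)
    eq <- EBImage::clahe(EBImage::Image(out), nx = nx, ny = ny,
                         limit = claheLimit)
    out <- EBImage::imageData(eq)
  }
  rng <- range(out)
  if (diff(rng) > 0) out <- (out - rng[1]) / diff(rng)
  out
}

#' Segment a histology image by seeded region growing
#'
#' Grows regions from user-supplied seeds: a pixel joins the 4-adjacent
#' region whose running mean intensity is within \code{tolerance} of the
#' pixel value; after the queues exhaust, remaining pixels are attached to
#' the neighbouring class with the nearest mean, in deterministic
#' row-major sweeps. The default tolerance is 2.5 x a robust noise SD:
#' the median absolute deviation of intensities about the class centers
#' of an exact 1-D clustering of a pixel subsample.
#'
#' @param image 2-D numeric matrix in [0, 1] (typically preprocessed)
#' @param seeds data.frame with columns \code{row}, \code{col},
#'   \code{class}; class is \code{"my"}, \code{"ie"} or \code{"ed"} (or
#'   integer codes 1-3). Multiple seeds per class are allowed.
#' @param tolerance intensity tolerance; NULL for the robust default
#' @param pixelSize micrometers per pixel for the returned label map
#' @return a \linkS4class{HistologyLabelMap}
#' @export
segmentRegions <- function(image, seeds, tolerance = NULL, pixelSize = 1) {
  if (!is.matrix(image)) stop("image must be a matrix")
  cls <- seeds$class
  if (is.character(cls) || is.factor(cls))
    cls <- match(as.character(cls), c("my", "ie", "ed"))
  cls <- as.integer(cls)
  if (anyNA(cls) || any(cls < 1) || any(cls > 3))
    stop("seed classes must be my/ie/ed (or 1..3)")
  r <- as.integer(seeds$row); cc <- as.integer(seeds$col)
  if (any(r < 1) || any(r > nrow(image)) || any(cc < 1) ||
      any(cc > ncol(image)))
    stop("seeds must lie inside the image")
  # ambiguity guard: seeds of different classes with indistinguishable
  # intensities cannot anchor distinct regions
  if (is.null(tolerance)) {
    # robust within-class noise SD: MAD of intensities about the centers
    # of an exact 1-D clustering of a pixel subsample
    v <- as.vector(image)
    idx <- round(seq(1, length(v), length.out = min(5000, length(v))))
    x <- v[idx]
    kcl <- length(unique(cls))
    labs <- .cluster1d(x, kcl)
    centers <- vapply(seq_len(kcl), function(c) mean(x[labs == c]),
                      numeric(1))
    sdn <- mad(x - centers[labs], center = 0)
    tolerance <- 2.5 * sdn
    if (!is.finite(tolerance) || tolerance <= 0) tolerance <- 1e-6
  }
  pos <- paste(r, cc)
  dup <- duplicated(pos) | duplicated(pos, fromLast = TRUE)
  if (any(dup) && length(unique(cls[dup])) > 1)
    stop("ambiguous seeds: seeds of different classes at the same position")
  lab <- .region_grow(image, r - 1L, cc - 1L, cls, 3L, tolerance)
  histologyLabelMap(lab, pixelSize)
}

#' Automatic seed proposal from intensity modes
#'
#' Convenience for tests and batch runs, standing in for the operator
#' clicks of semi-automatic use: clusters pixel intensities into \code{k}
#' groups (exact 1-D k-means on a subsample) and places seeds on a regular
#' pixel grid wherever the intensity lies within \code{band} robust SDs of
#' a class center. Many seeds per class are returned so that
#' disconnected structures (individual myelin rings, individual lesions)
#' each receive an anchor. Classes are ordered dark to bright, matching
#' the toluidine-blue convention myelin < intra/extra-axonal < edema.
#'
#' @param image 2-D matrix
#' @param k number of classes present (3 or 2)
#' @param nSample intensity subsample size for clustering
#' @param stride seed-grid spacing in pixels
#' @param band half-width of the seed acceptance band, in robust SDs
#' @return seed data.frame (row, col, class)
#' @export
seedsFromModes <- function(image, k = 3, nSample = 5000, stride = 8,
                           band = 1.5) {
  v <- as.vector(image)
  idx <- round(seq(1, length(v), length.out = min(nSample, length(v))))
  x <- v[idx]
  labs <- .cluster1d(x, k)
  centers <- vapply(seq_len(k), function(c) mean(x[labs == c]), numeric(1))
  sdn <- mad(x - centers[labs], center = 0)
  classes <- c("my", "ie", "ed")[seq_len(k)]
  rows <- seq(1 + stride %/% 2, nrow(image), by = stride)
  cols <- seq(1 + stride %/% 2, ncol(image), by = stride)
  gi <- as.matrix(expand.grid(row = rows, col = cols))
  gv <- image[gi]
  out <- lapply(seq_len(k), function(c) {
    sel <- abs(gv - centers[c]) <= band * sdn
    if (!any(sel)) {   # guarantee at least one seed per class
      j <- which.min(abs(v - centers[c]))
      return(data.frame(row = (j - 1) %% nrow(image) + 1,
                        col = (j - 1) %/% nrow(image) + 1,
                        class = classes[c]))
    }
    data.frame(row = gi[sel, 1], col = gi[sel, 2], class = classes[c])
  })
  do.call(rbind, out)
}

# exact 1-D k-means partition (contiguous DP); returns integer class per
# value, classes ordered by center
.cluster1d <- function(x, k) {
  ord <- order(x); xs <- x[ord]; n <- length(xs)
  cs <- c(0, cumsum(xs)); cs2 <- c(0, cumsum(xs^2))
  dp <- matrix(Inf, k, n); arg <- matrix(0L, k, n)
  i1 <- seq_len(n)
  dp[1, ] <- (cs2[i1 + 1] - cs2[1]) - (cs[i1 + 1] - cs[1])^2 / i1
  if (k > 1) for (c in 2:k) for (j in c:n) {
    i <- c:j
    m <- j - i + 1
    cost <- (cs2[j + 1] - cs2[i]) - (cs[j + 1] - cs[i])^2 / m
    v <- dp[c - 1, i - 1] + cost
    b <- which.min(v)
    dp[c, j] <- v[b]; arg[c, j] <- i[b]
  }
  bounds <- integer(k + 1); bounds[k + 1] <- n
  j <- n
  if (k > 1) for (c in k:2) { bounds[c] <- arg[c, j] - 1L; j <- bounds[c] }
  seg <- rep(seq_len(k), diff(bounds))
  out <- integer(n); out[ord] <- seg
  out
}

#' Compartment volume fractions from a label map
#'
#' Class pixel counts divided by the tissue (non-background) pixel count.
#'
#' @param labelmap a \linkS4class{HistologyLabelMap}
#' @return named fractions (my, ie, ed), summing to 1
#' @export
volumeFractions <- function(labelmap) {
  lab <- labelmap@labels
  counts <- tabulate(lab[lab > 0], nbins = 3)
  if (sum(counts) == 0) stop("label map contains no tissue pixels")
  setNames(counts / sum(counts), c("my", "ie", "ed"))
}

#' Water content fraction and compartment water fractions
#'
#' Total water content fraction \code{W = V_my rho_my + V_ie rho_ie +
#' V_ed rho_ed} and compartment water fractions \code{Wx = Vx rhox / W}.
#' The default relative water densities are rho_my = 0.4, rho_ie = 0.8,
#' rho_ed = 1.0.
#'
#' @param v volume fractions, named or ordered (my, ie, ed), summing to 1
#' @param rho relative water densities in the same order
#' @return a \linkS4class{WaterContent}
#' @examples
#' waterContent(c(my = 0.3, ie = 0.6, ed = 0.1))
#' @export
waterContent <- function(v, rho = c(my = 0.4, ie = 0.8, ed = 1.0)) {
  v <- unlist(v); rho <- unlist(rho)
  if (length(v) != 3 || length(rho) != 3)
    stop("v and rho must have three entries (my, ie, ed)")
  if (any(v < 0) || abs(sum(v) - 1) > 1e-9)
    stop("volume fractions must be non-negative and sum to 1")
  if (any(rho <= 0)) stop("water densities must be positive")
  nm <- c("my", "ie", "ed")
  v <- setNames(as.numeric(v), nm); rho <- setNames(as.numeric(rho), nm)
  w <- sum(v * rho)
  if (w == 0) stop("total water content is zero")
  new("WaterContent", v = v, rho = rho, w = w, wx = v * rho / w)
}

#' Lesion morphometry from a label map
#'
#' Labels 8-connected components of the edema class, discards components
#' below \code{minArea} pixels, and reports per-lesion areas, circular
#' equivalent diameters \code{d = 2 sqrt(A / pi)}, the lesion count and
#' the density per square millimeter of tissue.
#'
#' @param labelmap a \linkS4class{HistologyLabelMap}
#' @param minArea minimum component area in pixels (default 4)
#' @return list with count, density (1/mm^2), meanDiameter and sdDiameter
#'   (um), diameters_um, areas_um2 and tissueArea_mm2
#' @export
lesionMetrics <- function(labelmap, minArea = 4) {
  lab <- labelmap@labels
  px <- labelmap@pixelSize
  mask <- matrix(as.integer(lab == .lab_ed), nrow(lab), ncol(lab))
  comp <- .label_components8(mask)
  areas_px <- tabulate(comp[comp > 0])
  areas_px <- areas_px[areas_px >= minArea]
  areas_um2 <- areas_px * px^2
  diam <- 2 * sqrt(areas_um2 / pi)
  tissue_mm2 <- sum(lab > 0) * px^2 * 1e-6
  list(count = length(areas_px),
       density = length(areas_px) / tissue_mm2,
       meanDiameter = if (length(diam)) mean(diam) else NA_real_,
       sdDiameter = if (length(diam) > 1) sd(diam) else NA_real_,
       diameters_um = diam, areas_um2 = areas_um2,
       tissueArea_mm2 = tissue_mm2)
}

#' Read / write histology images and label maps
#'
#' Thin wrappers over the tiff and png packages: grayscale images are
#' matrices in [0, 1]; label maps are stored as 8-bit images with the
#' class code in the integer value.
#'
#' @param path file path (.tif/.tiff or .png)
#' @param image matrix in [0, 1]
#' @export
writeGrayTiff <- function(image, path) {
  tiff::writeTIFF(pmin(pmax(image, 0), 1), path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname writeGrayTiff
#' @export
readGrayTiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' @rdname writeGrayTiff
#' @param labelmap a \linkS4class{HistologyLabelMap}
#' @export
writeLabelTiff <- function(labelmap, path) {
  tiff::writeTIFF(labelmap@labels / 255, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname writeGrayTiff
#' @param pixelSize um/px to attach when reading a label map
#' @export
readLabelTiff <- function(path, pixelSize) {
  m <- round(tiff::readTIFF(path) * 255)
  histologyLabelMap(m, pixelSize)
}
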