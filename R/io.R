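# Readers for the tabular and imaging inputs the fitting functions expect.

#' Read a decay or recovery table from CSV
#'
#' Expects a time column (\code{time_ms} or \code{time_s}) and one or more
#' signal columns; extra columns beyond \code{signal}/\code{roi} are
#' treated as voxel replicates.
#'
#' @param path CSV file path
#' @return list with \code{times} (seconds), \code{signal} (primary
#'   column) and \code{voxels} (matrix or NULL)
#' @export
readDecayCSV <- function(path) {
  d <- read.csv(path)
  if ("time_s" %in% names(d)) times <- d$time_s
  else if ("time_ms" %in% names(d)) times <- d$time_ms / 1e3
  else stop("no time_s or time_ms column in ", path)
  sigcol <- intersect(c("signal", "roi"), names(d))[1]
  if (is.na(sigcol)) stop("no signal/roi column in ", path)
  vox <- d[, setdiff(names(d), c("time_s", "time_ms", sigcol)), drop = FALSE]
  list(times = times, signal = d[[sigcol]],
       voxels = if (ncol(vox)) as.matrix(vox) else NULL)
}

#' Read a NIfTI voxel stack and extract per-voxel decays under a mask
#'
#' Needs the RNifti package. The image must be 3-D or 4-D with the last
#' dimension indexing echo/inversion times; the mask is a 2-D/3-D image of
#' zeros and ones on the matching spatial grid.
#'
#' @param path NIfTI image path
#' @param maskPath NIfTI mask path
#' @return matrix with one column per masked voxel (rows = time points)
#' @export
readNiftiStack <- function(path, maskPath) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI requires the RNifti package")
  img <- RNifti::readNifti(path)
  msk <- RNifti::readNifti(maskPath)
  d <- dim(img)
  nt <- d[length(d)]
  spatial <- prod(d[-length(d)])
  m <- matrix(as.numeric(img), spatial, nt)
  sel <- as.logical(as.numeric(msk) != 0)
  if (length(sel) != spatial) stop("mask does not match image grid")
  t(m[sel, , drop = FALSE])
}
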