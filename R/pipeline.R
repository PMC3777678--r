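# Study-level orchestration: fit every ROI of a bundle, assemble the
# per-(group, animal, tract) metric table, run group comparisons and the
# MRI-vs-histology regressions.

#' Ordinary least squares regression between two metrics
#'
#' @param x,y numeric vectors, length >= 3; x must not be constant
#' @return list with slope, intercept, r2, p_value (two-sided on the
#'   slope) and n
#' @examples
#' regressMetrics(1:5, 2 * (1:5) + 1)
#' @export
regressMetrics <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (var(x) == 0) stop("x is constant; slope undefined")
  fit <- lm(y ~ x)
  # a perfect fit triggers a spurious precision warning from summary.lm
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(x)),
            class = "regressionResult")
}

#' @export
print.regressionResult <- function(x, ...) {
  cat(sprintf("OLS: y = %.4g x + %.4g, r2 = %.3f, p = %.3g, n = %d\n",
              x$slope, x$intercept, x$r2, x$p_value, x$n))
  invisible(x)
}

#' Welch two-sample comparison between groups
#'
#' Welch (unequal-variance) t-test. Degenerate inputs with zero variance
#' in both groups return p = 1 when the means are equal and p = 0
#' otherwise.
#'
#' @param a,b numeric vectors (n >= 2 each)
#' @param alpha significance level
#' @return list with difference (mean(b) - mean(a)), p, significant
#' @export
groupCompare <- function(a, b, alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  d <- mean(b) - mean(a)
  if (var(a) == 0 && var(b) == 0) {
    p <- if (d == 0) 1 else 0
  } else {
    p <- stats::t.test(a, b)$p.value
  }
  list(difference = d, p = p, significant = p < alpha)
}

.read_bundle_truth <- function(bundleDir) {
  f <- file.path(bundleDir, "truth.csv")
  if (!file.exists(f)) stop("bundle has no truth.csv")
  read.csv(f, stringsAsFactors = FALSE)
}

#' Run the full study analysis on a bundle
#'
#' Two-pass MET2 analysis of every ROI decay (fit 1-3 components, F-test
#' selection, then study-wide clustering of all fitted component T2s into
#' classes), SIR-qMT fitting of every inversion-recovery series, optional
#' histology quantification, group comparisons per tract and metric, and
#' the MRI-vs-histology regressions (EWF vs W_ed, MWF vs W_my, PSR vs
#' V_my). The histology columns come from segmented images when the
#' bundle contains them, otherwise from the bundle's ground-truth volume
#' fractions.
#'
#' @param bundleDir a directory written by \code{\link{generateStudy}}
#' @param out optional output directory for CSV reports
#' @param alpha significance level for F-tests and group stars
#' @param voxelwise compute intra-ROI standard errors by voxelwise fits
#'   (slower)
#' @param options MET2 options, see \code{\link{met2Options}}
#' @return list with table (the study data.frame), comparisons,
#'   regressions, breaks (T2 class boundaries, s)
#' @export
runStudy <- function(bundleDir, out = NULL, alpha = 0.05,
                     voxelwise = FALSE, options = met2Options()) {
  truth <- .read_bundle_truth(bundleDir)
  n <- nrow(truth)
  te <- NULL
  fitsel <- vector("list", n)

  # pass 1: per-ROI fits and component counts
  for (i in seq_len(n)) {
    f <- file.path(bundleDir, "met2",
                   sprintf("%s_a%02d_%s.csv", truth$group[i],
                           truth$animal[i], truth$tract[i]))
    d <- read.csv(f)
    te <- d$time_ms / 1e3
    fits <- lapply(1:3, function(m)
      fitGaussianComponents(d$roi, te, m, options))
    nsel <- selectNComponents(fits, length(te), alpha)
    fitsel[[i]] <- list(fit = fits[[nsel]], nsel = nsel, file = f)
  }

  # pass 2: study-wide clustering of component T2s
  allT2 <- unlist(lapply(fitsel, function(x) 10^x$fit@components$center))
  kClasses <- min(3, max(vapply(fitsel, function(x) x$nsel, integer(1))))
  cl <- clusterT2Classes(allT2, kClasses)
  breaks <- attr(cl, "breaks")

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fit <- fitsel[[i]]$fit
    labels <- classifyT2(10^fit@components$center, breaks)
    wf <- computeWaterFractions(fit, labels)

    se <- c(mwf_se = NA_real_, ewf_se = NA_real_)
    if (voxelwise) {
      d <- read.csv(fitsel[[i]]$file)
      vox <- as.matrix(d[, grep("^v", names(d)), drop = FALSE])
      if (ncol(vox) >= 2) {
        vu <- tryCatch(
          voxelwiseUncertainty(vox, te, fitsel[[i]]$nsel, breaks, options),
          error = function(e) NULL)
        if (!is.null(vu)) se <- c(mwf_se = vu$mwf_se, ewf_se = vu$ewf_se)
      }
    }

    fq <- file.path(bundleDir, "sir",
                    sprintf("%s_a%02d_%s.csv", truth$group[i],
                            truth$animal[i], truth$tract[i]))
    qrow <- c(psr_fit = NA_real_, kmf_fit = NA_real_, t1_fit = NA_real_,
              psr_se = NA_real_, kmf_se = NA_real_)
    if (file.exists(fq)) {
      dq <- read.csv(fq)
      qf <- tryCatch(fitSir(dq$signal, dq$time_s), error = function(e) NULL)
      if (!is.null(qf)) {
        est <- qmtEstimates(qf)
        qrow <- c(psr_fit = est[["psr"]], kmf_fit = est[["kmf"]],
                  t1_fit = 1 / est[["r1"]],
                  psr_se = qmtSE(qf)[["psr"]], kmf_se = qmtSE(qf)[["kmf"]])
      }
    } else {
      warning("missing SIR series for ", basename(fq))
    }

    hrow <- c(v_my_h = truth$v_my[i], v_ie_h = truth$v_ie[i],
              v_ed_h = truth$v_ed[i])
    fh <- file.path(bundleDir, "histology",
                    sprintf("%s_a%02d_%s_labels.tiff", truth$group[i],
                            truth$animal[i], truth$tract[i]))
    if (file.exists(fh)) {
      lm_ <- readLabelTiff(fh, pixelSize = 0.075)
      vf <- volumeFractions(lm_)
      hrow <- c(v_my_h = vf[["my"]], v_ie_h = vf[["ie"]],
                v_ed_h = vf[["ed"]])
    }
    wc <- waterContent(c(hrow[["v_my_h"]], hrow[["v_ie_h"]],
                         hrow[["v_ed_h"]]))

    rows[[i]] <- data.frame(
      group = truth$group[i], animal = truth$animal[i],
      tract = truth$tract[i],
      n_components = fitsel[[i]]$nsel,
      mwf = wf@mwf, ewf = wf@ewf,
      mwf_se = se[["mwf_se"]], ewf_se = se[["ewf_se"]],
      psr = qrow[["psr_fit"]], kmf = qrow[["kmf_fit"]],
      t1 = qrow[["t1_fit"]],
      psr_se = qrow[["psr_se"]], kmf_se = qrow[["kmf_se"]],
      v_my = hrow[["v_my_h"]], v_ie = hrow[["v_ie_h"]],
      v_ed = hrow[["v_ed_h"]],
      w = wc@w, w_my = wc@wx[["my"]], w_ed = wc@wx[["ed"]])
  }
  tab <- do.call(rbind, rows)

  # group comparisons per tract and metric (stars as in the figures)
  metrics <- c("mwf", "ewf", "psr", "kmf", "t1")
  groups <- unique(tab$group)
  comparisons <- list()
  if (length(groups) > 1) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    for (tr in unique(tab$tract)) for (m in metrics) for (pr in pairs) {
      a <- tab[tab$tract == tr & tab$group == pr[1], m]
      b <- tab[tab$tract == tr & tab$group == pr[2], m]
      if (sum(is.finite(a)) >= 2 && sum(is.finite(b)) >= 2) {
        gc <- groupCompare(a, b, alpha)
        comparisons[[length(comparisons) + 1]] <- data.frame(
          tract = tr, metric = m, group_a = pr[1], group_b = pr[2],
          difference = gc$difference, p = gc$p,
          significant = gc$significant)
      }
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons)
                 else NULL

  regressions <- list(
    ewf_wed = tryCatch(regressMetrics(tab$w_ed, tab$ewf),
                       error = function(e) NULL),
    mwf_wmy = tryCatch(regressMetrics(tab$w_my, tab$mwf),
                       error = function(e) NULL),
    psr_vmy = tryCatch(regressMetrics(tab$v_my, tab$psr),
                       error = function(e) NULL))

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(out, "study_table.csv"), row.names = FALSE)
    if (!is.null(comparisons))
      write.csv(comparisons, file.path(out, "group_comparisons.csv"),
                row.names = FALSE)
    reg_df <- do.call(rbind, lapply(names(regressions), function(nm) {
      r <- regressions[[nm]]
      if (is.null(r)) return(NULL)
      data.frame(comparison = nm, slope = r$slope, intercept = r$intercept,
                 r2 = r$r2, p_value = r$p_value, n = r$n)
    }))
    if (!is.null(reg_df))
      write.csv(reg_df, file.path(out, "regressions.csv"),
                row.names = FALSE)
  }

  list(table = tab, comparisons = comparisons, regressions = regressions,
       breaks = breaks)
}
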