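# Study-level synthetic bundle: 3 diet groups x 4 spinal white matter
# tracts, with per-animal decays, SIR series, ground-truth tables and
# (optionally) histology images, all reproducible from (config, seed).

#' Default study configuration
#'
#' Emulates a three-group (control / moderate / severe intoxication) by
#' four-tract (dCST, FG, RST, VST) design. Per tract the configuration
#' fixes the short-T2 (myelin) water fraction and the edema water
#' fraction targets; the edema pool exchanges with the adjacent
#' intra/extra-axonal water with a 200 ms residence time. Water exchange
#' is modelled as local to the lesion neighbourhood: the exchanging
#' subsystem keeps a 3:1 ie:edema composition (the composition of the
#' worked two-pool example), so the apparent long-T2 amplitude is twice
#' the edema water fraction for every tract. qMT truth shows a small PSR
#' decrease and T1 increase with intoxication severity.
#'
#' @param nAnimals animals per group
#' @param nVoxels voxels simulated per ROI (for intra-ROI standard errors)
#' @param snrMet2 SNR of the ROI-mean decay (Gaussian noise; voxel decays
#'   get Rician noise at snrMet2 / sqrt(nVoxels))
#' @param snrQmt SNR of the SIR series
#' @param tauEd residence time of the edema pool, seconds
#' @param interAnimalCv lognormal coefficient of variation applied to the
#'   per-animal edema fraction (and half of it to the myelin fraction)
#' @return nested configuration list
#' @export
studyConfig <- function(nAnimals = 8, nVoxels = 25, snrMet2 = 1000,
                        snrQmt = 200, tauEd = 0.2, interAnimalCv = 0.12) {
  tracts <- c("dCST", "FG", "RST", "VST")
  wMy <- c(dCST = 0.12, FG = 0.14, RST = 0.18, VST = 0.16)
  wEd <- list(
    control = c(dCST = 0, FG = 0, RST = 0, VST = 0),
    HCP300 = c(dCST = 0.08, FG = 0.06, RST = 0.05, VST = 0.04),
    HCP600 = c(dCST = 0.15, FG = 0.13, RST = 0.10, VST = 0.09))
  psr0 <- c(control = 0.16, HCP300 = 0.15, HCP600 = 0.14)
  r1 <- c(control = 0.55, HCP300 = 0.53, HCP600 = 0.51)
  groups <- lapply(names(wEd), function(g) {
    tr <- lapply(tracts, function(t) {
      list(wMy = wMy[[t]], wEd = wEd[[g]][[t]],
           qmt = list(psr = psr0[[g]] + 0.005 * (match(t, tracts) - 2.5),
                      kmf = 11, r1 = r1[[g]], sf = -0.95, sm = 0.83))
    })
    names(tr) <- tracts
    list(tracts = tr)
  })
  names(groups) <- names(wEd)
  list(groups = groups, nAnimals = nAnimals, nVoxels = nVoxels,
       snrMet2 = snrMet2, snrQmt = snrQmt, tauEd = tauEd,
       interAnimalCv = interAnimalCv,
       t2 = c(my = 0.015, ie = 0.060, ed = 0.300),
       rho = c(my = 0.4, ie = 0.8, ed = 1.0),
       echoScheme = unclass(echoScheme()),
       inversionTimes = list(n = 25, tmin = 0.0035, tmax = 10))
}

# pool system for one (tract, animal): myelin pool, far intra/extra-axonal
# pool, and an exchanging (ie_near, edema) subsystem with 3:1 composition
.tract_system <- function(wMy, wEd, t2, tauEd) {
  if (wEd <= 0) {
    return(poolSystem(c(wMy, 1 - wMy), t2 = c(t2[["my"]], t2[["ie"]])))
  }
  f <- c(wMy, 1 - wMy - 4 * wEd, 3 * wEd, wEd)
  if (any(f <= 0)) stop("infeasible tract fractions")
  k <- matrix(0, 4, 4)
  k[4, 3] <- 1 / tauEd
  k[3, 4] <- k[4, 3] * f[4] / f[3]
  poolSystem(f, t2 = c(t2[["my"]], t2[["ie"]], t2[["ie"]], t2[["ed"]]),
             k = k)
}

# water-compartment volume fractions consistent with the signal (water)
# fractions: Vx proportional to Wx / rhox
.volumes_from_water <- function(wx, rho) {
  v <- wx / rho
  v / sum(v)
}

#' Generate a complete synthetic study bundle
#'
#' Writes, for every (group, animal, tract): a multi-echo ROI decay with
#' per-voxel replicates (\code{met2/}), a SIR series (\code{sir/}), and a
#' ground-truth table (\code{truth.csv}) holding the per-animal water
#' fractions, volume fractions and qMT parameters. With
#' \code{histology = TRUE}, also writes a histology image and label map
#' per (histology animal, tract) whose lesion density is derived from the
#' tract's edema volume fraction. Re-running with the same (config, seed)
#' reproduces the bundle byte for byte.
#'
#' @param config see \code{\link{studyConfig}}
#' @param seed integer master seed
#' @param outDir output directory
#' @param overwrite allow writing into an existing non-empty directory
#' @param histology generate histology images for the first
#'   \code{nHistologyAnimals} animals per group
#' @param nHistologyAnimals animals per group with histology
#' @param histologyGrid image grid for generated histology (smaller grids
#'   speed up large studies)
#' @return invisibly, the truth table data.frame
#' @export
generateStudy <- function(config = studyConfig(), seed = 1, outDir,
                          overwrite = FALSE, histology = FALSE,
                          nHistologyAnimals = 3,
                          histologyGrid = c(800, 600)) {
  if (dir.exists(outDir) && length(dir(outDir)) && !overwrite)
    stop("output directory exists and is not empty (use overwrite = TRUE)")
  dir.create(file.path(outDir, "met2"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "sir"), showWarnings = FALSE)
  if (histology)
    dir.create(file.path(outDir, "histology"), showWarnings = FALSE)

  te_s <- makeEchoTimes(do.call(echoScheme, config$echoScheme)) / 1e3
  ti <- makeInversionTimes(config$inversionTimes$n,
                           config$inversionTimes$tmin,
                           config$inversionTimes$tmax)
  rows <- list()
  idx <- 0
  for (g in names(config$groups)) {
    for (a in seq_len(config$nAnimals)) {
      for (tr in names(config$groups[[g]]$tracts)) {
        idx <- idx + 1
        base <- config$groups[[g]]$tracts[[tr]]
        s_jit <- (seed * 1009 + idx * 7 + 1) %% .Machine$integer.max
        jit <- .with_seed(s_jit, {
          cv <- config$interAnimalCv
          c(ed = if (base$wEd > 0)
              exp(rnorm(1, -log(1 + cv^2) / 2, sqrt(log(1 + cv^2)))) else 1,
            my = exp(rnorm(1, -log(1 + (cv / 2)^2) / 2,
                           sqrt(log(1 + (cv / 2)^2)))),
            qmt = exp(rnorm(3, 0, 0.03)))
        })
        wEd <- base$wEd * jit[["ed"]]
        wMy <- base$wMy * jit[["my"]]
        # keep the 4-pool split feasible for extreme draws
        if (wEd > 0) wEd <- min(wEd, (1 - wMy) / 4 - 0.05)
        sys <- .tract_system(wMy, wEd, config$t2, config$tauEd)
        wIe <- 1 - wMy - wEd
        wx <- c(my = wMy, ie = wIe, ed = wEd)
        v <- .volumes_from_water(wx, config$rho)
        w_total <- 1 / sum(wx / config$rho)  # W with sum(V)=1

        # voxel decays: Rician; ROI decay: their mean-equivalent with
        # Gaussian noise at the ROI SNR
        nv <- config$nVoxels
        s_vox <- (seed * 2003 + idx * 13 + 2) %% .Machine$integer.max
        vox <- .with_seed(s_vox, {
          snr_v <- config$snrMet2 / sqrt(nv)
          vapply(seq_len(nv), function(i)
            simulateRoiDecay(sys, te_s, snr = snr_v, nAvg = 1,
                             noise = "rician"),
            numeric(length(te_s)))
        })
        s_roi <- (seed * 3001 + idx * 17 + 3) %% .Machine$integer.max
        roi <- simulateRoiDecay(sys, te_s, snr = config$snrMet2,
                                seed = s_roi, noise = "gaussian")
        met2_df <- data.frame(time_ms = te_s * 1e3, roi = roi)
        met2_df <- cbind(met2_df, as.data.frame(vox))
        names(met2_df)[-(1:2)] <- paste0("v", seq_len(nv))
        write.csv(met2_df,
                  file.path(outDir, "met2",
                            sprintf("%s_a%02d_%s.csv", g, a, tr)),
                  row.names = FALSE)

        qp <- qmtParams(m0 = 1,
                        psr = base$qmt$psr * jit[["qmt1"]],
                        kmf = base$qmt$kmf * jit[["qmt2"]],
                        r1 = base$qmt$r1 * jit[["qmt3"]],
                        sf = base$qmt$sf, sm = base$qmt$sm)
        s_sir <- (seed * 4001 + idx * 19 + 4) %% .Machine$integer.max
        sir <- simulateSirSeries(qp, ti, snr = config$snrQmt, seed = s_sir,
                                 noise = "gaussian")
        write.csv(data.frame(time_s = ti, signal = sir),
                  file.path(outDir, "sir",
                            sprintf("%s_a%02d_%s.csv", g, a, tr)),
                  row.names = FALSE)

        if (histology && a <= nHistologyAnimals) {
          mean_area_mm2 <- pi / 4 * (3.1^2 + 0.4^2) * 1e-6
          dens <- v[["ed"]] / mean_area_mm2
          hp <- histologyGenParams(grid = histologyGrid,
                                   fov = histologyGrid * 0.075,
                                   lesionDensity = dens)
          s_h <- (seed * 5003 + idx * 23 + 5) %% .Machine$integer.max
          h <- generateHistologyImage(hp, seed = s_h)
          stem <- sprintf("%s_a%02d_%s", g, a, tr)
          writeGrayTiff(h$image,
                        file.path(outDir, "histology",
                                  paste0(stem, ".tiff")))
          writeLabelTiff(h$labelMap,
                         file.path(outDir, "histology",
                                   paste0(stem, "_labels.tiff")))
        }

        rows[[idx]] <- data.frame(
          group = g, animal = a, tract = tr,
          w_my = wMy, w_ie = wIe, w_ed = wEd,
          v_my = v[["my"]], v_ie = v[["ie"]], v_ed = v[["ed"]],
          w = w_total,
          psr = qp@psr, kmf = qp@kmf, r1 = qp@r1, t1 = 1 / qp@r1,
          n_pools = length(sys@fractions))
      }
    }
  }
  truth <- do.call(rbind, rows)
  write.csv(truth, file.path(outDir, "truth.csv"), row.names = FALSE)
  cfg <- config
  cfg$seed <- seed
  jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}
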