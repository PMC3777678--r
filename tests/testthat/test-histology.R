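test_that("anisotropic diffusion leaves a constant image unchanged", {
  img <- matrix(0.4, 30, 30)
  out <- imerelax:::.pm_diffuse(img, 0.1, 0.15, 20L)
  expect_equal(out, img, tolerance = 1e-12)
})

test_that("diffusion smooths within regions but preserves the step edge", {
  set.seed(1)
  img <- cbind(matrix(0.2, 60, 30), matrix(0.8, 60, 30)) +
    matrix(rnorm(3600, 0, 0.05), 60)
  out <- imerelax:::.pm_diffuse(img, 0.1, 0.15, 20L)
  # within-region variance falls at least 5x
  v_in <- var(as.vector(img[, 5:25])); v_out <- var(as.vector(out[, 5:25]))
  expect_gt(v_in / v_out, 5)
  # the half-maximum crossing stays within one pixel of column 30/31
  prof <- colMeans(out)
  cross <- which(prof > 0.5)[1]
  expect_lte(abs(cross - 31), 1)
  # a second pass changes the image less than the first (contraction)
  out2 <- imerelax:::.pm_diffuse(out, 0.1, 0.15, 20L)
  expect_lt(sqrt(mean((out2 - out)^2)), sqrt(mean((out - img)^2)))
})

test_that("preprocessing rejects malformed inputs", {
  expect_error(preprocessImage(array(0, c(3, 3, 3))), "matrix")
  expect_error(preprocessImage(matrix(0.5, 8, 8), lambda = 0.4), "lambda")
})

test_that("noise-free three-intensity images segment exactly", {
  img <- matrix(0.55, 40, 40)
  img[5:15, 5:15] <- 0.2       # myelin block
  img[25:32, 25:32] <- 0.9     # edema block
  seeds <- data.frame(row = c(10, 2, 28), col = c(10, 2, 28),
                      class = c("my", "ie", "ed"))
  seg <- segmentRegions(img, seeds, tolerance = 0.05, pixelSize = 1)
  truth <- matrix(2L, 40, 40)
  truth[5:15, 5:15] <- 1L; truth[25:32, 25:32] <- 3L
  expect_identical(labelMatrix(seg), truth)
  # seed order does not matter
  seg2 <- segmentRegions(img, seeds[c(3, 1, 2), ], tolerance = 0.05,
                         pixelSize = 1)
  expect_identical(labelMatrix(seg2), labelMatrix(seg))
  expect_error(segmentRegions(img, data.frame(row = c(10, 10),
                                              col = c(10, 10),
                                              class = c("my", "ie"))),
               "ambiguous|coincide")
})

test_that("segmentation round-trips the histology generator within 0.02", {
  p <- histologyGenParams(grid = c(400, 300), fov = c(30, 22.5),
                          lesionDensity = 3000)
  h <- generateHistologyImage(p, seed = 12)
  pre <- preprocessImage(h$image)
  seg <- segmentRegions(pre, seedsFromModes(pre),
                        pixelSize = pixelSize(h$labelMap))
  vf <- volumeFractions(seg)
  expect_lt(max(abs(vf - h$truth)), 0.02)
})

test_that("volume fractions count pixels per class", {
  lab <- matrix(2L, 20, 20)
  lab[1:6, ] <- 1L          # 30% myelin
  lab[19:20, ] <- 3L        # 10% edema
  lm <- histologyLabelMap(lab, 0.1)
  expect_equal(volumeFractions(lm), c(my = 0.3, ie = 0.6, ed = 0.1))
  # rotation invariance
  rot <- histologyLabelMap(t(lab[nrow(lab):1, ]), 0.1)
  expect_equal(volumeFractions(rot), volumeFractions(lm))
  # single-class map
  expect_equal(volumeFractions(histologyLabelMap(matrix(1L, 4, 4), 1)),
               c(my = 1, ie = 0, ed = 0))
  expect_error(volumeFractions(histologyLabelMap(matrix(0L, 4, 4), 1)),
               "tissue")
})

test_that("water content follows the density-weighted mixture formulas", {
  wc <- waterContent(c(my = 1, ie = 0, ed = 0))
  expect_equal(wc@w, 0.4)
  expect_equal(wc@wx[["my"]], 1)
  wc2 <- waterContent(c(my = 0, ie = 0, ed = 1))
  expect_equal(wc2@w, 1.0)
  expect_equal(wc2@wx[["ed"]], 1)
  wc3 <- waterContent(c(my = 0.3, ie = 0.6, ed = 0.1))
  expect_equal(wc3@w, 0.3 * 0.4 + 0.6 * 0.8 + 0.1 * 1.0)  # 0.70
  expect_equal(wc3@wx[["my"]], 0.12 / 0.70, tolerance = 1e-12)
  expect_equal(wc3@wx[["ie"]], 0.48 / 0.70, tolerance = 1e-12)
  expect_equal(wc3@wx[["ed"]], 0.10 / 0.70, tolerance = 1e-12)
  expect_equal(sum(wc3@wx), 1, tolerance = 1e-12)
  # W increases with edema at fixed myelin (rho_ed > rho_ie)
  w_lo <- waterContent(c(0.3, 0.65, 0.05))@w
  w_hi <- waterContent(c(0.3, 0.55, 0.15))@w
  expect_gt(w_hi, w_lo)
  expect_error(waterContent(c(0.5, 0.2, 0.1)), "sum to 1")
})

test_that("lesion metrics recover disk geometry and density", {
  lab <- matrix(2L, 400, 400)
  # one disk of radius 10 px at 0.075 um/px -> diameter 1.5 um
  ctr <- c(200, 200)
  for (i in 1:400) for (j in 1:400)
    if ((i - ctr[1])^2 + (j - ctr[2])^2 <= 10^2) lab[i, j] <- 3L
  lm <- histologyLabelMap(lab, 0.075)
  met <- lesionMetrics(lm)
  expect_equal(met$count, 1)
  expect_equal(met$meanDiameter, 1.5, tolerance = 0.075)  # 1 px quantization

  # one lesion in a full 120 x 90 um^2 field: density 1 / 0.0108 mm^2
  lab2 <- matrix(2L, 1200, 1600)
  lab2[600 + (-5:5), 800 + (-5:5)] <- 3L
  met2 <- lesionMetrics(histologyLabelMap(lab2, 0.075))
  expect_equal(met2$density, 1 / (0.120 * 0.090), tolerance = 1e-6)

  # non-touching disks are counted exactly; tiny specks are filtered
  lab3 <- matrix(2L, 100, 100)
  lab3[10:14, 10:14] <- 3L
  lab3[40:44, 60:64] <- 3L
  lab3[80, 80] <- 3L            # 1 px < minArea
  met3 <- lesionMetrics(histologyLabelMap(lab3, 0.1))
  expect_equal(met3$count, 2)

  # diagonal connectivity joins components
  lab4 <- matrix(0L, 10, 10)
  lab4[3, 3] <- 3L; lab4[4, 4] <- 3L; lab4[5, 5] <- 3L; lab4[6, 6] <- 3L
  lab4[1, 1] <- 2L  # a tissue pixel so density is defined
  met4 <- lesionMetrics(histologyLabelMap(lab4, 1), minArea = 2)
  expect_equal(met4$count, 1)
})

test_that("images and label maps round-trip through TIFF", {
  dir <- withr::local_tempdir()
  img <- matrix(runif(120), 10, 12)
  f <- file.path(dir, "img.tiff")
  writeGrayTiff(img, f)
  expect_equal(readGrayTiff(f), img, tolerance = 1e-4)
  lab <- matrix(sample(0:3, 120, replace = TRUE), 10, 12)
  lm <- histologyLabelMap(lab, 0.075)
  fl <- file.path(dir, "lab.tiff")
  writeLabelTiff(lm, fl)
  lm2 <- readLabelTiff(fl, 0.075)
  expect_identical(labelMatrix(lm2), labelMatrix(lm))
})
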