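test_that("study bundles are byte-identical for the same (config, seed)", {
  cfg <- studyConfig(nAnimals = 1, nVoxels = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generateStudy(cfg, seed = 4, outDir = d1, overwrite = TRUE)
  generateStudy(cfg, seed = 4, outDir = d2, overwrite = TRUE)
  expect_identical(readLines(file.path(d1, "truth.csv")),
                   readLines(file.path(d2, "truth.csv")))
  f <- "HCP600_a01_dCST.csv"
  expect_identical(readLines(file.path(d1, "met2", f)),
                   readLines(file.path(d2, "met2", f)))
  expect_identical(readLines(file.path(d1, "sir", f)),
                   readLines(file.path(d2, "sir", f)))
  # different seed, different noise
  d3 <- withr::local_tempdir()
  generateStudy(cfg, seed = 5, outDir = d3, overwrite = TRUE)
  expect_false(identical(readLines(file.path(d1, "met2", f)),
                         readLines(file.path(d3, "met2", f))))
})

test_that("an existing non-empty output directory is protected", {
  cfg <- studyConfig(nAnimals = 1, nVoxels = 2)
  d <- withr::local_tempdir()
  generateStudy(cfg, seed = 4, outDir = d, overwrite = TRUE)
  expect_error(generateStudy(cfg, seed = 4, outDir = d), "overwrite")
})

test_that("study truth tables are internally consistent", {
  cfg <- studyConfig(nAnimals = 2, nVoxels = 2)
  d <- withr::local_tempdir()
  truth <- generateStudy(cfg, seed = 8, outDir = d, overwrite = TRUE)
  expect_equal(truth$w_my + truth$w_ie + truth$w_ed, rep(1, nrow(truth)),
               tolerance = 1e-9)
  expect_equal(truth$v_my + truth$v_ie + truth$v_ed, rep(1, nrow(truth)),
               tolerance = 1e-9)
  # W = sum(V rho) with rho = (0.4, 0.8, 1.0)
  expect_equal(truth$w,
               0.4 * truth$v_my + 0.8 * truth$v_ie + 1.0 * truth$v_ed,
               tolerance = 1e-9)
  # controls are two-pool, intoxicated tracts four-pool
  expect_true(all(truth$n_pools[truth$group == "control"] == 2))
  expect_true(all(truth$n_pools[truth$group != "control"] == 4))
})

test_that("group-level component selection responds to the study design", {
  # control tracts (2 pools) select 2 components, severe-intoxication
  # tracts (edema pool with exchange) select 3, at the study SNR
  cfg <- studyConfig(nAnimals = 3, nVoxels = 2)
  d <- withr::local_tempdir()
  generateStudy(cfg, seed = 13, outDir = d, overwrite = TRUE)
  te <- makeEchoTimes() / 1e3
  sel_of <- function(g) {
    files <- dir(file.path(d, "met2"), pattern = paste0("^", g),
                 full.names = TRUE)
    vapply(files, function(f) {
      dd <- read.csv(f)
      fits <- lapply(1:3, function(n)
        fitGaussianComponents(dd$roi, te, n))
      selectNComponents(fits, length(te))
    }, integer(1))
  }
  expect_gte(mean(sel_of("control") == 2), 0.9)
  expect_gte(mean(sel_of("HCP600") == 3), 0.9)
})
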