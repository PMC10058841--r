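test_that("calibration reproduces the ratio formula element-wise", {
  set.seed(42)
  n <- 40
  vt <- matrix(runif(101 * n, 0.1, 5), n, 101)
  vb <- runif(101, 0.5, 4)
  rb <- runif(101, 0.8, 0.99)
  cloud <- SpectralPointCloud(matrix(rnorm(3 * n), n, 3), vt,
                              kind = "intensity")
  panel <- ReferencePanel(vb, rb)
  out <- calibrateReflectance(cloud, panel)
  expect_identical(spectraKind(out), "reflectance")
  expect_equal(unname(spectra(out)), oracle_calibrate(vt, vb, rb),
               tolerance = 1e-14)
  # coordinates and labels pass through bit-for-bit
  expect_identical(coords(out), coords(cloud))
  # linearity: doubling V_t doubles rho_t
  cloud2 <- SpectralPointCloud(coords(cloud), 2 * vt, kind = "intensity")
  expect_equal(spectra(calibrateReflectance(cloud2, panel)),
               2 * spectra(out), tolerance = 1e-14)
  # scale invariance: common factor on V_t and V_b cancels
  panel3 <- ReferencePanel(3 * vb, rb)
  cloud3 <- SpectralPointCloud(coords(cloud), 3 * vt, kind = "intensity")
  expect_equal(spectra(calibrateReflectance(cloud3, panel3)), spectra(out),
               tolerance = 1e-12)
})

test_that("identity and single-channel calibration cases", {
  vb <- rep(1, 101)
  cloud <- SpectralPointCloud(matrix(0, 1, 3), matrix(1, 1, 101),
                              kind = "intensity")
  out <- calibrateReflectance(cloud, ReferencePanel(vb, 0.99))
  expect_equal(unname(spectra(out))[1, ], rep(0.99, 101))
  vt <- matrix(1, 1, 101); vt[1, 47] <- 0.5
  out2 <- calibrateReflectance(
    SpectralPointCloud(matrix(0, 1, 3), vt, kind = "intensity"),
    ReferencePanel(vb, 0.99))
  expect_equal(unname(spectra(out2))[1, 47], 0.495)
})

test_that("calibration rejects reflectance input and bad panels", {
  refl <- randomCloud(3, seed = 1)
  panel <- ReferencePanel(rep(1, 101))
  expect_error(calibrateReflectance(refl, panel), "already reflectance")
  expect_error(ReferencePanel(c(rep(1, 100), 0)), "strictly positive")
  expect_error(ReferencePanel(rep(1, 101), reflectance = 1.2), "\\(0, 1\\]")
  small <- SpectralPointCloud(matrix(0, 1, 3), matrix(1, 1, 11),
                              kind = "intensity",
                              grid = WavelengthGrid(550, 600, 5))
  expect_error(calibrateReflectance(small, panel), "grids differ")
})

test_that("negative intensities give negative reflectance unless clamped", {
  vt <- matrix(0.5, 2, 101); vt[1, 10] <- -0.2
  cloud <- SpectralPointCloud(matrix(rnorm(6), 2, 3), vt, kind = "intensity")
  panel <- ReferencePanel(rep(1, 101))
  expect_lt(spectra(calibrateReflectance(cloud, panel))[1, 10], 0)
  expect_equal(unname(spectra(calibrateReflectance(cloud, panel,
                                                   clampZero = TRUE))[1, 10]),
               0)
})

test_that("background segmentation separates two range-axis clusters", {
  set.seed(9)
  # sample at y ~ 5.00, backdrop cloth 10 cm behind at y ~ 5.10
  ys <- c(rnorm(20, 5.00, 0.005), rnorm(15, 5.10, 0.005))
  cl <- SpectralPointCloud(cbind(runif(35), ys, runif(35)),
                           matrix(0.3, 35, 101))
  near <- segmentBackground(cl, cut = 5.05, keep = "near")
  far <- segmentBackground(cl, cut = 5.05, keep = "far")
  expect_equal(nPoints(near), 20L)
  expect_equal(nPoints(far), 15L)
  expect_true(all(coords(near)[, "y"] < 5.05))
  # partition: no loss, no duplication
  expect_equal(sort(c(coords(near)[, "y"], coords(far)[, "y"])), sort(ys))
})

test_that("segmentation matches an independent filter on random points", {
  spc <- randomCloud(1000, seed = 77)
  cut <- median(coords(spc)[, "y"])
  near <- segmentBackground(spc, cut = cut, keep = "near")
  expect_equal(nPoints(near), sum(coords(spc)[, "y"] < cut))
  keep <- coords(spc)[, "y"] < cut
  expect_equal(unname(spectra(near)), unname(spectra(spc)[keep, ]))
  expect_identical(as.character(pointLabels(near)),
                   as.character(pointLabels(spc))[keep])
})

test_that("segmenting an empty cloud returns an empty cloud", {
  empty <- SpectralPointCloud(matrix(0, 0, 3), matrix(0, 0, 101))
  expect_equal(nPoints(segmentBackground(empty, cut = 1)), 0L)
})

test_that("panel CSVs resolve by exact wavelength match", {
  g <- WavelengthGrid(550, 600, 5)
  pv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength_nm = seq(550, 600, 5), value = 1:11), pv,
            row.names = FALSE)
  panel <- readPanel(pv, grid = g)
  expect_equal(panelVoltages(panel), as.numeric(1:11))
  expect_equal(panelReflectance(panel), rep(0.99, 11))
  # off-grid wavelength is an error
  write.csv(data.frame(wavelength_nm = c(seq(550, 595, 5), 602), value = 1:11),
            pv, row.names = FALSE)
  expect_error(readPanel(pv, grid = g), "off the grid")
  # missing grid wavelength is an error
  write.csv(data.frame(wavelength_nm = seq(550, 595, 5), value = 1:10), pv,
            row.names = FALSE)
  expect_error(readPanel(pv, grid = g), "600")
})
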