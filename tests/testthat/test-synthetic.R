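test_that("component counts and labels honor the configuration", {
  spc <- generateScene(sceneConfig(counts = c(UnripeFruit = 10, RipeFruit = 10,
                                              Wood = 10, Leaf = 10), seed = 1))
  expect_equal(nPoints(spc), 40L)
  expect_equal(unname(table(pointLabels(spc))), rep(10L, 4),
               ignore_attr = TRUE)
})

test_that("scenes are bit-identical for a fixed seed", {
  cfg <- sceneConfig(counts = c(UnripeFruit = 60, RipeFruit = 60,
                                Wood = 90, Leaf = 90), seed = 33)
  a <- generateScene(cfg)
  b <- generateScene(cfg)
  expect_identical(coords(a), coords(b))
  expect_identical(spectra(a), spectra(b))
  expect_identical(pointLabels(a), pointLabels(b))
  expect_identical(edgeFlags(a), edgeFlags(b))
})

test_that("edge fraction zero yields no edge flags", {
  spc <- smallScene(seed = 2, edgeFraction = 0)
  expect_false(any(edgeFlags(spc)))
})

test_that("empirical edge fraction tracks the configured value", {
  fracs <- vapply(1:10, function(s) {
    geo <- sampleComponentGeometry(sceneConfig(seed = s))
    mean(geo$edge)
  }, numeric(1))
  expect_true(all(abs(fracs - 0.15) <= 0.03))
})

test_that("template base curves satisfy their shape constraints", {
  wl <- gridWavelengths(WavelengthGrid())
  wood <- spectralTemplate("Wood")$base(wl)
  expect_true(all(diff(wood) >= 0))
  for (cl in c("Leaf", "UnripeFruit")) {
    b <- spectralTemplate(cl)$base
    expect_gte(b(800), 2 * b(680))  # red edge
  }
  ripe <- spectralTemplate("RipeFruit")$base(seq(600, 900, 5))
  expect_true(all(ripe >= 0.15 & ripe <= 0.25))  # ~20% plateau
})

test_that("zero-noise spectra reproduce the template closed forms", {
  tm <- spectralTemplate("Leaf", noiseSd = 0, edgeScaleSd = 0)
  wl <- gridWavelengths(WavelengthGrid())
  ne <- synthSpectrum(3, tm, edge = FALSE)
  expect_equal(ne, matrix(tm$base(wl), 3, 101, byrow = TRUE))
  # flattening 0: edge is exactly the attenuated base, mean lower by
  # the relative excess
  tm0 <- spectralTemplate("Leaf", noiseSd = 0, edgeScaleSd = 0,
                          edgeFlatten = 0)
  ed <- synthSpectrum(1, tm0, edge = TRUE)
  expect_equal(ed[1, ], tm0$base(wl) / (1 + tm0$edgeExcess))
  expect_equal(mean(tm0$base(wl)) / mean(ed[1, ]) - 1, tm0$edgeExcess,
               tolerance = 1e-12)
})

test_that("non-edge mean reflectance exceeds the edge mean by the configured class excesses", {
  # deterministic check of the parameterization (no per-point brightness
  # jitter), then a Monte-Carlo check under the full noise model
  wl <- gridWavelengths(WavelengthGrid())
  want <- c(UnripeFruit = 0.1036, RipeFruit = 0.1781,
            Wood = 0.1106, Leaf = 0.1818)
  for (cl in componentLevels()) {
    tm <- spectralTemplate(cl, noiseSd = 0, edgeScaleSd = 0)
    ed <- synthSpectrum(1, tm, edge = TRUE)
    expect_equal(mean(tm$base(wl)) / mean(ed[1, ]) - 1, want[[cl]],
                 tolerance = 1e-12)
  }
  set.seed(71)
  tm <- spectralTemplate("Leaf")
  ne <- synthSpectrum(4000, tm, edge = FALSE)
  ed <- synthSpectrum(4000, tm, edge = TRUE)
  expect_equal(mean(ne) / mean(ed) - 1, 0.1818, tolerance = 0.14)
})

test_that("class-mean index orderings match the spectral physiology", {
  spc <- generateScene(sceneConfig(counts = c(UnripeFruit = 250,
                                              RipeFruit = 250, Wood = 250,
                                              Leaf = 250), seed = 41))
  fx <- extractFeatures(spc)
  lab <- pointLabels(spc)
  ne <- !edgeFlags(spc)
  ndvi <- tapply(fx[ne, "NDVI"], lab[ne], mean)
  expect_gt(ndvi[["Leaf"]], ndvi[["Wood"]])
  expect_gt(ndvi[["UnripeFruit"]], ndvi[["Wood"]])
  ci <- tapply(fx[ne, "CI_red_edge"], lab[ne], mean)
  expect_lt(ci[["RipeFruit"]], ci[["Leaf"]])
  # edge spectra are darker in the NIR averaging window
  avg_ne <- tapply(fx[ne, "AVG_R760_R930"], lab[ne], mean)
  avg_ed <- tapply(fx[!ne, "AVG_R760_R930"], lab[!ne], mean)
  expect_true(all(avg_ed < avg_ne))
})

test_that("intensity scenes calibrate back to the reflectance scene", {
  cfg <- sceneConfig(counts = c(UnripeFruit = 30, RipeFruit = 30,
                                Wood = 40, Leaf = 40), seed = 9)
  refl <- generateScene(cfg)
  inten <- generateScene(cfg, kind = "intensity")
  expect_identical(spectraKind(inten), "intensity")
  back <- calibrateReflectance(inten, syntheticPanel())
  expect_equal(spectra(back), spectra(refl), tolerance = 1e-12)
})
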