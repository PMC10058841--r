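test_that("CSV clouds round-trip coords, spectra and labels", {
  spc <- randomCloud(50, seed = 101)
  for (fmt in c("csv", "ply")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeCloud(spc, path, format = fmt)
    back <- readCloud(path, format = fmt)
    expect_equal(coords(back), coords(spc), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(unname(spectra(back)), unname(spectra(spc)),
                 tolerance = 1e-6)
    expect_identical(as.character(pointLabels(back)),
                     as.character(pointLabels(spc)))
    expect_identical(spectraKind(back), "reflectance")
  }
})

test_that("an unlabeled 2-point reflectance CSV reads as such", {
  path <- withr::local_tempfile(fileext = ".csv")
  spc <- randomCloud(2, labeled = FALSE, seed = 5)
  writeCloud(spc, path)
  back <- readCloud(path)
  expect_equal(nPoints(back), 2L)
  expect_identical(spectraKind(back), "reflectance")
  expect_null(pointLabels(back))
})

test_that("intensity-kind columns (v prefix) set the spectra kind", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeCloud(randomCloud(3, kind = "intensity", seed = 8), path)
  expect_identical(spectraKind(readCloud(path)), "intensity")
})

test_that("wrong spectral column sets are format errors naming a column", {
  spc <- randomCloud(2, labeled = FALSE, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  writeCloud(spc, path)
  df <- read.csv(path, check.names = FALSE)
  # 103 spectral columns: two extra wavelengths beyond the grid
  df2 <- cbind(df, r1055 = 0.1, r1060 = 0.2)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, p2, row.names = FALSE)
  expect_error(readCloud(p2), "r1055")
  # one channel missing
  df3 <- df[, setdiff(names(df), "r700")]
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df3, p3, row.names = FALSE)
  expect_error(readCloud(p3), "r700")
})

test_that("a non-numeric cell is a parse error with its row index", {
  spc <- randomCloud(4, labeled = FALSE, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  writeCloud(spc, path)
  df <- read.csv(path, check.names = FALSE)
  df$r600 <- as.character(df$r600)
  df$r600[3] <- "oops"
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2 <- df, p2, row.names = FALSE)
  expect_error(readCloud(p2), "row 3")
})

test_that("an empty cloud writes a header-only CSV and a 0-vertex PLY", {
  empty <- SpectralPointCloud(coords = matrix(0, 0, 3),
                              spectra = matrix(0, 0, 101))
  pc <- withr::local_tempfile(fileext = ".csv")
  writeCloud(empty, pc)
  expect_equal(length(readLines(pc)), 1L)
  expect_equal(nPoints(readCloud(pc)), 0L)
  pp <- withr::local_tempfile(fileext = ".ply")
  exportReconstruction(empty, labels = character(0), path = pp)
  expect_equal(nrow(oracle_read_ply(pp)), 0L)
})

test_that("reconstruction PLY colors match the colormap (independent parser)", {
  spc <- randomCloud(100, seed = 33)
  cm <- defaultColorMap()
  path <- withr::local_tempfile(fileext = ".ply")
  exportReconstruction(spc, colormap = cm, path = path)
  v <- oracle_read_ply(path)
  lab <- as.character(pointLabels(spc))
  expect_equal(unname(v[, c("red", "green", "blue")]),
               unname(cm[lab, , drop = FALSE]), ignore_attr = TRUE)
  expect_equal(v[, "x"], coords(spc)[, "x"], tolerance = 1e-9,
               ignore_attr = TRUE)
  # one point per class gets exactly the four distinct colormap entries
  four <- SpectralPointCloud(coords = diag(3)[c(1, 2, 3, 1), ] * 1:4,
                             spectra = matrix(0.5, 4, 101),
                             labels = componentLevels())
  p4 <- withr::local_tempfile(fileext = ".ply")
  exportReconstruction(four, path = p4)
  v4 <- oracle_read_ply(p4)
  expect_equal(unname(v4[, c("red", "green", "blue")]), unname(cm),
               ignore_attr = TRUE)
})

test_that("a label missing from the colormap is a configuration error", {
  spc <- randomCloud(5, seed = 2)
  cm <- defaultColorMap()[1:3, ]
  expect_error(exportReconstruction(spc, colormap = cm,
                                    path = tempfile(fileext = ".ply")),
               "missing class")
})

test_that("colormap colors must be pairwise distinct", {
  cm <- defaultColorMap()
  cm["Wood", ] <- cm["Leaf", ]
  expect_error(exportReconstruction(randomCloud(3, seed = 1), colormap = cm,
                                    path = tempfile(fileext = ".ply")),
               "distinct")
})
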