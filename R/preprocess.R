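#' White-reference reflectance calibration
#'
#' Converts raw echo peak intensities to reflectance against a reference
#' whiteboard scan. Per point \eqn{t} and channel \eqn{i},
#' \deqn{\rho_t(\lambda_i) = \frac{V_t(\lambda_i)}{V_b(\lambda_i)}\,\rho_b(\lambda_i)}
#' where \eqn{V_t} and \eqn{V_b} are the sample and panel peak voltages and
#' \eqn{\rho_b} the known panel reflectance (nominally 0.99). The ratio
#' cancels the (arbitrary, linear) intensity units, so calibration is
#' invariant to a common rescaling of both scans. Coordinates and labels
#' pass through unchanged.
#'
#' Noisy negative or zero sample voltages are allowed and yield
#' \eqn{\rho_t \le 0}; set `clampZero = TRUE` to floor the result at 0.
#'
#' @param cloud an intensity-kind [SpectralPointCloud()].
#' @param panel a [ReferencePanel()] on the same grid.
#' @param clampZero floor calibrated reflectance at zero? Default `FALSE`.
#' @return A reflectance-kind `SpectralPointCloud`.
#' @export
calibrateReflectance <- function(cloud, panel, clampZero = FALSE) {
  stopifnot(is(cloud, "SpectralPointCloud"), is(panel, "ReferencePanel"))
  if (spectraKind(cloud) != "intensity")
    stop("cloud spectra are already reflectance; calibration needs intensity")
  if (!isTRUE(all.equal(gridWavelengths(cloud@grid),
                        gridWavelengths(panel@grid))))
    stop("cloud and panel wavelength grids differ")
  vb <- panelVoltages(panel)
  bad <- which(!(vb > 0))
  if (length(bad))
    stop(sprintf("panel peak voltage is <= 0 at %g nm",
                 gridWavelengths(panel@grid)[bad[1]]))
  rho <- sweep(spectra(cloud), 2L, panelReflectance(panel) / vb, `*`)
  if (clampZero) rho[rho < 0] <- 0
  SpectralPointCloud(coords = coords(cloud), spectra = rho,
                     kind = "reflectance", labels = pointLabels(cloud),
                     edge = edgeFlags(cloud), grid = cloud@grid)
}

#' Separate sample from background by a coordinate cut
#'
#' The scan geometry places the sample a fixed distance in front of a dark
#' backdrop, so sample and background separate cleanly along the range axis
#' (conventionally y, pointing away from the scanner). Points with axis
#' coordinate strictly below `cut` are the near side; points at or beyond
#' `cut` the far side.
#'
#' @param cloud a [SpectralPointCloud()].
#' @param cut coordinate threshold in metres; must be finite.
#' @param axis `"x"`, `"y"` or `"z"`; default `"y"` (range axis).
#' @param keep `"near"` (coordinate < cut, the sample by convention) or
#'   `"far"` (>= cut, the backdrop).
#' @return The retained subset as a `SpectralPointCloud` (possibly empty);
#'   spectra, labels and edge flags subset consistently.
#' @export
segmentBackground <- function(cloud, cut, axis = c("y", "x", "z"),
                              keep = c("near", "far")) {
  axis <- match.arg(axis)
  keep <- match.arg(keep)
  stopifnot(is(cloud, "SpectralPointCloud"))
  if (!is.finite(cut)) stop("cut must be finite")
  a <- colData(cloud)[[axis]]
  sel <- if (keep == "near") a < cut else a >= cut
  cloud[, sel]
}

#' Read a reference panel from two-column CSVs
#'
#' Each file has columns `wavelength_nm,value`. Values are matched exactly
#' onto the grid (no interpolation); a wavelength off the grid or a missing
#' grid wavelength is an error.
#'
#' @param voltagePath CSV of panel peak voltages per wavelength.
#' @param reflectancePath optional CSV of panel reflectance per wavelength;
#'   if omitted, a flat `reflectance` is used.
#' @param reflectance scalar panel reflectance used when no file is given.
#' @param grid the wavelength grid.
#' @return A [ReferencePanel()].
#' @export
readPanel <- function(voltagePath, reflectancePath = NULL,
                      reflectance = 0.99, grid = WavelengthGrid()) {
  read_col <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("wavelength_nm", "value") %in% names(df)))
      stop(path, ": expected columns wavelength_nm,value")
    idx <- wavelengthIndex(grid, df$wavelength_nm)
    v <- rep(NA_real_, nChannels(grid))
    v[idx] <- df$value
    if (anyNA(v))
      stop(path, sprintf(": no value for grid wavelength %g nm",
                         gridWavelengths(grid)[which(is.na(v))[1]]))
    v
  }
  vb <- read_col(voltagePath)
  rb <- if (is.null(reflectancePath)) reflectance else read_col(reflectancePath)
  ReferencePanel(peakVoltages = vb, reflectance = rb, grid = grid)
}
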