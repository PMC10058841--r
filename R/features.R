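#' Names of the nine spectral feature parameters
#'
#' Fixed order: five band reflectances (700, 730, 780, 850, 900 nm), the
#' average reflectance over 760--930 nm, the red-edge chlorophyll index,
#' NDVI and NDRE. Trained models record this order and refuse feature
#' tables that deviate from it.
#'
#' @return Character vector of length 9.
#' @export
featureNames <- function() {
  c("R700", "R730", "R780", "R850", "R900",
    "AVG_R760_R930", "CI_red_edge", "NDVI", "NDRE")
}

#' Reflectance at a single band
#'
#' Exact grid lookup (no interpolation): the requested wavelength must lie
#' on the grid.
#'
#' @param spectrum a spectral vector, or a points x channels matrix.
#' @param wavelength wavelength in nm, exactly on the grid.
#' @param grid the [WavelengthGrid()].
#' @return The reflectance value(s) at that band.
#' @examples
#' bandReflectance(seq(0, 1, length.out = 101), 780)
#' @export
bandReflectance <- function(spectrum, wavelength, grid = WavelengthGrid()) {
  i <- wavelengthIndex(grid, wavelength)
  if (is.matrix(spectrum)) spectrum[, i] else spectrum[i]
}

#' Extract the nine spectral feature parameters
#'
#' Computes, per point, the feature vector used for component
#' classification:
#' \itemize{
#'   \item `R700, R730, R780, R850, R900` — reflectance at five bands chosen
#'     for maximal between-component contrast (700/730 nm are
#'     chlorophyll-sensitive; 850/900 nm separate wood from foliage).
#'   \item `AVG_R760_R930` — mean reflectance over the 35 channels from
#'     760 nm to 930 nm inclusive.
#'   \item `CI_red_edge` \eqn{= R_{780}/R_{710} - 1}, the red-edge
#'     chlorophyll index.
#'   \item `NDVI` \eqn{= (R_{800} - R_{670})/(R_{800} + R_{670})}.
#'   \item `NDRE` \eqn{= (R_{790} - R_{720})/(R_{790} + R_{720})}.
#' }
#' Ratio and normalized-difference indices are invariant to an overall
#' scaling of the spectrum, which suppresses incidence-angle effects. A zero
#' denominator yields `NaN`, reported via a warning and left for downstream
#' consumers to reject.
#'
#' @param cloud a reflectance-kind [SpectralPointCloud()], or a points x
#'   channels reflectance matrix.
#' @param grid wavelength grid when `cloud` is a bare matrix.
#' @return Numeric matrix, points x 9, columns [featureNames()].
#' @export
extractFeatures <- function(cloud, grid = WavelengthGrid()) {
  if (is(cloud, "SpectralPointCloud")) {
    if (spectraKind(cloud) != "reflectance")
      stop("features require reflectance spectra; calibrate first")
    sp <- spectra(cloud)
    grid <- cloud@grid
  } else {
    sp <- as.matrix(cloud)
    if (ncol(sp) != nChannels(grid))
      stop("spectral matrix width does not match the grid")
  }
  b <- function(w) sp[, wavelengthIndex(grid, w), drop = TRUE]
  avg_idx <- wavelengthIndex(grid, seq(760, 930, by = 5))
  out <- cbind(
    R700 = b(700), R730 = b(730), R780 = b(780),
    R850 = b(850), R900 = b(900),
    AVG_R760_R930 = rowMeans(sp[, avg_idx, drop = FALSE]),
    CI_red_edge = b(780) / b(710) - 1,
    NDVI = (b(800) - b(670)) / (b(800) + b(670)),
    NDRE = (b(790) - b(720)) / (b(790) + b(720)))
  nbad <- sum(!is.finite(out))
  if (nbad)
    warning(sprintf("%d non-finite feature value(s) from degenerate spectra", nbad))
  out
}

#' Write a feature table as CSV
#'
#' @param features points x 9 matrix from [extractFeatures()].
#' @param path output file.
#' @export
writeFeatures <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
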