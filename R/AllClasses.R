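#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData colData<-
NULL

#' Component classes of a fruit tree
#'
#' The four tree components distinguished by the classifier, in their fixed
#' code order (code `j` runs 1 to 4 over this vector).
#'
#' @return Character vector of the four class names.
#' @examples
#' componentLevels()
#' @export
componentLevels <- function() {
  c("UnripeFruit", "RipeFruit", "Wood", "Leaf")
}

#' Coerce labels to the component factor
#'
#' @param x character, factor or integer codes (1--4).
#' @return Factor with levels `componentLevels()`.
#' @export
componentFactor <- function(x) {
  lev <- componentLevels()
  if (is.numeric(x)) {
    if (length(x) && (any(x < 1 | x > 4, na.rm = TRUE) ||
                      any(x != as.integer(x), na.rm = TRUE)))
      stop("component codes must be integers in 1..4")
    return(factor(lev[as.integer(x)], levels = lev))
  }
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), lev)
  if (length(bad))
    stop("unknown component label(s): ", paste(bad, collapse = ", "))
  factor(x, levels = lev)
}

# ---------------------------------------------------------------------------
# WavelengthGrid

#' @rdname WavelengthGrid
#' @export
setClass("WavelengthGrid",
  representation(startNm = "numeric", stopNm = "numeric", stepNm = "numeric"))

setValidity("WavelengthGrid", function(object) {
  s <- object@startNm; e <- object@stopNm; d <- object@stepNm
  if (length(s) != 1L || length(e) != 1L || length(d) != 1L)
    return("startNm, stopNm, stepNm must be scalars")
  if (!is.finite(s) || !is.finite(e) || !is.finite(d))
    return("grid endpoints and step must be finite")
  if (d <= 0) return("stepNm must be > 0")
  n <- (e - s) / d
  if (abs(n - round(n)) > 1e-9)
    return("stopNm - startNm must be an integer multiple of stepNm")
  TRUE
})

#' Spectral wavelength grid
#'
#' The fixed wavelength axis of a hyperspectral LiDAR scan. The instrument
#' convention is 101 channels from 550 nm to 1050 nm in 5 nm steps; channel
#' \eqn{i} (1-based in R) holds wavelength \eqn{550 + 5 (i - 1)} nm.
#'
#' @param startNm,stopNm,stepNm grid limits and spacing in nanometres.
#' @return A `WavelengthGrid` object.
#' @examples
#' g <- WavelengthGrid()
#' nChannels(g)          # 101
#' wavelengthIndex(g, 780)
#' @aliases WavelengthGrid-class
#' @export
WavelengthGrid <- function(startNm = 550, stopNm = 1050, stepNm = 5) {
  new("WavelengthGrid", startNm = startNm, stopNm = stopNm, stepNm = stepNm)
}

#' @describeIn WavelengthGrid number of channels on the grid.
#' @param grid a `WavelengthGrid`.
#' @export
nChannels <- function(grid) {
  as.integer(round((grid@stopNm - grid@startNm) / grid@stepNm)) + 1L
}

#' @describeIn WavelengthGrid the wavelengths (nm) of all channels, in order.
#' @export
gridWavelengths <- function(grid) {
  seq(grid@startNm, grid@stopNm, by = grid@stepNm)
}

#' @describeIn WavelengthGrid 1-based channel index of a wavelength; errors if
#'   `wavelength` does not lie exactly on the grid.
#' @param wavelength wavelength(s) in nm, exactly on the grid.
#' @export
wavelengthIndex <- function(grid, wavelength) {
  idx <- (wavelength - grid@startNm) / grid@stepNm
  off <- abs(idx - round(idx)) > 1e-9
  if (any(off | idx < -1e-9 | round(idx) > nChannels(grid) - 1L))
    stop("wavelength(s) off the grid: ",
         paste(wavelength[off | idx < 0 | round(idx) > nChannels(grid) - 1L],
               collapse = ", "), " nm")
  as.integer(round(idx)) + 1L
}

setMethod("show", "WavelengthGrid", function(object) {
  cat(sprintf("WavelengthGrid: %g-%g nm, step %g nm (%d channels)\n",
              object@startNm, object@stopNm, object@stepNm,
              nChannels(object)))
})

# ---------------------------------------------------------------------------
# SpectralPointCloud

#' @rdname SpectralPointCloud
#' @export
setClass("SpectralPointCloud",
  contains = "SummarizedExperiment",
  representation(grid = "WavelengthGrid"))

setValidity("SpectralPointCloud", function(object) {
  msg <- character()
  if (!"spectra" %in% names(assays(object)))
    msg <- c(msg, "assay 'spectra' is required")
  cd <- colData(object)
  if (!all(c("x", "y", "z") %in% colnames(cd)))
    msg <- c(msg, "colData must contain x, y, z coordinates")
  else {
    xyz <- as.matrix(cd[, c("x", "y", "z")])
    if (!is.numeric(xyz) || any(!is.finite(xyz)))
      msg <- c(msg, "coordinates must be finite numeric")
  }
  kind <- metadata(object)$spectraKind
  if (is.null(kind) || !kind %in% c("intensity", "reflectance"))
    msg <- c(msg, "metadata spectraKind must be 'intensity' or 'reflectance'")
  if (nrow(object) != nChannels(object@grid))
    msg <- c(msg, sprintf("spectra have %d channels but grid has %d",
                          nrow(object), nChannels(object@grid)))
  if ("label" %in% colnames(cd)) {
    lab <- cd$label
    if (!is.factor(lab) || !identical(levels(lab), componentLevels()))
      msg <- c(msg, "label column must be a factor with the component levels")
  }
  if (length(msg)) msg else TRUE
})

#' Spatial-spectral point cloud
#'
#' The central data container: per point, an XYZ coordinate (metres) and a
#' spectrum on a fixed [WavelengthGrid()], stored as a
#' `SummarizedExperiment` with wavelengths as rows and points as columns.
#' Spectra are either raw echo peak intensities (arbitrary linear units,
#' before white-reference calibration) or reflectances; the kind is recorded
#' in the object and checked by downstream operations. Optional per-point
#' ground-truth component labels and edge flags live in `colData`.
#'
#' @param coords numeric matrix, points x 3 (x, y, z in metres).
#' @param spectra numeric matrix, points x channels.
#' @param kind `"intensity"` or `"reflectance"`.
#' @param labels optional per-point component labels (see [componentFactor()]).
#' @param edge optional logical per-point edge flags.
#' @param grid the wavelength axis; defaults to the 101-channel
#'   550--1050 nm, 5 nm instrument grid.
#' @return A `SpectralPointCloud`.
#' @examples
#' spc <- SpectralPointCloud(coords = matrix(rnorm(6), 2),
#'                           spectra = matrix(0.2, 2, 101),
#'                           kind = "reflectance")
#' spc
#' @aliases SpectralPointCloud-class
#' @export
SpectralPointCloud <- function(coords, spectra, kind = c("reflectance", "intensity"),
                               labels = NULL, edge = NULL,
                               grid = WavelengthGrid()) {
  kind <- match.arg(kind)
  coords <- as.matrix(coords)
  spectra <- as.matrix(spectra)
  if (ncol(coords) != 3L)
    stop("coords must have 3 columns (x, y, z)")
  if (nrow(coords) != nrow(spectra))
    stop("coords and spectra must have one row per point")
  if (ncol(spectra) != nChannels(grid))
    stop(sprintf("spectra have %d channels but the grid has %d",
                 ncol(spectra), nChannels(grid)))
  cd <- DataFrame(x = coords[, 1], y = coords[, 2], z = coords[, 3])
  if (!is.null(labels)) {
    if (length(labels) != nrow(coords))
      stop("labels length must equal the point count")
    cd$label <- componentFactor(labels)
  }
  if (!is.null(edge)) {
    if (length(edge) != nrow(coords))
      stop("edge length must equal the point count")
    cd$edge <- as.logical(edge)
  }
  se <- SummarizedExperiment(
    assays = list(spectra = t(spectra)),
    rowData = DataFrame(wavelength_nm = gridWavelengths(grid)),
    colData = cd)
  metadata(se)$spectraKind <- kind
  new("SpectralPointCloud", se, grid = grid)
}

#' @describeIn SpectralPointCloud number of points.
#' @param spc a `SpectralPointCloud`.
#' @export
nPoints <- function(spc) ncol(spc)

#' @describeIn SpectralPointCloud points x 3 coordinate matrix (metres).
#' @export
coords <- function(spc) {
  cd <- colData(spc)
  m <- cbind(x = cd$x, y = cd$y, z = cd$z)
  rownames(m) <- colnames(spc)
  m
}

#' @describeIn SpectralPointCloud points x channels spectral matrix; column
#'   names are the wavelengths in nm.
#' @export
spectra <- function(spc) {
  m <- t(assay(spc, "spectra"))
  colnames(m) <- as.character(gridWavelengths(spc@grid))
  m
}

#' @describeIn SpectralPointCloud `"intensity"` or `"reflectance"`.
#' @export
spectraKind <- function(spc) metadata(spc)$spectraKind

#' @describeIn SpectralPointCloud per-point component labels (factor), or
#'   `NULL` when the cloud is unlabeled.
#' @export
pointLabels <- function(spc) colData(spc)$label

#' @describeIn SpectralPointCloud replace the per-point labels.
#' @param value new labels (anything [componentFactor()] accepts, or `NULL`).
#' @export
`pointLabels<-` <- function(spc, value) {
  colData(spc)$label <- if (is.null(value)) NULL else {
    if (length(value) != nPoints(spc))
      stop("labels length must equal the point count")
    componentFactor(value)
  }
  validObject(spc)
  spc
}

#' @describeIn SpectralPointCloud logical edge flags, or `NULL` if absent.
#' @export
edgeFlags <- function(spc) colData(spc)$edge

#' @describeIn SpectralPointCloud the wavelength grid of the cloud.
#' @export
wavelengthGrid <- function(spc) spc@grid

setMethod("show", "SpectralPointCloud", function(object) {
  lab <- pointLabels(object)
  cat(sprintf("SpectralPointCloud: %d points, %d channels (%g-%g nm), kind=%s\n",
              nPoints(object), nrow(object), object@grid@startNm,
              object@grid@stopNm, spectraKind(object)))
  if (!is.null(lab)) {
    tab <- table(lab)
    cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  if (!is.null(edgeFlags(object)))
    cat(sprintf("edge-flagged: %d\n", sum(edgeFlags(object))))
})

# ---------------------------------------------------------------------------
# ReferencePanel

#' @rdname ReferencePanel
#' @export
setClass("ReferencePanel",
  representation(peakVoltages = "numeric", reflectance = "numeric",
                 grid = "WavelengthGrid"))

setValidity("ReferencePanel", function(object) {
  n <- nChannels(object@grid)
  if (length(object@peakVoltages) != n)
    return(sprintf("peakVoltages must have %d channels", n))
  if (any(!is.finite(object@peakVoltages)) || any(object@peakVoltages <= 0))
    return("panel peak voltages must be finite and strictly positive")
  if (length(object@reflectance) != n)
    return(sprintf("reflectance must have %d channels", n))
  if (any(!is.finite(object@reflectance)) ||
      any(object@reflectance <= 0 | object@reflectance > 1))
    return("panel reflectance must lie in (0, 1]")
  TRUE
})

#' White reference panel
#'
#' Describes the diffuse reference whiteboard scanned before the sample: the
#' echo peak voltage per channel and the (certified) panel reflectance,
#' nominally 0.99 across the band. Both are used by [calibrateReflectance()].
#'
#' @param peakVoltages per-channel echo peak voltages of the panel, same
#'   arbitrary linear units as the sample intensities; strictly positive.
#' @param reflectance panel reflectance, a scalar (recycled) or a per-channel
#'   vector in (0, 1]. Default 0.99.
#' @param grid the wavelength grid.
#' @return A `ReferencePanel`.
#' @aliases ReferencePanel-class
#' @export
ReferencePanel <- function(peakVoltages, reflectance = 0.99,
                           grid = WavelengthGrid()) {
  n <- nChannels(grid)
  if (length(reflectance) == 1L) reflectance <- rep(reflectance, n)
  new("ReferencePanel", peakVoltages = as.numeric(peakVoltages),
      reflectance = as.numeric(reflectance), grid = grid)
}

#' @describeIn ReferencePanel panel peak voltages per channel.
#' @param panel a `ReferencePanel`.
#' @export
panelVoltages <- function(panel) panel@peakVoltages

#' @describeIn ReferencePanel panel reflectance per channel.
#' @export
panelReflectance <- function(panel) panel@reflectance

setMethod("show", "ReferencePanel", function(object) {
  cat(sprintf("ReferencePanel: %d channels, reflectance %.3g-%.3g, V_b %.3g-%.3g\n",
              nChannels(object@grid), min(object@reflectance),
              max(object@reflectance), min(object@peakVoltages),
              max(object@peakVoltages)))
})
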