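#' Default class colormap
#'
#' RGB colors (0--255) used for colored 3D reconstruction, one per component
#' class, pairwise distinct.
#'
#' @return Integer matrix 4 x 3 with rownames `componentLevels()` and columns
#'   `red`, `green`, `blue`.
#' @examples
#' defaultColorMap()
#' @export
defaultColorMap <- function() {
  m <- rbind(UnripeFruit = c(154L, 205L, 50L),   # yellow-green
             RipeFruit   = c(255L,  69L,  0L),   # orange-red
             Wood        = c(139L,  69L, 19L),   # brown
             Leaf        = c( 34L, 139L, 34L))   # forest green
  colnames(m) <- c("red", "green", "blue")
  m
}

.check_colormap <- function(colormap) {
  colormap <- as.matrix(colormap)
  missing <- setdiff(componentLevels(), rownames(colormap))
  if (length(missing))
    stop("colormap is missing class(es): ", paste(missing, collapse = ", "))
  colormap <- colormap[componentLevels(), , drop = FALSE]
  if (ncol(colormap) != 3L || any(colormap < 0) || any(colormap > 255))
    stop("colormap entries must be RGB triples in 0..255")
  if (anyDuplicated(apply(colormap, 1L, paste, collapse = ",")))
    stop("colormap colors must be pairwise distinct")
  storage.mode(colormap) <- "integer"
  colormap
}

.spectral_colnames <- function(grid, kind) {
  prefix <- if (kind == "reflectance") "r" else "v"
  paste0(prefix, gridWavelengths(grid))
}

# Validate a table of per-vertex columns against the expected schema and
# assemble a SpectralPointCloud. Shared by the CSV and PLY readers.
.table_to_cloud <- function(df, grid, what) {
  nm <- names(df)
  if (!all(c("x", "y", "z") %in% nm))
    stop(what, ": columns x, y, z are required")
  spec_nm <- grep("^[rv][0-9]+$", nm, value = TRUE)
  if (!length(spec_nm))
    stop(what, ": no spectral columns (r<wavelength> or v<wavelength>) found")
  prefix <- unique(substr(spec_nm, 1L, 1L))
  if (length(prefix) > 1L)
    stop(what, ": mixed r*/v* spectral columns")
  kind <- if (prefix == "r") "reflectance" else "intensity"
  expected <- .spectral_colnames(grid, kind)
  extra <- setdiff(spec_nm, expected)
  if (length(extra))
    stop(what, sprintf(": unexpected spectral column '%s' (grid has %d channels, %g-%g nm)",
                       extra[1], nChannels(grid), grid@startNm, grid@stopNm))
  missing <- setdiff(expected, spec_nm)
  if (length(missing))
    stop(what, sprintf(": missing spectral column '%s'", missing[1]))
  other <- setdiff(nm, c("x", "y", "z", "label", expected))
  for (col in c("x", "y", "z", expected)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "NA")
      if (length(bad))
        stop(what, sprintf(": non-numeric value in column '%s' at row %d",
                           col, bad[1]))
      df[[col]] <- vn
    }
  }
  labels <- if ("label" %in% nm) {
    if (is.numeric(df$label)) componentFactor(df$label) else
      componentFactor(as.character(df$label))
  }
  SpectralPointCloud(coords = cbind(df$x, df$y, df$z),
                     spectra = as.matrix(df[expected]),
                     kind = kind, labels = labels, grid = grid)
}

#' Read a spatial-spectral point cloud
#'
#' Reads a point cloud from a wide CSV (header
#' `x,y,z[,label],r550,...,r1050`, or `v550...` for uncalibrated
#' intensities) or from a PLY file carrying the same per-vertex property
#' names. The spectra kind is inferred from the `r`/`v` column prefix and a
#' `label` column, when present, is mapped onto the component classes.
#'
#' @param path file to read.
#' @param format `"csv"` or `"ply"`; default guesses from the file extension.
#' @param grid expected wavelength axis; the file's spectral columns must
#'   match it exactly (a file with more or fewer channels is a format error).
#' @return A [SpectralPointCloud()].
#' @seealso [writeCloud()], [exportReconstruction()]
#' @export
readCloud <- function(path, format = c("auto", "csv", "ply"),
                      grid = WavelengthGrid()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    .table_to_cloud(df, grid, what = path)
  } else {
    df <- .ply_read(path)
    # labels travel as uchar codes; comments carry the code -> name mapping,
    # which is fixed anyway (componentLevels() order)
    if ("label" %in% names(df)) {
      lab <- df$label
      df$label <- NULL
      cloud <- .table_to_cloud(df, grid, what = path)
      pointLabels(cloud) <- componentFactor(as.integer(lab))
      cloud
    } else .table_to_cloud(df, grid, what = path)
  }
}

#' Write a spatial-spectral point cloud
#'
#' Inverse of [readCloud()]: columns are `x,y,z[,label]` followed by the
#' spectral channels in ascending wavelength, prefixed `r` (reflectance) or
#' `v` (intensity). CSV serializes labels as class names; PLY (written
#' binary little-endian with double-precision properties) stores them as a
#' `uchar` code with the name mapping in header comments.
#'
#' @param cloud a [SpectralPointCloud()].
#' @param path output file.
#' @param format `"csv"` or `"ply"`; default guesses from the extension.
#' @export
writeCloud <- function(cloud, path, format = c("auto", "csv", "ply")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "csv"
  stopifnot(is(cloud, "SpectralPointCloud"))
  xyz <- coords(cloud)
  sp <- spectra(cloud)
  spec_nm <- .spectral_colnames(cloud@grid, spectraKind(cloud))
  lab <- pointLabels(cloud)
  if (format == "csv") {
    df <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    if (!is.null(lab)) df$label <- as.character(lab)
    df[spec_nm] <- as.data.frame(sp)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    types <- c(x = "double", y = "double", z = "double")
    comments <- "TreeSpectra spectral point cloud"
    if (!is.null(lab)) {
      df$label <- as.integer(lab)
      types["label"] <- "uchar"
      comments <- c(comments,
                    paste("label", seq_len(4L), componentLevels()))
    }
    df[spec_nm] <- as.data.frame(sp)
    types[spec_nm] <- "double"
    .ply_write(df, types, path, comments = comments)
  }
  invisible(path)
}

#' Export a colored 3D reconstruction
#'
#' Writes the classified point cloud as a standard colored PLY
#' (`x,y,z` plus `uchar` `red,green,blue` per vertex), assigning each point
#' the color of its class so the component layout of the tree can be
#' inspected in any point-cloud viewer.
#'
#' @param cloud a [SpectralPointCloud()] providing the coordinates.
#' @param labels per-point component labels; defaults to the cloud's own.
#' @param colormap class-to-RGB map as returned by [defaultColorMap()].
#' @param path output PLY file.
#' @export
exportReconstruction <- function(cloud, labels = pointLabels(cloud),
                                 colormap = defaultColorMap(), path) {
  if (is.null(labels))
    stop("labels are required (cloud is unlabeled)")
  labels <- componentFactor(labels)
  if (length(labels) != nPoints(cloud))
    stop("labels length must equal the point count")
  colormap <- .check_colormap(colormap)
  xyz <- coords(cloud)
  rgb <- colormap[as.character(labels), , drop = FALSE]
  df <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   red = rgb[, 1], green = rgb[, 2], blue = rgb[, 3])
  if (!nPoints(cloud))
    df <- df[0L, , drop = FALSE]
  .ply_write(df,
             c(x = "double", y = "double", z = "double",
               red = "uchar", green = "uchar", blue = "uchar"),
             path, comments = "TreeSpectra colored reconstruction")
  invisible(path)
}

#' Two-color changed-points PLY
#'
#' Companion to [reprogramLabels()]: writes the cloud with points colored by
#' whether reprogramming changed their class (green = changed,
#' red = unchanged), the conventional rendering for inspecting where label
#' corrections concentrate.
#'
#' @param cloud a [SpectralPointCloud()].
#' @param changed logical per-point mask.
#' @param path output PLY file.
#' @export
exportChangedMask <- function(cloud, changed, path) {
  if (length(changed) != nPoints(cloud))
    stop("changed mask length must equal the point count")
  xyz <- coords(cloud)
  df <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   red = ifelse(changed, 0L, 255L),
                   green = ifelse(changed, 255L, 0L),
                   blue = 0L)
  .ply_write(df,
             c(x = "double", y = "double", z = "double",
               red = "uchar", green = "uchar", blue = "uchar"),
             path, comments = "TreeSpectra changed-class mask")
  invisible(path)
}
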