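# Synthetic spectral-tree scenes. The generator emulates the statistical
# structure of hyperspectral-LiDAR orchard scans: four components whose mean
# reflectance curves have the characteristic shapes (wood rising
# monotonically with wavelength; leaf and unripe fruit with a strong red
# edge; ripe fruit plateauing near 20% over 600-900 nm), spatially coherent
# tree geometry built from simple primitives, and a fraction of edge points
# whose spectra are attenuated and flattened toward a slowly rising ramp,
# the footprint-spillover signature that drives edge misclassification.

#' Spectral template of a component class
#'
#' Analytic mean-reflectance curve plus the edge-degradation parameters of
#' one component. The per-class defaults for `edgeExcess` are the measured
#' non-edge-over-edge mean reflectance excesses (10.36% unripe fruit,
#' 17.81% ripe fruit, 18.18% leaf, 11.06% wood).
#'
#' @param class one of `componentLevels()`.
#' @param noiseSd per-channel Gaussian noise sd (reflectance units).
#' @param edgeExcess fractional excess of the non-edge over the edge mean
#'   reflectance: the edge base curve is `base / (1 + edgeExcess)`.
#' @param edgeFlatten mixing weight in `[0, 1)` pulling the edge curve
#'   toward a slowly increasing linear ramp of equal mean.
#' @param edgeScaleSd sd (log scale) of the mean-one lognormal per-point
#'   brightness jitter of edge spectra, modeling point-to-point variation
#'   in how much of the laser footprint misses the component. Zero makes
#'   edge spectra deterministic up to channel noise.
#' @return List with the class name, `base` (function of wavelength in nm),
#'   `noiseSd`, `edgeExcess`, `edgeFlatten`, `edgeScaleSd`.
#' @export
spectralTemplate <- function(class, noiseSd = 0.02, edgeExcess = NULL,
                             edgeFlatten = 0.9, edgeScaleSd = 0.35) {
  class <- match.arg(class, componentLevels())
  base <- switch(class,
    Wood = function(l) 0.15 + 0.40 * (l - 550) / 500,
    Leaf = function(l) 0.08 + 0.37 * stats::plogis((l - 715) / 12),
    UnripeFruit = function(l) 0.10 + 0.25 * stats::plogis((l - 715) / 14),
    RipeFruit = function(l) 0.155 + 0.045 * stats::plogis((l - 575) / 12) +
                            0.025 * (l - 550) / 500)
  if (is.null(edgeExcess))
    edgeExcess <- c(UnripeFruit = 0.1036, RipeFruit = 0.1781,
                    Wood = 0.1106, Leaf = 0.1818)[[class]]
  stopifnot(edgeExcess >= 0, edgeFlatten >= 0, edgeFlatten < 1,
            edgeScaleSd >= 0)
  list(class = class, base = base, noiseSd = noiseSd,
       edgeExcess = edgeExcess, edgeFlatten = edgeFlatten,
       edgeScaleSd = edgeScaleSd)
}

#' Synthesize reflectance spectra for one class
#'
#' Non-edge points get the class base curve plus channel noise. Edge points
#' start from the attenuated curve `base / (1 + edgeExcess)` — so the
#' non-edge mean exceeds the edge mean by exactly `edgeExcess` (relative) —
#' and are then mixed with a linear, slowly increasing ramp scaled to the
#' same mean, which flattens the curve shape without moving its level.
#' Each edge spectrum is additionally multiplied by a mean-one lognormal
#' brightness factor (`edgeScaleSd`), the point-to-point variability of
#' footprint spillover; being mean-one it leaves the class-mean edge
#' spectrum, and hence the non-edge-over-edge excess, unchanged in
#' expectation. Results are floored at 0.
#'
#' @param n number of spectra to draw.
#' @param template a [spectralTemplate()].
#' @param edge logical: draw edge-point spectra?
#' @param grid the [WavelengthGrid()].
#' @param noiseSd override of the template noise sd.
#' @return n x channels reflectance matrix. Uses the current RNG stream;
#'   seed via `set.seed()` or [generateScene()].
#' @export
synthSpectrum <- function(n, template, edge = FALSE, grid = WavelengthGrid(),
                          noiseSd = template$noiseSd) {
  wl <- gridWavelengths(grid)
  curve <- template$base(wl)
  if (edge) {
    att <- curve / (1 + template$edgeExcess)
    # slowly increasing ramp, strictly positive (0.5x to 1.5x its mean) so
    # channel noise is not clipped away at the short-wavelength end
    ramp <- 0.5 + (wl - grid@startNm) / (grid@stopNm - grid@startNm)
    ramp <- ramp * mean(att) / mean(ramp)
    curve <- (1 - template$edgeFlatten) * att + template$edgeFlatten * ramp
  }
  m <- matrix(curve, nrow = n, ncol = length(wl), byrow = TRUE)
  if (edge && template$edgeScaleSd > 0) {
    s <- stats::rlnorm(n, meanlog = -template$edgeScaleSd^2 / 2,
                       sdlog = template$edgeScaleSd)
    m <- m * s
  }
  if (noiseSd > 0)
    m <- m + matrix(stats::rnorm(n * length(wl), sd = noiseSd),
                    nrow = n)
  m[m < 0] <- 0
  m
}

#' Scene configuration
#'
#' Geometry, composition and noise settings of a synthetic tree scene. The
#' default scene has 5,000 points (1,000 per fruit class, 1,500 wood,
#' 1,500 leaf), a 15% edge-point fraction, per-channel noise sd 0.02 and
#' the per-class edge attenuations of [spectralTemplate()]. Geometry: a
#' vertical trunk with side branches (wood), fruit spheres at branch tips,
#' leaf discs scattered along the branches; sizes in metres. The scanner
#' looks along +y, which defines the silhouette used to flag edge points.
#'
#' @param counts named point counts per component class.
#' @param edgeFraction expected fraction of edge-flagged points per
#'   component, in `[0, 1)`.
#' @param noiseSd spectral noise sd (reflectance units).
#' @param edgeFlatten edge flattening weight, see [spectralTemplate()].
#' @param edgeScaleSd edge brightness-jitter sd, see [spectralTemplate()].
#' @param edgeExcess optional named per-class override of the edge excess.
#' @param trunkRadius,trunkHeight,branchRadius,branchLength,nBranches,
#'   fruitRadius,leafRadius geometry sizes (metres) and branch count.
#' @param distance scene distance from the scanner along y (metres).
#' @param seed integer seed; scenes are bit-identical for a fixed seed.
#' @return A list of class `sceneConfig`.
#' @export
sceneConfig <- function(counts = c(UnripeFruit = 1000L, RipeFruit = 1000L,
                                   Wood = 1500L, Leaf = 1500L),
                        edgeFraction = 0.15, noiseSd = 0.02,
                        edgeFlatten = 0.9, edgeScaleSd = 0.35,
                        edgeExcess = NULL,
                        trunkRadius = 0.05, trunkHeight = 2,
                        branchRadius = 0.02, branchLength = 0.5,
                        nBranches = 6L, fruitRadius = 0.04,
                        leafRadius = 0.03, distance = 5, seed = 1L) {
  stopifnot(all(componentLevels() %in% names(counts)),
            all(counts >= 0), edgeFraction >= 0, edgeFraction < 1,
            noiseSd >= 0)
  structure(list(counts = counts[componentLevels()],
                 edgeFraction = edgeFraction, noiseSd = noiseSd,
                 edgeFlatten = edgeFlatten, edgeScaleSd = edgeScaleSd,
                 edgeExcess = edgeExcess,
                 trunkRadius = trunkRadius, trunkHeight = trunkHeight,
                 branchRadius = branchRadius, branchLength = branchLength,
                 nBranches = as.integer(nBranches),
                 fruitRadius = fruitRadius, leafRadius = leafRadius,
                 distance = distance, seed = as.integer(seed)),
            class = "sceneConfig")
}

# --- geometry helpers -------------------------------------------------------

# unit vector orthonormal basis completing axis u
.ortho_basis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  list(v = v, w = w)
}

# n points on the lateral surface of a cylinder; edge = silhouette band
# w.r.t. the +y view direction, with the angular threshold chosen so the
# expected edge fraction is exactly f.
.sample_cylinder <- function(n, base, axis, radius, len, f) {
  u <- axis / sqrt(sum(axis^2))
  b <- .ortho_basis(u)
  t <- stats::runif(n, 0, len)
  phi <- stats::runif(n, 0, 2 * pi)
  normal <- outer(cos(phi), b$v) + outer(sin(phi), b$w)
  pts <- matrix(base, n, 3, byrow = TRUE) + outer(t, u) + radius * normal
  view <- c(0, 1, 0)
  s <- sqrt(sum((view - sum(view * u) * u)^2))  # |projection of view on the normal plane|
  thr <- if (s > 0) s * sin(pi * f / 2) else Inf
  edge <- if (s > 0) abs(normal %*% view) < thr else rep(f > 0, n)
  list(coords = pts, edge = as.vector(edge))
}

# n points uniform on a sphere; silhouette band |n . view| < f has expected
# fraction exactly f (cosine to the view axis is uniform on [-1, 1])
.sample_sphere <- function(n, center, radius, f) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  normal <- cbind(r * cos(phi), r * sin(phi), z)
  pts <- matrix(center, n, 3, byrow = TRUE) + radius * normal
  edge <- abs(normal[, 2]) < f  # view along +y
  list(coords = pts, edge = edge)
}

# n points uniform in a disc of random orientation; rim annulus of area
# fraction f is the edge
.sample_disc <- function(n, center, normal, radius, f) {
  u <- normal / sqrt(sum(normal^2))
  b <- .ortho_basis(u)
  r <- radius * sqrt(stats::runif(n))
  phi <- stats::runif(n, 0, 2 * pi)
  pts <- matrix(center, n, 3, byrow = TRUE) +
    outer(r * cos(phi), b$v) + outer(r * sin(phi), b$w)
  edge <- r > radius * sqrt(1 - f)
  list(coords = pts, edge = edge)
}

#' Sample the scene geometry
#'
#' Draws per-point coordinates, component labels and edge flags for a
#' synthetic tree: trunk and branch cylinders (wood), fruit spheres at and
#' near branch tips (half unripe, half ripe), leaf discs scattered along
#' the branches. A point is edge-flagged when it lies in the silhouette
#' band of its primitive as seen from the scanner (+y), a rim of expected
#' area fraction `edgeFraction`.
#'
#' @param config a [sceneConfig()].
#' @param seed overrides `config$seed`.
#' @return List with `coords` (n x 3), `labels` (component factor) and
#'   `edge` (logical).
#' @export
sampleComponentGeometry <- function(config = sceneConfig(),
                                    seed = config$seed) {
  set.seed(seed)
  cnt <- config$counts
  f <- config$edgeFraction
  d <- config$distance
  coords <- matrix(numeric(0), 0, 3)
  labels <- character(0)
  edge <- logical(0)
  add <- function(samp, class) {
    coords <<- rbind(coords, samp$coords)
    labels <<- c(labels, rep(class, nrow(samp$coords)))
    edge <<- c(edge, samp$edge)
  }
  nb <- config$nBranches
  bh <- seq(0.4, 0.95, length.out = nb) * config$trunkHeight
  baz <- stats::runif(nb, 0, 2 * pi)
  bax <- cbind(cos(baz), sin(baz), stats::runif(nb, 0.2, 0.6))
  bax <- bax / sqrt(rowSums(bax^2))
  tips <- cbind(0, d, bh) + config$branchLength * bax

  # wood: trunk + branches, points split by lateral area
  nwood <- cnt[["Wood"]]
  if (nwood > 0) {
    areas <- c(config$trunkRadius * config$trunkHeight,
               rep(config$branchRadius * config$branchLength, nb))
    alloc <- .alloc_counts(nwood, areas)
    if (alloc[1] > 0)
      add(.sample_cylinder(alloc[1], c(0, d, 0), c(0, 0, 1),
                           config$trunkRadius, config$trunkHeight, f), "Wood")
    for (i in seq_len(nb))
      if (alloc[i + 1] > 0)
        add(.sample_cylinder(alloc[i + 1], c(0, d, bh[i]), bax[i, ],
                             config$branchRadius, config$branchLength, f),
            "Wood")
  }
  # fruits: spheres hanging below the branches in interleaved, non-colliding
  # slots along each branch (unripe and ripe alternate, spaced farther apart
  # than a sphere diameter)
  slots <- list(UnripeFruit = c(0.35, 0.75), RipeFruit = c(0.55, 0.95))
  for (class in c("UnripeFruit", "RipeFruit")) {
    nfr <- cnt[[class]]
    if (nfr == 0) next
    per <- 100L
    nsph <- max(1L, ceiling(nfr / per))
    sl <- slots[[class]]
    bi <- 1 + (seq_len(nsph) - 1L) %% nb
    fr <- sl[1 + ((seq_len(nsph) - 1L) %/% nb) %% length(sl)]
    centers <- cbind(0, d, bh[bi]) + fr * config$branchLength * bax[bi, ] +
      matrix(stats::rnorm(3 * nsph, sd = 0.01), nsph, 3)
    centers[, 3] <- centers[, 3] - (config$fruitRadius + 0.06)
    alloc <- .alloc_counts(nfr, rep(1, nsph))
    for (i in seq_len(nsph))
      if (alloc[i] > 0)
        add(.sample_sphere(alloc[i], centers[i, ], config$fruitRadius, f),
            class)
  }
  # leaves: discs along branches, random orientation
  nleaf <- cnt[["Leaf"]]
  if (nleaf > 0) {
    per <- 40L
    ndisc <- max(1L, ceiling(nleaf / per))
    bi <- 1 + (seq_len(ndisc) - 1L) %% nb
    frac <- stats::runif(ndisc, 0.2, 1)
    onaxis <- cbind(0, d, bh[bi]) + frac * config$branchLength * bax[bi, ]
    # leaves surround the branch: offset perpendicular to the branch axis so
    # thin wood cores keep wood-majority spatial neighborhoods
    perp <- matrix(stats::rnorm(3 * ndisc), ndisc, 3)
    perp <- perp - bax[bi, , drop = FALSE] * rowSums(perp * bax[bi, , drop = FALSE])
    perp <- perp / sqrt(rowSums(perp^2))
    perp[, 3] <- abs(perp[, 3])  # foliage sits above the branch, fruit below
    centers <- onaxis + perp * stats::runif(ndisc, 0.10, 0.22) +
      matrix(stats::rnorm(3 * ndisc, sd = 0.02), ndisc, 3)
    normals <- matrix(stats::rnorm(3 * ndisc), ndisc, 3)
    alloc <- .alloc_counts(nleaf, rep(1, ndisc))
    for (i in seq_len(ndisc))
      if (alloc[i] > 0)
        add(.sample_disc(alloc[i], centers[i, ], normals[i, ],
                         config$leafRadius, f), "Leaf")
  }
  list(coords = coords, labels = componentFactor(labels), edge = edge)
}

# split n into integer shares proportional to weights, exactly summing to n
.alloc_counts <- function(n, w) {
  w <- w / sum(w)
  a <- floor(n * w)
  rem <- n - sum(a)
  if (rem > 0) {
    o <- order(n * w - a, decreasing = TRUE)
    a[o[seq_len(rem)]] <- a[o[seq_len(rem)]] + 1L
  }
  as.integer(a)
}

#' Synthetic white-reference panel
#'
#' A deterministic, smooth panel response (arbitrary linear units) used by
#' the intensity mode of [generateScene()] so calibration can be exercised
#' on synthetic data: scene intensities are `reflectance * V_b / rho_b` and
#' [calibrateReflectance()] recovers the reflectances exactly.
#'
#' @param grid the [WavelengthGrid()].
#' @param reflectance panel reflectance (scalar).
#' @return A [ReferencePanel()].
#' @export
syntheticPanel <- function(grid = WavelengthGrid(), reflectance = 0.99) {
  wl <- gridWavelengths(grid)
  vb <- 1.2 + 0.8 * exp(-((wl - 800) / 180)^2)  # smooth source/detector response
  ReferencePanel(peakVoltages = vb, reflectance = reflectance, grid = grid)
}

#' Generate a labeled synthetic tree scene
#'
#' Composes [sampleComponentGeometry()] and [synthSpectrum()] into a fully
#' labeled [SpectralPointCloud()] with edge flags, deterministic for a
#' fixed seed. With `kind = "intensity"` the reflectances are converted to
#' synthetic echo intensities against [syntheticPanel()] so the calibration
#' stage has something to do.
#'
#' @param config a [sceneConfig()].
#' @param kind `"reflectance"` (default) or `"intensity"`.
#' @param grid the [WavelengthGrid()].
#' @return A labeled `SpectralPointCloud` with edge flags in
#'   `edgeFlags()`.
#' @examples
#' spc <- generateScene(sceneConfig(counts = c(UnripeFruit = 50, RipeFruit = 50,
#'                                             Wood = 80, Leaf = 80), seed = 7))
#' spc
#' @export
generateScene <- function(config = sceneConfig(),
                          kind = c("reflectance", "intensity"),
                          grid = WavelengthGrid()) {
  kind <- match.arg(kind)
  geo <- sampleComponentGeometry(config, seed = config$seed)
  n <- nrow(geo$coords)
  sp <- matrix(0, n, nChannels(grid))
  for (class in componentLevels()) {
    tmpl <- spectralTemplate(class, noiseSd = config$noiseSd,
                             edgeExcess = config$edgeExcess[[class]],
                             edgeFlatten = config$edgeFlatten,
                             edgeScaleSd = config$edgeScaleSd)
    for (e in c(FALSE, TRUE)) {
      sel <- geo$labels == class & geo$edge == e
      if (any(sel))
        sp[sel, ] <- synthSpectrum(sum(sel), tmpl, edge = e, grid = grid)
    }
  }
  if (kind == "intensity") {
    panel <- syntheticPanel(grid)
    sp <- sweep(sp, 2L, panelVoltages(panel) / panelReflectance(panel), `*`)
  }
  SpectralPointCloud(coords = geo$coords, spectra = sp, kind = kind,
                     labels = geo$labels, edge = geo$edge, grid = grid)
}
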