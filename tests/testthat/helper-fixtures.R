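# Fixture builders shared across test files.

randomCloud <- function(n, labeled = TRUE, kind = "reflectance", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  SpectralPointCloud(
    coords = matrix(runif(3 * n, 0, 2), n, 3),
    spectra = matrix(runif(101 * n, 0.01, 0.9), n, 101),
    kind = kind,
    labels = if (labeled) sample(componentLevels(), n, replace = TRUE))
}

# two well-separated spatial clusters with planted wrong labels: cluster A
# is Wood, cluster B is Leaf, `mislabels` indices per cluster flipped
twoClusterCloud <- function(nA = 15, nB = 15, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(3 * nA, sd = 0.1), nA, 3)
  b <- matrix(rnorm(3 * nB, sd = 0.1), nB, 3)
  b[, 1] <- b[, 1] + 5
  coords <- rbind(a, b)
  labels <- rep(c("Wood", "Leaf"), c(nA, nB))
  list(coords = coords, labels = labels)
}

smallScene <- function(seed = 1, n = c(UnripeFruit = 100, RipeFruit = 100,
                                       Wood = 150, Leaf = 150), ...) {
  generateScene(sceneConfig(counts = n, seed = seed, ...))
}
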