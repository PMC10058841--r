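test_that("pairwise distances match the Euclidean formula", {
  expect_equal(pairwiseDistances(rbind(c(0, 0, 0), c(1, 2, 2)))[1, 2], 3)
  expect_equal(pairwiseDistances(matrix(1:3, 1)), matrix(0, 1, 1))
  set.seed(21)
  xyz <- matrix(rnorm(600), 200, 3)
  S <- pairwiseDistances(xyz)
  expect_equal(S, oracle_dist(xyz), tolerance = 1e-12)
  expect_identical(S, t(S))
  expect_true(all(diag(S) == 0))
})

test_that("nearest neighbors of collinear points are forced by geometry", {
  xyz <- cbind(c(0, 1, 3), 0, 0)
  nn <- nearestNeighbors(xyz, N = 1)
  expect_equal(nn$index[, 1], c(2L, 1L, 2L))
})

test_that("N = n-1 returns a permutation of all other indices", {
  set.seed(3)
  xyz <- matrix(runif(30), 10, 3)
  nn <- nearestNeighbors(xyz, N = 9)
  for (k in 1:10)
    expect_setequal(nn$index[k, ], setdiff(1:10, k))
})

test_that("N >= n clips to n-1 with a warning", {
  xyz <- matrix(runif(9), 3, 3)
  expect_warning(nn <- nearestNeighbors(xyz, N = 5), "clipped")
  expect_equal(ncol(nn$index), 2L)
})

test_that("blocked neighbor search equals the full-sort oracle across block sizes", {
  set.seed(14)
  xyz <- matrix(runif(900), 300, 3)
  want <- oracle_knn(xyz, 12)
  for (bs in c(7, 64, 1024))
    expect_identical(nearestNeighbors(xyz, 12, blockSize = bs)$index, want)
})

test_that("tie handling picks the lower index", {
  # point 1 at origin; points 2 and 3 equidistant mirror images
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(5, 5, 5))
  nn <- nearestNeighbors(xyz, N = 2)
  expect_equal(nn$index[1, ], c(2L, 3L))
})

test_that("a unanimous neighborhood overrides the point's label", {
  set.seed(5)
  xyz <- rbind(matrix(rnorm(36, sd = 0.05), 12, 3), c(0, 0, 0))
  labels <- c(rep("Leaf", 12), "Wood")
  rp <- reprogramLabels(xyz, labels, reprogramConfig(N = 12))
  expect_identical(as.character(rp$labels[13]), "Leaf")
  expect_identical(rp$changed, c(rep(FALSE, 12), TRUE))
})

test_that("homogeneous clouds are fixed points with an all-false mask", {
  set.seed(6)
  xyz <- matrix(runif(90), 30, 3)
  rp <- reprogramLabels(xyz, rep("RipeFruit", 30), reprogramConfig(N = 12))
  expect_identical(as.character(rp$labels), rep("RipeFruit", 30))
  expect_false(any(rp$changed))
})

test_that("sequential reprogramming equals the step-by-step trace and fixes planted edge mislabels", {
  tc <- twoClusterCloud(15, 15, seed = 8)
  planted <- c(2, 7, 11, 17, 22, 28)
  labels <- tc$labels
  labels[planted] <- ifelse(labels[planted] == "Wood", "Leaf", "Wood")
  rp <- reprogramLabels(tc$coords, labels, reprogramConfig(N = 12))
  expect_identical(as.character(rp$labels),
                   oracle_reprogram_seq(tc$coords, labels, 12))
  expect_identical(as.character(rp$labels), tc$labels)
  expect_identical(which(rp$changed), as.integer(planted))
})

test_that("no new classes are invented", {
  set.seed(30)
  for (i in 1:10) {
    xyz <- matrix(runif(60), 20, 3)
    labels <- sample(c("Wood", "Leaf"), 20, replace = TRUE)
    rp <- reprogramLabels(xyz, labels, reprogramConfig(N = 5))
    expect_true(all(as.character(rp$labels) %in% unique(labels)))
  }
})

test_that("frozen mode is permutation equivariant", {
  set.seed(31)
  xyz <- matrix(runif(150), 50, 3)
  labels <- sample(componentLevels(), 50, replace = TRUE)
  cfg <- reprogramConfig(N = 7, updateMode = "frozen")
  base <- reprogramLabels(xyz, labels, cfg)
  perm <- sample(50)
  permuted <- reprogramLabels(xyz[perm, ], labels[perm], cfg)
  expect_identical(as.character(permuted$labels),
                   as.character(base$labels)[perm])
})

test_that("frozen mode ignores the visiting order, sequential may not", {
  set.seed(32)
  xyz <- matrix(runif(120), 40, 3)
  labels <- sample(componentLevels(), 40, replace = TRUE)
  cfg <- reprogramConfig(N = 5, updateMode = "frozen")
  a <- reprogramLabels(xyz, labels, cfg)
  b <- reprogramLabels(xyz, labels, cfg, order = rev(seq_len(40)))
  expect_identical(a$labels, b$labels)
})

test_that("pure agreeing neighborhoods make reprogramming the identity", {
  # two far-apart pure clusters: every neighborhood is class-pure
  tc <- twoClusterCloud(10, 10, seed = 12)
  rp <- reprogramLabels(tc$coords, tc$labels, reprogramConfig(N = 9))
  expect_identical(as.character(rp$labels), tc$labels)
})

test_that("nearest_class tie-break takes the nearest tied class", {
  # point 5 has 2 Wood and 2 Leaf neighbors; nearest is Wood
  xyz <- rbind(c(0.1, 0, 0), c(0.2, 0, 0), c(-0.3, 0, 0), c(-0.4, 0, 0),
               c(0, 0, 0))
  labels <- c("Wood", "Wood", "Leaf", "Leaf", "Leaf")
  cfg <- reprogramConfig(N = 4, tieBreak = "nearest_class",
                         updateMode = "frozen")
  rp <- reprogramLabels(xyz, labels, cfg)
  expect_identical(as.character(rp$labels[5]), "Wood")
  # keep_current keeps Leaf on the same tie
  cfg2 <- reprogramConfig(N = 4, tieBreak = "keep_current",
                          updateMode = "frozen")
  expect_identical(as.character(reprogramLabels(xyz, labels, cfg2)$labels[5]),
                   "Leaf")
})
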