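#' @rdname scoreClassification
#' @export
setClass("ClassificationReport",
  representation(correct = "numeric", totals = "numeric",
                 perClass = "numeric", overall = "numeric",
                 confusion = "matrix", nUnmatchedPred = "integer",
                 nUnmatchedTruth = "integer"))

setValidity("ClassificationReport", function(object) {
  lev <- componentLevels()
  if (!identical(names(object@correct), lev) ||
      !identical(names(object@totals), lev))
    return("correct/totals must be named by the component classes")
  if (any(object@correct > object@totals))
    return("per-class correct counts cannot exceed totals")
  if (!identical(dim(object@confusion), c(4L, 4L)))
    return("confusion matrix must be 4 x 4")
  TRUE
})

#' Pair predicted and truth points by coordinates
#'
#' Matches each predicted point to the truth point at the same spatial
#' position, within a coordinate tolerance (default 1e-9 m) that stands in
#' for exact floating-point equality. Unmatched points on either side are
#' counted and reported; two truth points inside the tolerance ball of one
#' predicted point (or two predictions claiming the same truth point) make
#' the matching ambiguous and raise an error.
#'
#' @param predicted,truth labeled [SpectralPointCloud()]s (non-empty).
#' @param tol coordinate tolerance in metres.
#' @param blockSize rows per block of the distance computation.
#' @return List with factors `predLabels` and `truthLabels` over the
#'   matched pairs, the pair index matrix `pairs`, and counts
#'   `nUnmatchedPred`, `nUnmatchedTruth`.
#' @export
matchPoints <- function(predicted, truth, tol = 1e-9, blockSize = 512L) {
  stopifnot(is(predicted, "SpectralPointCloud"), is(truth, "SpectralPointCloud"))
  if (!nPoints(predicted) || !nPoints(truth))
    stop("matching requires non-empty clouds")
  if (is.null(pointLabels(predicted)) || is.null(pointLabels(truth)))
    stop("both clouds must carry labels")
  cp <- coords(predicted); cq <- coords(truth)
  np <- nrow(cp)
  tol2 <- tol^2
  hit <- rep(NA_integer_, np)
  for (start in seq(1L, np, by = blockSize)) {
    rows <- start:min(start + blockSize - 1L, np)
    d2 <- outer(cp[rows, 1], cq[, 1], `-`)^2 +
          outer(cp[rows, 2], cq[, 2], `-`)^2 +
          outer(cp[rows, 3], cq[, 3], `-`)^2
    inball <- d2 <= tol2
    nhits <- rowSums(inball)
    if (any(nhits > 1L))
      stop(sprintf("ambiguous match: %d truth points within tolerance of predicted point %d",
                   max(nhits), rows[which(nhits > 1L)[1L]]))
    m <- nhits == 1L
    hit[rows[m]] <- max.col(inball, ties.method = "first")[m]
  }
  dup <- hit[!is.na(hit)][duplicated(hit[!is.na(hit)])]
  if (length(dup))
    stop(sprintf("ambiguous match: truth point %d claimed by multiple predicted points",
                 dup[1L]))
  matched <- which(!is.na(hit))
  list(predLabels = pointLabels(predicted)[matched],
       truthLabels = pointLabels(truth)[hit[matched]],
       pairs = cbind(predicted = matched, truth = hit[matched]),
       nUnmatchedPred = np - length(matched),
       nUnmatchedTruth = nrow(cq) - length(matched))
}

#' Classification accuracy report
#'
#' Scores paired predicted/truth labels. With \eqn{T_j} the correctly
#' classified points of class \eqn{j} and \eqn{H_j} the truth-set total of
#' class \eqn{j}, the per-class accuracy is \eqn{K_j = T_j / H_j} and the
#' overall accuracy \eqn{K_{Overall} = \sum_j T_j / \sum_j H_j}, i.e. all
#' correctly classified points over all matched sample points. Classes
#' absent from the truth set get `K_j = NA` and contribute nothing to the
#' overall accuracy. The 4 x 4 confusion matrix (rows = truth,
#' columns = predicted) has row sums \eqn{H_j} and trace \eqn{\sum_j T_j}.
#'
#' @param predLabels,truthLabels paired per-point labels (equal length,
#'   non-empty), e.g. from [matchPoints()], or both taken from the same
#'   cloud for index-matched evaluation.
#' @param nUnmatchedPred,nUnmatchedTruth optional unmatched counts carried
#'   into the report.
#' @return A `ClassificationReport`.
#' @aliases ClassificationReport-class
#' @examples
#' truth <- rep(c("Wood", "Leaf"), c(6, 4))
#' pred <- truth; pred[c(1, 7)] <- c("Leaf", "Wood")
#' scoreClassification(pred, truth)
#' @export
scoreClassification <- function(predLabels, truthLabels,
                                nUnmatchedPred = 0L, nUnmatchedTruth = 0L) {
  predLabels <- componentFactor(predLabels)
  truthLabels <- componentFactor(truthLabels)
  if (!length(predLabels) || length(predLabels) != length(truthLabels))
    stop("paired labels must be non-empty and of equal length")
  conf <- table(truth = truthLabels, predicted = predLabels)
  conf <- unclass(conf)
  totals <- rowSums(conf)
  correct <- diag(conf)
  names(correct) <- rownames(conf)
  perClass <- ifelse(totals > 0, correct / totals, NA_real_)
  names(perClass) <- names(totals)
  new("ClassificationReport", correct = correct, totals = totals,
      perClass = perClass, overall = sum(correct) / sum(totals),
      confusion = conf, nUnmatchedPred = as.integer(nUnmatchedPred),
      nUnmatchedTruth = as.integer(nUnmatchedTruth))
}

#' Evaluate a predicted cloud against a truth cloud
#'
#' Convenience wrapper: coordinate-matches the two clouds ([matchPoints()])
#' and scores the paired labels ([scoreClassification()]). When prediction
#' and truth live on the same points, calling [scoreClassification()]
#' directly on the two label vectors is equivalent and faster; both paths
#' agree on shared-cloud inputs.
#'
#' @inheritParams matchPoints
#' @return A `ClassificationReport`.
#' @export
evaluateClouds <- function(predicted, truth, tol = 1e-9) {
  m <- matchPoints(predicted, truth, tol = tol)
  scoreClassification(m$predLabels, m$truthLabels,
                      nUnmatchedPred = m$nUnmatchedPred,
                      nUnmatchedTruth = m$nUnmatchedTruth)
}

#' @describeIn scoreClassification per-class accuracy \eqn{K_j}.
#' @param report a `ClassificationReport`.
#' @export
classAccuracy <- function(report) report@perClass

#' @describeIn scoreClassification overall accuracy \eqn{K_{Overall}}.
#' @export
overallAccuracy <- function(report) report@overall

#' @describeIn scoreClassification confusion matrix (truth x predicted).
#' @export
confusionMatrix <- function(report) report@confusion

#' @describeIn scoreClassification plain-list form (for JSON export).
#' @export
reportAsList <- function(report) {
  list(correct = as.list(report@correct),
       totals = as.list(report@totals),
       perClassAccuracy = as.list(report@perClass),
       overallAccuracy = report@overall,
       confusion = report@confusion,
       nUnmatchedPred = report@nUnmatchedPred,
       nUnmatchedTruth = report@nUnmatchedTruth)
}

setMethod("show", "ClassificationReport", function(object) {
  cat("ClassificationReport\n")
  df <- data.frame(class = names(object@totals),
                   total = as.integer(object@totals),
                   correct = as.integer(object@correct),
                   K = round(object@perClass, 4))
  print(df, row.names = FALSE)
  cat(sprintf("K_Overall = %.4f (%d/%d points)\n", object@overall,
              sum(object@correct), sum(object@totals)))
  if (object@nUnmatchedPred || object@nUnmatchedTruth)
    cat(sprintf("unmatched: %d predicted, %d truth\n",
                object@nUnmatchedPred, object@nUnmatchedTruth))
})
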