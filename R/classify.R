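#' Classifier configuration
#'
#' Bundles the preliminary-classifier settings. Defaults follow the
#' reference configuration: a random forest of 8 trees; an RBF support
#' vector machine with kernel coefficient `gamma = 0.1` and penalty
#' `C = 10`; a back-propagation neural network with one hidden layer of 5
#' sigmoid units (9 inputs, 4 outputs). Feature standardization defaults ON
#' for the scale-sensitive SVM and BPNN and OFF for the random forest, is
#' fitted on training data only, and is reused at prediction time.
#'
#' @param method `"rf"`, `"svm"` or `"bpnn"`.
#' @param rfTrees number of decision trees for `"rf"`.
#' @param svmGamma,svmCost RBF kernel coefficient and penalty for `"svm"`.
#' @param bpnnHidden hidden-layer size for `"bpnn"`.
#' @param bpnnMaxit maximum training epochs for `"bpnn"`.
#' @param scaling `"standardize"` or `"none"`; `NULL` picks the per-method
#'   default described above.
#' @param seed integer seed controlling all training randomness.
#' @return A list of class `classifierConfig`.
#' @export
classifierConfig <- function(method = c("rf", "svm", "bpnn"),
                             rfTrees = 8L, svmGamma = 0.1, svmCost = 10,
                             bpnnHidden = 5L, bpnnMaxit = 500L,
                             scaling = NULL, seed = 1L) {
  method <- match.arg(method)
  if (is.null(scaling))
    scaling <- if (method == "rf") "none" else "standardize"
  scaling <- match.arg(scaling, c("standardize", "none"))
  stopifnot(rfTrees >= 1, svmGamma > 0, svmCost > 0, bpnnHidden >= 1)
  structure(list(method = method, rfTrees = as.integer(rfTrees),
                 svmGamma = svmGamma, svmCost = svmCost,
                 bpnnHidden = as.integer(bpnnHidden),
                 bpnnMaxit = as.integer(bpnnMaxit),
                 scaling = scaling, seed = as.integer(seed)),
            class = "classifierConfig")
}

#' Random train/validation split
#'
#' Uniform random (unstratified) split of point indices in the configured
#' ratio, 7:3 by default. The training-set size is `round(n * trainFraction)`.
#'
#' @param n number of points, or anything with one row per point.
#' @param trainFraction fraction assigned to training, in (0, 1).
#' @param seed integer seed; the split is reproducible for a fixed seed.
#' @param labels optional per-point labels; a warning is issued when a class
#'   present in the data is absent from the training split.
#' @return List with integer index vectors `train` and `validation`,
#'   disjoint and jointly exhaustive.
#' @export
splitDataset <- function(n, trainFraction = 0.7, seed = 1L, labels = NULL) {
  if (!is.numeric(n) || length(n) != 1L) n <- nrow(n)
  stopifnot(trainFraction > 0, trainFraction < 1)
  set.seed(seed)
  ntrain <- round(n * trainFraction)
  train <- sort(sample.int(n, ntrain))
  validation <- setdiff(seq_len(n), train)
  if (!is.null(labels)) {
    lost <- setdiff(unique(as.character(labels)),
                    unique(as.character(labels[train])))
    if (length(lost))
      warning("class(es) absent from the training split: ",
              paste(lost, collapse = ", "))
  }
  list(train = train, validation = validation)
}

#' @rdname trainClassifier
#' @export
setClass("ComponentClassifier",
  representation(fit = "ANY", config = "list", featureNames = "character",
                 center = "numeric", scale = "numeric",
                 trainCounts = "table"))

setMethod("show", "ComponentClassifier", function(object) {
  cat(sprintf("ComponentClassifier (%s), %d features, trained on %d points\n",
              object@config$method, length(object@featureNames),
              sum(object@trainCounts)))
  print(object@trainCounts)
})

.standardize_fit <- function(x) {
  ctr <- colMeans(x)
  sc <- apply(x, 2L, stats::sd)
  sc[!is.finite(sc) | sc < 1e-12] <- 1  # variance floor: constant features
  list(center = ctr, scale = sc)
}

#' Train a preliminary component classifier
#'
#' Fits the configured model on a per-point feature table. The heavy
#' lifting is delegated to `randomForest`, `e1071::svm` and `nnet::nnet`;
#' this wrapper owns the feature-name contract, the train-only
#' standardization, the class codebook and seed control.
#'
#' @param features points x 9 matrix with columns [featureNames()].
#' @param labels per-point component labels; at least two classes must be
#'   present and features must be free of missing values.
#' @param config a [classifierConfig()].
#' @return A `ComponentClassifier`.
#' @aliases ComponentClassifier-class predict,ComponentClassifier-method
#' @export
trainClassifier <- function(features, labels, config = classifierConfig()) {
  features <- as.matrix(features)
  if (!identical(colnames(features), featureNames()))
    stop("feature columns must be exactly featureNames(), in order")
  labels <- componentFactor(labels)
  if (nrow(features) != length(labels))
    stop("features and labels disagree on point count")
  bad <- which(!stats::complete.cases(features) | !is.finite(rowSums(features)))
  if (length(bad))
    stop("missing/non-finite feature values at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ...")
  present <- droplevels(labels)
  if (nlevels(present) < 2L)
    stop("training requires at least two classes present")
  ctr <- rep(0, ncol(features)); sc <- rep(1, ncol(features))
  if (config$scaling == "standardize") {
    s <- .standardize_fit(features)
    ctr <- s$center; sc <- s$scale
  }
  x <- scale(features, center = ctr, scale = sc)
  set.seed(config$seed)
  fit <- switch(config$method,
    rf = randomForest::randomForest(x = x, y = present,
                                    ntree = config$rfTrees),
    svm = e1071::svm(x = x, y = present, kernel = "radial",
                     gamma = config$svmGamma, cost = config$svmCost,
                     scale = FALSE),
    bpnn = nnet::nnet(x = x, y = nnet::class.ind(present),
                      size = config$bpnnHidden, softmax = TRUE,
                      maxit = config$bpnnMaxit, trace = FALSE))
  new("ComponentClassifier", fit = fit, config = unclass(config),
      featureNames = colnames(features), center = ctr, scale = sc,
      trainCounts = table(labels))
}

#' @describeIn trainClassifier predict component labels for a new feature
#'   table (names/order must match training). Returns a factor with the
#'   component levels, one per row; predictions are invariant to row order.
#' @param object a trained `ComponentClassifier`.
#' @param newdata points x 9 feature matrix.
#' @param ... ignored.
#' @export
setMethod("predict", "ComponentClassifier", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!identical(colnames(newdata), object@featureNames))
    stop("feature columns do not match the training feature names/order")
  if (!nrow(newdata))
    return(factor(character(), levels = componentLevels()))
  x <- scale(newdata, center = object@center, scale = object@scale)
  cls <- switch(object@config$method,
    rf = {
      # aggregate votes ourselves: randomForest's own tie-break is random,
      # which would make predictions depend on row order
      v <- predict(object@fit, x, type = "vote", norm.votes = FALSE)
      colnames(v)[max.col(v, ties.method = "first")]
    },
    svm = as.character(predict(object@fit, x)),
    bpnn = {
      p <- predict(object@fit, x)
      colnames(p)[max.col(p, ties.method = "first")]
    })
  componentFactor(cls)
})
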