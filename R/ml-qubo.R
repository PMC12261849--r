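#' Training configuration for the learned quadratic yield model
#'
#' Defaults mirror the standard training recipe for this model family:
#' 200 epochs of full-batch Adam at learning rate 1e-3, an ensemble of 5
#' members, and an 80:10:10 train/validation/test split drawn independently
#' per member.
#'
#' @param epochs training epochs per member.
#' @param learningRate Adam step size.
#' @param ensembleSize number of ensemble members.
#' @param seed master seed; member seeds are derived deterministically.
#' @param splitRatios train/validation/test fractions summing to 1.
#' @param batchSize rows per gradient step; `NULL` = full batch.
#' @param initScale standard deviation of the random initial Q entries.
#' @param lrDecay final-epoch learning-rate fraction; the step size decays
#'   geometrically from `learningRate` to `learningRate * lrDecay`. The
#'   default 1 keeps it constant (the standard recipe); a small value
#'   (e.g. 1e-3) drives the optimizer to machine-level convergence on
#'   noiseless data, where constant-step Adam stalls at a floor
#'   proportional to the step size.
#' @return a named list.
#' @export
mlTrainConfig <- function(epochs = 200, learningRate = 1e-3, ensembleSize = 5,
                          seed = 1, splitRatios = c(0.8, 0.1, 0.1),
                          batchSize = NULL, initScale = 0.01, lrDecay = 1) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (abs(sum(splitRatios) - 1) > 1e-8) stop("splitRatios must sum to 1")
  if (lrDecay <= 0 || lrDecay > 1) stop("lrDecay must be in (0, 1]")
  list(epochs = as.integer(epochs), learningRate = learningRate,
       ensembleSize = as.integer(ensembleSize), seed = as.integer(seed),
       splitRatios = splitRatios, batchSize = batchSize,
       initScale = initScale, lrDecay = lrDecay)
}

.memberSeed <- function(master, m) (as.integer(master) * 1009L + m) %% .Machine$integer.max

#' Initialise a learned-Q ensemble
#'
#' Each member is an unconstrained n-by-n matrix initialised as
#' `initScale * N(0, 1)` draws under a member-specific seed derived from
#' the master seed, so early predictions start near the target mean and
#' the whole ensemble is reproducible.
#'
#' @param n input dimension (length of the feature vector).
#' @param config a [mlTrainConfig()].
#' @return an untrained [MlQuboModel-class] (target stats set to 0/1).
#' @export
mlQuboModel <- function(n, config = mlTrainConfig()) {
  if (n < 1) stop("n must be >= 1")
  members <- lapply(seq_len(config$ensembleSize), function(m) {
    set.seed(.memberSeed(config$seed, m))
    matrix(stats::rnorm(n * n, sd = config$initScale), n, n)
  })
  new("MlQuboModel", members = members, targetMean = 0, targetStd = 1,
      segments = data.frame(), config = config,
      history = data.frame(member = integer(0), epoch = integer(0),
                           train = numeric(0), validation = numeric(0)))
}

.quadForm <- function(X, Q) rowSums((X %*% Q) * X)

#' Train the learned-Q ensemble by Adam on the RMSE loss
#'
#' Targets are standardized to zero mean and unit standard deviation (the
#' statistics are stored in the model and inverted at prediction). Each
#' member draws its own 80:10:10 split with its member seed, minimises the
#' RMSE between `x' Q x` and the standardized target by full-batch Adam,
#' and keeps the epoch checkpoint with the lowest validation RMSE.
#'
#' @param model an [MlQuboModel-class] from [mlQuboModel()].
#' @param features numeric matrix (rows = samples, values in \{-1, 0, 1\})
#'   or list of [FeatureVector-class] objects.
#' @param yields numeric targets in \[0, 1\].
#' @param segments optional segment map stored with the model.
#' @return the trained model; per-epoch history in `mlHistory()`.
#' @export
trainMlQubo <- function(model, features, yields, segments = NULL) {
  X <- .asFeatureMatrix(features)
  n <- nrow(model@members[[1]])
  if (ncol(X) != n)
    stop("feature dimension ", ncol(X), " != model dimension ", n)
  if (nrow(X) != length(yields)) stop("features/yields length mismatch")
  cfg <- model@config
  mu <- mean(yields)
  sdv <- stats::sd(yields)
  if (!is.finite(sdv) || sdv < 1e-8) sdv <- 1  # constant-target guard
  t_all <- (yields - mu) / sdv

  hist <- list()
  members <- model@members
  for (m in seq_along(members)) {
    set.seed(.memberSeed(cfg$seed, m) + 7L)
    idx <- sample(nrow(X))
    nTr <- max(1L, floor(cfg$splitRatios[1] * nrow(X)))
    nVal <- floor(cfg$splitRatios[2] * nrow(X))
    tr <- idx[seq_len(nTr)]
    val <- if (nVal > 0) idx[nTr + seq_len(nVal)] else integer(0)
    if (!length(tr)) stop("empty training split")
    Xtr <- X[tr, , drop = FALSE]; ttr <- t_all[tr]
    Xval <- X[val, , drop = FALSE]; tval <- t_all[val]

    Q <- members[[m]]
    mAd <- matrix(0, n, n); vAd <- matrix(0, n, n)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    bestQ <- Q; bestVal <- Inf
    trH <- valH <- numeric(cfg$epochs)
    batch <- cfg$batchSize
    decay <- if (is.null(cfg$lrDecay)) 1 else cfg$lrDecay
    lrAt <- if (cfg$epochs > 1)
      cfg$learningRate * decay^((seq_len(cfg$epochs) - 1) / (cfg$epochs - 1))
    else cfg$learningRate
    for (ep in seq_len(cfg$epochs)) {
      if (is.null(batch) || batch >= length(tr)) {
        groups <- list(seq_along(tr))
      } else {
        ord <- sample(length(tr))
        groups <- split(ord, ceiling(seq_along(ord) / batch))
      }
      for (g in groups) {
        Xb <- Xtr[g, , drop = FALSE]
        err <- .quadForm(Xb, Q) - ttr[g]
        rmse <- sqrt(mean(err^2))
        if (rmse < 1e-15) next
        grad <- crossprod(Xb, Xb * err) / (length(g) * rmse)
        mAd <- b1 * mAd + (1 - b1) * grad
        vAd <- b2 * vAd + (1 - b2) * grad^2
        mh <- mAd / (1 - b1^ep)
        vh <- vAd / (1 - b2^ep)
        Q <- Q - lrAt[ep] * mh / (sqrt(vh) + eps)
      }
      trH[ep] <- sqrt(mean((.quadForm(Xtr, Q) - ttr)^2))
      valH[ep] <- if (length(val))
        sqrt(mean((.quadForm(Xval, Q) - tval)^2)) else trH[ep]
      if (valH[ep] < bestVal) {
        bestVal <- valH[ep]
        bestQ <- Q
      }
    }
    members[[m]] <- bestQ
    hist[[m]] <- data.frame(member = m, epoch = seq_len(cfg$epochs),
                            train = trH, validation = valH)
  }
  model@members <- members
  model@targetMean <- mu
  model@targetStd <- sdv
  if (!is.null(segments)) model@segments <- segments
  model@history <- do.call(rbind, hist)
  model
}

.asFeatureMatrix <- function(features) {
  if (is.matrix(features)) return(features)
  if (is.numeric(features)) return(matrix(features, nrow = 1))
  if (is.list(features)) {
    if (methods::is(features[[1]], "FeatureVector"))
      return(do.call(rbind, lapply(features, featureValues)))
    return(do.call(rbind, features))
  }
  stop("features must be a matrix, numeric vector, or list of FeatureVectors")
}

#' Predict yields from a learned-Q ensemble
#'
#' The prediction for an input `x` is the ensemble mean of
#' `(x' Q x) * targetStd + targetMean`, i.e. the full (unsymmetrised)
#' bilinear form of each member mapped back to the yield scale. Predictions
#' are reported raw; clamp to \[0, 1\] only in presentation layers.
#'
#' @param object a trained [MlQuboModel-class].
#' @param newdata numeric vector, matrix (rows = samples), or list of
#'   [FeatureVector-class] objects.
#' @param ... unused.
#' @return numeric vector of predicted yields (fraction scale).
#' @export
setMethod("predict", "MlQuboModel", function(object, newdata, ...) {
  X <- .asFeatureMatrix(newdata)
  n <- nrow(object@members[[1]])
  if (ncol(X) != n)
    stop("input dimension ", ncol(X), " != model dimension ", n)
  P <- matrix(unlist(lapply(object@members, function(Q) .quadForm(X, Q))),
              nrow = nrow(X))
  rowMeans(P) * object@targetStd + object@targetMean
})

#' Export a member (or the ensemble mean) as a triangular QuboMatrix
#'
#' Folds the unconstrained n-by-n training matrix into single-count
#' upper-triangular form: `diag' = diag`, `off'[i,j] = Q[i,j] + Q[j,i]`
#' for `i < j`. The triangular energy equals the full bilinear form for
#' every assignment, so annealer inference over the export is exact. The
#' exported matrix is in standardized target units; map an energy `E` back
#' to a yield as `E * targetStd + targetMean`.
#'
#' @param model a trained [MlQuboModel-class].
#' @param member member index, or `NULL` for the ensemble-mean matrix
#'   (energies then equal the mean of per-member energies).
#' @param labels optional variable names.
#' @return a [QuboMatrix-class].
#' @export
exportTriangular <- function(model, member = NULL, labels = NULL) {
  Q <- if (is.null(member)) Reduce(`+`, model@members) / length(model@members)
       else model@members[[member]]
  n <- nrow(Q)
  up <- which(upper.tri(Q), arr.ind = TRUE)
  i <- c(seq_len(n), up[, 1])
  j <- c(seq_len(n), up[, 2])
  v <- c(diag(Q), Q[up] + t(Q)[up])
  QuboMatrix(n, i, j, v, offset = 0, labels = labels)
}

#' Conditional Q matrix for a fixed reaction
#'
#' Exports the (ensemble-mean) triangular Q, substitutes the fixed reaction
#' segment values, and returns the conditional matrix over the free
#' condition bits together with the affine map from conditional energy to
#' predicted yield: `yield = scale * quboEnergy(qubo, x) + shift`.
#'
#' @param model a trained [MlQuboModel-class].
#' @param fixed length-n vector with reaction values (-1/0/1) at fixed
#'   positions and `NA` at the free condition bits.
#' @return list with `qubo`, `scale`, `shift`.
#' @export
mlConditionQubo <- function(model, fixed) {
  tri <- exportTriangular(model)
  red <- reduceConditional(tri, fixed)
  list(qubo = red$qubo,
       scale = model@targetStd,
       shift = red$offsetDelta * model@targetStd + model@targetMean)
}
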