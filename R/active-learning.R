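#' Initialise active-learning folds
#'
#' Each fold is an independent restart: a seeded random draw of `nInit`
#' labelled points, with the rest of the dataset as the unlabelled pool.
#' Folds may overlap; they exist to average the stochastic trajectory.
#'
#' @param datasetSize number of rows in the fully labelled dataset.
#' @param nInit initial labelled set size (default 100).
#' @param nFolds number of folds (default 5).
#' @param seed master seed.
#' @return list of states, each `list(labeled, pool, fold, iteration)`.
#' @export
initFolds <- function(datasetSize, nInit = 100, nFolds = 5, seed = 1) {
  if (nInit >= datasetSize)
    stop("nInit (", nInit, ") must be smaller than the dataset (",
         datasetSize, ")")
  lapply(seq_len(nFolds), function(f) {
    set.seed(as.integer(seed) * 131L + f)
    lab <- sort(sample.int(datasetSize, nInit))
    list(labeled = lab, pool = setdiff(seq_len(datasetSize), lab),
         fold = f, iteration = 0L)
  })
}

#' Select the next labelling batch
#'
#' Selection rules:
#' \itemize{
#'   \item `random`: uniform without replacement from the pool.
#'   \item `strategic`: the `batch` pool points with the highest predicted
#'     yields (ties broken by smaller pool index).
#'   \item `adaptive`: at iteration `i` of `n`, `s = round(batch * i / n)`
#'     strategic picks first (round-half-up), then `batch - s` random picks
#'     from the remainder -- exploration early, exploitation late.
#' }
#' Selection reads only the predictions, never the pool's true yields.
#'
#' @param pool integer indices of the unlabelled pool.
#' @param poolPredictions predicted yields aligned with `pool`.
#' @param strategy `"random"`, `"strategic"` or `"adaptive"`.
#' @param batch batch size.
#' @param iteration,nIterations adaptive blend position `i` of `n`.
#' @return selected dataset indices (subset of `pool`).
#' @export
selectBatch <- function(pool, poolPredictions,
                        strategy = c("random", "strategic", "adaptive"),
                        batch = 50, iteration = 1, nIterations = 9) {
  strategy <- match.arg(strategy)
  if (length(pool) < batch) {
    warning("pool smaller than batch; returning the whole pool",
            call. = FALSE)
    return(pool)
  }
  strategicPick <- function(k) {
    if (k == 0) return(integer(0))
    ord <- order(-poolPredictions, seq_along(pool))
    pool[ord[seq_len(k)]]
  }
  if (strategy == "random")
    return(sample(pool, batch))
  if (strategy == "strategic")
    return(strategicPick(batch))
  s <- floor(batch * iteration / nIterations + 0.5)  # round half up
  s <- min(s, batch)
  strat <- strategicPick(s)
  rest <- setdiff(pool, strat)
  c(strat, if (batch - s > 0) sample(rest, batch - s) else integer(0))
}

#' Run the active-learning loop
#'
#' Per iteration: retrain the model from scratch on the labelled set,
#' score the model's top-k retrieval against the full dataset's true
#' ranking, predict the pool, select a batch with [selectBatch()], and
#' reveal its labels. The recorded history has `iters + 1` entries
#' (iteration 0 is the model on the seed set); with the defaults the
#' labelled set marches 100, 150, ..., 550.
#'
#' @param features numeric feature matrix (ML model) -- rows aligned with
#'   `yields`.
#' @param yields full ground-truth yields (revealed only on selection).
#' @param strategy selection strategy.
#' @param modelKind `"ml"` (learned-Q ensemble) or `"dau"` (binary-coded
#'   least-squares; requires `slotData`).
#' @param slotData data.frame of condition labels (DAU model only).
#' @param nInit,batch,iters,nFolds loop shape (defaults 100/50/9/5).
#' @param k top-k retrieval size scored each iteration.
#' @param seed master seed.
#' @param trainConfig an [mlTrainConfig()] for the ML model (its seed is
#'   re-derived per fold).
#' @return data.frame with one row per (fold, iteration): `fold`,
#'   `iteration`, `labeledSize`, `topk`.
#' @export
runActiveLearning <- function(features, yields,
                              strategy = c("random", "strategic", "adaptive"),
                              modelKind = c("ml", "dau"), slotData = NULL,
                              nInit = 100, batch = 50, iters = 9, nFolds = 5,
                              k = 10, seed = 1,
                              trainConfig = mlTrainConfig()) {
  strategy <- match.arg(strategy)
  modelKind <- match.arg(modelKind)
  if (modelKind == "dau" && is.null(slotData))
    stop("modelKind = 'dau' requires slotData")
  nAll <- length(yields)
  states <- initFolds(nAll, nInit = nInit, nFolds = nFolds, seed = seed)
  out <- list()
  for (st in states) {
    set.seed(as.integer(seed) * 7919L + st$fold)
    labeled <- st$labeled
    pool <- st$pool
    for (it in 0:iters) {
      predAll <- .alFitPredict(modelKind, features, slotData, labeled,
                               yields[labeled], trainConfig,
                               foldSeed = as.integer(seed) * 100L + st$fold)
      score <- topKScore(predAll, yields, k)
      out[[length(out) + 1L]] <- data.frame(
        fold = st$fold, iteration = it, labeledSize = length(labeled),
        topk = score)
      if (it == iters) break
      picked <- selectBatch(pool, predAll[pool], strategy, batch = batch,
                            iteration = it + 1L, nIterations = iters)
      labeled <- c(labeled, picked)
      pool <- setdiff(pool, picked)
    }
  }
  do.call(rbind, out)
}

.alFitPredict <- function(modelKind, features, slotData, labeled, labels,
                          trainConfig, foldSeed) {
  if (modelKind == "ml") {
    cfg <- trainConfig
    cfg$seed <- foldSeed %% .Machine$integer.max
    model <- mlQuboModel(ncol(features), cfg)
    model <- trainMlQubo(model, features[labeled, , drop = FALSE], labels)
    predict(model, features)
  } else {
    tab <- enumerateTerms(slotData[labeled, , drop = FALSE], names(slotData))
    model <- fitDau(slotData[labeled, , drop = FALSE], labels, tab,
                    seed = foldSeed)
    vapply(seq_len(nrow(slotData)), function(r) {
      asg <- vapply(names(slotData), function(s)
        as.character(slotData[[s]][r]), character(1))
      tryCatch(
        suppressWarnings(dauPredict(model, asg, unit = "fraction")),
        error = function(e) 0)  # unseen value: no information yet
    }, numeric(1))
  }
}
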