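#' @import methods
NULL

#' QuboMatrix: an upper-triangular quadratic form over binary variables
#'
#' Stores the coefficients of a quadratic unconstrained binary optimization
#' (QUBO) instance in single-count upper-triangular form: the energy of an
#' assignment `x` is `offset + sum over i <= j of Q[i,j] * x[i] * x[j]`.
#' Off-diagonal coefficients are stored once; use [symmetricMatrix()] for the
#' conventional symmetric display in which each pair coefficient appears in
#' both cells.
#'
#' @slot n number of binary variables.
#' @slot i,j 1-based term indices with `i <= j` (equal for diagonal terms).
#' @slot v term coefficients; finite, non-zero.
#' @slot offset constant added to every energy.
#' @slot labels optional variable names (length 0 or `n`).
#' @export
setClass("QuboMatrix",
  representation(n = "integer", i = "integer", j = "integer",
                 v = "numeric", offset = "numeric", labels = "character"),
  prototype(n = 0L, i = integer(0), j = integer(0), v = numeric(0),
            offset = 0, labels = character(0)))

setValidity("QuboMatrix", function(object) {
  msg <- character(0)
  if (length(object@i) != length(object@j) ||
      length(object@i) != length(object@v))
    msg <- c(msg, "i, j and v must have equal length")
  if (length(object@i)) {
    if (any(object@i < 1L) || any(object@j > object@n) ||
        any(object@i > object@j))
      msg <- c(msg, "term indices must satisfy 1 <= i <= j <= n")
    key <- paste(object@i, object@j)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (i, j) terms")
    if (!all(is.finite(object@v)))
      msg <- c(msg, "coefficients must be finite")
  }
  if (!is.finite(object@offset)) msg <- c(msg, "offset must be finite")
  if (length(object@labels) && length(object@labels) != object@n)
    msg <- c(msg, "labels must be empty or length n")
  if (length(msg)) msg else TRUE
})

#' FeatureVector: a segmented model input
#'
#' Concatenation of a reaction encoding (values in \{-1, 0, 1\}; fingerprints
#' or one-hot bits) and one-hot condition encodings (binary), with a segment
#' map so each block can be recovered exactly.
#'
#' @slot values numeric vector over \{-1, 0, 1\}.
#' @slot segments data.frame with columns `name`, `start`, `length`, `kind`
#'   (`"reaction"` or `"condition"`); segments partition the vector.
#' @export
setClass("FeatureVector",
  representation(values = "numeric", segments = "data.frame"))

setValidity("FeatureVector", function(object) {
  seg <- object@segments
  msg <- character(0)
  need <- c("name", "start", "length", "kind")
  if (!all(need %in% names(seg)))
    return("segments needs columns name, start, length, kind")
  if (nrow(seg)) {
    cover <- unlist(Map(function(s, l) seq.int(s, length.out = l),
                        seg$start, seg$length))
    if (!identical(sort(cover), seq_along(object@values)))
      msg <- c(msg, "segments must partition the vector")
    for (r in seq_len(nrow(seg))) {
      idx <- seq.int(seg$start[r], length.out = seg$length[r])
      if (seg$kind[r] == "condition" &&
          !all(object@values[idx] %in% c(0, 1)))
        msg <- c(msg, sprintf("condition segment '%s' must be binary",
                              seg$name[r]))
    }
  } else if (length(object@values)) {
    msg <- c(msg, "non-empty values require segments")
  }
  if (!all(object@values %in% c(-1, 0, 1)))
    msg <- c(msg, "values must lie in {-1, 0, 1}")
  if (length(msg)) msg else TRUE
})

#' TermTable: condition terms of the binary-coded least-squares model
#'
#' Maps every observed condition value (singleton term) and every observed
#' cross-slot pair of condition values (pair term) to a contiguous block of
#' `width` binary variables. Each block encodes one signed integer
#' coefficient via `sum(2^k * b_k) - 2^(width - 1)`.
#'
#' @slot terms data.frame with columns `kind` ("single"/"pair"), `slotA`,
#'   `valueA`, `slotB`, `valueB` (NA for singletons), `start` (1-based first
#'   bit of the block).
#' @slot width bits per coefficient (default 10, giving the range
#'   \[-512, 511\]).
#' @slot slotNames declared slot order.
#' @export
setClass("TermTable",
  representation(terms = "data.frame", width = "integer",
                 slotNames = "character"))

setValidity("TermTable", function(object) {
  msg <- character(0)
  if (object@width < 1L) msg <- c(msg, "width must be >= 1")
  tt <- object@terms
  if (nrow(tt)) {
    expect <- seq.int(1L, by = object@width, length.out = nrow(tt))
    if (!identical(as.integer(tt$start), expect))
      msg <- c(msg, "bit blocks must be contiguous and disjoint")
    pair <- tt$kind == "pair"
    if (any(pair & (tt$slotA == tt$slotB)))
      msg <- c(msg, "pair terms must span two different slots")
  }
  if (length(msg)) msg else TRUE
})

#' DauModel: fitted binary-coded least-squares yield model
#'
#' Holds one decoded integer coefficient (per-mille of yield) per term of a
#' [TermTable], the sum of squared errors of the fit, and the target scale.
#'
#' @slot table the [TermTable] the model was fitted over.
#' @slot coefficients decoded integer coefficient per term, in table order.
#' @slot sse sum of squared errors (scaled-target units) at the fit.
#' @slot scale target multiplier (default 1000: yields fitted in per-mille).
#' @export
setClass("DauModel",
  representation(table = "TermTable", coefficients = "numeric",
                 sse = "numeric", scale = "numeric"))

setValidity("DauModel", function(object) {
  msg <- character(0)
  if (length(object@coefficients) != nrow(object@table@terms))
    msg <- c(msg, "one coefficient per term required")
  half <- 2^(object@table@width - 1)
  if (length(object@coefficients) &&
      (any(object@coefficients < -half) || any(object@coefficients > half - 1)))
    msg <- c(msg, sprintf("coefficients must lie in [%d, %d]", -half, half - 1))
  if (length(msg)) msg else TRUE
})

#' MlQuboModel: ensemble of learned quadratic yield models
#'
#' Each member is an unconstrained n-by-n real matrix Q; a standardized
#' yield is predicted as the bilinear form `x' Q x` and mapped back through
#' the stored target mean and standard deviation. Predictions average over
#' members.
#'
#' @slot members list of n-by-n numeric matrices.
#' @slot targetMean,targetStd normalization statistics of the training
#'   targets (std floored at a small positive value).
#' @slot segments optional segment map of the expected input (data.frame as
#'   in [FeatureVector]).
#' @slot config training configuration (see [mlTrainConfig()]).
#' @slot history per-epoch train/validation RMSE per member.
#' @export
setClass("MlQuboModel",
  representation(members = "list", targetMean = "numeric",
                 targetStd = "numeric", segments = "data.frame",
                 config = "list", history = "data.frame"))

setValidity("MlQuboModel", function(object) {
  msg <- character(0)
  if (!length(object@members)) msg <- c(msg, "at least one member required")
  dims <- vapply(object@members, function(m) {
    if (!is.matrix(m) || nrow(m) != ncol(m)) -1L else nrow(m)
  }, integer(1))
  if (any(dims < 0L) || length(unique(dims)) > 1L)
    msg <- c(msg, "members must be square matrices of a common size")
  if (length(object@targetStd) != 1L || object@targetStd <= 0)
    msg <- c(msg, "targetStd must be a single positive number")
  if (length(msg)) msg else TRUE
})

setMethod("show", "QuboMatrix", function(object) {
  cat(sprintf("QuboMatrix: %d variables, %d terms, offset %g\n",
              object@n, length(object@v), object@offset))
  if (length(object@labels))
    cat("  labels:", paste(utils::head(object@labels, 6), collapse = ", "),
        if (object@n > 6) "..." else "", "\n")
})

setMethod("show", "FeatureVector", function(object) {
  cat(sprintf("FeatureVector: length %d, %d segments (%s)\n",
              length(object@values), nrow(object@segments),
              paste(object@segments$name, collapse = ", ")))
})

setMethod("show", "TermTable", function(object) {
  tt <- object@terms
  cat(sprintf("TermTable: %d terms (%d singletons, %d pairs), %d bits\n",
              nrow(tt), sum(tt$kind == "single"), sum(tt$kind == "pair"),
              nrow(tt) * object@width))
})

setMethod("show", "DauModel", function(object) {
  cat(sprintf("DauModel: %d coefficients, SSE %.6g, scale %g\n",
              length(object@coefficients), object@sse, object@scale))
})

setMethod("show", "MlQuboModel", function(object) {
  cat(sprintf(
    "MlQuboModel: %d members of size %dx%d, target mean %.4g, sd %.4g\n",
    length(object@members), nrow(object@members[[1]]),
    ncol(object@members[[1]]), object@targetMean, object@targetStd))
})

#' @rdname QuboMatrix-class
#' @param q a `QuboMatrix`.
#' @export
quboDim <- function(q) q@n

#' @rdname QuboMatrix-class
#' @export
quboOffset <- function(q) q@offset

#' @rdname QuboMatrix-class
#' @export
quboLabels <- function(q) q@labels

#' @rdname QuboMatrix-class
#' @return `quboTerms()`: data.frame with columns `i`, `j`, `value`.
#' @export
quboTerms <- function(q) data.frame(i = q@i, j = q@j, value = q@v)

#' @rdname FeatureVector-class
#' @param x a `FeatureVector`.
#' @export
featureValues <- function(x) x@values

#' @rdname FeatureVector-class
#' @export
featureSegments <- function(x) x@segments

#' Extract one segment of a FeatureVector
#'
#' @param x a [FeatureVector].
#' @param name segment name.
#' @return the numeric values of that segment.
#' @export
sliceSegment <- function(x, name) {
  seg <- x@segments
  r <- match(name, seg$name)
  if (is.na(r)) stop("no segment named '", name, "'")
  x@values[seq.int(seg$start[r], length.out = seg$length[r])]
}

#' @rdname TermTable-class
#' @param table a `TermTable`.
#' @export
termTable <- function(table) table@terms

#' @rdname TermTable-class
#' @export
termBits <- function(table) nrow(table@terms) * table@width

#' @rdname DauModel-class
#' @param model a `DauModel`.
#' @export
dauCoefficients <- function(model) {
  tt <- model@table@terms
  nm <- ifelse(tt$kind == "single",
               paste(tt$slotA, tt$valueA, sep = ":"),
               paste(paste(tt$slotA, tt$valueA, sep = ":"),
                     paste(tt$slotB, tt$valueB, sep = ":"), sep = "|"))
  stats::setNames(model@coefficients, nm)
}

#' @rdname MlQuboModel-class
#' @param model a `MlQuboModel`.
#' @export
mlMembers <- function(model) model@members

#' @rdname MlQuboModel-class
#' @export
mlHistory <- function(model) model@history
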