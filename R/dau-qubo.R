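#' Enumerate terms for the binary-coded least-squares model
#'
#' Creates one singleton term per distinct (slot, value) and one pair term
#' per distinct cross-slot value pair that co-occurs in at least one row;
#' unobserved pairs get no variables. Order is deterministic: slots in the
#' declared order, values in first appearance, slot pairs in declared-order
#' combination. Each term receives a contiguous block of `width` bits.
#'
#' @param data data.frame with one single-valued label column per slot.
#' @param slotNames condition slots, in declared order.
#' @param width bits per coefficient (default 10: signed range
#'   \[-512, 511\] at 1 per-mille granularity).
#' @return a [TermTable-class].
#' @export
enumerateTerms <- function(data, slotNames, width = 10) {
  if (!nrow(data)) stop("empty dataset")
  missing <- setdiff(slotNames, names(data))
  if (length(missing))
    stop("unknown slot(s): ", paste(missing, collapse = ", "))
  rows <- list()
  for (s in slotNames) {
    for (v in unique(as.character(data[[s]])))
      rows[[length(rows) + 1L]] <-
        data.frame(kind = "single", slotA = s, valueA = v,
                   slotB = NA_character_, valueB = NA_character_,
                   stringsAsFactors = FALSE)
  }
  if (length(slotNames) > 1) {
    for (a in seq_len(length(slotNames) - 1)) {
      for (b in (a + 1):length(slotNames)) {
        sa <- slotNames[a]; sb <- slotNames[b]
        pairKey <- paste(data[[sa]], data[[sb]], sep = "\r")
        firsts <- !duplicated(pairKey)
        for (r in which(firsts))
          rows[[length(rows) + 1L]] <-
            data.frame(kind = "pair", slotA = sa,
                       valueA = as.character(data[[sa]][r]), slotB = sb,
                       valueB = as.character(data[[sb]][r]),
                       stringsAsFactors = FALSE)
      }
    }
  }
  tt <- do.call(rbind, rows)
  tt$start <- seq.int(1L, by = as.integer(width), length.out = nrow(tt))
  new("TermTable", terms = tt, width = as.integer(width),
      slotNames = as.character(slotNames))
}

#' Decode a coefficient code
#'
#' A block of `width` bits encodes the signed integer
#' `sum(2^k * b_k) - 2^(width - 1)`; with the default 10 bits the 1024
#' codes map bijectively onto the integers \[-512, 511\].
#'
#' @param bits 0/1 vector of length `width` (bit k weights `2^k`).
#' @param width expected code width.
#' @return the decoded integer.
#' @examples
#' b <- integer(10); b[c(7, 9)] <- 1L  # bits 6 and 8 set
#' decodeCoefficient(b)  # -192
#' @export
decodeCoefficient <- function(bits, width = 10) {
  if (length(bits) != width)
    stop("expected ", width, " bits, got ", length(bits))
  if (!all(bits %in% c(0, 1))) stop("bits must be 0/1")
  sum(bits * 2^(seq_along(bits) - 1)) - 2^(width - 1)
}

#' @rdname decodeCoefficient
#' @param value integer in `[-2^(width-1), 2^(width-1) - 1]`.
#' @return `encodeCoefficient()`: the 0/1 code of length `width`.
#' @export
encodeCoefficient <- function(value, width = 10) {
  half <- 2^(width - 1)
  if (value < -half || value > half - 1)
    stop("value ", value, " outside [", -half, ", ", half - 1, "]")
  u <- value + half
  as.integer(bitwAnd(u %/% 2^(0:(width - 1)), 1L))
}

.activeTerms <- function(row, table) {
  tt <- table@terms
  out <- integer(0)
  for (s in table@slotNames) {
    hit <- which(tt$kind == "single" & tt$slotA == s &
                   tt$valueA == as.character(row[[s]]))
    if (!length(hit))
      stop("row references value '", row[[s]], "' absent from the term ",
           "table for slot '", s, "'")
    out <- c(out, hit)
  }
  pr <- which(tt$kind == "pair")
  for (p in pr) {
    if (as.character(row[[tt$slotA[p]]]) == tt$valueA[p] &&
        as.character(row[[tt$slotB[p]]]) == tt$valueB[p])
      out <- c(out, p)
  }
  # every cross-slot pair of this row must be in the table
  ns <- length(table@slotNames)
  if (ns > 1) {
    nPairsExpected <- choose(ns, 2)
    if (sum(tt$kind[out] == "pair") != nPairsExpected)
      stop("row references a condition pair absent from the term table")
  }
  out
}

#' Build the least-squares QUBO over all coefficient code bits
#'
#' For each data row the predicted (scaled) yield is affine in the code
#' bits: `P = sum over active terms of (sum_k 2^k b_k - 2^(width-1))`.
#' Expanding `sum over rows of (P - scale * Y)^2` with `b^2 = b` gives a
#' QUBO whose energy plus the returned constant equals the sum of squared
#' errors exactly, for every assignment. Minimising it is least-squares
#' fitting by annealing.
#'
#' @param data data.frame of condition labels (one column per slot).
#' @param yields numeric yields in \[0, 1\].
#' @param table a [TermTable-class] from [enumerateTerms()].
#' @param scale target multiplier (default 1000: fit in per-mille).
#' @return list with `qubo` (offset 0) and `constant`;
#'   `quboEnergy(qubo, x) + constant == SSE(x)`.
#' @export
buildLsqQubo <- function(data, yields, table, scale = 1000) {
  if (!nrow(data)) stop("empty dataset")
  if (nrow(data) != length(yields)) stop("data/yields length mismatch")
  w <- table@width
  half <- 2^(w - 1)
  nBits <- termBits(table)
  diag_ <- numeric(nBits)
  M <- matrix(0, nBits, nBits)  # upper-triangular pair accumulation
  const <- 0
  pw <- 2^(0:(w - 1))
  for (r in seq_len(nrow(data))) {
    act <- .activeTerms(data[r, , drop = FALSE], table)
    bitIdx <- unlist(lapply(act, function(t)
      seq.int(table@terms$start[t], length.out = w)))
    wts <- rep(pw, length(act))
    ci <- -half * length(act) - scale * yields[r]
    diag_[bitIdx] <- diag_[bitIdx] + wts^2 + 2 * ci * wts
    cross <- outer(wts, wts)
    M[bitIdx, bitIdx] <- M[bitIdx, bitIdx] + 2 * cross
    const <- const + ci^2
  }
  up <- which(upper.tri(M) & M != 0, arr.ind = TRUE)
  q <- QuboMatrix(nBits,
                  i = c(seq_len(nBits), up[, 1]),
                  j = c(seq_len(nBits), up[, 2]),
                  v = c(diag_, M[up]),
                  offset = 0)
  list(qubo = q, constant = const)
}

#' Fit the binary-coded least-squares model
#'
#' Builds the least-squares QUBO and minimises it -- exactly by
#' enumeration when the instance has at most 24 bits (so small fits are
#' deterministic), otherwise with the simulated annealer -- then decodes
#' the best assignment term by term into integer per-mille coefficients.
#'
#' @param data data.frame of condition labels.
#' @param yields numeric yields in \[0, 1\].
#' @param table a [TermTable-class]; defaults to [enumerateTerms()] over all
#'   label columns of `data`.
#' @param scale target multiplier.
#' @param seed,sweeps,restarts annealer settings (ignored on the exact path).
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default: exact iff total bits <= 24.
#' @return a [DauModel-class].
#' @export
fitDau <- function(data, yields, table = NULL, scale = 1000, seed = 1,
                   sweeps = 4000, restarts = 20, exact = NULL) {
  if (is.null(table))
    table <- enumerateTerms(data, names(data))
  built <- buildLsqQubo(data, yields, table, scale)
  nBits <- termBits(table)
  if (is.null(exact)) exact <- nBits <= 24
  sol <- if (exact) bruteForceMinimize(built$qubo)
         else annealQubo(built$qubo, sweeps = sweeps, restarts = restarts,
                         seed = seed, topM = 1)[[1]]
  w <- table@width
  coefs <- vapply(seq_len(nrow(table@terms)), function(t) {
    bits <- sol$bits[seq.int(table@terms$start[t], length.out = w)]
    decodeCoefficient(bits, width = w)
  }, numeric(1))
  new("DauModel", table = table, coefficients = coefs,
      sse = sol$energy + built$constant, scale = scale)
}

#' Predict a yield from a fitted binary-coded model
#'
#' The prediction for a condition assignment is the sum of its singleton
#' coefficients plus every table-present pair coefficient among the
#' assigned values. Pairs unobserved at fit time carry no variables and
#' contribute 0 (with a warning). Values are reported raw (per-mille by
#' default); clamping to \[0, 1000\] is presentation only.
#'
#' @param model a [DauModel-class].
#' @param assignment named character vector, one value per slot.
#' @param unit `"permille"` or `"fraction"`.
#' @return the predicted yield.
#' @export
dauPredict <- function(model, assignment, unit = c("permille", "fraction")) {
  unit <- match.arg(unit)
  tt <- model@table@terms
  slots <- model@table@slotNames
  miss <- setdiff(slots, names(assignment))
  if (length(miss)) stop("assignment missing slot(s): ",
                         paste(miss, collapse = ", "))
  total <- 0
  for (s in slots) {
    hit <- which(tt$kind == "single" & tt$slotA == s &
                   tt$valueA == assignment[[s]])
    if (!length(hit))
      stop("unknown value '", assignment[[s]], "' for slot '", s, "'")
    total <- total + model@coefficients[hit]
  }
  if (length(slots) > 1) {
    for (a in seq_len(length(slots) - 1)) {
      for (b in (a + 1):length(slots)) {
        hit <- which(tt$kind == "pair" & tt$slotA == slots[a] &
                       tt$valueA == assignment[[slots[a]]] &
                       tt$slotB == slots[b] &
                       tt$valueB == assignment[[slots[b]]])
        if (length(hit)) {
          total <- total + model@coefficients[hit]
        } else {
          warning("pair (", slots[a], "=", assignment[[slots[a]]], ", ",
                  slots[b], "=", assignment[[slots[b]]],
                  ") unobserved at fit time; contributes 0", call. = FALSE)
        }
      }
    }
  }
  if (unit == "fraction") total / model@scale else total
}

#' Assemble the fitted coefficients into a Q matrix
#'
#' One QUBO variable per (slot, value) singleton, in table order; diagonal
#' cells hold the singleton coefficients and upper-triangular off-diagonal
#' cells the pair coefficients. [symmetricMatrix()] gives the conventional
#' symmetric display in which each pair coefficient is printed in both
#' cells. The triangular energy at an assignment activating one value per
#' slot equals [dauPredict()] for that assignment.
#'
#' @param model a [DauModel-class].
#' @return a [QuboMatrix-class] labelled `"slot:value"`.
#' @export
dauToQmatrix <- function(model) {
  tt <- model@table@terms
  singles <- which(tt$kind == "single")
  key <- paste(tt$slotA[singles], tt$valueA[singles], sep = ":")
  varOf <- stats::setNames(seq_along(singles), key)
  i <- seq_along(singles); j <- seq_along(singles)
  v <- model@coefficients[singles]
  for (p in which(tt$kind == "pair")) {
    a <- varOf[[paste(tt$slotA[p], tt$valueA[p], sep = ":")]]
    b <- varOf[[paste(tt$slotB[p], tt$valueB[p], sep = ":")]]
    i <- c(i, a); j <- c(j, b); v <- c(v, model@coefficients[p])
  }
  QuboMatrix(length(singles), i, j, v, offset = 0, labels = key)
}

#' Condition space implied by a fitted binary-coded model
#'
#' Builds the exactly-one-per-slot [conditionSpace()] whose bit order
#' matches the variable order of [dauToQmatrix()].
#'
#' @param model a [DauModel-class].
#' @return a condition space.
#' @export
dauConditionSpace <- function(model) {
  tt <- model@table@terms
  slots <- lapply(model@table@slotNames, function(s)
    tt$valueA[tt$kind == "single" & tt$slotA == s])
  names(slots) <- model@table@slotNames
  conditionSpace(slots)
}
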