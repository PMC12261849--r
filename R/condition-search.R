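#' Condition search spaces
#'
#' A condition space lists, per slot, the candidate value labels and the
#' cardinality bounds on how many may be selected at once. Bit order is
#' slot by slot, values in the given order, matching one-hot condition
#' segments. Typical shapes: one-value-per-slot screens use bounds
#' `c(1, 1)` (the default); sparse-literature searches use, e.g., 1-4
#' reagents and 0-2 solvents.
#'
#' @param slots named list of character vectors (candidate labels per slot).
#' @param bounds named list of `c(min, max)` per slot; missing entries
#'   default to `c(1, 1)`.
#' @return a `conditionSpace` list with `slots`, `bounds`, `starts`, `n`.
#' @export
conditionSpace <- function(slots, bounds = list()) {
  if (!length(slots)) stop("at least one slot required")
  for (nm in names(slots)) {
    b <- bounds[[nm]]
    if (is.null(b)) b <- c(1, 1)
    if (length(b) != 2 || b[1] < 0 || b[2] < b[1])
      stop("invalid bounds for slot '", nm, "'")
    if (b[2] > length(slots[[nm]]))
      stop("bounds for slot '", nm, "' exceed its vocabulary size")
    bounds[[nm]] <- as.integer(b)
  }
  lens <- lengths(slots)
  starts <- cumsum(c(1L, utils::head(lens, -1)))
  structure(list(slots = slots, bounds = bounds[names(slots)],
                 starts = stats::setNames(as.integer(starts), names(slots)),
                 n = as.integer(sum(lens))),
            class = "conditionSpace")
}

#' Count the feasible condition combinations of a space
#'
#' The product over slots of `sum over c in [min, max] of choose(m, c)`
#' where `m` is the slot's vocabulary size. Exact integer arithmetic (the
#' counts of interest fit a double exactly).
#'
#' @param space a [conditionSpace()].
#' @return the number of feasible assignments.
#' @export
countSpace <- function(space) {
  prod(vapply(names(space$slots), function(nm) {
    m <- length(space$slots[[nm]])
    b <- space$bounds[[nm]]
    sum(choose(m, b[1]:b[2]))
  }, numeric(1)))
}

#' Enumerate all feasible assignments of a small space
#'
#' @param space a [conditionSpace()]; total feasible count must be modest.
#' @param limit safety cap on the number of assignments.
#' @return integer 0/1 matrix, one row per feasible assignment, columns in
#'   the space's bit order.
#' @export
enumerateConditions <- function(space, limit = 2e5) {
  total <- countSpace(space)
  if (total > limit)
    stop("space has ", total, " feasible assignments; enumeration capped at ",
         limit)
  perSlot <- lapply(names(space$slots), function(nm) {
    m <- length(space$slots[[nm]])
    b <- space$bounds[[nm]]
    rows <- list()
    for (c_ in b[1]:b[2]) {
      sets <- if (c_ == 0) matrix(integer(0), nrow = 1, ncol = 0)
              else t(utils::combn(m, c_))
      for (r in seq_len(nrow(sets))) {
        bits <- integer(m)
        bits[sets[r, ]] <- 1L
        rows[[length(rows) + 1L]] <- bits
      }
    }
    do.call(rbind, rows)
  })
  out <- perSlot[[1]]
  for (k in seq_along(perSlot)[-1]) {
    a <- out[rep(seq_len(nrow(out)), each = nrow(perSlot[[k]])), , drop = FALSE]
    b <- perSlot[[k]][rep(seq_len(nrow(perSlot[[k]])), times = nrow(out)), ,
                      drop = FALSE]
    out <- cbind(a, b)
  }
  out
}

.checkFeasible <- function(bits, space) {
  for (nm in names(space$slots)) {
    idx <- seq.int(space$starts[[nm]], length.out = length(space$slots[[nm]]))
    s <- sum(bits[idx])
    b <- space$bounds[[nm]]
    if (s < b[1] || s > b[2]) return(FALSE)
  }
  TRUE
}

.decodeAssignment <- function(bits, space) {
  out <- lapply(names(space$slots), function(nm) {
    idx <- seq.int(space$starts[[nm]], length.out = length(space$slots[[nm]]))
    space$slots[[nm]][bits[idx] == 1]
  })
  stats::setNames(out, names(space$slots))
}

#' Build the penalty-constrained condition-search QUBO
#'
#' Negates the conditional yield matrix (so minimising energy maximises
#' predicted yield) and embeds the space's cardinality bounds as quadratic
#' penalties: exactly-one for `c(1, 1)` slots, otherwise an at-least-one
#' penalty when `min >= 1` plus an at-most-k penalty when `max` is below
#' the vocabulary size (slack bits are appended after the condition bits).
#' When the penalty weight does not dominate the energy span of the
#' negated objective, infeasible minimisers are possible and a warning is
#' issued.
#'
#' @param quboCond conditional [QuboMatrix-class] over exactly the space's
#'   condition bits.
#' @param space a [conditionSpace()].
#' @param lambda penalty strength; default `2 * max|coef| * n_cond`, a
#'   cheap dominance bound.
#' @return a [QuboMatrix-class] over condition + slack bits.
#' @export
buildSearchQubo <- function(quboCond, space, lambda = NULL) {
  if (quboCond@n != space$n)
    stop("conditional matrix spans ", quboCond@n, " bits but the space has ",
         space$n)
  userLambda <- !is.null(lambda)
  if (!userLambda)
    lambda <- 2 * max(abs(quboCond@v), 1e-9) * space$n
  if (userLambda) {
    span <- if (quboCond@n <= 16 && length(quboCond@v)) {
      e <- quboStateEnergies(quboCond)
      max(e) - min(e)
    } else {
      sum(abs(quboCond@v))
    }
    if (lambda < span)
      warning("penalty lambda (", signif(lambda, 4),
              ") below the energy span bound (", signif(span, 4),
              "); infeasible minimisers are possible", call. = FALSE)
  }
  q <- QuboMatrix(quboCond@n, quboCond@i, quboCond@j, -quboCond@v,
                  offset = -quboCond@offset,
                  labels = if (length(quboCond@labels)) quboCond@labels)
  for (nm in names(space$slots)) {
    idx <- seq.int(space$starts[[nm]], length.out = length(space$slots[[nm]]))
    b <- space$bounds[[nm]]
    if (b[1] == 1 && b[2] == 1) {
      q <- addPenalty(q, "exactly_one", idx, lambda = lambda)
    } else {
      if (b[1] >= 1) {
        if (b[1] > 1) stop("lower bounds above 1 are not supported")
        q <- addPenalty(q, "at_least_one", idx, lambda = lambda)
      }
      if (b[2] < length(idx))
        q <- addPenalty(q, "at_most_k", idx, k = b[2], lambda = lambda)
    }
  }
  q
}

#' Annealer-driven top-k condition search
#'
#' The hybrid inference workflow: a conditional Q matrix (learned
#' classically) is negated, constrained by quadratic penalties, and handed
#' to a solver -- exact enumeration when the penalised instance has at most
#' 20 bits, otherwise the simulated annealer. Returned assignments are
#' hard-filtered for feasibility (penalties are also in the QUBO, so
#' feasibility is double-enforced), deduplicated over slack bits, and
#' ranked by predicted yield `scale * energy(quboCond, x) + shift`.
#'
#' @param quboCond conditional [QuboMatrix-class] over the space's bits
#'   (e.g. from [mlConditionQubo()] or [dauToQmatrix()]).
#' @param space a [conditionSpace()].
#' @param k number of conditions to return.
#' @param scale,shift affine map from conditional energy to yield.
#' @param lambda penalty strength (see [buildSearchQubo()]).
#' @param seed,sweeps,restarts,budgetSeconds annealer settings.
#' @param solver `"auto"` (exact enumeration up to 20 penalised bits, else
#'   annealer), `"exact"`, or `"anneal"`.
#' @return data.frame with columns `rank`, `assignment` (labels,
#'   `"slot=v1+v2"` per slot, `; `-joined), `yield`, `energy`; the selected
#'   bit vectors are attached as `attr(, "bits")` and solver diagnostics as
#'   `attr(, "diagnostics")`.
#' @export
searchTopK <- function(quboCond, space, k, scale = 1, shift = 0,
                       lambda = NULL, seed = 1, sweeps = 3000, restarts = 20,
                       budgetSeconds = NULL,
                       solver = c("auto", "exact", "anneal")) {
  if (k < 1) stop("k must be >= 1")
  solver <- match.arg(solver)
  qs <- buildSearchQubo(quboCond, space, lambda = lambda)
  nCond <- space$n
  useExact <- switch(solver, exact = TRUE, anneal = FALSE,
                     auto = qs@n <= .maxStateTable)
  if (useExact) {
    e <- quboStateEnergies(qs)
    ord <- order(e)
    # keep enough states to cover slack degeneracy
    keep <- ord[seq_len(min(length(ord), max(4096, 64 * k)))]
    bits <- stateBits(keep - 1L, qs@n)[, seq_len(nCond), drop = FALSE]
    examined <- length(e)
    solver <- "exact"
  } else {
    sols <- annealQubo(qs, sweeps = sweeps, restarts = restarts, seed = seed,
                       topM = max(8 * k, 64), budgetSeconds = budgetSeconds)
    bits <- do.call(rbind, lapply(sols, function(s)
      s$bits[seq_len(nCond)]))
    examined <- length(sols)
    solver <- "anneal"
  }
  key <- apply(bits, 1, paste, collapse = "")
  bits <- bits[!duplicated(key), , drop = FALSE]
  feas <- apply(bits, 1, .checkFeasible, space = space)
  nInfeasible <- sum(!feas)
  bits <- bits[feas, , drop = FALSE]
  diag_ <- list(solver = solver, seed = seed, examined = examined,
                infeasibleFiltered = nInfeasible)
  if (!nrow(bits)) {
    res <- data.frame(rank = integer(0), assignment = character(0),
                      yield = numeric(0), energy = numeric(0))
    attr(res, "bits") <- bits
    attr(res, "diagnostics") <- diag_
    return(res)
  }
  energy <- apply(bits, 1, function(b) quboEnergy(quboCond, b))
  yield <- scale * energy + shift
  # yield ties broken by the lexicographically smallest bit vector so the
  # ranking is solver-independent
  ord <- order(-yield, apply(bits, 1, paste, collapse = ""))
  take <- ord[seq_len(min(k, length(ord)))]
  bits <- bits[take, , drop = FALSE]
  asg <- apply(bits, 1, function(b) {
    parts <- .decodeAssignment(b, space)
    paste(vapply(names(parts), function(nm)
      paste0(nm, "=", paste(parts[[nm]], collapse = "+")), character(1)),
      collapse = "; ")
  })
  res <- data.frame(rank = seq_along(take), assignment = asg,
                    yield = yield[take], energy = energy[take],
                    stringsAsFactors = FALSE)
  attr(res, "bits") <- bits
  attr(res, "diagnostics") <- diag_
  res
}

#' Random-sampling baseline over feasible conditions
#'
#' Samples assignments uniformly from the feasible set (per slot: a
#' cardinality drawn with probability proportional to the number of
#' subsets of that size, then a uniform subset), predicts each, and
#' summarises the yield distribution -- the classical-sampling comparator
#' to the annealer search.
#'
#' @param quboCond conditional [QuboMatrix-class].
#' @param space a [conditionSpace()].
#' @param nSamples number of random draws.
#' @param seed RNG seed.
#' @param scale,shift affine map from energy to yield.
#' @return list with `bestBits`, `bestYield`, `yields` (all samples), and
#'   `summary` (quantiles).
#' @export
randomBaseline <- function(quboCond, space, nSamples, seed = 1,
                           scale = 1, shift = 0) {
  if (nSamples < 1) stop("nSamples must be >= 1")
  set.seed(as.integer(seed))
  n <- space$n
  bits <- matrix(0L, nSamples, n)
  for (nm in names(space$slots)) {
    m <- length(space$slots[[nm]])
    b <- space$bounds[[nm]]
    sizes <- b[1]:b[2]
    wts <- choose(m, sizes)
    cs <- sample(sizes, nSamples, replace = TRUE, prob = wts)
    idx0 <- space$starts[[nm]] - 1L
    for (r in seq_len(nSamples)) {
      if (cs[r] > 0) {
        sel <- sample.int(m, cs[r])
        bits[r, idx0 + sel] <- 1L
      }
    }
  }
  yields <- apply(bits, 1, function(x)
    scale * quboEnergy(quboCond, x) + shift)
  best <- which.max(yields)
  list(bestBits = bits[best, ], bestYield = yields[best], yields = yields,
       summary = stats::quantile(yields))
}
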