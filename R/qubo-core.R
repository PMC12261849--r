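#' Construct a QuboMatrix
#'
#' Terms are given as parallel index/value vectors; indices with `i > j` are
#' transposed into the upper triangle, duplicate `(i, j)` keys are summed,
#' and exact-zero coefficients are dropped.
#'
#' @param n number of binary variables.
#' @param i,j 1-based term indices.
#' @param v coefficients.
#' @param offset constant energy offset.
#' @param labels optional variable names.
#' @return a [QuboMatrix-class] object.
#' @examples
#' q <- QuboMatrix(2, i = c(1, 1, 2), j = c(1, 2, 2), v = c(-192, 16, 256))
#' quboEnergy(q, c(1, 1))
#' @export
QuboMatrix <- function(n, i = integer(0), j = integer(0), v = numeric(0),
                       offset = 0, labels = NULL) {
  n <- as.integer(n)
  if (length(i) != length(j) || length(i) != length(v))
    stop("i, j and v must have equal length")
  i <- as.integer(i); j <- as.integer(j); v <- as.numeric(v)
  swap <- i > j
  if (any(swap)) {
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  }
  if (length(i)) {
    key <- paste(i, j)
    if (anyDuplicated(key)) {
      agg <- rowsum(v, key, reorder = FALSE)
      first <- !duplicated(key)
      i <- i[first]; j <- j[first]
      v <- as.numeric(agg[match(key[first], rownames(agg)), 1])
    }
    keep <- v != 0
    i <- i[keep]; j <- j[keep]; v <- v[keep]
    ord <- order(i, j)
    i <- i[ord]; j <- j[ord]; v <- v[ord]
  }
  new("QuboMatrix", n = n, i = i, j = j, v = v, offset = as.numeric(offset),
      labels = if (is.null(labels)) character(0) else as.character(labels))
}

#' Energy of an assignment under a triangular QUBO
#'
#' Computes `offset + sum over i <= j of Q[i,j] x[i] x[j]`. The assignment
#' may be binary or ternary (\{-1, 0, 1\}): ternary values arise when a fixed
#' reaction-difference segment is evaluated alongside binary condition bits.
#'
#' @param q a [QuboMatrix-class].
#' @param x assignment of length `quboDim(q)` over \{-1, 0, 1\}.
#' @return the scalar energy.
#' @export
quboEnergy <- function(q, x) {
  if (length(x) != q@n)
    stop("assignment length ", length(x), " != n = ", q@n)
  if (!all(x %in% c(-1, 0, 1)))
    stop("assignment values must lie in {-1, 0, 1}")
  q@offset + sum(q@v * x[q@i] * x[q@j])
}

.maxBruteForce <- 24L
.maxStateTable <- 20L

#' Exact minimisation of a small QUBO by exhaustive enumeration
#'
#' Enumerates all `2^n` assignments (Gray-code order, incremental energy
#' updates) and returns the global minimum; ties are broken by the
#' lexicographically smallest bit vector. Intended as the exact oracle for
#' [annealQubo()] on instances with at most 24 variables.
#'
#' @param q a [QuboMatrix-class] with `quboDim(q) <= 24`.
#' @param filter optional feasibility predicate `function(bits) -> logical`;
#'   requires `n <= 20` (the full state table is materialised).
#' @return list with `bits` (integer 0/1 vector) and `energy`.
#' @export
bruteForceMinimize <- function(q, filter = NULL) {
  n <- q@n
  if (n < 1L) stop("empty QUBO")
  if (n > .maxBruteForce)
    stop("n = ", n, " exceeds the brute-force cap of ", .maxBruteForce,
         "; use annealQubo()")
  if (is.null(filter))
    return(bf_minimize_cpp(n, q@i, q@j, q@v, q@offset))
  if (n > .maxStateTable)
    stop("filtered enumeration requires n <= ", .maxStateTable)
  e <- bf_energies_cpp(n, q@i, q@j, q@v, q@offset)
  states <- 0:(2^n - 1)
  bits <- stateBits(states, n)
  ok <- vapply(seq_along(states), function(r) isTRUE(filter(bits[r, ])),
               logical(1))
  if (!any(ok)) stop("no assignment satisfies the feasibility filter")
  e[!ok] <- Inf
  best <- which(e == min(e))
  # lexicographic tie-break on (x1, x2, ...)
  if (length(best) > 1L) {
    bb <- bits[best, , drop = FALSE]
    ordc <- do.call(order, as.data.frame(bb))
    best <- best[ordc[1]]
  }
  list(bits = bits[best, ], energy = e[best])
}

#' Energies of every assignment of a small QUBO
#'
#' @param q a [QuboMatrix-class] with at most 20 variables.
#' @return numeric vector of length `2^n`; entry `s + 1` is the energy of
#'   the assignment with `x[i] = bit (i-1) of s` (variable 1 is the
#'   least-significant bit).
#' @export
quboStateEnergies <- function(q) {
  if (q@n < 1L) stop("empty QUBO")
  if (q@n > .maxStateTable)
    stop("state table requires n <= ", .maxStateTable)
  bf_energies_cpp(q@n, q@i, q@j, q@v, q@offset)
}

#' Decode state indices into bit matrices
#'
#' @param states integer state indices (0-based).
#' @param n number of variables.
#' @return integer matrix, one row per state, column i = variable i.
#' @export
stateBits <- function(states, n) {
  m <- matrix(0L, length(states), n)
  for (b in seq_len(n))
    m[, b] <- bitwAnd(states %/% 2^(b - 1L), 1L)
  m
}

#' Simulated annealing for QUBO minimisation
#'
#' Single-bit-flip Metropolis dynamics under a geometric inverse-temperature
#' schedule, restarted from independent random states. The solver stands in
#' for special-purpose annealing hardware: it returns the `topM` distinct
#' lowest-energy assignments encountered, sorted by energy (ties broken by
#' the lexicographically smallest bit vector), and is fully deterministic
#' for a fixed `(seed, sweeps, restarts)`. When `budgetSeconds` is given,
#' additional restart batches are run until the wall-clock budget is spent;
#' leave it `NULL` for reproducible fixed-sweep runs.
#'
#' @param q a [QuboMatrix-class].
#' @param sweeps Monte-Carlo sweeps per restart (one attempted flip per
#'   variable per sweep).
#' @param restarts independent restarts per batch.
#' @param seed integer seed for the solver's own RNG stream.
#' @param topM number of distinct solutions to report.
#' @param budgetSeconds optional wall-clock budget; `NULL` = one batch.
#' @param betaRange optional `c(betaMin, betaMax)`; by default scaled to the
#'   largest absolute coefficient so early acceptance is near-free and the
#'   final temperature is effectively frozen.
#' @return list of solutions, each `list(bits, energy)`, energies
#'   non-decreasing.
#' @export
annealQubo <- function(q, sweeps = 2000, restarts = 10, seed = 1, topM = 1,
                       budgetSeconds = NULL, betaRange = NULL) {
  if (q@n < 1L) stop("empty QUBO")
  if (is.null(betaRange)) {
    cmax <- max(abs(q@v), 1e-9)
    betaRange <- c(0.1 / cmax, 100 / cmax)
  }
  run <- function(offsetIdx, nr) {
    anneal_cpp(q@n, q@i, q@j, q@v, q@offset, as.integer(sweeps),
               as.integer(nr), as.numeric(seed), as.integer(topM),
               betaRange[1], betaRange[2], as.integer(offsetIdx))
  }
  if (is.null(budgetSeconds)) {
    sols <- run(0L, restarts)
  } else {
    t0 <- Sys.time()
    all <- list()
    off <- 0L
    repeat {
      all <- c(all, run(off, restarts))
      off <- off + as.integer(restarts)
      if (as.numeric(difftime(Sys.time(), t0, units = "secs")) >=
          budgetSeconds) break
    }
    # merge batches: dedupe on bits, keep sorted top-M
    key <- vapply(all, function(s) paste(s$bits, collapse = ""), character(1))
    all <- all[!duplicated(key)]
    en <- vapply(all, `[[`, numeric(1), "energy")
    sols <- all[order(en)][seq_len(min(topM, length(all)))]
  }
  sols
}

#' Add a quadratic penalty constraint to a QUBO
#'
#' Constraints are embedded as squared affine penalties that vanish exactly
#' on feasible assignments:
#' \itemize{
#'   \item `exactly_one` over a set S: `lambda * (sum x_i - 1)^2`, i.e.
#'     diagonal `-lambda`, pairwise `+2 lambda`, offset `+lambda`.
#'   \item `at_most_k`: `lambda * (sum x_i + sum w_b s_b - k)^2` with
#'     `ceiling(log2(k + 1))` fresh slack bits; slack weights are plain
#'     powers of two with the top weight clamped so the encodable slack
#'     range is exactly `[0, k]`.
#'   \item `at_least_one`: `lambda * (sum x_i - 1 - sum w_b s_b)^2` with
#'     slack bits spanning `[0, |S| - 1]` (the complement-count form of an
#'     at-most constraint).
#' }
#' Slack variables are appended after the existing ones; the returned
#' matrix therefore may have a larger dimension.
#'
#' @param q a [QuboMatrix-class].
#' @param kind one of `"exactly_one"`, `"at_most_k"`, `"at_least_one"`.
#' @param variables 1-based indices the constraint ranges over.
#' @param k cardinality bound (only for `at_most_k`).
#' @param lambda positive penalty strength; must dominate the unpenalised
#'   energy span for minima to be feasible.
#' @return a new [QuboMatrix-class] (possibly with appended slack bits).
#' @export
addPenalty <- function(q, kind = c("exactly_one", "at_most_k", "at_least_one"),
                       variables, k = NULL, lambda) {
  kind <- match.arg(kind)
  variables <- as.integer(variables)
  if (!length(variables)) stop("empty variable set")
  if (any(variables < 1L) || any(variables > q@n))
    stop("constraint variables out of range")
  if (lambda <= 0) stop("lambda must be positive")

  slackW <- function(range) {
    # binary weights encoding exactly the integers [0, range]
    if (range <= 0) return(numeric(0))
    m <- ceiling(log2(range + 1))
    if (m == 1) return(range)
    c(2^(0:(m - 2)), range - (2^(m - 1) - 1))
  }

  if (kind == "exactly_one") {
    coefIdx <- variables; coefA <- rep(1, length(variables)); const <- -1
    w <- numeric(0)
  } else if (kind == "at_most_k") {
    if (is.null(k) || k < 0) stop("at_most_k requires k >= 0")
    w <- slackW(k)
    coefIdx <- c(variables, if (length(w)) q@n + seq_along(w))
    coefA <- c(rep(1, length(variables)), w)
    const <- -k
  } else { # at_least_one
    w <- slackW(length(variables) - 1L)
    coefIdx <- c(variables, if (length(w)) q@n + seq_along(w))
    coefA <- c(rep(1, length(variables)), -w)
    const <- -1
  }

  nNew <- q@n + length(w)
  # expand lambda * (sum a_u x_u + const)^2 with x^2 = x
  di <- coefIdx
  dv <- lambda * (coefA^2 + 2 * const * coefA)
  np <- length(coefIdx)
  pi_ <- integer(0); pj_ <- integer(0); pv_ <- numeric(0)
  if (np > 1) {
    cmb <- utils::combn(np, 2)
    pi_ <- coefIdx[cmb[1, ]]
    pj_ <- coefIdx[cmb[2, ]]
    pv_ <- 2 * lambda * coefA[cmb[1, ]] * coefA[cmb[2, ]]
  }
  labels <- q@labels
  if (length(labels) && length(w))
    labels <- c(labels, paste0("slack", q@n + seq_along(w)))
  QuboMatrix(nNew,
             i = c(q@i, di, pi_), j = c(q@j, di, pj_),
             v = c(q@v, dv, pv_),
             offset = q@offset + lambda * const^2,
             labels = if (length(labels)) labels else NULL)
}

#' Conditional reduction: substitute fixed variables into a QUBO
#'
#' Fixing a subset of variables (values may be -1, 0 or 1, as for a frozen
#' reaction-difference segment) folds fixed-fixed terms into a constant,
#' fixed-free terms into the free variables' diagonal, and copies free-free
#' terms, yielding the conditional matrix `Q_cond` over the remaining
#' binary condition variables. Energies are preserved exactly:
#' `quboEnergy(Q_cond, xf) + offsetDelta == quboEnergy(q, merged)` for every
#' free assignment `xf`.
#'
#' @param q a [QuboMatrix-class].
#' @param fixed numeric vector of length `quboDim(q)` with the fixed value
#'   (-1, 0 or 1) at fixed positions and `NA` at free positions.
#' @return list with `qubo` (the reduced matrix over free variables, same
#'   offset as `q`) and `offsetDelta` (energy folded out of the fixed part).
#' @export
reduceConditional <- function(q, fixed) {
  if (length(fixed) != q@n)
    stop("fixed must have length n = ", q@n)
  isFixed <- !is.na(fixed)
  if (any(!(fixed[isFixed] %in% c(-1, 0, 1))))
    stop("fixed values must lie in {-1, 0, 1}")
  freeIdx <- which(!isFixed)
  remap <- integer(q@n)
  remap[freeIdx] <- seq_along(freeIdx)

  delta <- 0
  ni <- integer(0); nj <- integer(0); nv <- numeric(0)
  for (t in seq_along(q@v)) {
    a <- q@i[t]; b <- q@j[t]; val <- q@v[t]
    fa <- isFixed[a]; fb <- isFixed[b]
    if (fa && fb) {
      delta <- delta + val * fixed[a] * fixed[b]
    } else if (fa || fb) {
      fr <- if (fa) b else a
      fx <- if (fa) a else b
      ni <- c(ni, remap[fr]); nj <- c(nj, remap[fr])
      nv <- c(nv, val * fixed[fx])
    } else {
      ni <- c(ni, remap[a]); nj <- c(nj, remap[b]); nv <- c(nv, val)
    }
  }
  labels <- if (length(q@labels)) q@labels[freeIdx] else NULL
  list(qubo = QuboMatrix(length(freeIdx), ni, nj, nv, offset = q@offset,
                         labels = labels),
       offsetDelta = delta)
}

#' Symmetric display form of a triangular QUBO
#'
#' Returns the dense matrix in which every off-diagonal pair coefficient is
#' printed in both cells, the convention used when Q matrices are displayed
#' as tables. This is presentation only: evaluating `x' M x` on the
#' symmetric form double-counts the pair terms relative to [quboEnergy()].
#'
#' @param q a [QuboMatrix-class].
#' @return an n-by-n numeric matrix.
#' @export
symmetricMatrix <- function(q) {
  m <- matrix(0, q@n, q@n)
  for (t in seq_along(q@v)) {
    m[q@i[t], q@j[t]] <- m[q@i[t], q@j[t]] + q@v[t]
    if (q@i[t] != q@j[t])
      m[q@j[t], q@i[t]] <- m[q@j[t], q@i[t]] + q@v[t]
  }
  if (length(q@labels)) dimnames(m) <- list(q@labels, q@labels)
  m
}

#' Read/write a QuboMatrix as JSON
#'
#' The on-disk form is `{"n": ..., "offset": ..., "terms": [[i, j, value],
#' ...], "labels": [...]}` with 1-based indices and full-precision decimal
#' values, so a write/read cycle is bit-exact.
#'
#' @param q a [QuboMatrix-class].
#' @param path file path.
#' @return `readQubo()` returns a [QuboMatrix-class]; `writeQubo()` its path,
#'   invisibly.
#' @export
writeQubo <- function(q, path) {
  # coefficients go out as 17-significant-digit decimal strings: that is
  # the shortest form guaranteed to reproduce an IEEE double bit-exactly
  terms <- if (length(q@v))
    lapply(seq_along(q@v), function(t)
      list(q@i[t], q@j[t], sprintf("%.17g", q@v[t])))
  else list()
  obj <- list(n = q@n, offset = sprintf("%.17g", q@offset), terms = terms)
  if (length(q@labels)) obj$labels <- as.list(q@labels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeQubo
#' @export
readQubo <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  terms <- obj$terms
  i <- vapply(terms, function(t) as.integer(t[[1]]), integer(1))
  j <- vapply(terms, function(t) as.integer(t[[2]]), integer(1))
  v <- vapply(terms, function(t) as.numeric(t[[3]]), numeric(1))
  QuboMatrix(as.integer(obj$n), i, j, v, offset = as.numeric(obj$offset),
             labels = if (!is.null(obj$labels)) unlist(obj$labels) else NULL)
}
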