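#' Specification of a synthetic high-throughput-experimentation grid
#'
#' Describes a full-factorial reaction screen with a planted quadratic
#' yield surface: per-value singleton effects, cross-slot pairwise effects,
#' Gaussian noise, and an optional right-skewed Beta base-yield for
#' emulating screens where most reactions perform poorly. The default slot
#' shape (15 substrates x 4 ligands x 3 bases x 20 additives = 3,600 wells)
#' matches a standard C-N cross-coupling screen layout.
#'
#' @param slots named integer vector of slot sizes.
#' @param mu base yield (fraction).
#' @param singletonScale sd of the planted per-value effects.
#' @param pairScale sd of the planted cross-slot pair effects.
#' @param sigma sd of the well-level Gaussian noise.
#' @param alpha,beta Beta shape parameters for skewed base yields
#'   (right-skewed when `alpha < beta`).
#' @param seed RNG seed; generation is byte-deterministic in (spec, seed).
#' @return a `hteGridSpec` list.
#' @export
hteGridSpec <- function(slots = c(substrate = 15, ligand = 4, base = 3,
                                  additive = 20),
                        mu = 0.3, singletonScale = 0.10, pairScale = 0.03,
                        sigma = 0.02, alpha = 2, beta = 8, seed = 1) {
  if (any(slots < 1)) stop("slot sizes must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  structure(list(slots = slots, mu = mu, singletonScale = singletonScale,
                 pairScale = pairScale, sigma = sigma, alpha = alpha,
                 beta = beta, seed = as.integer(seed)),
            class = "hteGridSpec")
}

#' Generate a full-factorial synthetic HTE grid
#'
#' Draws a planted model (singleton effects `N(0, singletonScale)` per
#' (slot, value), pairwise effects `N(0, pairScale)` per cross-slot value
#' pair), then emits every slot-value combination exactly once with
#' `yield = clip01(base + sum singleton + sum pairwise + eps)`,
#' `eps ~ N(0, sigma)`. With `skewed = FALSE` the base is the constant
#' `mu`; with `skewed = TRUE` each well draws its base from
#' `Beta(alpha, beta)`. Clipping to \[0, 1\] is the only nonlinearity, so
#' the planted surface stays inside the quadratic model class wherever the
#' clip is inactive.
#'
#' @param spec an [hteGridSpec()].
#' @param skewed use Beta-distributed base yields.
#' @return list with `data` (data.frame: `id`, one label column per slot,
#'   `yield`) and `model` (the planted ground truth: `mu`, `singleton`,
#'   `pairwise`, `sigma`).
#' @export
generateGrid <- function(spec, skewed = FALSE) {
  set.seed(spec$seed)
  slotNames <- names(spec$slots)
  values <- lapply(slotNames, function(s)
    paste0(s, seq_len(spec$slots[[s]])))
  names(values) <- slotNames

  singleton <- numeric(0)
  for (s in slotNames) {
    eff <- stats::rnorm(spec$slots[[s]], sd = spec$singletonScale)
    names(eff) <- paste(s, values[[s]], sep = ":")
    singleton <- c(singleton, eff)
  }
  pairwise <- numeric(0)
  if (length(slotNames) > 1) {
    for (a in seq_len(length(slotNames) - 1)) {
      for (b in (a + 1):length(slotNames)) {
        combos <- expand.grid(va = values[[slotNames[a]]],
                              vb = values[[slotNames[b]]],
                              stringsAsFactors = FALSE)
        eff <- stats::rnorm(nrow(combos), sd = spec$pairScale)
        names(eff) <- paste(paste(slotNames[a], combos$va, sep = ":"),
                            paste(slotNames[b], combos$vb, sep = ":"),
                            sep = "|")
        pairwise <- c(pairwise, eff)
      }
    }
  }

  grid <- expand.grid(values, stringsAsFactors = FALSE)
  n <- nrow(grid)
  base <- if (skewed) stats::rbeta(n, spec$alpha, spec$beta) else rep(spec$mu, n)
  y <- base
  for (s in slotNames)
    y <- y + singleton[paste(s, grid[[s]], sep = ":")]
  if (length(slotNames) > 1) {
    for (a in seq_len(length(slotNames) - 1)) {
      for (b in (a + 1):length(slotNames)) {
        key <- paste(paste(slotNames[a], grid[[slotNames[a]]], sep = ":"),
                     paste(slotNames[b], grid[[slotNames[b]]], sep = ":"),
                     sep = "|")
        y <- y + pairwise[key]
      }
    }
  }
  if (spec$sigma > 0) y <- y + stats::rnorm(n, sd = spec$sigma)
  y <- pmin(pmax(y, 0), 1)
  data <- cbind(data.frame(id = paste0("rxn", seq_len(n)),
                           stringsAsFactors = FALSE),
                grid, data.frame(yield = unname(y)))
  list(data = data,
       model = list(mu = spec$mu, singleton = singleton,
                    pairwise = pairwise, sigma = spec$sigma,
                    skewed = skewed, alpha = spec$alpha, beta = spec$beta))
}

#' @rdname generateGrid
#' @export
skewedYields <- function(spec) generateGrid(spec, skewed = TRUE)

#' Generate sparse literature-style reaction records
#'
#' Emulates reaction databases where each reaction carries a single
#' recorded condition set: 1-4 reagents and 0-2 solvents sampled per
#' record, a binary fingerprint whose active-bit probabilities are tilted
#' by the planted profiles of the chosen reagents, one temperature in
#' \[20, 150\], and a yield from a planted model (reagent and solvent main
#' effects plus a fingerprint-reagent bilinear term) plus noise, clipped to
#' \[0, 1\].
#'
#' @param nReactions number of records.
#' @param fpDim fingerprint width.
#' @param nReagents,nSolvents vocabulary sizes.
#' @param sigma noise sd.
#' @param seed RNG seed.
#' @return list with `data` (records: `id`, `reagents`, `solvents`,
#'   `temperatures`, `yield`), `fingerprints` (0/1 matrix, rows = records),
#'   and `model` (planted effects).
#' @export
generateReaxysLike <- function(nReactions, fpDim = 64, nReagents = 20,
                               nSolvents = 8, sigma = 0.03, seed = 1) {
  if (nReactions < 1 || fpDim < 1 || nReagents < 1 || nSolvents < 1)
    stop("all sizes must be >= 1")
  set.seed(as.integer(seed))
  reagentEff <- stats::rnorm(nReagents, sd = 0.08)
  solventEff <- stats::rnorm(nSolvents, sd = 0.05)
  profile <- matrix(stats::rnorm(fpDim * nReagents, sd = 1.0), fpDim)
  W <- matrix(stats::rnorm(fpDim * nReagents, sd = 0.05 / sqrt(fpDim)), fpDim)

  fp <- matrix(0L, nReactions, fpDim)
  reag <- character(nReactions)
  solv <- character(nReactions)
  temp <- character(nReactions)
  y <- numeric(nReactions)
  for (r in seq_len(nReactions)) {
    nr <- sample(1:4, 1)
    rs <- sample.int(nReagents, nr)
    ns <- sample(0:2, 1)
    ss <- if (ns > 0) sample.int(nSolvents, ns) else integer(0)
    tilt <- rowSums(profile[, rs, drop = FALSE])
    p <- stats::plogis(-1 + tilt)
    bits <- as.integer(stats::runif(fpDim) < p)
    fp[r, ] <- bits
    bi <- sum(vapply(rs, function(j) sum(bits * W[, j]), numeric(1)))
    yr <- 0.35 + sum(reagentEff[rs]) + sum(solventEff[ss]) + bi +
      stats::rnorm(1, sd = sigma)
    y[r] <- min(max(yr, 0), 1)
    reag[r] <- paste(paste0("rg", rs), collapse = ";")
    solv[r] <- paste(paste0("sv", ss), collapse = ";")
    temp[r] <- as.character(round(stats::runif(1, 20, 150)))
  }
  list(data = data.frame(id = paste0("rx", seq_len(nReactions)),
                         reagents = reag, solvents = solv,
                         temperatures = temp, yield = y,
                         stringsAsFactors = FALSE),
       fingerprints = fp,
       model = list(reagentEff = reagentEff, solventEff = solventEff,
                    bilinear = W, profile = profile, sigma = sigma))
}
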