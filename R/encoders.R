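#' Build per-slot vocabularies from records
#'
#' A vocabulary is the ordered set of distinct labels seen in a slot, in
#' first-appearance order (so encoded columns line up visually with the
#' input file). Works on single-valued slot columns and on `";"`-joined
#' multi-valued columns alike.
#'
#' @param records a data.frame of reaction records.
#' @param slotNames columns to build vocabularies for.
#' @return named list of character vectors (label order = index order).
#' @export
buildVocabularies <- function(records, slotNames) {
  missing <- setdiff(slotNames, names(records))
  if (length(missing))
    stop("unknown slot(s): ", paste(missing, collapse = ", "))
  out <- lapply(slotNames, function(s) {
    labs <- unlist(.splitField(as.character(records[[s]])))
    unique(labs)
  })
  stats::setNames(out, slotNames)
}

#' One-hot encode a label against a vocabulary
#'
#' @param label a single label.
#' @param vocabulary character vector of known labels.
#' @return 0/1 vector of length `length(vocabulary)` with one bit set.
#' @export
encodeOneHot <- function(label, vocabulary) {
  idx <- match(label, vocabulary)
  if (is.na(idx))
    stop("label '", label, "' not in vocabulary (bin-based one-hot cannot ",
         "encode unseen labels; the model must be reformulated)")
  bits <- integer(length(vocabulary))
  bits[idx] <- 1L
  bits
}

#' Substructure tables and two-hot substrate encoding
#'
#' Substrates built by combining one substructure from a "top" row with one
#' from a "bottom" row are encoded in `nTop + nBottom` bits with exactly
#' two bits set: the top index, and `nTop + bottom index`. The default
#' fixture table pairs 5 top with 3 bottom substructures (8 bits, 15
#' substrates), the only split consistent with both counts.
#'
#' @param nTop,nBottom row sizes.
#' @param substrates substrate labels, assigned to (top, bottom) index pairs
#'   in row-major order; defaults to `s1 ... s(nTop*nBottom)`.
#' @return a substructure table: list with `map` (label -> c(top, bottom),
#'   1-based), `nTop`, `nBottom`.
#' @export
makeSubstructureTable <- function(nTop = 5, nBottom = 3, substrates = NULL) {
  n <- nTop * nBottom
  if (is.null(substrates)) substrates <- paste0("s", seq_len(n))
  if (length(substrates) != n) stop("need ", n, " substrate labels")
  combos <- expand.grid(bottom = seq_len(nBottom), top = seq_len(nTop))
  map <- Map(function(t, b) c(top = t, bottom = b), combos$top, combos$bottom)
  names(map) <- substrates
  list(map = map, nTop = nTop, nBottom = nBottom)
}

#' @rdname makeSubstructureTable
#' @param substrate substrate label present in the table.
#' @param table a substructure table.
#' @return `encodeSubstructure()`: 0/1 vector with exactly two bits set.
#' @export
encodeSubstructure <- function(substrate, table) {
  pos <- table$map[[substrate]]
  if (is.null(pos)) stop("substrate '", substrate, "' not in table")
  bits <- integer(table$nTop + table$nBottom)
  bits[pos[1]] <- 1L
  bits[table$nTop + pos[2]] <- 1L
  bits
}

#' Reaction fingerprint encodings
#'
#' Builds the reaction segment from binary reactant/product fingerprints.
#' The difference `diff = product - reactant` takes values in \{-1, 0, 1\},
#' reading +1 as the addition and -1 as the disappearance of a
#' substructure. Modes: `reac_prod` (concatenation, length 2d), `reac_only`
#' / `prod_only` / `diff_only` (length d), `reac_diff` / `prod_diff`
#' (block plus difference, length 2d).
#'
#' @param reactFp,prodFp binary vectors of equal length.
#' @param mode encoding mode.
#' @return numeric vector over \{-1, 0, 1\}.
#' @export
encodeReactionFp <- function(reactFp, prodFp,
                             mode = c("reac_prod", "reac_only", "prod_only",
                                      "reac_diff", "prod_diff", "diff_only")) {
  mode <- match.arg(mode)
  if (length(reactFp) != length(prodFp))
    stop("fingerprint length mismatch: ", length(reactFp), " vs ",
         length(prodFp))
  if (!all(reactFp %in% c(0, 1)) || !all(prodFp %in% c(0, 1)))
    stop("fingerprints must be binary")
  d <- prodFp - reactFp
  switch(mode,
         reac_prod = c(reactFp, prodFp),
         reac_only = reactFp,
         prod_only = prodFp,
         diff_only = d,
         reac_diff = c(reactFp, d),
         prod_diff = c(prodFp, d))
}

#' Assemble encoded pieces into a segmented feature vector
#'
#' Concatenates an optional reaction segment (may contain -1), one-hot
#' condition segments (binary only -- a -1 in a condition segment is an
#' error because condition bits must remain annealable), and an optional
#' temperature segment.
#'
#' @param reaction numeric vector over \{-1, 0, 1\} or `NULL`.
#' @param conditions named list of binary vectors, one per condition slot.
#' @param temperature binary vector or `NULL`.
#' @return a [FeatureVector-class].
#' @export
assembleInput <- function(reaction = NULL, conditions = list(),
                          temperature = NULL) {
  pieces <- list()
  kinds <- character(0)
  if (!is.null(reaction) && length(reaction)) {
    pieces$reaction <- reaction
    kinds <- c(kinds, "reaction")
  }
  for (nm in names(conditions)) {
    pieces[[nm]] <- conditions[[nm]]
    kinds <- c(kinds, "condition")
  }
  if (!is.null(temperature) && length(temperature)) {
    pieces$temperature <- temperature
    kinds <- c(kinds, "condition")
  }
  if (!length(pieces)) stop("nothing to assemble")
  lens <- lengths(pieces)
  starts <- cumsum(c(1L, utils::head(lens, -1)))
  seg <- data.frame(name = names(pieces), start = as.integer(starts),
                    length = as.integer(lens), kind = kinds,
                    stringsAsFactors = FALSE)
  for (r in which(seg$kind == "condition"))
    if (!all(pieces[[r]] %in% c(0, 1)))
      stop("condition segment '", seg$name[r],
           "' contains non-binary values; conditions must stay binary ",
           "for annealer inference")
  new("FeatureVector", values = as.numeric(unlist(pieces, use.names = FALSE)),
      segments = seg)
}

#' Encode a table of reactions into a feature matrix
#'
#' One-hot encodes the given condition slots of every record against
#' vocabularies built from (or supplied for) the table, producing the model
#' input matrix plus the shared segment map.
#'
#' @param records data.frame with one single-valued label column per slot.
#' @param slotNames condition slots to encode.
#' @param vocabularies optional named list of vocabularies; built from the
#'   records when `NULL`.
#' @param reactionMatrix optional numeric matrix (rows = records) prepended
#'   as the reaction segment.
#' @return list with `features` (numeric matrix), `segments` (segment map),
#'   `vocabularies`.
#' @export
encodeConditionTable <- function(records, slotNames, vocabularies = NULL,
                                 reactionMatrix = NULL) {
  if (is.null(vocabularies))
    vocabularies <- buildVocabularies(records, slotNames)
  rows <- lapply(seq_len(nrow(records)), function(r) {
    conds <- lapply(slotNames, function(s)
      encodeOneHot(as.character(records[[s]][r]), vocabularies[[s]]))
    names(conds) <- slotNames
    fv <- assembleInput(
      reaction = if (!is.null(reactionMatrix)) reactionMatrix[r, ] else NULL,
      conditions = conds)
    fv
  })
  feats <- do.call(rbind, lapply(rows, featureValues))
  list(features = feats, segments = featureSegments(rows[[1]]),
       vocabularies = vocabularies)
}
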