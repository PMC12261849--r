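#' @name reaction-records
#' @title Reaction record tables
#' @description
#' Reaction records are plain data.frames with one row per reaction and the
#' columns `id`, `reactants`, `products`, `reagents`, `solvents`,
#' `temperatures` (multi-valued fields joined with `";"`), a numeric `yield`
#' in \[0, 1\], and optionally further single-valued condition-slot columns
#' (e.g. `substrate`, `ligand`, `base`, `additive`). [readReactions()] and
#' [writeReactions()] round-trip this schema through CSV.
NULL

.splitField <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(p) p[nzchar(trimws(p))])
}

.joinField <- function(lst) vapply(lst, paste, character(1), collapse = ";")

.numField <- function(x) lapply(.splitField(x), as.numeric)

#' Clean reaction records
#'
#' Applies the seven-rule cleaning pipeline used to prepare reaction tables
#' for encoding. Each record is attributed to the first rule it violates
#' (in order i-vii), so the per-rule counts plus the retained count always
#' equal the input size. Rules:
#' \describe{
#'   \item{i}{missing yield, solvent, reaction structures, or temperature;
#'     a yield outside \[0, 1\] is removed here with a warning.}
#'   \item{ii}{half reactions (reactants or products absent).}
#'   \item{iii}{syntactically invalid SMILES (allowed-alphabet and balanced
#'     bracket check; chemistry-level parsing is out of the core path).}
#'   \item{iv}{more than one product, more than two solvents, more than four
#'     reagents, or no reagents. (A multiple-yield sub-rule cannot fire in
#'     this schema, which stores one numeric yield per record.)}
#'   \item{v}{only the maximum temperature is retained (reactions are
#'     assumed to run at the highest recorded temperature); records whose
#'     maximum lies outside \[20, 150\] degrees Celsius are removed.}
#'   \item{vi}{label canonicalization -- performed separately by
#'     [canonicalizeLabels()], never a removal.}
#'   \item{vii}{exact duplicates of the (reaction, condition set) tuple,
#'     yield excluded; the first occurrence is kept.}
#' }
#'
#' @param records a reaction record data.frame (see [reaction-records]).
#' @param rules character vector of enabled rules, subset of
#'   `c("i","ii","iii","iv","v","vii")`.
#' @param tempRange retained temperature range in degrees Celsius.
#' @return list with `records` (the retained rows, rule-v temperatures
#'   collapsed to their maximum) and `report` (list of per-rule removal
#'   counts, `retained`, and `input`).
#' @examples
#' r <- data.frame(id = "r1", reactants = "CCO", products = "CC=O",
#'                 reagents = "ox", solvents = "water", temperatures = "25",
#'                 yield = 0.8)
#' cleanReactions(r)$report$retained
#' @export
cleanReactions <- function(records,
                           rules = c("i", "ii", "iii", "iv", "v", "vii"),
                           tempRange = c(20, 150)) {
  counts <- stats::setNames(rep(0L, 7),
                            c("i", "ii", "iii", "iv", "v", "vi", "vii"))
  if (!nrow(records))
    return(list(records = records,
                report = c(as.list(counts), list(retained = 0L, input = 0L))))

  reac <- .splitField(records$reactants)
  prod <- .splitField(records$products)
  reag <- .splitField(records$reagents)
  solv <- .splitField(records$solvents)
  temps <- .numField(records$temperatures)
  yield <- records$yield

  removedBy <- rep(NA_character_, nrow(records))
  mark <- function(bad, rule) {
    bad <- bad & is.na(removedBy)
    removedBy[bad] <<- rule
    invisible(NULL)
  }

  if ("i" %in% rules) {
    badYield <- !is.na(yield) & (yield < 0 | yield > 1)
    if (any(badYield))
      warning(sum(badYield), " record(s) with yield outside [0, 1] removed",
              call. = FALSE)
    missing <- is.na(yield) | lengths(solv) == 0 |
      (lengths(reac) == 0 & lengths(prod) == 0) |
      vapply(temps, function(t) length(t) == 0 || all(is.na(t)), logical(1))
    mark(missing | badYield, "i")
  }
  if ("ii" %in% rules)
    mark(lengths(reac) == 0 | lengths(prod) == 0, "ii")
  if ("iii" %in% rules) {
    okSmiles <- function(parts) all(vapply(parts, .smilesOk, logical(1)))
    mark(!vapply(Map(c, reac, prod), okSmiles, logical(1)), "iii")
  }
  if ("iv" %in% rules)
    mark(lengths(prod) > 1 | lengths(solv) > 2 | lengths(reag) > 4 |
           lengths(reag) == 0, "iv")
  if ("v" %in% rules) {
    tmax <- vapply(temps, function(t) suppressWarnings(max(t, na.rm = TRUE)),
                   numeric(1))
    mark(!is.finite(tmax) | tmax < tempRange[1] | tmax > tempRange[2], "v")
  }

  keep <- is.na(removedBy)
  out <- records[keep, , drop = FALSE]
  if ("v" %in% rules && nrow(out)) {
    tm <- vapply(temps[keep], max, numeric(1))
    out$temperatures <- as.character(tm)
  }
  if ("vii" %in% rules && nrow(out)) {
    condCols <- setdiff(names(out), c("id", "yield"))
    key <- do.call(paste, c(out[condCols], sep = "\r"))
    dup <- duplicated(key)
    counts["vii"] <- sum(dup)
    out <- out[!dup, , drop = FALSE]
  }
  tab <- table(removedBy)
  counts[names(tab)] <- as.integer(tab)
  rownames(out) <- NULL
  list(records = out,
       report = c(as.list(counts),
                  list(retained = nrow(out), input = nrow(records))))
}

# Syntactic SMILES sanity check: allowed alphabet, balanced () and [].
.smilesOk <- function(s) {
  if (!nzchar(s)) return(FALSE)
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$%/\\\\.:*]", s)) return(FALSE)
  for (pair in list(c("(", ")"), c("[", "]"))) {
    depth <- cumsum((strsplit(s, "")[[1]] == pair[1]) -
                    (strsplit(s, "")[[1]] == pair[2]))
    if (any(depth < 0) || utils::tail(depth, 1) != 0) return(FALSE)
  }
  TRUE
}

#' Canonicalize reagent/solvent labels through a SMILES mapping table
#'
#' Labels that resolve to the same canonical SMILES are merged under the
#' most frequently used original label (frequency counted across all listed
#' slots of all records; ties broken lexicographically). Labels absent from
#' the mapping table pass through unchanged; their count is reported via a
#' message.
#'
#' @param records a reaction record data.frame.
#' @param mapping data.frame with columns `label` and `smiles`.
#' @param slots multi-valued label columns to canonicalize.
#' @return the records with merged labels.
#' @export
canonicalizeLabels <- function(records, mapping,
                               slots = c("reagents", "solvents")) {
  if (!nrow(records) || !nrow(mapping)) return(records)
  slots <- intersect(slots, names(records))
  all_labels <- unlist(lapply(slots, function(s) unlist(.splitField(records[[s]]))))
  if (!length(all_labels)) return(records)
  freq <- table(all_labels)
  smiles <- mapping$smiles[match(names(freq), mapping$label)]
  unresolved <- sum(freq[is.na(smiles)])
  if (unresolved > 0)
    message(unresolved, " label occurrence(s) had no SMILES mapping")
  rep_map <- character(0)
  for (sm in unique(smiles[!is.na(smiles)])) {
    grp <- names(freq)[!is.na(smiles) & smiles == sm]
    best <- grp[order(-as.integer(freq[grp]), grp)][1]
    rep_map[grp] <- best
  }
  for (s in slots) {
    parts <- .splitField(records[[s]])
    parts <- lapply(parts, function(p) {
      hit <- p %in% names(rep_map)
      p[hit] <- rep_map[p[hit]]
      p
    })
    records[[s]] <- .joinField(parts)
  }
  records
}

#' Quantile-based temperature discretization
#'
#' Partitions values into `q` approximately equally occupied bins using the
#' sample quantiles (the inclusive-median convention of standard
#' quantile-based discretization); values equal to an interior edge fall in
#' the lower bin. The edges are returned so the same binning can be reused
#' at inference time.
#'
#' @param values finite numeric vector.
#' @param q number of bins (>= 2).
#' @return list with `bins` (0-based bin index per value) and `edges`
#'   (the `q + 1` quantile edges; fewer if distinct values collapsed).
#' @export
discretizeTemperatures <- function(values, q) {
  if (!length(values)) stop("empty input")
  if (!all(is.finite(values))) stop("values must be finite")
  if (q < 2) stop("q must be >= 2")
  nd <- length(unique(values))
  if (nd == 1L) {
    warning("all values identical; single bin", call. = FALSE)
    return(list(bins = rep(0L, length(values)), edges = range(values)))
  }
  if (nd < q) {
    warning("fewer distinct values (", nd, ") than bins (", q,
            "); collapsing to distinct-value bins", call. = FALSE)
    q <- nd
  }
  edges <- unique(stats::quantile(values, probs = seq(0, 1, length.out = q + 1),
                                  names = FALSE, type = 7))
  inner <- edges[-c(1, length(edges))]
  bins <- findInterval(values, inner, left.open = TRUE)
  list(bins = as.integer(bins), edges = edges)
}

#' Binary encoding of an integer temperature
#'
#' Standard unsigned base-2 encoding, least-significant bit first. The
#' default 8-bit width covers the retained 20-150 degree range with
#' headroom.
#'
#' @param t integer temperature in degrees Celsius, in `[0, 2^width)`.
#' @param width number of bits.
#' @return integer 0/1 vector of length `width`.
#' @examples
#' encodeTemperatureBits(20) # 0 0 1 0 1 0 0 0
#' @export
encodeTemperatureBits <- function(t, width = 8) {
  if (length(t) != 1L || is.na(t) || t != round(t))
    stop("t must be a single integer")
  if (t < 0 || t >= 2^width)
    stop("t = ", t, " outside the representable range [0, ", 2^width - 1, "]")
  as.integer(bitwAnd(t %/% 2^(0:(width - 1)), 1L))
}

#' @rdname encodeTemperatureBits
#' @param bits an LSB-first 0/1 vector.
#' @export
decodeTemperatureBits <- function(bits) sum(bits * 2^(seq_along(bits) - 1))
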