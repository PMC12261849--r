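#' Read and write reaction record tables
#'
#' Reaction tables are CSV files with the columns described in
#' [reaction-records]; multi-valued cells are `";"`-joined. Yields may be
#' stored as fractions (column `yield`) or percentages (column
#' `yield_pct`, divided by 100 on ingest); `yieldUnit` overrides the
#' column-name heuristic.
#'
#' @param path CSV file path.
#' @param yieldUnit `"auto"`, `"fraction"` or `"percent"`.
#' @return `readReactions()`: a reaction record data.frame.
#' @export
readReactions <- function(path, yieldUnit = c("auto", "fraction", "percent")) {
  yieldUnit <- match.arg(yieldUnit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  ycol <- intersect(c("yield", "yield_pct"), names(df))
  if (!length(ycol)) stop("missing required column 'yield' (or 'yield_pct')")
  ycol <- ycol[1]
  yraw <- suppressWarnings(as.numeric(df[[ycol]]))
  bad <- which(!is.na(df[[ycol]]) & nzchar(df[[ycol]]) & is.na(yraw))
  if (length(bad))
    stop("unparseable yield at line ", bad[1] + 1L, " of ", path)
  pct <- switch(yieldUnit, auto = ycol == "yield_pct",
                fraction = FALSE, percent = TRUE)
  df[[ycol]] <- NULL
  df$yield <- if (pct) yraw / 100 else yraw
  for (col in c("reactants", "products", "reagents", "solvents",
                "temperatures"))
    if (!col %in% names(df)) df[[col]] <- ""
  df
}

#' @rdname readReactions
#' @param records a reaction record data.frame.
#' @export
writeReactions <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Save and load a trained learned-Q ensemble as JSON
#'
#' @param model a [MlQuboModel-class].
#' @param path JSON file path.
#' @export
writeMlModel <- function(model, path) {
  obj <- list(
    type = "MlQuboModel",
    n = nrow(model@members[[1]]),
    # column-major entries as full-precision decimal strings
    members = lapply(model@members, function(m) sprintf("%.17g", as.vector(m))),
    targetMean = sprintf("%.17g", model@targetMean),
    targetStd = sprintf("%.17g", model@targetStd),
    segments = model@segments,
    config = model@config[!vapply(model@config, is.null, logical(1))])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMlModel
#' @export
readMlModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  n <- as.integer(obj$n)
  members <- lapply(obj$members, function(v)
    matrix(as.numeric(unlist(v)), n, n))
  seg <- if (!is.null(obj$segments) && length(obj$segments))
    do.call(rbind, lapply(obj$segments, function(r)
      data.frame(name = r$name, start = as.integer(r$start),
                 length = as.integer(r$length), kind = r$kind,
                 stringsAsFactors = FALSE)))
    else data.frame()
  new("MlQuboModel", members = members,
      targetMean = as.numeric(obj$targetMean),
      targetStd = as.numeric(obj$targetStd),
      segments = seg, config = as.list(obj$config),
      history = data.frame())
}

#' Save and load a fitted binary-coded model as JSON
#'
#' @param model a [DauModel-class].
#' @param path JSON file path.
#' @export
writeDauModel <- function(model, path) {
  obj <- list(type = "DauModel",
              slotNames = model@table@slotNames,
              width = model@table@width,
              terms = model@table@terms,
              coefficients = model@coefficients,
              sse = model@sse, scale = model@scale)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDauModel
#' @export
readDauModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tt <- as.data.frame(obj$terms)
  tt$start <- as.integer(tt$start)
  tab <- new("TermTable", terms = tt, width = as.integer(obj$width),
             slotNames = as.character(obj$slotNames))
  new("DauModel", table = tab,
      coefficients = as.numeric(obj$coefficients),
      sse = as.numeric(obj$sse), scale = as.numeric(obj$scale))
}

#' Write a feature matrix with its segment map
#'
#' A self-describing portable container: a JSON header (dimensions and
#' segment map) plus the matrix as CSV.
#'
#' @param features numeric matrix.
#' @param segments segment map data.frame.
#' @param path base path; writes `<path>.json` and `<path>.csv`.
#' @export
writeFeatures <- function(features, segments, path) {
  jsonlite::write_json(list(nrow = nrow(features), ncol = ncol(features),
                            segments = segments),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(features, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(paste0(path, ".csv"), header = FALSE))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == hdr$nrow, ncol(m) == hdr$ncol)
  list(features = m, segments = as.data.frame(hdr$segments))
}
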