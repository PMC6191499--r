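#' Read a TPS landmark file
#'
#' Parses the TPS dialect written by tpsDig2/tpsUtil: each record starts with
#' an `LM=` line giving the landmark count, followed by that many coordinate
#' lines, then optional `IMAGE=`, `ID=` and `SCALE=` lines. Keys are matched
#' case-insensitively and CRLF line endings are accepted. `CURVES=`/`POINTS=`
#' blocks (semilandmark outlines) are skipped. The scale factor is stored on
#' the dataset but never applied to the coordinates.
#'
#' The specimen identifier is taken from `IMAGE=`, falling back to `ID=` and
#' finally to the record index.
#'
#' @param path path to a `.TPS` file
#' @return a [landmark_dataset()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  recs <- list()
  i <- 1L; nl <- length(lines); rec_no <- 0L
  while (i <= nl) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^lm3?=", tolower(ln)))
      stop(sprintf("TPS parse error at line %d: expected an LM= line, got '%s'", i, ln))
    rec_no <- rec_no + 1L
    p <- suppressWarnings(as.integer(sub("^[^=]*=", "", ln)))
    if (is.na(p) || p < 1L)
      stop(sprintf("TPS parse error: malformed landmark count in record %d (line %d)", rec_no, i))
    i <- i + 1L
    coords <- matrix(NA_real_, p, 2L)
    ncoord <- 0L
    in_curve <- FALSE
    image <- NA_character_; id <- NA_character_; scale <- NA_real_
    while (i <= nl) {
      ln <- trimws(lines[i])
      low <- tolower(ln)
      if (grepl("^lm3?=", low)) break
      if (ln == "") { i <- i + 1L; next }
      if (grepl("^curves=", low)) { in_curve <- TRUE; i <- i + 1L; next }
      if (grepl("^points=", low)) { i <- i + 1L; next }
      if (grepl("^image=", low)) { image <- sub("^[^=]*=", "", ln); i <- i + 1L; next }
      if (grepl("^id=", low)) { id <- sub("^[^=]*=", "", ln); i <- i + 1L; next }
      if (grepl("^scale=", low)) {
        scale <- suppressWarnings(as.numeric(sub("^[^=]*=", "", ln)))
        i <- i + 1L; next
      }
      # a coordinate line
      if (!in_curve) {
        xy <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1L]]))
        if (length(xy) < 2L || anyNA(xy))
          stop(sprintf("TPS parse error: non-numeric coordinate in record %d (line %d): '%s'",
                       rec_no, i, ln))
        if (ncoord >= p)
          stop(sprintf("TPS parse error: too many coordinate lines in record %d (line %d)",
                       rec_no, i))
        ncoord <- ncoord + 1L
        coords[ncoord, ] <- xy[1:2]
      }
      i <- i + 1L
    }
    if (ncoord != p)
      stop(sprintf("TPS parse error: record %d declares %d landmarks but has %d coordinate lines",
                   rec_no, p, ncoord))
    sid <- if (!is.na(image) && nzchar(image)) image
           else if (!is.na(id) && nzchar(id)) id
           else sprintf("record%03d", rec_no)
    recs[[rec_no]] <- list(coords = coords, id = sid, scale = scale)
  }
  if (!length(recs)) stop("no records found in TPS file: ", path)
  ps <- vapply(recs, function(r) nrow(r$coords), 1L)
  if (length(unique(ps)) != 1L)
    stop("all records in a dataset must share the same landmark count; found p = ",
         paste(unique(ps), collapse = ", "))
  coords <- array(unlist(lapply(recs, `[[`, "coords")), c(ps[1L], 2L, length(recs)))
  # unlist concatenates column-major per record, matching array filling order
  for (k in seq_along(recs)) coords[, , k] <- recs[[k]]$coords
  scales <- vapply(recs, `[[`, 1, "scale")
  landmark_dataset(coords, ids = vapply(recs, `[[`, "", "id"),
                   scales = if (!all(is.na(scales))) ifelse(is.na(scales), 1, scales))
}

#' Write a TPS landmark file
#'
#' Records are written in dataset order with an `LM=` line, one coordinate
#' pair per line, an `IMAGE=` line carrying the specimen id and a `SCALE=`
#' line (6-decimal fixed format) when a scale factor is present.
#'
#' @param dataset a [landmark_dataset()]
#' @param path output path
#' @param digits decimal places for coordinates (default 6)
#' @return `path`, invisibly
#' @export
write_tps <- function(dataset, path, digits = 6L) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  n <- n_configurations(dataset); p <- n_landmarks(dataset)
  fmt <- sprintf("%%.%df %%.%df", digits, digits)
  out <- character(0)
  for (k in seq_len(n)) {
    out <- c(out, sprintf("LM=%d", p),
             sprintf(fmt, dataset$coords[, 1L, k], dataset$coords[, 2L, k]),
             sprintf("IMAGE=%s", dataset$ids[k]))
    if (!is.null(dataset$scales))
      out <- c(out, sprintf("SCALE=%.6f", dataset$scales[k]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an NTS landmark file
#'
#' Reads the minimal rectangular-matrix NTS dialect: a header line
#' `1 nL v 0` (the `L` suffix marks labelled rows) where `v = p*d`, followed
#' by one labelled row of `v` coordinates per specimen in the flat order
#' x1 y1 x2 y2 ... Rows may wrap across physical lines; `"`-quoted comment
#' lines are ignored.
#'
#' @param path path to an `.nts` file
#' @param d landmark dimensionality (the NTS format does not encode it;
#'   default 2)
#' @return a [landmark_dataset()]
#' @export
read_nts <- function(path, d = 2L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^\\s*\"", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty NTS file: ", path)
  hdr <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  if (length(hdr) < 3L) stop("NTS parse error: malformed header line")
  labelled <- grepl("[Ll]$", hdr[2L])
  n <- suppressWarnings(as.integer(sub("[Ll]$", "", hdr[2L])))
  v <- suppressWarnings(as.integer(hdr[3L]))
  if (is.na(n) || is.na(v)) stop("NTS parse error: malformed header line")
  if (v %% d != 0L)
    stop(sprintf("NTS parse error: %d variables are not divisible by d=%d", v, d))
  p <- v %/% d
  toks <- unlist(strsplit(trimws(lines[-1L]), "[ \t]+"))
  per_row <- v + as.integer(labelled)
  if (length(toks) != n * per_row)
    stop(sprintf("NTS parse error: header declares %d rows of %d values but %d tokens found",
                 n, per_row, length(toks)))
  coords <- array(NA_real_, c(p, d, n))
  ids <- character(n)
  for (k in seq_len(n)) {
    row <- toks[((k - 1L) * per_row + 1L):(k * per_row)]
    ids[k] <- if (labelled) row[1L] else sprintf("row%03d", k)
    val <- suppressWarnings(as.numeric(if (labelled) row[-1L] else row))
    if (anyNA(val))
      stop(sprintf("NTS parse error: non-numeric coordinate in row %d", k))
    coords[, , k] <- .unflatten(val, d)
  }
  landmark_dataset(coords, ids = ids)
}

#' Write an NTS landmark file
#'
#' Writes the minimal rectangular-matrix NTS dialect (see [read_nts()]).
#' When `apply_scale` is set, every coordinate is multiplied by the
#' configuration's stored scale factor, converting pixels to physical units;
#' scale application is always this explicit flag, never implicit.
#'
#' @param dataset a [landmark_dataset()]
#' @param path output path
#' @param apply_scale multiply coordinates by per-configuration scale factors
#' @param digits decimal places (default 6)
#' @return `path`, invisibly
#' @export
write_nts <- function(dataset, path, apply_scale = FALSE, digits = 6L) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  n <- n_configurations(dataset); p <- n_landmarks(dataset); d <- n_dimensions(dataset)
  flat <- flatten_coords(dataset)
  if (apply_scale) {
    if (is.null(dataset$scales))
      stop("apply_scale = TRUE but the dataset carries no scale factors")
    flat <- flat * dataset$scales
  }
  fmt <- sprintf("%%.%df", digits)
  rows <- vapply(seq_len(n), function(k)
    paste(dataset$ids[k], paste(sprintf(fmt, flat[k, ]), collapse = " ")), "")
  writeLines(c(sprintf("1 %dL %d 0", n, p * d), rows), path)
  invisible(path)
}

#' Extract a classifier from specimen identifiers
#'
#' Creates a categorical classifier from a 1-based inclusive character range
#' of each specimen id, mirroring the convention of interactive morphometric
#' software (e.g. id `"Fedia01a1b1.jpg"` with `first = 1, last = 7` gives the
#' individual classifier `"Fedia01"`, `8:9` the imaging session `"a1"`, and
#' `10:11` the digitising session `"b1"`).
#'
#' @param dataset a [landmark_dataset()]
#' @param name name of the new classifier
#' @param first,last 1-based inclusive character positions
#' @return the dataset with the classifier added
#' @export
extract_classifier <- function(dataset, name, first, last) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  first <- as.integer(first); last <- as.integer(last)
  if (first < 1L || last < first) stop("need 1 <= first <= last")
  lens <- nchar(dataset$ids)
  if (any(lens < last)) {
    bad <- dataset$ids[which(lens < last)[1L]]
    stop(sprintf("classifier range [%d,%d] exceeds the length of specimen id '%s'",
                 first, last, bad))
  }
  value <- substr(dataset$ids, first, last)
  if (is.null(dataset$classifiers))
    dataset$classifiers <- data.frame(row.names = seq_along(dataset$ids))
  dataset$classifiers[[name]] <- value
  dataset
}
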