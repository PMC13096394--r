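#' @include AllClasses.R AllGenerics.R
NULL

#' Read a descriptor table
#'
#' Reads a comma- or tab-separated descriptor table (the \code{Inp_data}
#' layout: optional identifier column, one classification column, descriptor
#' columns).  The delimiter is auto-detected from the header row; trailing
#' empty lines are skipped, since a stray final empty line is a classic way
#' to turn every numeric descriptor into text.  All cells are kept as
#' character; numeric parsing is deferred to [buildScales()].
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param classColumn name of the classification column (e.g.
#'   \code{"Outcome"}).
#' @param idColumn name of the identifier column, or \code{NULL} to generate
#'   sequential identifiers \code{"S1"} ... \code{"Sn"}.
#' @param sep field delimiter; \code{NULL} (default) auto-detects tab vs
#'   comma from the header.
#' @return a [DescriptorTable-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,Outcome,XlogP", "a,Active,1.2", "b,Inactive,3.4"), f)
#' tab <- readDescriptorTable(f, classColumn = "Outcome", idColumn = "id")
#' objectIds(tab)
#' @export
readDescriptorTable <- function(path, classColumn, idColumn = NULL,
                                sep = NULL) {
  if (!file.exists(path)) .stopf("input file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  # drop trailing empty lines only; an interior blank line is a parse error
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) < 2L) .stopf("file has no data rows: %s", path)
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  # split drops trailing empty fields; pad against the header width
  width <- length(fields[[1L]])
  nf <- lengths(fields) +
    as.integer(endsWith(lines, sep))  # trailing delimiter = empty last cell
  ragged <- which(nf != width & !(lengths(fields) == width))
  if (length(ragged))
    .stopf("ragged row at line %d: expected %d fields, found %d",
           ragged[1L], width, nf[ragged[1L]])
  cells <- lapply(fields, function(f) c(f, rep("", width - length(f))))
  header <- .normalizeToken(cells[[1L]])
  if (anyDuplicated(header)) .stopf("duplicate column names in header")
  if (!classColumn %in% header)
    .stopf("class column '%s' not found in header", classColumn)
  if (!is.null(idColumn) && !idColumn %in% header)
    .stopf("id column '%s' not found in header", idColumn)
  body <- cells[-1L]
  mat <- matrix(unlist(body), nrow = length(body), ncol = width, byrow = TRUE)
  colnames(mat) <- header
  mat[!nzchar(trimws(mat))] <- NA_character_

  classLabels <- mat[, classColumn]
  if (anyNA(classLabels))
    .stopf("class column '%s' has missing values (first at data row %d)",
           classColumn, which(is.na(classLabels))[1L])
  if (is.null(idColumn)) {
    ids <- paste0("S", seq_len(nrow(mat)))
    idName <- ""
  } else {
    ids <- mat[, idColumn]
    if (anyNA(ids)) .stopf("id column '%s' has missing values", idColumn)
    if (anyDuplicated(ids))
      .stopf("duplicate object ids in column '%s' (e.g. '%s')", idColumn,
             ids[duplicated(ids)][1L])
    idName <- idColumn
  }
  keep <- setdiff(header, c(classColumn, idColumn))
  data <- as.data.frame(mat[, keep, drop = FALSE],
                        stringsAsFactors = FALSE, check.names = FALSE)
  rownames(data) <- NULL
  new("DescriptorTable", objectIds = unname(ids),
      classLabels = unname(.normalizeToken(classLabels)),
      className = classColumn, idName = idName, data = data,
      columnOrder = header)
}

#' Write a descriptor table
#'
#' Writes a [DescriptorTable-class] back to disk in its original column
#' order and delimiter, so that a clean read/write cycle is lossless.
#'
#' @param table a [DescriptorTable-class].
#' @param path output path.
#' @param sep field delimiter (default comma).
#' @return \code{path}, invisibly.
#' @export
writeDescriptorTable <- function(table, path, sep = ",") {
  stopifnot(is(table, "DescriptorTable"))
  cols <- table@columnOrder
  out <- matrix("", nrow = length(table@objectIds), ncol = length(cols))
  colnames(out) <- cols
  for (nm in cols) {
    out[, nm] <-
      if (nm == table@className) table@classLabels
      else if (nzchar(table@idName) && nm == table@idName) table@objectIds
      else {
        v <- table@data[[nm]]
        ifelse(is.na(v), "", v)
      }
  }
  lines <- c(paste(cols, collapse = sep),
             apply(out, 1L, paste, collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Build classification and descriptive scales
#'
#' Formalizes every column of a descriptor table into a scale with discrete
#' gradations.  A column is numeric iff every non-missing value parses as a
#' number: a single stray token makes the whole column text, mirroring how a
#' tabular import that misreads one cell silently degrades the column.
#' Numeric columns with at most \code{numericBins} distinct values get one
#' point gradation per value (so a 0/1 blood-brain-barrier flag yields
#' exactly two gradations); otherwise they are partitioned into
#' \code{numericBins} contiguous intervals, half-open \code{[lo, hi)} with
#' the final interval closed.  Text values are whitespace-normalized before
#' forming gradations, so a stray internal or surrounding space does not
#' spawn a spurious feature value.
#'
#' @param table a [DescriptorTable-class].
#' @param numericBins number of interval gradations for numeric columns
#'   (default 3).
#' @param binning \code{"equal_frequency"} (default; robust to the
#'   heavy-tailed MW/PSA-like descriptor distributions typical of screening
#'   sets) or \code{"equal_width"}.
#' @return a [ScaleSet-class].  All-missing columns are dropped with a
#'   warning; constant columns become single-gradation scales.
#' @export
buildScales <- function(table, numericBins = 3L,
                        binning = c("equal_frequency", "equal_width")) {
  stopifnot(is(table, "DescriptorTable"))
  binning <- match.arg(binning)
  if (numericBins < 1L) .stopf("numericBins must be >= 1")
  classLevelsv <- sort(unique(table@classLabels))
  scales <- list()
  dropped <- character()
  for (nm in names(table@data)) {
    raw <- .normalizeToken(table@data[[nm]])
    raw[!is.na(raw) & !nzchar(raw)] <- NA_character_
    vals <- raw[!is.na(raw)]
    if (length(vals) == 0L) { dropped <- c(dropped, nm); next }
    if (.isNumericColumn(vals)) {
      num <- as.numeric(vals)
      d <- sort(unique(num))
      if (length(d) <= numericBins) {
        scales[[nm]] <- list(name = nm, kind = "numeric", points = d)
      } else {
        br <- if (binning == "equal_width")
          seq(min(num), max(num), length.out = numericBins + 1L)
        else
          unname(stats::quantile(num, probs = seq(0, 1, length.out =
                                                    numericBins + 1L),
                                 type = 7))
        br <- unique(br)
        if (length(br) < 2L) br <- c(d[1L], d[length(d)])
        scales[[nm]] <- list(name = nm, kind = "numeric", breaks = br)
      }
    } else {
      scales[[nm]] <- list(name = nm, kind = "text",
                           levels = sort(unique(vals)))
    }
  }
  if (length(dropped))
    .warnf("dropped all-missing column(s): %s", paste(dropped, collapse = ", "))
  grad <- do.call(rbind, lapply(scales, .gradationRows))
  if (is.null(grad))
    grad <- data.frame(scale = character(), kind = character(),
                       index = integer(), label = character(),
                       id = character(), stringsAsFactors = FALSE)
  rownames(grad) <- NULL
  new("ScaleSet",
      classScale = list(name = table@className, levels = classLevelsv),
      scales = scales, gradations = grad)
}

.gradationRows <- function(s) {
  labels <- .gradationLabels(s)
  data.frame(scale = s$name, kind = s$kind, index = seq_along(labels),
             label = labels, id = paste0(s$name, "::", labels),
             stringsAsFactors = FALSE)
}

.gradationLabels <- function(s) {
  fmt <- function(v) vapply(v, function(x)
    format(x, trim = TRUE, digits = 12), character(1))
  if (s$kind == "text") return(s$levels)
  if (!is.null(s$points)) return(fmt(s$points))
  b <- fmt(s$breaks)
  k <- length(s$breaks) - 1L
  cl <- c(rep(")", k - 1L), "]")
  paste0("[", b[-length(b)], ",", b[-1L], cl)
}

# interval index for numeric values against a scale; values outside the
# covered range clamp to the boundary interval (recognition-time only)
.numericGradIndex <- function(v, s) {
  if (!is.null(s$points)) {
    idx <- match(v, s$points)
    out <- is.na(idx)
    if (any(out)) {
      near <- vapply(v[out], function(x) which.min(abs(s$points - x)),
                     integer(1))
      idx[out] <- near
    }
    list(index = idx, clamped = out)
  } else {
    b <- s$breaks
    k <- length(b) - 1L
    idx <- findInterval(v, b, rightmost.closed = TRUE)
    clamped <- idx < 1L | idx > k
    idx[idx < 1L] <- 1L
    idx[idx > k] <- k
    list(index = idx, clamped = clamped)
  }
}

#' Code objects against a scale set
#'
#' Codes every object of a descriptor table into binary incidence form: for
#' each descriptive scale with a non-missing value, the single matching
#' gradation bit is set.  Numeric values falling outside the trained
#' interval range (possible when coding new data against trained scales) are
#' clamped to the nearest boundary interval with a warning; text values
#' never seen at training time set no bit for that scale, also with a
#' warning.  Missing values set no bit and contribute no evidence.
#'
#' @param table a [DescriptorTable-class] with the same descriptor columns
#'   the scales were built from.
#' @param scales a [ScaleSet-class].
#' @return a [CodedSample-class].
#' @export
codeObjects <- function(table, scales) {
  stopifnot(is(table, "DescriptorTable"), is(scales, "ScaleSet"))
  missingCols <- setdiff(names(scales@scales), names(table@data))
  if (length(missingCols))
    .stopf("table lacks descriptor column(s): %s",
           paste(missingCols, collapse = ", "))
  unseenClass <- setdiff(unique(table@classLabels), scales@classScale$levels)
  if (length(unseenClass))
    .stopf("class label(s) outside the classification scale: %s",
           paste(unseenClass, collapse = ", "))
  n <- length(table@objectIds)
  grad <- scales@gradations
  offsets <- c(0L, cumsum(vapply(scales@scales, .nGradations, integer(1))))
  names(offsets) <- c(names(scales@scales), "..end")
  ii <- jj <- vector("list", length(scales@scales))
  nClamped <- 0L
  nUnseen <- 0L
  for (k in seq_along(scales@scales)) {
    s <- scales@scales[[k]]
    raw <- .normalizeToken(table@data[[s$name]])
    raw[!is.na(raw) & !nzchar(raw)] <- NA_character_
    obs <- which(!is.na(raw))
    if (!length(obs)) next
    if (s$kind == "numeric") {
      v <- suppressWarnings(as.numeric(raw[obs]))
      bad <- is.na(v)
      if (any(bad)) { nUnseen <- nUnseen + sum(bad); obs <- obs[!bad]; v <- v[!bad] }
      if (!length(obs)) next
      g <- .numericGradIndex(v, s)
      nClamped <- nClamped + sum(g$clamped)
      ii[[k]] <- obs
      jj[[k]] <- offsets[[k]] + g$index
    } else {
      idx <- match(raw[obs], s$levels)
      unseen <- is.na(idx)
      nUnseen <- nUnseen + sum(unseen)
      ii[[k]] <- obs[!unseen]
      jj[[k]] <- offsets[[k]] + idx[!unseen]
    }
  }
  if (nClamped > 0L)
    .warnf("%d numeric value(s) outside trained intervals were clamped to the nearest boundary gradation", nClamped)
  if (nUnseen > 0L)
    .warnf("%d value(s) matched no trained gradation and were coded as absent", nUnseen)
  inc <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = 1,
    dims = c(n, nrow(grad)),
    dimnames = list(table@objectIds, grad$id))
  new("CodedSample", incidence = inc,
      classOf = factor(table@classLabels,
                       levels = scales@classScale$levels),
      scaleSet = scales)
}

#' Serialize a scale set to JSON
#'
#' @param scales a [ScaleSet-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScaleSet <- function(scales, path) {
  stopifnot(is(scales, "ScaleSet"))
  payload <- list(
    classScale = scales@classScale,
    scales = unname(scales@scales))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a scale set from JSON
#'
#' @param path a file written by [writeScaleSet()].
#' @return a [ScaleSet-class].
#' @export
readScaleSet <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  scales <- lapply(payload$scales, function(s) {
    s$kind <- as.character(s$kind)
    if (!is.null(s$points)) s$points <- as.numeric(s$points)
    if (!is.null(s$breaks)) s$breaks <- as.numeric(s$breaks)
    if (!is.null(s$levels)) s$levels <- as.character(s$levels)
    s
  })
  names(scales) <- vapply(scales, `[[`, character(1), "name")
  grad <- do.call(rbind, lapply(scales, .gradationRows))
  rownames(grad) <- NULL
  new("ScaleSet",
      classScale = list(name = as.character(payload$classScale$name),
                        levels = as.character(payload$classScale$levels)),
      scales = scales, gradations = grad)
}

#' Export a coded sample as sparse triplets
#'
#' Writes the incidence structure as a TSV of (object_id, gradation_id, 1)
#' triplets plus the class label per object.
#'
#' @param sample a [CodedSample-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCodedTriplets <- function(sample, path) {
  stopifnot(is(sample, "CodedSample"))
  tm <- Matrix::summary(sample@incidence)
  df <- data.frame(object_id = rownames(sample@incidence)[tm$i],
                   gradation_id = colnames(sample@incidence)[tm$j],
                   value = 1L)
  df <- df[order(tm$i, tm$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
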