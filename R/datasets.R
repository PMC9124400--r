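# Datasets are plain x/y pairs; loading handles csv/tsv dialects, an optional
# header row, and non-finite rows.

#' Construct a dataset
#'
#' @param x Independent-variable values (sorted ascending on construction,
#'   with `y` carried along).
#' @param y Observed values; same length as `x`.
#' @param name Dataset name.
#' @param source_path Optional originating file path.
#' @return An object of class `sf_dataset`.
#' @export
xy_dataset <- function(x, y, name = "data", source_path = NA_character_) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 1L) {
    stop("'x' and 'y' must have equal length >= 1", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("dataset values must all be finite", call. = FALSE)
  }
  o <- order(x)
  structure(
    list(name = name, x = x[o], y = y[o], source_path = source_path),
    class = "sf_dataset"
  )
}

#' @export
print.sf_dataset <- function(x, ...) {
  cat(sprintf(
    "<sf_dataset> %s: %d points, x in [%g, %g]\n",
    x$name, length(x$x), min(x$x), max(x$x)
  ))
  invisible(x)
}

#' Read a two-column x/y table
#'
#' The delimiter is chosen from the file extension (`.tsv` means tab,
#' everything else comma).  A single header row is auto-detected (first row
#' non-numeric) and skipped.  Exactly the first two columns are used (extras
#' are ignored with a message); rows with non-finite entries are dropped with
#' a message stating the count.
#'
#' @param path File path.
#' @param name Dataset name; defaults to the file name without extension.
#' @return An [xy_dataset()].
#' @export
read_xy_table <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("data file not found: %s", path), call. = FALSE)
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path,
    sep = sep, header = FALSE,
    colClasses = "character", stringsAsFactors = FALSE,
    blank.lines.skip = TRUE, strip.white = TRUE
  )
  if (ncol(raw) < 2L) {
    stop(sprintf("%s: fewer than two columns", path), call. = FALSE)
  }
  if (ncol(raw) > 2L) {
    message(sprintf(
      "%s: using first two of %d columns", path, ncol(raw)
    ))
  }
  first_numeric <- !anyNA(suppressWarnings(as.numeric(raw[1L, 1:2])))
  if (!first_numeric) raw <- raw[-1L, , drop = FALSE]
  x <- suppressWarnings(as.numeric(raw[[1L]]))
  y <- suppressWarnings(as.numeric(raw[[2L]]))
  keep <- is.finite(x) & is.finite(y)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("%s: dropped %d non-finite row(s)", path, dropped))
  }
  if (sum(keep) == 0L) {
    stop(sprintf("%s: no usable rows after filtering", path), call. = FALSE)
  }
  if (is.null(name)) {
    name <- sub("\\.[^.]*$", "", basename(path))
  }
  xy_dataset(x[keep], y[keep], name = name, source_path = path)
}

#' Write a dataset as a two-column CSV
#'
#' @param dataset An `sf_dataset`.
#' @param path Output file path; header line is `x,y`.
#' @return The path, invisibly.
#' @export
write_xy_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "sf_dataset"))
  utils::write.csv(
    data.frame(x = dataset$x, y = dataset$y),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
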