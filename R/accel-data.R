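#' Construct an accelerometer dataset
#'
#' An `accel_dataset` is an ordered collection of tri-axial acceleration
#' samples with a known sample rate.  It is stored as a `data.frame` with
#' columns `t` (seconds), `x`, `y`, `z` (acceleration in g) and, when
#' labelled, `label` (behaviour name), plus a `sample_rate` attribute.
#' Classification uses only `(x, y, z)`; `t` is metadata and may be
#' reconstructed from the sample rate when not supplied.
#'
#' @param x,y,z Numeric vectors of equal length: acceleration along the
#'   three orthogonal device axes, in g.  Must be finite.
#' @param sample_rate Sampling frequency in Hz (positive scalar).
#' @param t Optional numeric vector of non-negative, non-decreasing
#'   timestamps in seconds.  Defaults to `(seq_along(x) - 1) / sample_rate`.
#' @param label Optional character vector of behaviour names (non-empty
#'   strings).  `NA` entries mark unlabelled samples.
#'
#' @return An object of class `accel_dataset`.
#' @examples
#' d <- accel_dataset(x = c(0, 0.1), y = c(0, 0), z = c(-1, -0.9),
#'                    sample_rate = 20, label = c("Stand", "Walk"))
#' is_fully_labeled(d)
#' @export
accel_dataset <- function(x, y, z, sample_rate, t = NULL, label = NULL) {
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y and z must have equal length", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be a positive number (Hz)", call. = FALSE)
  if (is.null(t)) t <- (seq_len(n) - 1) / sample_rate
  d <- data.frame(t = as.numeric(t), x = as.numeric(x),
                  y = as.numeric(y), z = as.numeric(z))
  if (!is.null(label)) d$label <- as.character(label)
  attr(d, "sample_rate") <- as.numeric(sample_rate)
  class(d) <- c("accel_dataset", "data.frame")
  validate_accel_dataset(d)
}

validate_accel_dataset <- function(d) {
  if (nrow(d) > 0L) {
    bad <- !is.finite(d$x) | !is.finite(d$y) | !is.finite(d$z)
    if (any(bad))
      stop("non-finite acceleration value at row ", which(bad)[1L],
           call. = FALSE)
    if (any(!is.finite(d$t)) || any(d$t < 0))
      stop("timestamps must be finite and non-negative", call. = FALSE)
    if (is.unsorted(d$t))
      stop("timestamps must be non-decreasing", call. = FALSE)
    if (!is.null(d$label)) {
      present <- !is.na(d$label)
      if (any(present & !nzchar(d$label)))
        stop("labels, when present, must be non-empty strings",
             call. = FALSE)
    }
  }
  d
}

#' @rdname accel_dataset
#' @param d An `accel_dataset`.
#' @return `is_fully_labeled()`: `TRUE` iff every sample carries a label.
#' @export
is_fully_labeled <- function(d) {
  !is.null(d$label) && nrow(d) > 0L && !anyNA(d$label)
}

#' @rdname accel_dataset
#' @return `sample_rate()`: the sampling frequency in Hz.
#' @export
sample_rate <- function(d) attr(d, "sample_rate")

#' @export
print.accel_dataset <- function(x, ...) {
  cat(sprintf("<accel_dataset> %d samples at %g Hz (%.1f s)%s\n",
              nrow(x), sample_rate(x), nrow(x) / sample_rate(x),
              if (is_fully_labeled(x)) ", fully labelled" else ""))
  if (!is.null(x$label) && is_fully_labeled(x)) {
    tab <- table(x$label)
    cat("  behaviours:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a tri-axial acceleration CSV
#'
#' Reads a comma-separated file with a header row naming columns
#' `time,x,y,z` and optionally `label` ("." decimal mark, UTF-8).  Row
#' order is preserved; rows with missing or non-numeric coordinates are
#' rejected with an error naming the offending data row.  A missing `time`
#' column is reconstructed from `sample_rate` and row index.
#'
#' @param path Path to the CSV file.
#' @param has_labels Logical: is a `label` column required?  When `TRUE`
#'   the column must exist and every row must carry a non-empty label.
#' @param sample_rate Sampling frequency in Hz of the recording.
#' @return An [accel_dataset].
#' @export
read_accel_csv <- function(path, has_labels = FALSE, sample_rate) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  names(raw) <- trimws(names(raw))
  need <- c("x", "y", "z")
  if (!all(need %in% names(raw)))
    stop("CSV must have columns x, y, z (found: ",
         paste(names(raw), collapse = ", "), ")", call. = FALSE)
  if (has_labels && !"label" %in% names(raw))
    stop("has_labels = TRUE but no 'label' column in ", path,
         call. = FALSE)
  num <- function(col) {
    v <- trimws(raw[[col]])
    v[v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- is.na(out)
    if (any(bad))
      stop("non-numeric or missing '", col, "' value at data row ",
           which(bad)[1L], call. = FALSE)
    out
  }
  t <- if ("time" %in% names(raw) && nrow(raw) > 0L) num("time") else NULL
  label <- if (has_labels) {
    lab <- trimws(raw$label)
    bad <- is.na(lab) | !nzchar(lab)
    if (any(bad))
      stop("missing label at data row ", which(bad)[1L], call. = FALSE)
    lab
  } else NULL
  accel_dataset(x = if (nrow(raw)) num("x") else numeric(0),
                y = if (nrow(raw)) num("y") else numeric(0),
                z = if (nrow(raw)) num("z") else numeric(0),
                sample_rate = sample_rate, t = t, label = label)
}

#' Write a tri-axial acceleration CSV
#'
#' Writes the dataset in the same dialect [read_accel_csv()] reads
#' (`time,x,y,z[,label]`, comma-separated, "." decimal mark).  Coordinates
#' are printed with 15 significant digits so that a read-back reproduces
#' them to full printed precision and labels exactly.
#'
#' @param dataset A non-empty [accel_dataset].
#' @param path Output file path.
#' @param include_labels Write the `label` column; requires the dataset to
#'   be fully labelled.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(dataset, path, include_labels = FALSE) {
  stopifnot(inherits(dataset, "accel_dataset"))
  if (nrow(dataset) == 0L)
    stop("refusing to write an empty dataset", call. = FALSE)
  if (include_labels && !is_fully_labeled(dataset))
    stop("include_labels = TRUE requires a fully labelled dataset",
         call. = FALSE)
  fmt <- function(v) sprintf("%.15g", v)
  out <- data.frame(time = fmt(dataset$t), x = fmt(dataset$x),
                    y = fmt(dataset$y), z = fmt(dataset$z),
                    stringsAsFactors = FALSE)
  if (include_labels) out$label <- dataset$label
  con <- tryCatch(suppressWarnings(file(path, open = "wt",
                                        encoding = "UTF-8")),
                  error = function(e)
                    stop("cannot open '", path, "' for writing: ",
                         conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
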