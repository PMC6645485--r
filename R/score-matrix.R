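#' Coerce a data frame or matrix to a validated score matrix
#'
#' A score matrix holds the raw data of a reliability study: one row per
#' subject (i = 1..n), one column per repeated measurement (j = 1..k; a
#' rater, a day, a trial). The matrix must be complete and numeric with
#' n >= 2 and k >= 2. Orientation is fixed — rows are always subjects —
#' and no transposition is attempted.
#'
#' @param data A data frame or numeric matrix, subjects in rows and
#'   measurements in columns. Non-numeric columns are rejected.
#' @return A numeric matrix of class `score_matrix` with column names kept
#'   as measurement labels.
#' @examples
#' as_score_matrix(data.frame(day1 = c(1, 3), day2 = c(2, 4)))
#' @export
as_score_matrix <- function(data) {
  if (inherits(data, "score_matrix")) return(data)
  if (is.data.frame(data)) {
    bad <- names(data)[!vapply(data, is.numeric, logical(1))]
    if (length(bad) > 0) {
      stop_parse(paste0(
        "all measurement columns must be numeric; offending column(s): ",
        paste(bad, collapse = ", ")
      ))
    }
    m <- as.matrix(data)
  } else if (is.matrix(data) && is.numeric(data)) {
    m <- data
  } else {
    stop_parse("`data` must be a data frame or a numeric matrix")
  }
  if (nrow(m) < 2) stop_parse("need at least 2 subjects (rows)")
  if (ncol(m) < 2) stop_parse("need at least 2 measurements (columns)")
  if (anyNA(m) || any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop_parse(sprintf(
      "score matrix must be complete and finite; first bad cell at row %d, column %d",
      idx[1], idx[2]
    ))
  }
  storage.mode(m) <- "double"
  structure(m, class = c("score_matrix", class(m)))
}

#' Read a score matrix from a delimited text file
#'
#' Reads a CSV/TSV/semicolon-delimited file with one row per subject and one
#' column per measurement. The delimiter is auto-detected among comma, tab
#' and semicolon; a single header row of measurement labels is detected by a
#' non-numeric first line. Decimal separator is `.`.
#'
#' @param path Path to the file.
#' @param delim Optional explicit delimiter; by default detected from the
#'   first line.
#' @return A `score_matrix` (see [as_score_matrix()]); header labels, if
#'   present, become column names.
#' @export
read_score_matrix <- function(path, delim = NULL) {
  if (!file.exists(path)) stop_parse(paste0("file not found: ", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) stop_parse("empty file")
  if (is.null(delim)) {
    counts <- vapply(c(",", "\t", ";"), function(d) {
      length(strsplit(first, d, fixed = TRUE)[[1]])
    }, integer(1))
    delim <- c(",", "\t", ";")[which.max(counts)]
  }
  cells <- strsplit(first, delim, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(cells)))
  df <- tryCatch(
    read.table(path, sep = delim, header = has_header,
               stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) stop_parse(paste0("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  )
  as_score_matrix(df)
}

#' Electromyographic median frequency reliability data
#'
#' Median frequencies (Hz) of the surface electromyogram recorded over the
#' lumbar back muscles (left side) of 10 subjects on three separate days,
#' morning sessions, extracted from a published physiotherapy test-retest
#' reliability study (Elfving et al., 1999). A small, complete 10 x 3
#' subjects-by-days score matrix, useful as a worked example.
#'
#' @param as_matrix If `TRUE` return a `score_matrix`; otherwise (default) a
#'   tibble with columns `day1`, `day2`, `day3`.
#' @return A 10-row tibble or a 10 x 3 `score_matrix`.
#' @examples
#' emg_mf()
#' colMeans(emg_mf())
#' @export
emg_mf <- function(as_matrix = FALSE) {
  path <- system.file("extdata", "emg_mf.csv", package = "iccsim",
                      mustWork = TRUE)
  m <- read_score_matrix(path)
  if (as_matrix) m else as_tibble(as.data.frame(unclass(m)))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix: %d subjects x %d measurements>\n",
              nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}
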