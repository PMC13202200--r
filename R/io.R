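#' Read a unit-interval sample from a text file
#'
#' Accepts one numeric value per line, or a single-column CSV/TSV with an
#' optional header line. Values must lie in \eqn{(0, 1]}; offending lines are
#' reported by number.
#'
#' @param path Path to the file.
#' @return A validated [unit_sample].
#' @examples
#' f <- system.file("extdata", "failure_times_50.txt", package = "rterd")
#' x <- read_unit_sample(f)
#' length(x)   # 50
#' @export
read_unit_sample <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(raw)))
  if (length(keep) == 0) stop(sprintf("empty file: %s", path), call. = FALSE)
  lines <- trimws(raw[keep])
  # single-column CSV/TSV tolerance: strip one trailing separator if present
  lines <- sub("[,\t;]\\s*$", "", lines)
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(vals))
  # a single leading non-numeric line is treated as a header
  if (length(bad) >= 1 && bad[1] == 1L) {
    vals <- vals[-1]
    keep <- keep[-1]
    bad <- which(is.na(vals))
  }
  if (length(bad) > 0) {
    stop(sprintf("non-numeric value(s) at line(s) %s of %s",
                 paste(keep[bad], collapse = ", "), path), call. = FALSE)
  }
  if (length(vals) == 0) stop(sprintf("no data rows in %s", path), call. = FALSE)
  out <- which(!is.finite(vals) | vals <= 0 | vals > 1)
  if (length(out) > 0) {
    stop(sprintf(
      "value(s) outside (0, 1] at line(s) %s of %s (values: %s)",
      paste(keep[out], collapse = ", "), path,
      paste(signif(vals[out], 6), collapse = ", ")), call. = FALSE)
  }
  unit_sample(vals)
}

#' Write a sample to a plain-text file, one value per line
#'
#' Values are written with full precision (17 significant digits) so that
#' [read_unit_sample()] round-trips them exactly.
#'
#' @param x Numeric vector or [unit_sample].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_unit_sample <- function(x, path) {
  writeLines(formatC(as.numeric(x), format = "g", digits = 17), path)
  invisible(path)
}

#' Bundled dataset: failure times of 50 components
#'
#' Convenience loader for the packaged application dataset: the failure times
#' of 50 components, in thousands of hours, a complete right-skewed sample on
#' the unit interval (n = 50, range 0.061 to 0.992).
#'
#' @return A [unit_sample] of length 50.
#' @examples
#' x <- failure_times_50()
#' mean(x)
#' @export
failure_times_50 <- function() {
  read_unit_sample(system.file("extdata", "failure_times_50.txt",
                               package = "rterd"))
}
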