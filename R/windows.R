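#' Analysis windows
#'
#' A half-open interval of study days \[start, end) over which time in range
#' is evaluated. The named windows tile the two-year period on a 364-day
#' year, so Year 1 is exactly 52.0 weeks — the convention under which 80%
#' of Year 1 equals 41.6 weeks:
#' * `"year1"`: days \[0, 364)
#' * `"year2"`: days \[364, 728)
#' * `"full"`:  days \[0, 728)
#'
#' @param window A window name above, a string `"start:end"`, or an existing
#'   `tir_window`.
#' @param start,end Integer day bounds, used when `window` is missing.
#' @return A `tir_window` object with fields `start`, `end`, `label` and
#'   `length_weeks = (end - start) / 7`.
#' @examples
#' analysis_window("year1")
#' analysis_window(start = 0, end = 182)
#' @export
analysis_window <- function(window = NULL, start = NULL, end = NULL) {
  if (inherits(window, "tir_window")) {
    return(window)
  }
  named <- list(year1 = c(0L, 364L), year2 = c(364L, 728L), full = c(0L, 728L))
  if (is.character(window) && length(window) == 1L) {
    if (window %in% names(named)) {
      bounds <- named[[window]]
      start <- bounds[1]
      end <- bounds[2]
      label <- window
    } else if (grepl("^[0-9]+:[0-9]+$", window)) {
      bounds <- as.integer(strsplit(window, ":", fixed = TRUE)[[1]])
      start <- bounds[1]
      end <- bounds[2]
      label <- window
    } else {
      stop("Unknown window '", window,
           "'; use year1, year2, full or 'start:end'.", call. = FALSE)
    }
  } else if (!is.null(start) && !is.null(end)) {
    assert_scalar_number(start, "start")
    assert_scalar_number(end, "end")
    label <- sprintf("%d:%d", as.integer(start), as.integer(end))
  } else {
    stop("Provide a window name or both `start` and `end`.", call. = FALSE)
  }
  start <- as.integer(start)
  end <- as.integer(end)
  if (start < 0 || end <= start) {
    stop("Window requires 0 <= start < end (half-open [start, end)).",
         call. = FALSE)
  }
  structure(
    list(start = start, end = end, label = label,
         length_weeks = (end - start) / 7),
    class = "tir_window"
  )
}

#' @export
print.tir_window <- function(x, ...) {
  cat(sprintf("<tir_window '%s'> days [%d, %d), %.1f weeks\n",
              x$label, x$start, x$end, x$length_weeks))
  invisible(x)
}

#' @export
format.tir_window <- function(x, ...) x$label
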