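#' Two-channel EOG trace
#'
#' Container for a uniformly sampled two-channel electrooculogram recording.
#' Channel 1 carries the vertical-motion electrode signal, channel 2 the
#' horizontal one; both are in microvolts on a common time grid.
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing on
#'   a uniform grid.
#' @param ch1,ch2 Numeric vectors of samples in microvolts, same length as
#'   `time`.
#' @param sample_rate Sampling rate in Hz. If `NULL`, inferred from the median
#'   time step. Must exceed 120 Hz so that a 60 Hz filter cutoff stays below
#'   the Nyquist frequency.
#' @param tol_ppm Allowed relative deviation of any time step from the nominal
#'   step, in parts per million.
#'
#' @return An object of class `eog_trace`: a list with elements `time`, `ch1`,
#'   `ch2` and `sample_rate`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 500)
#' tr <- eog_trace(t, sin(2 * pi * 2 * t), cos(2 * pi * 2 * t))
#' tr$sample_rate
eog_trace <- function(time, ch1, ch2, sample_rate = NULL, tol_ppm = 1) {
  time <- as.numeric(time)
  ch1 <- as.numeric(ch1)
  ch2 <- as.numeric(ch2)
  n <- length(time)
  if (n < 2L) stop_invalid_input("an EOG trace needs at least two samples")
  if (length(ch1) != n || length(ch2) != n) {
    stop_invalid_input("`time`, `ch1` and `ch2` must have equal length")
  }
  steps <- diff(time)
  if (any(steps <= 0)) stop_invalid_input("timestamps must be strictly increasing")
  step <- stats::median(steps)
  if (any(abs(steps - step) > tol_ppm * 1e-6 * step)) {
    stop_invalid_input("timestamps are not uniformly sampled (beyond tolerance)")
  }
  if (is.null(sample_rate)) sample_rate <- 1 / step
  sample_rate <- check_number(sample_rate, "sample_rate")
  if (abs(1 / sample_rate - step) > tol_ppm * 1e-6 * step) {
    stop_invalid_input("`sample_rate` disagrees with the time grid")
  }
  if (sample_rate <= 120) {
    stop_invalid_config("sample_rate must exceed 120 Hz for a meaningful 60 Hz cutoff")
  }
  structure(
    list(time = time, ch1 = ch1, ch2 = ch2, sample_rate = sample_rate),
    class = "eog_trace"
  )
}

#' @export
print.eog_trace <- function(x, ...) {
  cat(sprintf(
    "<eog_trace> %d samples @ %.6g Hz (%.3f s)\n",
    length(x$time), x$sample_rate, length(x$time) / x$sample_rate
  ))
  cat(sprintf(
    "  ch1 (vertical):   [%.3g, %.3g] uV\n  ch2 (horizontal): [%.3g, %.3g] uV\n",
    min(x$ch1), max(x$ch1), min(x$ch2), max(x$ch2)
  ))
  invisible(x)
}

#' @export
length.eog_trace <- function(x) length(x$time)

#' Read / write EOG trace files
#'
#' Traces travel as delimited text with header `time,ch1,ch2`; time in
#' seconds, channels in microvolts. Uniform sampling is validated on read
#' (1 ppm step tolerance).
#'
#' @param path File path.
#' @param trace An [eog_trace()].
#' @return `read_eog_trace()` returns an [eog_trace()]; `write_eog_trace()`
#'   returns `path` invisibly.
#' @export
read_eog_trace <- function(path) {
  if (!file.exists(path)) stop_invalid_input(sprintf("trace file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time", "ch1", "ch2")
  if (!all(need %in% names(df))) {
    stop_invalid_input("trace file must have columns time,ch1,ch2")
  }
  eog_trace(df$time, df$ch1, df$ch2)
}

#' @rdname read_eog_trace
#' @export
write_eog_trace <- function(trace, path) {
  stopifnot(inherits(trace, "eog_trace"))
  df <- data.frame(time = trace$time, ch1 = trace$ch1, ch2 = trace$ch2)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
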