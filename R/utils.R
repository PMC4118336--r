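#' @keywords internal
"_PACKAGE"

# Classed condition helper so callers can distinguish configuration errors,
# invalid inputs and runtime (unreachable / incomplete-session) failures.
abort_eogaze <- function(message, class, data = list()) {
  cond <- structure(
    class = c(class, "eogaze_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cond)
}

stop_invalid_config <- function(message, data = list()) {
  abort_eogaze(message, "eogaze_invalid_config", data)
}

stop_invalid_input <- function(message, data = list()) {
  abort_eogaze(message, "eogaze_invalid_input", data)
}

stop_runtime <- function(message, class, data = list()) {
  abort_eogaze(message, c(class, "eogaze_runtime_error"), data)
}

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x))) {
    stop_invalid_input(sprintf("`%s` must be a single finite number", name))
  }
  as.numeric(x)
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

# 17 significant digits round-trip an IEEE double exactly through text,
# which is what the calibration file relies on.
format_double <- function(x) sprintf("%.17g", x)

as_point_matrix <- function(p, name = "points") {
  if (is.null(dim(p))) {
    if (length(p) != 2L || !is.numeric(p)) {
      stop_invalid_input(sprintf("`%s` must be a length-2 numeric or an n x 2 matrix", name))
    }
    matrix(as.numeric(p), nrow = 1L)
  } else {
    p <- as.matrix(p)
    if (ncol(p) != 2L) {
      stop_invalid_input(sprintf("`%s` must have 2 columns (u, v)", name))
    }
    storage.mode(p) <- "double"
    p
  }
}

# Return in the same shape the caller supplied.
restore_point_shape <- function(result, original) {
  if (is.null(dim(original))) drop(result) else result
}
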