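#' Low-pass filter specification
#'
#' The analog prototype is the second-order low-pass transfer function
#' \deqn{H(s) = \omega_n^2 / (s^2 + 2\cos(\pi/4)\,\omega_n s + \omega_n^2),
#'   \quad \omega_n = 2\pi f_c,}
#' i.e. a Butterworth section (damping ratio \eqn{\cos(\pi/4) = 1/\sqrt2})
#' with unit DC gain and -40 dB/decade roll-off above the cutoff. The default
#' 60 Hz cutoff suppresses mains-frequency interference while leaving saccade
#' energy (a few Hz) untouched.
#'
#' @param cutoff_hz Cutoff frequency \eqn{f_c} in Hz.
#' @return An object of class `eog_filter_spec` with fields `cutoff_hz`,
#'   `order` (fixed at 2) and `damping` (fixed at `cos(pi/4)`).
#' @export
filter_spec <- function(cutoff_hz = 60) {
  cutoff_hz <- check_number(cutoff_hz, "cutoff_hz")
  if (cutoff_hz <= 0) stop_invalid_config("cutoff frequency must be positive")
  structure(
    list(cutoff_hz = cutoff_hz, order = 2L, damping = cos(pi / 4)),
    class = "eog_filter_spec"
  )
}

# Bilinear transform s = K (1 - z^-1) / (1 + z^-1), K = 2 fs, applied to the
# analog biquad wn^2 / (s^2 + sqrt(2) wn s + wn^2). Returns the digital
# difference-equation coefficients (b, a), a[1] normalized to 1. At z = 1 the
# numerator and denominator sums are both 4 wn^2, so DC gain is exactly 1.
butter2_coefficients <- function(cutoff_hz, sample_rate) {
  wn <- 2 * pi * cutoff_hz
  K <- 2 * sample_rate
  c1 <- 2 * cos(pi / 4) * wn
  c0 <- wn^2
  a0 <- K^2 + c1 * K + c0
  a <- c(a0, -2 * K^2 + 2 * c0, K^2 - c1 * K + c0) / a0
  b <- c0 * c(1, 2, 1) / a0
  list(b = b, a = a)
}

# Analytic magnitude |H(j 2 pi f)| of the analog prototype; used for
# documentation and by callers wanting the ideal response.
#' Analog magnitude response of the low-pass prototype
#'
#' @param freq_hz Frequencies in Hz (vectorized).
#' @param spec A [filter_spec()].
#' @return `|H(j 2 pi f)|` of the continuous-time second-order section.
#' @export
filter_response <- function(freq_hz, spec = filter_spec()) {
  wn <- 2 * pi * spec$cutoff_hz
  s <- 1i * 2 * pi * freq_hz
  Mod(wn^2 / (s^2 + 2 * spec$damping * wn * s + wn^2))
}

#' Low-pass filter an EOG trace
#'
#' Applies the second-order 60 Hz low-pass section of [filter_spec()] to both
#' channels, discretized by the bilinear transform at the trace's sample rate
#' and run as a causal difference equation
#' `y[n] = b0 x[n] + b1 x[n-1] + b2 x[n-2] - a1 y[n-1] - a2 y[n-2]`.
#'
#' @param trace An [eog_trace()].
#' @param spec A [filter_spec()].
#' @return A filtered [eog_trace()] of identical length and sampling.
#' @export
#' @examples
#' t <- seq(0, 0.5, by = 1 / 1000)
#' tr <- eog_trace(t, rep(3, length(t)), sin(2 * pi * 200 * t))
#' f <- lowpass_filter(tr)
#' tail(f$ch1, 1)            # DC passes at unit gain
#' max(abs(tail(f$ch2, 100)))  # 200 Hz strongly attenuated
lowpass_filter <- function(trace, spec = filter_spec()) {
  stopifnot(inherits(trace, "eog_trace"))
  if (!inherits(spec, "eog_filter_spec")) stop_invalid_config("`spec` must be a filter_spec()")
  if (spec$cutoff_hz >= trace$sample_rate / 2) {
    stop_invalid_config("filter cutoff must be below the Nyquist frequency")
  }
  cf <- butter2_coefficients(spec$cutoff_hz, trace$sample_rate)
  run <- function(x) as.numeric(signal::filter(cf$b, cf$a, x))
  eog_trace(trace$time, run(trace$ch1), run(trace$ch2),
            sample_rate = trace$sample_rate)
}
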