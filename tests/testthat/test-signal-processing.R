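test_that("low-pass filter preserves DC and matches the analytic magnitude response", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)

  # constant input passes at unit gain (after the transient settles)
  tr <- eog_trace(t, rep(3.7, length(t)), rep(-1.2, length(t)))
  f <- lowpass_filter(tr)
  expect_lt(abs(tail(f$ch1, 1) - 3.7), 1e-9)
  expect_lt(abs(tail(f$ch2, 1) + 1.2), 1e-9)

  # in-band and out-of-band sinusoids against the analytic transfer function
  spec <- filter_spec(60)
  for (freq in c(5, 200)) {
    x <- sin(2 * pi * freq * t)
    ftr <- lowpass_filter(eog_trace(t, x, x), spec)
    gain <- steady_amplitude(ftr$ch1)
    if (freq == 5) {
      expect_lt(abs(gain - filter_response(5, spec)) / filter_response(5, spec), 0.01)
    } else {
      expect_lt(gain, 0.12)  # analytic |H| at 200 Hz is ~0.09
    }
  }

  # cutoff at or above Nyquist is a configuration error
  slow <- eog_trace(seq(0, 1, by = 1 / 125), numeric(126), numeric(126))
  expect_error(lowpass_filter(slow, filter_spec(80)), class = "eogaze_invalid_config")
})

test_that("polarity detection honors the first threshold crossing", {
  th <- eog_thresholds(10, -10)
  expect_identical(detect_polarity(c(1, -4, 8, 9), th), "rest")

  x <- numeric(50)
  x[10] <- 15   # crosses positive first ...
  x[30] <- -20  # ... then negative
  expect_identical(detect_polarity(x, th), "+")
  expect_identical(detect_polarity(-x, th), "-")

  expect_error(detect_polarity(numeric(0), th), class = "eogaze_invalid_input")

  # sign-flip symmetry over random sequences, symmetric thresholds
  set.seed(11)
  for (i in 1:50) {
    x <- stats::rnorm(100, sd = 8)
    p <- detect_polarity(x, th)
    q <- detect_polarity(-x, th)
    if (p == "rest") expect_identical(q, "rest") else expect_true(p != q && q != "rest")
  }
})

test_that("the polarity pair maps onto the four screen quadrants", {
  expect_identical(classify_area("-", "-"), 1L)
  expect_identical(classify_area("+", "-"), 2L)
  expect_identical(classify_area("+", "+"), 3L)
  expect_identical(classify_area("-", "+"), 4L)

  # total on the 3x3 grid; exactly 4 combinations yield an area
  grid <- expand.grid(p1 = c("+", "-", "rest"), p2 = c("+", "-", "rest"),
                      stringsAsFactors = FALSE)
  areas <- mapply(classify_area, grid$p1, grid$p2)
  expect_length(areas, 9L)
  expect_identical(sum(!is.na(areas)), 4L)
  expect_setequal(areas[!is.na(areas)], 1:4)
})

test_that("wave segmentation brackets the full biphasic wave", {
  fs <- 1000
  th <- eog_thresholds(10, -10)

  # single half-sine above threshold flanked by zeros
  lobe <- 50 * sin(pi * seq(0, 1, length.out = 101))
  x <- c(numeric(100), lobe, numeric(200))
  seg <- segment_wave(x, th, fs)
  expect_true(seg$crossed)
  expect_identical(seg$polarity, "+")
  expect_lte(seg$start, 102L)  # zero crossing just before the lobe
  expect_gte(seg$start, 100L)
  expect_gte(seg$end, max(which(abs(x) > 10)))  # covers the supra-threshold support

  # biphasic pulse: segment spans both lobes despite the mid-wave zero pass
  x2 <- c(numeric(100), lobe, -0.5 * lobe, numeric(200))
  seg2 <- segment_wave(x2, th, fs)
  expect_gte(seg2$end, max(which(abs(x2) > 10)))  # past the second lobe too

  # sub-threshold noise stays a rest segment
  set.seed(5)
  seg3 <- segment_wave(stats::rnorm(500, sd = 2), th, fs)
  expect_false(seg3$crossed)
  expect_identical(seg3$polarity, "rest")
  expect_identical(integrate_wave(stats::rnorm(500, sd = 2), seg3, fs), 0)
})

test_that("full-wave integration matches analytic areas and is sign symmetric", {
  fs <- 1000
  th <- eog_thresholds(10, -10)

  # rectangular pulse of height h and duration d integrates to ~ h*d
  h <- 80
  d <- 0.2
  x <- c(numeric(50), rep(h, d * fs), numeric(150))
  seg <- segment_wave(x, th, fs)
  expect_lt(abs(integrate_wave(x, seg, fs) - h * d) / (h * d), 0.01)

  # sign flip with symmetric thresholds leaves the integral unchanged
  lobe <- 60 * sin(pi * seq(0, 1, length.out = 151))
  bi <- c(numeric(60), lobe, -0.5 * lobe, numeric(120))
  i1 <- integrate_wave(bi, segment_wave(bi, th, fs), fs)
  i2 <- integrate_wave(-bi, segment_wave(-bi, th, fs), fs)
  expect_equal(i1, i2, tolerance = 1e-12)
  expect_gte(i1, 0)

  # monotone non-decreasing as the pulse scales up with fixed shape
  ints <- vapply(c(1, 1.5, 2, 3), function(k) {
    xk <- k * bi
    integrate_wave(xk, segment_wave(xk, th, fs), fs)
  }, 0)
  expect_true(all(diff(ints) > 0))
})

test_that("integral normalization scales into [0, 1] and validates its maximum", {
  expect_identical(normalize_integral(0, 40), 0)
  expect_identical(normalize_integral(40, 40), 1)
  expect_identical(normalize_integral(20, 40), 0.5)
  expect_identical(normalize_integral(80, 40), 1)  # clamps
  expect_error(normalize_integral(1, 0), class = "eogaze_invalid_config")
})

test_that("trace files round-trip and uniform sampling is enforced", {
  t <- seq(0, 0.5, by = 1 / 500)
  tr <- eog_trace(t, sin(t), cos(t))
  path <- withr::local_tempfile(fileext = ".csv")
  write_eog_trace(tr, path)
  back <- read_eog_trace(path)
  expect_equal(back$ch1, tr$ch1, tolerance = 1e-6)
  expect_equal(back$sample_rate, 500, tolerance = 1e-6)

  expect_error(eog_trace(c(0, 0.001, 0.003), 1:3, 1:3),
               class = "eogaze_invalid_input")
  expect_error(eog_trace(c(0, 0.01, 0.02), 1:3, 1:3),  # 100 Hz too slow
               class = "eogaze_invalid_config")
})
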