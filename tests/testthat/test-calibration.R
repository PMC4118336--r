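test_that("the 24-target layout has the documented geometry", {
  layout <- target_layout()
  expect_identical(nrow(layout), 24L)
  expect_identical(as.integer(table(layout$area)), rep(6L, 4))
  expect_equal(unlist(layout[layout$name == "2,2", c("u", "v")]),
               c(u = 510, v = 360))
  # the two de-duplicated axis targets
  expect_equal(unlist(layout[layout$name == "2,0", c("u", "v")]),
               c(u = 510, v = 0))
  expect_equal(unlist(layout[layout$name == "-2,0", c("u", "v")]),
               c(u = -510, v = 0))
  # every area owns exactly two on-axis anchor targets
  for (a in 1:4) {
    anchors <- eogaze:::area_anchor_targets(layout, a)
    expect_identical(nrow(anchors), 2L)
  }
  # file round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_target_layout(layout, path)
  expect_identical(read_target_layout(path), layout)
})

test_that("reference lines pass through their anchors in both representations", {
  l <- fit_reference_line(c(0, 0), c(1, 1))
  expect_equal(c(l$a, l$b), c(1, 0))
  l2 <- fit_reference_line(c(0, 5), c(2, 5))
  expect_equal(c(l2$a, l2$b), c(0, 5))

  # a reported operator line (slope 1.27, intercept 6.99) is representable:
  # two points generated from it refit to the same coefficients
  p1 <- c(10, 1.27 * 10 + 6.99)
  p2 <- c(200, 1.27 * 200 + 6.99)
  l3 <- fit_reference_line(p1, p2, area = 1L)
  expect_equal(l3$a, 1.27, tolerance = 1e-9)
  expect_equal(l3$b, 6.99, tolerance = 1e-9)
  expect_equal(l3$a * p1[1] + l3$b, p1[2], tolerance = 1e-9)
  expect_equal(l3$a * p2[1] + l3$b, p2[2], tolerance = 1e-9)

  expect_error(fit_reference_line(c(1, 1), c(1, 1)), class = "eogaze_degenerate_line")

  # near-vertical anchors: slope/intercept unavailable, direction still exact
  lv <- fit_reference_line(c(5, 0), c(5 + 1e-9, 300))
  expect_true(is.na(lv$a) && is.na(lv$b))
  expect_equal(abs(lv$angle), pi / 2, tolerance = 1e-6)
})

test_that("staged area fitting is exact on its own family and order invariant", {
  layout <- target_layout()
  # identity data -> identity params
  sub <- layout[layout$area == 2L, ]
  pts <- cbind(sub$u, sub$v)
  fit <- fit_area_calibration(pts, pts, area = 2L)
  expect_equal(fit$params$theta, 0, tolerance = 1e-6)
  expect_equal(c(fit$params$m1, fit$params$m2), c(0, 0), tolerance = 1e-6)
  expect_equal(c(fit$params$s1, fit$params$s2), c(1, 1), tolerance = 1e-6)
  expect_equal(fit$matrix, diag(3), tolerance = 1e-6)

  # known factored distortion, zero noise: all six targets reproduced
  for (a in 1:4) {
    truth <- area_distortion(a, theta_deg = 25, s1 = 1 / 0.7, s2 = 0.8, shear = 0.1)
    M <- compose_homogeneous(truth)
    sub <- layout[layout$area == a, ]
    target <- cbind(sub$u, sub$v)
    actual <- apply_transform(solve(M), target)
    fit <- fit_area_calibration(actual, target, area = a)
    reproduced <- apply_transform(fit$matrix, actual)
    expect_lt(max(sqrt(rowSums((reproduced - target)^2))), 0.5)
    expect_equal(fit$params$theta, truth$theta, tolerance = 1e-9)

    # anchor residual no worse than leaving the points untouched
    anchors <- eogaze:::area_anchor_targets(layout, a)
    ai <- match(anchors$name, sub$name)
    res_fit <- sum((reproduced[ai, ] - target[ai, ])^2)
    res_id <- sum((actual[ai, ] - target[ai, ])^2)
    expect_lte(res_fit, res_id + 1e-9)

    # permutation of the training pairs changes nothing
    perm <- sample(nrow(actual))
    fit2 <- fit_area_calibration(actual[perm, ], target[perm, ], area = a)
    expect_equal(unlist(fit2$params), unlist(fit$params), tolerance = 1e-9)
  }

  expect_error(fit_area_calibration(rbind(c(0, 0), c(1, 1)), rbind(c(0, 0), c(1, 1)), 1L),
               class = "eogaze_underdetermined")
  coll <- cbind(1:5, 2 * (1:5))
  expect_error(fit_area_calibration(coll, coll, 1L), class = "eogaze_underdetermined")
})

test_that("full-session calibration recovers known distortions and averages repeats", {
  # identity distortion, zero noise: all four matrices are the identity
  cal_id <- identity_calibration()
  for (a in 1:4) expect_equal(cal_id$areas[[a]]$matrix, diag(3), tolerance = 1e-6)

  # known per-area distortion, zero noise: every target back within 0.5 px
  cfg <- quiet_sim_config(seed = 13, distortions = default_distortions(13))
  ses <- generate_training_session(cfg)
  cal <- calibrate_all(ses, normalizers = default_normalizers())
  corrected <- correct_pixels(cal, cbind(ses$actual_u, ses$actual_v), areas = ses$area)
  err <- sqrt(rowSums((corrected - cbind(ses$target_u, ses$target_v))^2))
  expect_lt(max(err), 0.5)
  # fitted rotations sit in the configured band
  for (a in 1:4) {
    expect_equal(cal$areas[[a]]$params$theta, cfg$distortions[[a]]$theta,
                 tolerance = 1e-6)
  }

  # repeats are averaged before fitting: symmetric scatter cancels exactly
  layout <- target_layout()
  clean <- data.frame(name = layout$name, target_u = layout$u, target_v = layout$v,
                      actual_u = layout$u, actual_v = layout$v)
  d <- 3
  noisy <- rbind(transform(clean, actual_u = actual_u + d, actual_v = actual_v - d),
                 transform(clean, actual_u = actual_u - d, actual_v = actual_v + d))
  cal_avg <- calibrate_all(noisy)
  for (a in 1:4) expect_equal(cal_avg$areas[[a]]$matrix, diag(3), tolerance = 1e-6)

  # a missing target is an incomplete session
  expect_error(calibrate_all(clean[-1, ]), class = "eogaze_incomplete_session")
})

test_that("accuracy evaluation reports pixel and angular errors", {
  cal <- identity_calibration()
  layout <- target_layout()
  tgt <- cbind(layout$u, layout$v)

  rep0 <- evaluate_accuracy(cal, tgt, tgt)
  expect_equal(unname(rep0$horizontal_px["mean"]), 0, tolerance = 1e-9)
  expect_equal(unname(rep0$euclidean_px["mean"]), 0, tolerance = 1e-9)

  one <- evaluate_accuracy(cal, rbind(c(111, 200)), rbind(c(100, 200)))
  expect_equal(unname(one$horizontal_px["mean"]), 11, tolerance = 1e-9)
  expect_equal(unname(one$horizontal_px["sd"]), 0)

  # an 18 px horizontal error is ~0.86 degrees at this geometry
  e18 <- evaluate_accuracy(cal, rbind(c(118, 200)), rbind(c(100, 200)))
  expect_equal(unname(e18$horizontal_deg["mean"]),
               180 / pi * atan(18 * 34 / 1020 / 40), tolerance = 1e-9)
  expect_identical(round(unname(e18$horizontal_deg["mean"]), 2), 0.86)

  expect_error(evaluate_accuracy(cal, tgt[0, , drop = FALSE], tgt[0, , drop = FALSE]),
               class = "eogaze_invalid_input")

  # calibration never hurts in-sample on its own training session
  for (seed in 1:5) {
    cfg <- simulation_config(distortions = default_distortions(seed),
                             pixel_noise_sd = 2, repeats = 3, seed = seed)
    ses <- generate_training_session(cfg)
    cal_s <- calibrate_all(ses)
    act <- cbind(ses$actual_u, ses$actual_v)
    tg <- cbind(ses$target_u, ses$target_v)
    fitted_err <- evaluate_accuracy(cal_s, act, tg, areas = ses$area)
    raw_err <- mean(sqrt(rowSums((act - tg)^2)))
    expect_lt(unname(fitted_err$euclidean_px["mean"]), raw_err)
  }
})

test_that("calibration files round-trip bit-exactly", {
  cfg <- quiet_sim_config(seed = 21, distortions = default_distortions(21))
  ses <- generate_training_session(cfg)
  cal <- calibrate_all(ses, normalizers = default_normalizers(), session_id = "s21")
  p1 <- withr::local_tempfile(fileext = ".txt")
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_calibration(cal, p1)
  back <- read_calibration(p1)
  write_calibration(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  for (a in 1:4) {
    expect_identical(back$areas[[a]]$matrix, cal$areas[[a]]$matrix)
    expect_identical(unlist(back$areas[[a]]$params), unlist(cal$areas[[a]]$params))
  }
  expect_identical(back$session_id, "s21")
  expect_identical(unclass(back$gains), unclass(cal$gains))
})
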