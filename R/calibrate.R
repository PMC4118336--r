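#' Calibration target layout
#'
#' The 24-target training grid: six targets per screen quadrant on a lattice
#' of 255 px horizontal and 180 px vertical spacing, named by their lattice
#' coordinates (e.g. `"2,1"` is `(510, 180)`). Targets on the positive /
#' negative half-axes belong to Areas 1-4 as in the experimental design. Two
#' printed grid entries (`"2,0"` and `"-2,0"`) duplicate their neighbours at
#' one lattice step; the shipped layout places them at `(510, 0)` and
#' `(-510, 0)`, completing the symmetric pattern and keeping the two
#' horizontal-axis anchors of Areas 2 and 4 distinct.
#'
#' @return A data frame with columns `name`, `u`, `v` (signed pixels from
#'   screen center) and `area` (1..4).
#' @export
#' @examples
#' layout <- target_layout()
#' layout[layout$name == "2,2", ]  # (510, 360), Area 1
target_layout <- function() {
  rows <- list(
    # Area 1 (upper right)
    c("0,1", 0, 180, 1), c("0,2", 0, 360, 1), c("1,1", 255, 180, 1),
    c("1,2", 255, 360, 1), c("2,1", 510, 180, 1), c("2,2", 510, 360, 1),
    # Area 2 (lower right)
    c("1,0", 255, 0, 2), c("1,-1", 255, -180, 2), c("1,-2", 255, -360, 2),
    c("2,0", 510, 0, 2), c("2,-1", 510, -180, 2), c("2,-2", 510, -360, 2),
    # Area 3 (lower left)
    c("0,-1", 0, -180, 3), c("0,-2", 0, -360, 3), c("-1,-1", -255, -180, 3),
    c("-1,-2", -255, -360, 3), c("-2,-1", -510, -180, 3), c("-2,-2", -510, -360, 3),
    # Area 4 (upper left)
    c("-1,0", -255, 0, 4), c("-1,1", -255, 180, 4), c("-1,2", -255, 360, 4),
    c("-2,0", -510, 0, 4), c("-2,1", -510, 180, 4), c("-2,2", -510, 360, 4)
  )
  data.frame(
    name = vapply(rows, `[`, "", 1L),
    u = as.numeric(vapply(rows, `[`, "", 2L)),
    v = as.numeric(vapply(rows, `[`, "", 3L)),
    area = as.integer(vapply(rows, `[`, "", 4L))
  )
}

#' Read / write a target layout file
#'
#' Rows of `name,u,v,area` in CSV; the default file content equals
#' [target_layout()].
#'
#' @param path File path.
#' @param layout A layout data frame.
#' @export
read_target_layout <- function(path) {
  if (!file.exists(path)) stop_invalid_input(sprintf("layout file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = c(name = "character"))
  need <- c("name", "u", "v", "area")
  if (!all(need %in% names(df))) stop_invalid_input("layout file must have columns name,u,v,area")
  df$u <- as.numeric(df$u)
  df$v <- as.numeric(df$v)
  df$area <- as.integer(df$area)
  df[, need]
}

#' @rdname read_target_layout
#' @export
write_target_layout <- function(layout, path) {
  utils::write.csv(layout, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# The two anchor targets of an area: the targets lying on the screen axis
# owned by the area (vertical axis for Areas 1/3, horizontal for 2/4),
# nearest-to-origin first.
area_anchor_targets <- function(layout, area) {
  sub <- layout[layout$area == area, ]
  onaxis <- if (area %in% c(1L, 3L)) sub[sub$u == 0, ] else sub[sub$v == 0, ]
  if (nrow(onaxis) != 2L) {
    stop_runtime(sprintf("area %d does not have exactly two axis anchor targets", area),
                 "eogaze_incomplete_session")
  }
  onaxis[order(onaxis$u^2 + onaxis$v^2), ]
}

area_axis_angle <- function(area) if (area %in% c(1L, 3L)) pi / 2 else 0

# Wrap an angle to (-pi/2, pi/2]: line directions are defined modulo pi.
wrap_half <- function(ang) {
  ang <- (ang + pi / 2) %% pi - pi / 2
  if (ang == -pi / 2) pi / 2 else ang
}

#' Fit a quadrant reference line
#'
#' The reference line of an area is the straight line through the two
#' designated anchor actual pixels (the actuals recorded for the area's two
#' on-axis targets). It defines the rotation pivot axis and shear frame of
#' the calibration. Internally the line is stored in direction-angle + point
#' form, which stays well defined for near-vertical data; the slope/intercept
#' representation `y = a x + b` is additionally reported when the anchor
#' abscissae differ by more than `1e-6` px, and is `NA` otherwise.
#'
#' @param p1,p2 The two anchor actual pixels, `c(u, v)`; `p1` is the anchor
#'   nearest the screen origin.
#' @param area Optional area label 1..4 stored on the line.
#' @return An object of class `reference_line`: list with `area`, `a`, `b`
#'   (slope/intercept or `NA`), `angle` (direction in radians, `(-pi/2,
#'   pi/2]`), and the generating points `p1`, `p2`.
#' @export
#' @examples
#' fit_reference_line(c(0, 0), c(1, 1))$a  # slope 1
fit_reference_line <- function(p1, p2, area = NA_integer_) {
  p1 <- drop(as_point_matrix(p1, "p1"))
  p2 <- drop(as_point_matrix(p2, "p2"))
  d <- p2 - p1
  if (all(d == 0)) {
    abort_eogaze("anchor points coincide: reference line is degenerate",
                 "eogaze_degenerate_line")
  }
  angle <- wrap_half(atan2(d[2L], d[1L]))
  if (abs(d[1L]) < 1e-6) {
    a <- NA_real_
    b <- NA_real_
  } else {
    a <- d[2L] / d[1L]
    b <- p1[2L] - a * p1[1L]
  }
  structure(
    list(area = as.integer(area), a = a, b = b, angle = angle, p1 = p1, p2 = p2),
    class = "reference_line"
  )
}

#' @export
print.reference_line <- function(x, ...) {
  ab <- if (is.na(x$a)) "near-vertical (slope unavailable)" else
    sprintf("y = %.4f x + %.4f", x$a, x$b)
  cat(sprintf("<reference_line> area %s: %s (direction %.2f deg)\n",
              ifelse(is.na(x$area), "?", x$area), ab, rad2deg(x$angle)))
  invisible(x)
}

project_onto_line <- function(point, line) {
  d <- c(cos(line$angle), sin(line$angle))
  line$p1 + sum((point - line$p1) * d) * d
}

#' Fit the factored affine calibration of one quadrant
#'
#' Staged estimation of the seven transform parameters that move an area's
#' actual pixels onto its target pixels:
#' 1. the rotation pivot is the orthogonal projection of the anchor actual
#'    nearest the origin onto the reference line, and `(Tx, Ty)` is its
#'    negation;
#' 2. `theta` rotates the reference line onto the area's target axis (the
#'    vertical axis for Areas 1/3, horizontal for Areas 2/4);
#' 3. after translate-rotate-translate, the shear `(m1, m2)` is estimated by
#'    per-axis least squares of the targets on the rotated actuals (no
#'    intercept), which absorbs the residual cross-axis terms;
#' 4. the dilatation `(s1, s2)` is the per-axis ratio of the target span to
#'    the sheared-actual span.
#'
#' The procedure is deterministic, invariant to the order of the pairs, and
#' exact (zero residual) on pairs generated by a distortion of the same
#' factored family (see [area_distortion()]).
#'
#' @param actual,target n x 2 matrices (or data frames) of corresponding
#'   actual and target pixels; at least 3 non-collinear pairs.
#' @param area Area label 1..4 (decides the target axis).
#' @param line Optional [fit_reference_line()] result; if `NULL` it is fitted
#'   from the rows of `actual` whose targets lie on the area's axis, which
#'   requires `target` to contain the two anchor targets.
#' @return A list with `params` ([geometry_params()]), `matrix` (the composed
#'   3 x 3 transform) and `line`.
#' @export
fit_area_calibration <- function(actual, target, area, line = NULL) {
  actual <- as_point_matrix(as.matrix(actual), "actual")
  target <- as_point_matrix(as.matrix(target), "target")
  n <- nrow(actual)
  if (n != nrow(target)) stop_invalid_input("`actual` and `target` must pair up")
  if (n < 3L || qr(cbind(actual - matrix(colMeans(actual), n, 2, byrow = TRUE)))$rank < 2L) {
    abort_eogaze("need at least 3 non-collinear pairs to fit an area",
                 "eogaze_underdetermined")
  }
  if (!area %in% 1:4) stop_invalid_input("`area` must be 1..4")

  if (is.null(line)) {
    onaxis <- if (area %in% c(1L, 3L)) target[, 1L] == 0 else target[, 2L] == 0
    idx <- which(onaxis)
    if (length(idx) != 2L) {
      stop_invalid_input("cannot derive the reference line: supply `line` or the two axis anchors")
    }
    idx <- idx[order(rowSums(target[idx, , drop = FALSE]^2))]
    line <- fit_reference_line(actual[idx[1L], ], actual[idx[2L], ], area)
  }

  pivot <- project_onto_line(line$p1, line)
  theta <- wrap_half(area_axis_angle(area) - line$angle)

  trt <- translation_matrix(pivot[1L], pivot[2L]) %*% rotation_matrix(theta) %*%
    translation_matrix(-pivot[1L], -pivot[2L])
  q <- apply_transform(trt, actual)

  cu <- stats::lsfit(q, target[, 1L], intercept = FALSE)$coefficients
  cv <- stats::lsfit(q, target[, 2L], intercept = FALSE)$coefficients
  if (abs(cu[1L]) < 1e-12 || abs(cv[2L]) < 1e-12) {
    abort_eogaze("degenerate shear fit: rotated actuals carry no on-axis signal",
                 "eogaze_underdetermined")
  }
  m1 <- unname(cu[2L] / cu[1L])
  m2 <- unname(cv[1L] / cv[2L])

  sheared <- apply_transform(shear_matrix(m1, m2), q)
  span <- function(x) diff(range(x))
  if (span(sheared[, 1L]) == 0 || span(sheared[, 2L]) == 0) {
    abort_eogaze("degenerate dilatation fit: sheared actuals have zero span",
                 "eogaze_underdetermined")
  }
  s1 <- span(target[, 1L]) / span(sheared[, 1L])
  s2 <- span(target[, 2L]) / span(sheared[, 2L])

  params <- geometry_params(tx = -pivot[1L], ty = -pivot[2L], theta = theta,
                            m1 = m1, m2 = m2, s1 = s1, s2 = s2)
  list(params = params, matrix = compose_homogeneous(params), line = line)
}

#' Calibrate all four quadrants from a training session
#'
#' Averages the repeated gazes recorded for each training target and fits
#' one reference line, one set of [geometry_params()] and one composed
#' homogeneous matrix per area.
#'
#' @param session Data frame of training observations with columns
#'   `target_u`, `target_v`, `actual_u`, `actual_v` and optionally `name`
#'   (target names are matched against `layout` by name when present,
#'   otherwise by target position). Repeated rows per target are averaged.
#' @param layout Target layout (default [target_layout()]); every layout
#'   target must appear in the session.
#' @param gains The [gain_table()] in force when the actual pixels were
#'   estimated (stored for provenance).
#' @param normalizers Optional per-channel/direction integral normalizers
#'   (stored for provenance and used by the tracking pipeline).
#' @param session_id Optional identifier stored in the calibration.
#' @return An object of class `calibration_set`: per-area `line`, `params`,
#'   `matrix` and averaged training `pairs`, plus `gains`, `normalizers` and
#'   `session_id`.
#' @export
calibrate_all <- function(session, layout = target_layout(), gains = gain_table(),
                          normalizers = NULL, session_id = NULL) {
  need <- c("target_u", "target_v", "actual_u", "actual_v")
  if (!all(need %in% names(session))) {
    stop_invalid_input("`session` must have columns target_u,target_v,actual_u,actual_v")
  }
  if ("name" %in% names(session)) {
    key <- match(session$name, layout$name)
  } else {
    key <- match(paste(session$target_u, session$target_v),
                 paste(layout$u, layout$v))
  }
  if (anyNA(key)) stop_invalid_input("session contains targets absent from the layout")

  agg_u <- tapply(session$actual_u, key, mean)
  agg_v <- tapply(session$actual_v, key, mean)
  rows <- as.integer(names(agg_u))
  missing <- setdiff(seq_len(nrow(layout)), rows)
  if (length(missing) > 0L) {
    stop_runtime(
      sprintf("incomplete session: no gazes for target(s) %s",
              paste(layout$name[missing], collapse = ", ")),
      "eogaze_incomplete_session"
    )
  }
  averaged <- data.frame(
    name = layout$name[rows],
    area = layout$area[rows],
    target_u = layout$u[rows],
    target_v = layout$v[rows],
    actual_u = as.numeric(agg_u),
    actual_v = as.numeric(agg_v)
  )

  areas <- lapply(1:4, function(a) {
    sub <- averaged[averaged$area == a, ]
    anchors <- area_anchor_targets(layout, a)
    i1 <- match(anchors$name[1L], sub$name)
    i2 <- match(anchors$name[2L], sub$name)
    line <- fit_reference_line(c(sub$actual_u[i1], sub$actual_v[i1]),
                               c(sub$actual_u[i2], sub$actual_v[i2]), a)
    fit <- fit_area_calibration(
      cbind(sub$actual_u, sub$actual_v),
      cbind(sub$target_u, sub$target_v),
      a, line = line
    )
    list(line = line, params = fit$params, matrix = fit$matrix, pairs = sub)
  })
  names(areas) <- as.character(1:4)
  structure(
    list(areas = areas, gains = gains, normalizers = normalizers,
         session_id = if (is.null(session_id)) NA_character_ else as.character(session_id)),
    class = "calibration_set"
  )
}

#' @export
print.calibration_set <- function(x, ...) {
  cat("<calibration_set>\n")
  for (a in 1:4) {
    p <- x$areas[[a]]$params
    cat(sprintf("  area %d: theta=%6.2f deg, s=(%.3f, %.3f), m=(%+.3f, %+.3f)\n",
                a, rad2deg(p$theta), p$s1, p$s2, p$m1, p$m2))
  }
  invisible(x)
}

#' Apply a calibration to actual pixels
#'
#' Moves estimated gaze pixels onto the target frame using the homogeneous
#' matrix of each point's quadrant.
#'
#' @param cal A [calibrate_all()] result.
#' @param points Length-2 numeric or n x 2 matrix of actual pixels.
#' @param areas Optional integer vector of areas; defaults to the sign-based
#'   quadrant of each point ([area_for_point()]).
#' @return Corrected pixel point(s), same shape as `points`.
#' @export
correct_pixels <- function(cal, points, areas = NULL) {
  stopifnot(inherits(cal, "calibration_set"))
  m <- as_point_matrix(points)
  if (is.null(areas)) areas <- area_for_point(m[, 1L], m[, 2L])
  areas <- as.integer(areas)
  if (length(areas) != nrow(m)) stop_invalid_input("`areas` must match the number of points")
  out <- m
  for (a in unique(areas)) {
    sel <- areas == a
    out[sel, ] <- apply_transform(cal$areas[[a]]$matrix, m[sel, , drop = FALSE])
  }
  restore_point_shape(out, points)
}

mean_sd <- function(x) c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0)

#' Tracking accuracy of a calibration
#'
#' Corrects the supplied actual pixels and summarizes the deviation from
#' their targets: per-area mean and standard deviation of the Euclidean and
#' per-axis pixel errors, plus overall horizontal and vertical errors in
#' pixels and visual-angle degrees (each pixel error converted through
#' [pixels_to_visual_angle()] before averaging).
#'
#' @param cal A [calibrate_all()] result.
#' @param actual,target n x 2 matrices of test pairs (non-empty).
#' @param areas Optional area assignment of the pairs; defaults to the
#'   quadrant of the target.
#' @param geometry A [display_geometry()].
#' @return An object of class `accuracy_report`.
#' @export
evaluate_accuracy <- function(cal, actual, target, areas = NULL,
                              geometry = display_geometry()) {
  actual <- as_point_matrix(as.matrix(actual), "actual")
  target <- as_point_matrix(as.matrix(target), "target")
  if (nrow(actual) == 0L) stop_invalid_input("no test pairs supplied")
  if (nrow(actual) != nrow(target)) stop_invalid_input("`actual` and `target` must pair up")
  if (is.null(areas)) areas <- area_for_point(target[, 1L], target[, 2L])
  corrected <- correct_pixels(cal, actual, areas)
  corrected <- as_point_matrix(corrected)
  du <- abs(corrected[, 1L] - target[, 1L])
  dv <- abs(corrected[, 2L] - target[, 2L])
  eu <- sqrt(du^2 + dv^2)
  per_area <- lapply(sort(unique(areas)), function(a) {
    sel <- areas == a
    list(area = a, n = sum(sel), euclidean = mean_sd(eu[sel]),
         horizontal = mean_sd(du[sel]), vertical = mean_sd(dv[sel]))
  })
  structure(
    list(
      per_area = per_area,
      horizontal_px = mean_sd(du),
      vertical_px = mean_sd(dv),
      euclidean_px = mean_sd(eu),
      horizontal_deg = mean_sd(pixels_to_visual_angle(du, "horizontal", geometry)),
      vertical_deg = mean_sd(pixels_to_visual_angle(dv, "vertical", geometry)),
      n = nrow(actual)
    ),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %d test pairs\n", x$n))
  cat(sprintf("  horizontal: %.2f +/- %.2f px  (%.3f +/- %.3f deg)\n",
              x$horizontal_px["mean"], x$horizontal_px["sd"],
              x$horizontal_deg["mean"], x$horizontal_deg["sd"]))
  cat(sprintf("  vertical:   %.2f +/- %.2f px  (%.3f +/- %.3f deg)\n",
              x$vertical_px["mean"], x$vertical_px["sd"],
              x$vertical_deg["mean"], x$vertical_deg["sd"]))
  for (pa in x$per_area) {
    cat(sprintf("  area %d: %.2f +/- %.2f px (Euclidean, n=%d)\n",
                pa$area, pa$euclidean["mean"], pa$euclidean["sd"], pa$n))
  }
  invisible(x)
}

#' Read / write a calibration file
#'
#' Calibrations persist as human-readable structured text: one
#' whitespace-separated record per line holding the gain table, normalizers,
#' per-area reference line, the seven transform parameters, the composed
#' 3 x 3 matrix (row-major) and the averaged training pairs. Doubles are
#' written with 17 significant digits, so a write-read-write cycle is
#' bit-exact.
#'
#' @param cal A [calibrate_all()] result.
#' @param path File path.
#' @return `read_calibration()` returns the `calibration_set`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_set"))
  fd <- function(x) vapply(x, format_double, "")
  lines <- c("eogaze-calibration 1",
             paste("session_id", ifelse(is.na(cal$session_id), "-", cal$session_id)))
  for (d in names(cal$gains)) {
    lines <- c(lines, paste("gain", d, paste(fd(cal$gains[[d]]), collapse = " ")))
  }
  if (!is.null(cal$normalizers)) {
    for (ch in names(cal$normalizers)) {
      for (d in names(cal$normalizers[[ch]])) {
        lines <- c(lines, paste("normalizer", ch, d, format_double(cal$normalizers[[ch]][[d]])))
      }
    }
  }
  for (a in 1:4) {
    ar <- cal$areas[[a]]
    ln <- ar$line
    ab <- if (is.na(ln$a)) c("NA", "NA") else fd(c(ln$a, ln$b))
    lines <- c(
      lines,
      paste("line", a, format_double(ln$angle), paste(fd(ln$p1), collapse = " "),
            paste(fd(ln$p2), collapse = " "), paste(ab, collapse = " ")),
      paste("params", a, paste(fd(unlist(ar$params)), collapse = " ")),
      paste("matrix", a, paste(fd(as.numeric(t(ar$matrix))), collapse = " "))
    )
    for (i in seq_len(nrow(ar$pairs))) {
      p <- ar$pairs[i, ]
      lines <- c(lines, paste("pair", a, p$name,
                              paste(fd(c(p$target_u, p$target_v, p$actual_u, p$actual_v)),
                                    collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop_invalid_input(sprintf("calibration file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "eogaze-calibration")) {
    stop_invalid_input("not an eogaze calibration file")
  }
  toks <- strsplit(lines[-1L], "[[:space:]]+")
  num <- function(x) {
    out <- suppressWarnings(as.numeric(x))
    out[x == "NA"] <- NA_real_
    out
  }
  gains <- list()
  normalizers <- list()
  session_id <- NA_character_
  areas <- stats::setNames(vector("list", 4L), as.character(1:4))
  pairs <- stats::setNames(lapply(1:4, function(a) list()), as.character(1:4))
  for (tk in toks) {
    if (length(tk) == 0L || tk[1L] == "") next
    kind <- tk[1L]
    if (kind == "session_id") {
      session_id <- if (tk[2L] == "-") NA_character_ else tk[2L]
    } else if (kind == "gain") {
      gains[[tk[2L]]] <- stats::setNames(num(tk[3:4]), c("A", "B"))
    } else if (kind == "normalizer") {
      normalizers[[tk[2L]]][[tk[3L]]] <- num(tk[4L])
    } else if (kind == "line") {
      a <- tk[2L]
      v <- num(tk[-(1:2)])
      ln <- structure(
        list(area = as.integer(a), a = v[6L], b = v[7L], angle = v[1L],
             p1 = v[2:3], p2 = v[4:5]),
        class = "reference_line"
      )
      areas[[a]]$line <- ln
    } else if (kind == "params") {
      v <- num(tk[-(1:2)])
      areas[[tk[2L]]]$params <- geometry_params(v[1L], v[2L], v[3L], v[4L], v[5L], v[6L], v[7L])
    } else if (kind == "matrix") {
      v <- num(tk[-(1:2)])
      areas[[tk[2L]]]$matrix <- matrix(v, 3L, 3L, byrow = TRUE)
    } else if (kind == "pair") {
      v <- num(tk[4:7])
      pairs[[tk[2L]]] <- c(pairs[[tk[2L]]], list(
        data.frame(name = tk[3L], area = as.integer(tk[2L]),
                   target_u = v[1L], target_v = v[2L],
                   actual_u = v[3L], actual_v = v[4L])
      ))
    }
  }
  for (a in as.character(1:4)) {
    if (is.null(areas[[a]]$matrix)) {
      stop_invalid_input(sprintf("calibration file is missing area %s", a))
    }
    areas[[a]]$pairs <- if (length(pairs[[a]]) > 0L) do.call(rbind, pairs[[a]]) else NULL
  }
  structure(
    list(areas = areas, gains = do.call(gain_table, gains),
         normalizers = if (length(normalizers)) normalizers else NULL,
         session_id = session_id),
    class = "calibration_set"
  )
}
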