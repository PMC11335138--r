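#' Rectangular analysis window
#' @param xmin,xmax,ymin,ymax Window bounds in calibrated units.
#' @return A `rect_window` object.
#' @export
rect_window <- function(xmin, xmax, ymin, ymax) {
  if (xmax <= xmin || ymax <= ymin) stop("degenerate window", call. = FALSE)
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                 area = (xmax - xmin) * (ymax - ymin)),
            class = "rect_window")
}

#' Ripley's L clustering curve
#'
#' Uncorrected estimator `K(r) = |A| / (n (n-1)) * sum_{i != j} 1[d_ij <= r]`,
#' reported as `L(r) - r` with `L(r) = sqrt(K(r) / pi)`; values above zero
#' indicate clustering at that radius. No analytic edge correction is
#' applied — significance is judged against a Monte-Carlo envelope computed
#' in the same window ([csr_envelope()]), which shares the edge bias.
#'
#' @param points Two-column matrix or data frame of x/y positions inside
#'   the window.
#' @param radii Increasing radii at which to evaluate the curve.
#' @param window A [rect_window()].
#' @return Tibble with columns `r`, `K`, `L`, `L_minus_r`.
#' @export
ripley_l <- function(points, radii, window) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 2) stop("Ripley's L needs >= 2 points", call. = FALSE)
  if (!inherits(window, "rect_window")) {
    stop("window must be a rect_window", call. = FALSE)
  }
  d <- stats::dist(pts)
  counts <- vapply(radii, function(r) sum(d <= r), numeric(1)) * 2
  K <- window$area * counts / (n * (n - 1))
  L <- sqrt(K / pi)
  tibble::tibble(r = radii, K = K, L = L, L_minus_r = L - radii)
}

#' Monte-Carlo envelope under complete spatial randomness
#'
#' Simulates `n_simulations` uniform point patterns with the same `n` in
#' the same window, and returns the pointwise `alpha/2` and `1 - alpha/2`
#' empirical quantiles of `L(r) - r`.
#'
#' @param n_points Number of points per simulation.
#' @param window A [rect_window()].
#' @param radii Radii (as in [ripley_l()]).
#' @param n_simulations Number of CSR simulations.
#' @param alpha Two-sided envelope level.
#' @param seed Integer seed.
#' @return Tibble with `r`, `envelope_low`, `envelope_high`, `mean_sim`.
#' @export
csr_envelope <- function(n_points, window, radii, n_simulations = 100,
                         alpha = 0.05, seed = 42) {
  if (n_points < 2) stop("need n_points >= 2", call. = FALSE)
  if (n_simulations < 20) {
    warning("fewer than 20 simulations: envelope quantiles are unstable")
  }
  set.seed(seed)
  sims <- matrix(NA_real_, n_simulations, length(radii))
  for (s in seq_len(n_simulations)) {
    pts <- cbind(stats::runif(n_points, window$xmin, window$xmax),
                 stats::runif(n_points, window$ymin, window$ymax))
    sims[s, ] <- ripley_l(pts, radii, window)$L_minus_r
  }
  tibble::tibble(
    r = radii,
    envelope_low = apply(sims, 2, stats::quantile, probs = alpha / 2),
    envelope_high = apply(sims, 2, stats::quantile, probs = 1 - alpha / 2),
    mean_sim = colMeans(sims)
  )
}

#' Ripley analysis of track positions in one field of view
#'
#' Reduces each track to a single point (its position at the first frame by
#' default, avoiding temporal pseudo-replication) and runs [ripley_l()]
#' plus [csr_envelope()].
#'
#' @param ds A 2-D `track_dataset` (one FOV is customary).
#' @param radii Radii.
#' @param window A [rect_window()]; default: bounding box of the points.
#' @param point_rule `"first_frame"`, `"mean_position"`, or a frame number.
#' @param n_simulations,alpha,seed Passed to [csr_envelope()].
#' @return A `ripley_result`: list with `$curve`, `$envelope`, `$n_points`,
#'   `$window`.
#' @export
ripley_track_analysis <- function(ds, radii, window = NULL,
                                  point_rule = "first_frame",
                                  n_simulations = 100, alpha = 0.05,
                                  seed = 42) {
  assert_dataset(ds)
  if (ds$dimensionality != 2L) {
    stop("spatial analysis supports 2-D + time datasets only", call. = FALSE)
  }
  sp <- dplyr::arrange(ds$spots, .data$unique_track_id, .data$frame)
  pts <- if (identical(point_rule, "first_frame")) {
    sp |> dplyr::group_by(.data$unique_track_id) |>
      dplyr::slice_head(n = 1) |> dplyr::ungroup()
  } else if (identical(point_rule, "mean_position")) {
    sp |> dplyr::group_by(.data$unique_track_id) |>
      dplyr::summarise(x = mean(.data$x), y = mean(.data$y),
                       .groups = "drop")
  } else {
    fr <- as.integer(point_rule)
    sp |> dplyr::filter(.data$frame == fr)
  }
  m <- cbind(pts$x, pts$y)
  if (is.null(window)) {
    window <- rect_window(min(m[, 1]), max(m[, 1]), min(m[, 2]), max(m[, 2]))
  }
  curve <- ripley_l(m, radii, window)
  env <- csr_envelope(nrow(m), window, radii, n_simulations = n_simulations,
                      alpha = alpha, seed = seed)
  structure(list(curve = curve, envelope = env, n_points = nrow(m),
                 window = window, n_simulations = n_simulations,
                 seed = seed),
            class = "ripley_result")
}

segments_self_intersect <- function(v, closed) {
  n <- nrow(v)
  segs <- cbind(v, rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]))
  m <- if (closed) n else n - 1
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i + 1) next
      if (closed && i == 1 && j == m) next  # adjacent around the loop
      p <- segs[i, 1:2]; p2 <- segs[i, 3:4]
      q <- segs[j, 1:2]; q2 <- segs[j, 3:4]
      d1 <- cross2(q[1], q[2], q2[1], q2[2], p[1], p[2])
      d2 <- cross2(q[1], q[2], q2[1], q2[2], p2[1], p2[2])
      d3 <- cross2(p[1], p[2], p2[1], p2[2], q[1], q[2])
      d4 <- cross2(p[1], p[2], p2[1], p2[2], q2[1], q2[2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Region of interest from a polygon (or open polyline)
#'
#' @param vertices Two-column matrix/data frame of calibrated x/y vertices.
#' @param closed Close the boundary back to the first vertex (`TRUE` for a
#'   region outline, `FALSE` for an open edge such as a monolayer leading
#'   edge).
#' @return A `roi_geometry` object.
#' @export
roi_polygon <- function(vertices, closed = TRUE) {
  v <- as.matrix(vertices)[, 1:2, drop = FALSE]
  if (nrow(v) < 2) stop("polygon needs >= 2 vertices", call. = FALSE)
  if (nrow(v) >= 4 && segments_self_intersect(v, closed)) {
    stop("polygon is self-intersecting", call. = FALSE)
  }
  structure(list(type = "polygon", vertices = v, closed = closed),
            class = "roi_geometry")
}

#' Region of interest from a binary mask
#'
#' Boundary pixels are mask pixels 4-adjacent to a non-mask pixel inside
#' the image (the image frame itself is not treated as a boundary);
#' distances are measured to boundary pixel centres and multiplied by
#' `pixel_size`.
#'
#' @param mask Logical (or 0/1) matrix, rows = y, columns = x.
#' @param pixel_size Calibrated length per pixel.
#' @return A `roi_geometry` object.
#' @export
roi_mask <- function(mask, pixel_size) {
  mask <- mask != 0
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  # pad with TRUE: mask pixels on the image border are not boundary unless
  # they touch a non-mask pixel inside the image (the image frame is not a
  # biological edge)
  pad <- matrix(TRUE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  inner <- pad[2:(nr + 1), 2:(nc + 1)]
  nb <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  boundary <- inner & !nb
  idx <- which(boundary, arr.ind = TRUE)
  # pixel centres: x from column index, y from row index
  coords <- cbind(x = (idx[, "col"] - 0.5) * pixel_size,
                  y = (idx[, "row"] - 0.5) * pixel_size)
  structure(list(type = "mask", mask = mask, pixel_size = pixel_size,
                 boundary_coords = coords),
            class = "roi_geometry")
}

point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  tt <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx +
                                                 (py - ay) * vy) / len2))
  sqrt((px - (ax + tt * vx))^2 + (py - (ay + tt * vy))^2)
}

roi_boundary_distance <- function(roi, px, py) {
  if (roi$type == "polygon") {
    v <- roi$vertices
    n <- nrow(v)
    ends <- if (roi$closed) c(2:n, 1) else 2:n
    starts <- if (roi$closed) 1:n else 1:(n - 1)
    dmin <- rep(Inf, length(px))
    for (k in seq_along(starts)) {
      dmin <- pmin(dmin, point_segment_distance(
        px, py, v[starts[k], 1], v[starts[k], 2],
        v[ends[k], 1], v[ends[k], 2]))
    }
    dmin
  } else {
    nn <- FNN::get.knnx(roi$boundary_coords, cbind(px, py), k = 1)
    as.numeric(nn$nn.dist)
  }
}

#' Distance of every spot to the ROI boundary
#'
#' Appends an unsigned Euclidean distance-to-boundary column
#' (`roi_distance`) to the spot table. ROI and coordinates must share the
#' calibrated frame.
#'
#' @param ds A 2-D `track_dataset`.
#' @param roi A [roi_polygon()] or [roi_mask()].
#' @return The dataset with a `roi_distance` spot column.
#' @export
distance_to_roi <- function(ds, roi) {
  assert_dataset(ds)
  if (ds$dimensionality != 2L) {
    stop("spatial analysis supports 2-D + time datasets only", call. = FALSE)
  }
  if (!inherits(roi, "roi_geometry")) {
    stop("roi must be a roi_geometry", call. = FALSE)
  }
  sp <- ds$spots
  sp$roi_distance <- roi_boundary_distance(roi, sp$x, sp$y)
  track_dataset(sp, ds$tracks, frame_interval = ds$frame_interval,
                space_unit = ds$space_unit, time_unit = ds$time_unit,
                dimensionality = ds$dimensionality)
}

#' Track-level ROI proximity metrics
#'
#' Summarises each track's distance-to-edge series `d(t)`:
#' `StartDistance_edge`/`EndDistance_edge` (first/last frame),
#' `Max/Min/MedianDistance_edge`, `StdDevDistance_edge` (sample SD),
#' `DirectionMovement_edge = End - Start` (positive = moving away from the
#' edge over time), `AvgRateChange_edge = (End - Start) / Duration`,
#' `PercentageChange_edge = 100 (End - Start) / Start` (`NaN` when
#' `Start = 0`), and `TrendSlope_edge`, the least-squares slope of `d`
#' against `t`. Single-spot tracks get `NaN` rates/slopes.
#'
#' @param ds A `track_dataset` after [distance_to_roi()].
#' @return The dataset with `*_edge` columns appended to `$tracks`.
#' @export
roi_track_metrics <- function(ds) {
  assert_dataset(ds)
  if (!"roi_distance" %in% names(ds$spots)) {
    stop("run distance_to_roi() first (no roi_distance spot column)",
         call. = FALSE)
  }
  ls_slope <- function(d, t) {
    if (length(d) < 2 || stats::var(t) == 0) return(NaN)
    stats::cov(t, d) / stats::var(t)
  }
  mt <- ds$spots |>
    dplyr::group_by(.data$unique_track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      StartDistance_edge = dplyr::first(.data$roi_distance),
      EndDistance_edge = dplyr::last(.data$roi_distance),
      MaxDistance_edge = max(.data$roi_distance),
      MinDistance_edge = min(.data$roi_distance),
      MedianDistance_edge = stats::median(.data$roi_distance),
      StdDevDistance_edge = ifelse(dplyr::n() > 1,
                                   stats::sd(.data$roi_distance), NaN),
      DirectionMovement_edge = dplyr::last(.data$roi_distance) -
        dplyr::first(.data$roi_distance),
      AvgRateChange_edge = ifelse(
        max(.data$t) > min(.data$t),
        (dplyr::last(.data$roi_distance) - dplyr::first(.data$roi_distance)) /
          (max(.data$t) - min(.data$t)), NaN),
      PercentageChange_edge = ifelse(
        dplyr::first(.data$roi_distance) == 0, NaN,
        100 * (dplyr::last(.data$roi_distance) -
                 dplyr::first(.data$roi_distance)) /
          dplyr::first(.data$roi_distance)),
      TrendSlope_edge = ls_slope(.data$roi_distance, .data$t),
      .groups = "drop"
    )
  tracks <- ds$tracks[, !names(ds$tracks) %in% setdiff(names(mt),
                                                       "unique_track_id")]
  tracks <- dplyr::left_join(tracks, mt, by = "unique_track_id")
  track_dataset(ds$spots, tracks, frame_interval = ds$frame_interval,
                space_unit = ds$space_unit, time_unit = ds$time_unit,
                dimensionality = ds$dimensionality)
}

#' Label tracks close/far from the edge by maximal distance
#'
#' `close` when `MaxDistance_edge < threshold`, `far` when `> threshold`;
#' a value exactly at the threshold is labelled `close` (documented
#' boundary rule).
#'
#' @param ds A `track_dataset` after [roi_track_metrics()].
#' @param threshold Distance cutoff (default 75, in the dataset's space
#'   unit).
#' @return The dataset with a `distance_stratum` track column.
#' @export
stratify_by_distance <- function(ds, threshold = 75) {
  assert_dataset(ds)
  if (!"MaxDistance_edge" %in% names(ds$tracks)) {
    stop("run roi_track_metrics() first (no MaxDistance_edge column)",
         call. = FALSE)
  }
  tracks <- dplyr::mutate(
    ds$tracks,
    distance_stratum = ifelse(.data$MaxDistance_edge <= threshold,
                              "close", "far"))
  track_dataset(ds$spots, tracks, frame_interval = ds$frame_interval,
                space_unit = ds$space_unit, time_unit = ds$time_unit,
                dimensionality = ds$dimensionality)
}
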