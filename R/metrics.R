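#' @keywords internal
#' Convex hull area by the shoelace formula (0 for < 3 distinct points).
hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# All motility metrics for one track; positions as n x d matrix sorted by
# frame. Returns a named list. Conventions:
#  - single-spot tracks: duration/distances 0, speed metrics NaN
#  - Directionality = 0 when total distance is 0; Tortuosity NaN when
#    displacement is 0
#  - turning angles unsigned in [0, pi]; pairs involving a zero-length step
#    are skipped (angle undefined)
track_metrics_one <- function(p, t, frame) {
  n <- nrow(p)
  dframe <- diff(frame)
  gaps <- sum(dframe > 1L)
  longest_gap <- if (gaps > 0) max(dframe) - 1L else 0L
  if (n == 1L) {
    return(list(
      NUMBER_SPOTS = 1, NUMBER_GAPS = 0, LONGEST_GAP = 0,
      `Track Duration` = 0, `Total Distance Traveled` = 0,
      TRACK_DISPLACEMENT = 0, Directionality = 0, CONFINEMENT_RATIO = 0,
      Tortuosity = NaN, `Mean Speed` = NaN, `Median Speed` = NaN,
      `Max Speed` = NaN, `Min Speed` = NaN,
      `Speed Standard Deviation` = NaN, MEAN_STRAIGHT_LINE_SPEED = NaN,
      LINEARITY_OF_FORWARD_PROGRESSION = NaN, MAX_DISTANCE_TRAVELED = 0,
      `Total Turning Angle` = 0, MEAN_DIRECTIONAL_CHANGE_RATE = NaN,
      `Spatial Coverage` = 0
    ))
  }
  steps <- diff(p)
  dt <- diff(t)
  len <- sqrt(rowSums(steps^2))
  total <- sum(len)
  disp <- sqrt(sum((p[n, ] - p[1, ])^2))
  duration <- t[n] - t[1]
  directionality <- if (total > 0) disp / total else 0
  tortuosity <- if (disp > 0) total / disp else NaN
  speeds <- len / dt
  mean_speed <- mean(speeds)
  msls <- if (duration > 0) disp / duration else NaN
  from_start <- sqrt(rowSums(sweep(p, 2, p[1, ])^2))
  # turning angles between successive steps
  tta <- 0
  mdcr <- NaN
  if (n >= 3) {
    v1 <- steps[-nrow(steps), , drop = FALSE]
    v2 <- steps[-1, , drop = FALSE]
    l1 <- len[-length(len)]; l2 <- len[-1]
    ok <- l1 > 0 & l2 > 0
    if (any(ok)) {
      cosang <- rowSums(v1[ok, , drop = FALSE] * v2[ok, , drop = FALSE]) /
        (l1[ok] * l2[ok])
      ang <- acos(pmin(1, pmax(-1, cosang)))
      tta <- sum(ang)
      # each angle divided by its leading step's duration
      mdcr <- mean(ang / dt[-length(dt)][ok])
    } else {
      tta <- 0
      mdcr <- NaN
    }
  }
  list(
    NUMBER_SPOTS = n, NUMBER_GAPS = gaps, LONGEST_GAP = longest_gap,
    `Track Duration` = duration, `Total Distance Traveled` = total,
    TRACK_DISPLACEMENT = disp, Directionality = directionality,
    CONFINEMENT_RATIO = directionality, Tortuosity = tortuosity,
    `Mean Speed` = mean_speed, `Median Speed` = stats::median(speeds),
    `Max Speed` = max(speeds), `Min Speed` = min(speeds),
    `Speed Standard Deviation` = if (length(speeds) > 1)
      stats::sd(speeds) else NaN,
    MEAN_STRAIGHT_LINE_SPEED = msls,
    LINEARITY_OF_FORWARD_PROGRESSION = if (is.finite(msls) && mean_speed > 0)
      msls / mean_speed else NaN,
    MAX_DISTANCE_TRAVELED = max(from_start),
    `Total Turning Angle` = tta,
    MEAN_DIRECTIONAL_CHANGE_RATE = mdcr,
    `Spatial Coverage` = hull_area(p[, 1], p[, 2])
  )
}

#' Compute track-level motility metrics
#'
#' Appends the standard motility metrics to the track table, computed from
#' the (possibly smoothed) spot coordinates: spot/gap counts, duration,
#' total distance travelled, net displacement, directionality (net
#' displacement over path length; also exported as `CONFINEMENT_RATIO`),
#' tortuosity (its reciprocal), per-step speed summaries, mean straight-line
#' speed and linearity of forward progression, maximal distance from the
#' start point, total turning angle and mean directional change rate
#' (radians per unit time), and spatial coverage (convex-hull area).
#'
#' Degenerate tracks yield defined sentinels: single-spot tracks have zero
#' duration/distances and `NaN` speeds; zero-displacement loops have
#' directionality 0 and tortuosity `NaN`.
#'
#' @param ds A `track_dataset`.
#' @return The dataset with metric columns appended to `$tracks`.
#' @export
compute_track_metrics <- function(ds) {
  assert_dataset(ds)
  cc <- coord_cols(ds)
  sp <- dplyr::arrange(ds$spots, .data$unique_track_id, .data$frame)
  idx <- split(seq_len(nrow(sp)), sp$unique_track_id)
  pm <- as.matrix(sp[, cc])
  res <- lapply(idx, function(i) {
    track_metrics_one(pm[i, , drop = FALSE], sp$t[i], sp$frame[i])
  })
  mt <- tibble::as_tibble(do.call(rbind, lapply(res, function(r)
    unlist(r, use.names = TRUE))))
  names(mt) <- names(res[[1]])
  mt$unique_track_id <- names(idx)
  tracks <- ds$tracks[, !names(ds$tracks) %in% setdiff(names(mt),
                                                       "unique_track_id")]
  tracks <- dplyr::left_join(tracks, mt, by = "unique_track_id")
  track_dataset(ds$spots, tracks, frame_interval = ds$frame_interval,
                space_unit = ds$space_unit, time_unit = ds$time_unit,
                dimensionality = ds$dimensionality)
}

#' Aggregate numeric spot features to track level
#'
#' For each numeric spot feature `F` (any numeric spot column that is not a
#' position/time/bookkeeping column) and each requested statistic `S`,
#' appends a track column `S_F` (e.g. `MEAN_CIRCULARITY`). `NA` spot values
#' are ignored; `STD` is the sample standard deviation and is `NA` for a
#' single observation.
#'
#' @param ds A `track_dataset`.
#' @param stats Subset of `c("MEAN", "MEDIAN", "STD", "MIN", "MAX")`.
#' @param features Optional character vector restricting which spot columns
#'   to aggregate; default: all numeric feature columns.
#' @return The dataset with aggregated columns appended to `$tracks`.
#' @export
aggregate_spot_features <- function(ds,
                                    stats = c("MEAN", "MEDIAN", "STD",
                                              "MIN", "MAX"),
                                    features = NULL) {
  assert_dataset(ds)
  stats <- match.arg(stats, several.ok = TRUE)
  reserved <- c("unique_track_id", "file_name", "condition", "replicate",
                "frame", "t", "x", "y", "z", "x_raw", "y_raw", "z_raw")
  num_cols <- names(ds$spots)[vapply(ds$spots, is.numeric, logical(1))]
  feats <- setdiff(num_cols, reserved)
  if (!is.null(features)) feats <- intersect(feats, features)
  if (length(feats) == 0) {
    warning("no numeric spot feature columns to aggregate; dataset unchanged")
    return(ds)
  }
  fns <- list(
    MEAN = function(v) mean(v, na.rm = TRUE),
    MEDIAN = function(v) stats::median(v, na.rm = TRUE),
    STD = function(v) stats::sd(v, na.rm = TRUE),
    MIN = function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE),
    MAX = function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  )
  agg <- ds$spots |>
    dplyr::group_by(.data$unique_track_id) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(feats),
      stats::setNames(fns[stats], stats),
      .names = "{.fn}_{.col}"
    ), .groups = "drop")
  tracks <- ds$tracks[, !names(ds$tracks) %in% setdiff(names(agg),
                                                       "unique_track_id")]
  tracks <- dplyr::left_join(tracks, agg, by = "unique_track_id")
  track_dataset(ds$spots, tracks, frame_interval = ds$frame_interval,
                space_unit = ds$space_unit, time_unit = ds$time_unit,
                dimensionality = ds$dimensionality)
}

#' Names of the computed motility metric columns
#' @return Character vector of metric column names added by
#'   [compute_track_metrics()].
#' @export
track_metric_names <- function() {
  c("NUMBER_SPOTS", "NUMBER_GAPS", "LONGEST_GAP", "Track Duration",
    "Total Distance Traveled", "TRACK_DISPLACEMENT", "Directionality",
    "CONFINEMENT_RATIO", "Tortuosity", "Mean Speed", "Median Speed",
    "Max Speed", "Min Speed", "Speed Standard Deviation",
    "MEAN_STRAIGHT_LINE_SPEED", "LINEARITY_OF_FORWARD_PROGRESSION",
    "MAX_DISTANCE_TRAVELED", "Total Turning Angle",
    "MEAN_DIRECTIONAL_CHANGE_RATE", "Spatial Coverage")
}
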