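#' Track filtering thresholds
#'
#' Thresholds follow the usual post-tracking phrasing: tracks are kept when
#' duration >= `min_duration` (a track "lasting for less than" the cutoff is
#' removed), spot count is strictly greater than `min_spots` ("more than 6
#' spots"), and total distance travelled is strictly greater than
#' `min_total_distance` ("greater than 89 um").
#'
#' @param min_duration Minimum track duration (inclusive), >= 0.
#' @param min_spots Spot-count threshold (strict >), >= 1.
#' @param min_total_distance Total-distance threshold (strict >), >= 0.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(min_duration = 0, min_spots = 1,
                        min_total_distance = 0) {
  vals <- c(min_duration, min_spots, min_total_distance)
  if (any(!is.finite(vals)) || any(vals < 0) || min_spots < 1) {
    stop("filter_spec thresholds must be finite, non-negative, min_spots >= 1",
         call. = FALSE)
  }
  structure(list(min_duration = min_duration, min_spots = as.integer(min_spots),
                 min_total_distance = min_total_distance),
            class = "filter_spec")
}

moving_average <- function(v, window) {
  n <- length(v)
  if (window == 1L || n == 1L) return(v)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth track coordinates with a centred moving average
#'
#' Each coordinate is replaced by the mean over a centred window of up to
#' `window` spots; windows are truncated (not padded) at the track ends.
#' Frame and time are unchanged. The original coordinates are preserved in
#' companion `x_raw`/`y_raw` (/`z_raw`) columns; repeated smoothing always
#' starts from the raw coordinates already stored.
#'
#' @param ds A `track_dataset`.
#' @param window Odd integer window size (1 = identity).
#' @return A `track_dataset` with smoothed coordinates.
#' @export
smooth_tracks <- function(ds, window = 3L) {
  assert_dataset(ds)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 1", call. = FALSE)
  }
  sp <- ds$spots
  cols <- intersect(c("x", "y", "z"), names(sp))
  for (cc in cols) {
    raw <- paste0(cc, "_raw")
    if (!raw %in% names(sp)) sp[[raw]] <- sp[[cc]]
  }
  sp <- sp |>
    dplyr::group_by(.data$unique_track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE)
  for (cc in cols) {
    src <- paste0(cc, "_raw")
    sp <- dplyr::mutate(sp, !!cc := moving_average(.data[[src]], window))
  }
  sp <- dplyr::ungroup(sp)
  track_dataset(sp, ds$tracks, frame_interval = ds$frame_interval,
                space_unit = ds$space_unit, time_unit = ds$time_unit,
                dimensionality = ds$dimensionality)
}

track_filter_stats <- function(ds) {
  cc <- coord_cols(ds)
  ds$spots |>
    dplyr::group_by(.data$unique_track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      n_spots = dplyr::n(),
      duration = max(.data$t) - min(.data$t),
      total_distance = {
        pm <- as.matrix(dplyr::pick(dplyr::all_of(cc)))
        if (nrow(pm) < 2) 0 else sum(sqrt(rowSums(diff(pm)^2)))
      },
      .groups = "drop"
    )
}

#' Remove tracks failing the filter thresholds
#'
#' Tracks failing any criterion of the [filter_spec()] are removed from
#' both tables. The removed-count report is attached as the
#' `"filter_report"` attribute.
#'
#' @param ds A `track_dataset`.
#' @param spec A [filter_spec()].
#' @return Filtered `track_dataset` (attribute `filter_report` holds a
#'   one-row tibble of kept/removed counts).
#' @export
filter_tracks <- function(ds, spec = filter_spec()) {
  assert_dataset(ds)
  if (!inherits(spec, "filter_spec")) {
    stop("spec must be a filter_spec object", call. = FALSE)
  }
  st <- track_filter_stats(ds)
  keep <- st$duration >= spec$min_duration &
    st$n_spots > spec$min_spots &
    st$total_distance > spec$min_total_distance
  if (!any(keep)) stop("all tracks removed by the filter", call. = FALSE)
  out <- subset_tracks(ds, st$unique_track_id[keep])
  attr(out, "filter_report") <- tibble::tibble(
    n_input = nrow(st), n_kept = sum(keep), n_removed = sum(!keep),
    min_duration = spec$min_duration, min_spots = spec$min_spots,
    min_total_distance = spec$min_total_distance
  )
  out
}
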