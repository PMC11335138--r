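#' Unified tracking dataset
#'
#' A `track_dataset` pairs a spot-level table (one row per detected object
#' per frame) with a track-level table (one row per track) under a shared
#' `unique_track_id` key, plus calibration metadata. All positions are in
#' calibrated units (typically micrometres) as exported by the tracking
#' software; time is `frame * frame_interval` unless an explicit time column
#' was supplied.
#'
#' Canonical spot columns: `unique_track_id`, `file_name`, `condition`,
#' `replicate`, `frame` (0-based integer), `t`, `x`, `y`, optional `z`, plus
#' any numeric spot features (e.g. `AREA`, `CIRCULARITY`). Canonical track
#' columns: `unique_track_id`, `file_name`, `condition`, `replicate`, plus
#' imported or computed track metrics.
#'
#' @param spots Tibble of spot rows with the canonical columns above.
#' @param tracks Optional tibble of track rows; derived from `spots` when
#'   `NULL`.
#' @param frame_interval Time between consecutive frames (> 0), in
#'   `time_unit`.
#' @param space_unit,time_unit Unit labels carried as metadata.
#' @param dimensionality 2 or 3. Defaults to 3 when a `z` column with any
#'   non-zero value is present.
#'
#' @return An object of class `track_dataset`.
#' @export
track_dataset <- function(spots, tracks = NULL, frame_interval = 1,
                          space_unit = "micron", time_unit = "s",
                          dimensionality = NULL) {
  spots <- tibble::as_tibble(spots)
  required <- c("unique_track_id", "file_name", "condition", "replicate",
                "frame", "t", "x", "y")
  missing <- setdiff(required, names(spots))
  if (length(missing) > 0) {
    stop("spots table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be a single positive number", call. = FALSE)
  }
  spots$frame <- as.integer(spots$frame)
  if (any(spots$frame < 0)) stop("frames must be >= 0", call. = FALSE)
  if (any(!nzchar(spots$condition)) || any(!nzchar(spots$replicate))) {
    stop("condition and replicate must be non-empty for every spot",
         call. = FALSE)
  }
  spots <- dplyr::arrange(spots, .data$unique_track_id, .data$frame)
  if (anyDuplicated(spots[, c("unique_track_id", "frame")]) > 0) {
    stop("duplicate (unique_track_id, frame) pairs in spots table",
         call. = FALSE)
  }
  if (is.null(dimensionality)) {
    dimensionality <- if ("z" %in% names(spots) &&
                          any(is.finite(spots$z) & spots$z != 0)) 3L else 2L
  }
  dimensionality <- as.integer(dimensionality)
  if (!dimensionality %in% c(2L, 3L)) {
    stop("dimensionality must be 2 or 3", call. = FALSE)
  }
  if (is.null(tracks)) {
    tracks <- dplyr::distinct(
      spots, .data$unique_track_id, .data$file_name, .data$condition,
      .data$replicate
    )
  }
  tracks <- tibble::as_tibble(tracks)
  if (anyDuplicated(tracks$unique_track_id) > 0) {
    stop("duplicate unique_track_id in tracks table", call. = FALSE)
  }
  if (!setequal(tracks$unique_track_id, unique(spots$unique_track_id))) {
    stop("tracks table key set does not match spots table", call. = FALSE)
  }
  tracks <- dplyr::arrange(tracks, .data$unique_track_id)
  structure(
    list(
      spots = spots,
      tracks = tracks,
      frame_interval = as.numeric(frame_interval),
      space_unit = space_unit,
      time_unit = time_unit,
      dimensionality = dimensionality
    ),
    class = "track_dataset"
  )
}

#' @export
print.track_dataset <- function(x, ...) {
  cat("<track_dataset>\n")
  cat(sprintf("  %d tracks, %d spots (%dD + time)\n",
              nrow(x$tracks), nrow(x$spots), x$dimensionality))
  cat(sprintf("  conditions: %s\n",
              paste(sort(unique(x$tracks$condition)), collapse = ", ")))
  cat(sprintf("  frame interval: %g %s; space unit: %s\n",
              x$frame_interval, x$time_unit, x$space_unit))
  cat(sprintf("  track metric columns: %d\n",
              ncol(x$tracks) - 4L))
  invisible(x)
}

#' @export
dim.track_dataset <- function(x) c(nrow(x$tracks), nrow(x$spots))

is_track_dataset <- function(x) inherits(x, "track_dataset")

assert_dataset <- function(ds) {
  if (!is_track_dataset(ds)) {
    stop("expected a track_dataset object", call. = FALSE)
  }
  invisible(ds)
}

coord_cols <- function(ds) {
  if (ds$dimensionality == 3L && "z" %in% names(ds$spots)) c("x", "y", "z")
  else c("x", "y")
}

#' Subset a dataset to a set of tracks
#'
#' Keeps the given tracks in both tables (spots of removed tracks are
#' removed too).
#'
#' @param ds A `track_dataset`.
#' @param track_ids Character vector of `unique_track_id` values to keep.
#' @return A `track_dataset`.
#' @export
subset_tracks <- function(ds, track_ids) {
  assert_dataset(ds)
  keep <- intersect(ds$tracks$unique_track_id, track_ids)
  if (length(keep) == 0) stop("no tracks left after subsetting", call. = FALSE)
  track_dataset(
    spots = dplyr::filter(ds$spots, .data$unique_track_id %in% keep),
    tracks = dplyr::filter(ds$tracks, .data$unique_track_id %in% keep),
    frame_interval = ds$frame_interval,
    space_unit = ds$space_unit,
    time_unit = ds$time_unit,
    dimensionality = ds$dimensionality
  )
}
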