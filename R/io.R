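#' Declare how a generic CSV maps onto the canonical spot columns
#'
#' Minimal requirements for a tracking export are a track id, a frame (or
#' time) column and x/y positions. When `t` is not mapped, time is computed
#' as `frame * frame_interval`. When `pixel_size` is given, x/y (/z) are
#' declared to be in pixels and are multiplied by `pixel_size` on load;
#' otherwise coordinates are taken as already calibrated.
#'
#' @param track_id,frame,x,y Source column names (required).
#' @param t,z,condition,replicate Optional source column names.
#' @param dialect `"plain"` for an ordinary CSV; `"trackmate"` for the
#'   TrackMate CSV export, which carries three extra descriptive sub-header
#'   rows that are skipped on load.
#' @param pixel_size Optional pixel size (length per pixel) used to convert
#'   pixel coordinates to calibrated units.
#' @return A `column_map` object.
#' @export
column_map <- function(track_id = "TRACK_ID", frame = "FRAME",
                       x = "POSITION_X", y = "POSITION_Y",
                       t = NULL, z = NULL,
                       condition = NULL, replicate = NULL,
                       dialect = c("plain", "trackmate"),
                       pixel_size = NULL) {
  dialect <- match.arg(dialect)
  required <- list(track_id = track_id, frame = frame, x = x, y = y)
  bad <- names(required)[!vapply(required, function(v)
    is.character(v) && length(v) == 1 && nzchar(v), logical(1))]
  if (length(bad) > 0) {
    stop("column_map: required mapping(s) missing or empty: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(track_id = track_id, frame = frame, x = x, y = y, t = t, z = z,
         condition = condition, replicate = replicate,
         dialect = dialect, pixel_size = pixel_size),
    class = "column_map"
  )
}

#' Built-in column map for TrackMate spot CSV exports
#' @return A `column_map` with the TrackMate dialect preset.
#' @export
trackmate_column_map <- function() {
  column_map(track_id = "TRACK_ID", frame = "FRAME",
             x = "POSITION_X", y = "POSITION_Y", t = "POSITION_T",
             dialect = "trackmate")
}

num_attr <- function(nodes, attr) suppressWarnings(as.numeric(xml2::xml_attr(nodes, attr)))

#' Load a TrackMate model XML file (one field of view)
#'
#' Reads the `AllSpots` and `AllTracks` sections of a TrackMate XML export.
#' Spots are assigned to tracks through the track edges; spots that belong
#' to no track are dropped (their count is reported in a message). Numeric
#' track-level features exported by TrackMate (e.g. `NUMBER_SPLITS`) are
#' carried into the track table as imported columns. Positions are kept in
#' the file's calibrated units.
#'
#' @param path Path to a TrackMate XML file.
#' @param frame_interval Time between frames; used for `t` when the file
#'   carries no `POSITION_T`.
#' @return A single-FOV `track_dataset` fragment; `condition`/`replicate`
#'   are set to `"?"` and are overwritten by [compile_dataset()].
#' @export
load_trackmate_xml <- function(path, frame_interval = 1) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed TrackMate XML in ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  model <- xml2::xml_find_first(doc, ".//Model")
  if (inherits(model, "xml_missing")) {
    stop("malformed TrackMate XML: no <Model> element in ", path,
         call. = FALSE)
  }
  spot_nodes <- xml2::xml_find_all(doc, ".//AllSpots//Spot")
  if (length(spot_nodes) == 0) {
    stop("malformed TrackMate XML: no <Spot> elements under <AllSpots> in ",
         path, call. = FALSE)
  }
  spot_id <- xml2::xml_attr(spot_nodes, "ID")
  spots <- tibble::tibble(
    spot_id = spot_id,
    frame = as.integer(num_attr(spot_nodes, "FRAME")),
    x = num_attr(spot_nodes, "POSITION_X"),
    y = num_attr(spot_nodes, "POSITION_Y")
  )
  zvals <- num_attr(spot_nodes, "POSITION_Z")
  if (any(is.finite(zvals) & zvals != 0)) spots$z <- zvals
  tvals <- num_attr(spot_nodes, "POSITION_T")
  spots$t <- if (all(is.finite(tvals))) tvals else spots$frame * frame_interval

  # optional per-spot features (shape/intensity), any numeric extra attrs
  known <- c("ID", "name", "FRAME", "POSITION_X", "POSITION_Y", "POSITION_Z",
             "POSITION_T", "QUALITY", "RADIUS", "VISIBILITY")
  extra <- setdiff(unique(unlist(lapply(spot_nodes[1], function(n)
    names(xml2::xml_attrs(n))))), known)
  for (a in extra) {
    v <- num_attr(spot_nodes, a)
    if (any(is.finite(v))) spots[[a]] <- v
  }

  track_nodes <- xml2::xml_find_all(doc, ".//AllTracks/Track")
  if (length(track_nodes) == 0) {
    stop("malformed TrackMate XML: no <Track> elements under <AllTracks> in ",
         path, call. = FALSE)
  }
  track_rows <- lapply(track_nodes, function(tn) {
    attrs <- xml2::xml_attrs(tn)
    edges <- xml2::xml_find_all(tn, "./Edge")
    members <- unique(c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                        xml2::xml_attr(edges, "SPOT_TARGET_ID")))
    list(track_id = attrs[["TRACK_ID"]], attrs = attrs, members = members)
  })
  spot_to_track <- stats::setNames(
    rep(vapply(track_rows, `[[`, character(1), "track_id"),
        vapply(track_rows, function(r) length(r$members), integer(1))),
    unlist(lapply(track_rows, `[[`, "members"))
  )
  missing_spots <- setdiff(names(spot_to_track), spots$spot_id)
  if (length(missing_spots) > 0) {
    stop("TrackMate XML integrity error: edge references spot id(s) absent ",
         "from AllSpots: ", paste(utils::head(missing_spots, 5),
                                  collapse = ", "), call. = FALSE)
  }
  n_untracked <- sum(!spots$spot_id %in% names(spot_to_track))
  if (n_untracked > 0) {
    message("load_trackmate_xml: dropped ", n_untracked,
            " spot(s) not assigned to any track")
  }
  spots <- spots[spots$spot_id %in% names(spot_to_track), , drop = FALSE]
  spots$source_track_id <- unname(spot_to_track[spots$spot_id])
  spots$spot_id <- NULL

  stem <- tools::file_path_sans_ext(basename(path))
  spots$unique_track_id <- paste0(stem, "::", spots$source_track_id)
  spots$file_name <- stem
  spots$condition <- "?"
  spots$replicate <- "?"
  spots$source_track_id <- NULL

  # imported numeric track features
  tr_tab <- dplyr::distinct(spots, .data$unique_track_id, .data$file_name,
                            .data$condition, .data$replicate)
  feat_names <- setdiff(
    unique(unlist(lapply(track_rows, function(r) names(r$attrs)))),
    c("name", "TRACK_ID")
  )
  if (length(feat_names) > 0) {
    feats <- lapply(track_rows, function(r) {
      v <- suppressWarnings(as.numeric(r$attrs[feat_names]))
      stats::setNames(v, feat_names)
    })
    fm <- do.call(rbind, feats)
    fm <- fm[, colSums(is.finite(fm)) > 0, drop = FALSE]
    if (ncol(fm) > 0) {
      fm_tb <- tibble::as_tibble(fm)
      fm_tb$unique_track_id <- paste0(
        stem, "::", vapply(track_rows, `[[`, character(1), "track_id"))
      tr_tab <- dplyr::left_join(tr_tab, fm_tb, by = "unique_track_id")
    }
  }

  units <- xml2::xml_attrs(model)
  track_dataset(
    spots = spots, tracks = tr_tab, frame_interval = frame_interval,
    space_unit = if ("spatialunits" %in% names(units))
      units[["spatialunits"]] else "micron",
    time_unit = if ("timeunits" %in% names(units))
      units[["timeunits"]] else "s"
  )
}

#' Load a tracking CSV (one field of view) through a column map
#'
#' @param spots_path Path to the spot-level CSV.
#' @param map A [column_map()]. The TrackMate dialect skips the three
#'   descriptive sub-header rows below the column names.
#' @param frame_interval Time between frames; `t = frame * frame_interval`
#'   when no time column is mapped.
#' @return A single-FOV `track_dataset` fragment.
#' @export
load_tracking_csv <- function(spots_path, map = column_map(),
                              frame_interval = 1) {
  if (!inherits(map, "column_map")) {
    stop("map must be a column_map object", call. = FALSE)
  }
  raw <- readr::read_csv(spots_path, show_col_types = FALSE,
                         progress = FALSE, name_repair = "minimal")
  if (map$dialect == "trackmate" && nrow(raw) >= 3) {
    # TrackMate exports carry 3 descriptive rows (full name, short name,
    # unit) below the header; they are non-numeric in the FRAME column.
    raw <- raw[-seq_len(3), , drop = FALSE]
  }
  needed <- c(track_id = map$track_id, frame = map$frame, x = map$x, y = map$y)
  opt <- c(t = map$t, z = map$z, condition = map$condition,
           replicate = map$replicate)
  missing <- needed[!needed %in% names(raw)]
  if (length(missing) > 0) {
    stop("load_tracking_csv: mapped column(s) not found in ", spots_path,
         ": ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    source_track_id = as.character(raw[[map$track_id]]),
    frame = suppressWarnings(as.integer(as.numeric(raw[[map$frame]]))),
    x = suppressWarnings(as.numeric(raw[[map$x]])),
    y = suppressWarnings(as.numeric(raw[[map$y]]))
  )
  if (!is.null(map$z) && map$z %in% names(raw)) {
    out$z <- suppressWarnings(as.numeric(raw[[map$z]]))
  }
  if (!is.null(map$t) && map$t %in% names(raw)) {
    out$t <- suppressWarnings(as.numeric(raw[[map$t]]))
  } else {
    out$t <- out$frame * frame_interval
  }
  # untracked spots (empty/NA track id) are dropped
  untracked <- is.na(out$source_track_id) | !nzchar(out$source_track_id) |
    out$source_track_id %in% c("NA", "None", "-1")
  if (any(untracked)) {
    message("load_tracking_csv: dropped ", sum(untracked),
            " untracked spot(s)")
    out <- out[!untracked, , drop = FALSE]
  }
  bad <- !is.finite(out$x) | !is.finite(out$y) | is.na(out$frame)
  if (any(bad)) {
    message("load_tracking_csv: rejected ", sum(bad),
            " row(s) with non-finite position or frame")
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0) stop("no valid spot rows in ", spots_path, call. = FALSE)
  if (!is.null(map$pixel_size)) {
    for (cc in intersect(c("x", "y", "z"), names(out))) {
      out[[cc]] <- out[[cc]] * map$pixel_size
    }
  }
  # carry extra numeric feature columns
  mapped <- unname(c(needed, opt))
  for (cn in setdiff(names(raw), mapped)) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    if (any(is.finite(v)) && !cn %in% names(out)) out[[cn]] <- v[!untracked][!bad]
  }
  stem <- tools::file_path_sans_ext(basename(spots_path))
  out$unique_track_id <- paste0(stem, "::", out$source_track_id)
  out$file_name <- stem
  out$condition <- if (!is.null(map$condition) && map$condition %in% names(raw))
    as.character(raw[[map$condition]])[!untracked][!bad] else "?"
  out$replicate <- if (!is.null(map$replicate) && map$replicate %in% names(raw))
    as.character(raw[[map$replicate]])[!untracked][!bad] else "?"
  out$source_track_id <- NULL
  track_dataset(out, frame_interval = frame_interval)
}

#' Compile a Condition/Repeat directory tree into one dataset
#'
#' Walks `root_dir/<condition>/<replicate>/<file>` and concatenates the
#' per-file fragments. The first-level folder name becomes `condition`, the
#' second-level folder name `replicate`, and the file stem `file_name`;
#' `unique_track_id` is `"<file stem>::<source track id>"`, which is
#' globally unique as long as file stems are unique across the tree.
#'
#' @param root_dir Root of the directory tree.
#' @param format `"trackmate_xml"` or `"csv"`.
#' @param map A [column_map()] (CSV format only).
#' @param frame_interval Time between frames.
#' @return A compiled `track_dataset`.
#' @export
compile_dataset <- function(root_dir, format = c("trackmate_xml", "csv"),
                            map = trackmate_column_map(), frame_interval = 1) {
  format <- match.arg(format)
  ext <- if (format == "trackmate_xml") "\\.xml$" else "\\.csv$"
  files <- sort(list.files(root_dir, pattern = ext, recursive = TRUE,
                           full.names = TRUE))
  rel <- strsplit(substring(files, nchar(root_dir) + 2L), "/")
  keep <- vapply(rel, length, integer(1)) == 3L
  files <- files[keep]; rel <- rel[keep]
  if (length(files) == 0) {
    stop("no ", format, " files found under the Condition/Repeat tree at ",
         root_dir, call. = FALSE)
  }
  frags <- vector("list", length(files))
  for (i in seq_along(files)) {
    frag <- if (format == "trackmate_xml") {
      load_trackmate_xml(files[i], frame_interval = frame_interval)
    } else {
      load_tracking_csv(files[i], map = map, frame_interval = frame_interval)
    }
    frag$spots$condition <- rel[[i]][1]
    frag$spots$replicate <- rel[[i]][2]
    frag$tracks$condition <- rel[[i]][1]
    frag$tracks$replicate <- rel[[i]][2]
    frags[[i]] <- frag
  }
  spots <- dplyr::bind_rows(lapply(frags, `[[`, "spots"))
  tracks <- dplyr::bind_rows(lapply(frags, `[[`, "tracks"))
  if (anyDuplicated(tracks$unique_track_id) > 0) {
    stop("integrity error: duplicate unique_track_id after prefixing; ",
         "file stems must be unique across the tree", call. = FALSE)
  }
  f1 <- frags[[1]]
  track_dataset(spots, tracks, frame_interval = frame_interval,
                space_unit = f1$space_unit, time_unit = f1$time_unit)
}

#' Save / reload a dataset in the unified on-disk format
#'
#' Writes `spots.csv`, `tracks.csv` and a `dataset.json` metadata sidecar.
#' Numbers are written at full precision so that
#' `load_saved_dataset(save_dataset(ds))` is an exact round trip.
#'
#' @param ds A `track_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
save_dataset <- function(ds, out_dir) {
  assert_dataset(ds)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    stop("cannot write to ", out_dir, call. = FALSE)
  }
  readr::write_csv(ds$spots, file.path(out_dir, "spots.csv"), progress = FALSE)
  readr::write_csv(ds$tracks, file.path(out_dir, "tracks.csv"),
                   progress = FALSE)
  meta <- list(frame_interval = ds$frame_interval, space_unit = ds$space_unit,
               time_unit = ds$time_unit, dimensionality = ds$dimensionality)
  jsonlite::write_json(meta, file.path(out_dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @rdname save_dataset
#' @param dir Directory previously written by [save_dataset()].
#' @export
load_saved_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  spots <- readr::read_csv(file.path(dir, "spots.csv"),
                           show_col_types = FALSE, progress = FALSE)
  tracks <- readr::read_csv(file.path(dir, "tracks.csv"),
                            show_col_types = FALSE, progress = FALSE)
  for (cn in c("unique_track_id", "file_name", "condition", "replicate")) {
    spots[[cn]] <- as.character(spots[[cn]])
    tracks[[cn]] <- as.character(tracks[[cn]])
  }
  track_dataset(spots, tracks, frame_interval = meta$frame_interval,
                space_unit = meta$space_unit, time_unit = meta$time_unit,
                dimensionality = meta$dimensionality)
}
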