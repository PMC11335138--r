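#' Persistent-random-walk motion model
#'
#' Parameters of the per-track motion simulation: step lengths are drawn
#' from a normal truncated at zero with mean `speed_mean * frame_interval`
#' and SD `speed_sd * frame_interval`; step direction is the normalized
#' persistence-weighted mix of the previous direction and a fresh random
#' unit vector (`persistence = 1` gives straight tracks, `0` an
#' uncorrelated walk); `bias_vector` adds a constant drift velocity;
#' frames after the first are dropped i.i.d. with `frame_drop_prob`,
#' creating gaps.
#'
#' @param speed_mean,speed_sd Step speed mean/SD (length per time).
#' @param persistence Direction correlation in `[0, 1]`.
#' @param bias_vector Length-2 drift velocity.
#' @param frame_drop_prob Per-frame drop probability in `[0, 1)`.
#' @param n_frames Frames per track (>= 2).
#' @param frame_interval Time between frames.
#' @return A `motion_model` object.
#' @export
motion_model <- function(speed_mean = 1, speed_sd = 0.25, persistence = 0.5,
                         bias_vector = c(0, 0), frame_drop_prob = 0,
                         n_frames = 30L, frame_interval = 1) {
  if (speed_mean < 0 || speed_sd < 0) {
    stop("speeds must be non-negative", call. = FALSE)
  }
  if (persistence < 0 || persistence > 1) {
    stop("persistence must lie in [0, 1]", call. = FALSE)
  }
  structure(list(speed_mean = speed_mean, speed_sd = speed_sd,
                 persistence = persistence, bias_vector = bias_vector,
                 frame_drop_prob = frame_drop_prob,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval),
            class = "motion_model")
}

#' Scene specification for the synthetic generator
#'
#' @param conditions Named list of [motion_model()]s, one per condition.
#' @param repeats Biological repeats per condition.
#' @param fovs_per_repeat Fields of view per repeat.
#' @param tracks_per_fov Tracks per field of view.
#' @param field Length-4 field rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param seed Integer seed.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(conditions, repeats = 2L, fovs_per_repeat = 1L,
                       tracks_per_fov = 10L, field = c(0, 500, 0, 500),
                       seed = 42L) {
  if (!is.list(conditions) || length(conditions) == 0 ||
      is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    stop("conditions must be a non-empty named list of motion models",
         call. = FALSE)
  }
  if (any(c(repeats, fovs_per_repeat, tracks_per_fov) < 1)) {
    stop("all counts must be >= 1", call. = FALSE)
  }
  structure(list(conditions = conditions, repeats = as.integer(repeats),
                 fovs_per_repeat = as.integer(fovs_per_repeat),
                 tracks_per_fov = as.integer(tracks_per_fov),
                 field = field, seed = as.integer(seed)),
            class = "scene_spec")
}

rtrunc_norm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- out < 0
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < 0
  }
  out
}

reflect_into <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  out <- ifelse(v > span, 2 * span - v, v)
  out + lo
}

simulate_track <- function(model, field) {
  n <- model$n_frames
  dt <- model$frame_interval
  pos <- matrix(NA_real_, n, 2)
  pos[1, ] <- c(stats::runif(1, field[1], field[2]),
                stats::runif(1, field[3], field[4]))
  theta0 <- stats::runif(1, 0, 2 * pi)
  dir <- c(cos(theta0), sin(theta0))
  lens <- rtrunc_norm_pos(n - 1, model$speed_mean * dt, model$speed_sd * dt)
  clipped <- FALSE
  for (i in 2:n) {
    theta <- stats::runif(1, 0, 2 * pi)
    rnd <- c(cos(theta), sin(theta))
    mix <- model$persistence * dir + (1 - model$persistence) * rnd
    nrm <- sqrt(sum(mix^2))
    if (nrm == 0) { mix <- rnd; nrm <- 1 }
    dir <- mix / nrm
    pos[i, ] <- pos[i - 1, ] + dir * lens[i - 1] + model$bias_vector * dt
    if (pos[i, 1] < field[1] || pos[i, 1] > field[2] ||
        pos[i, 2] < field[3] || pos[i, 2] > field[4]) {
      clipped <- TRUE
      pos[i, 1] <- reflect_into(pos[i, 1], field[1], field[2])
      pos[i, 2] <- reflect_into(pos[i, 2], field[3], field[4])
    }
  }
  frames <- 0:(n - 1)
  keep <- c(TRUE, stats::runif(n - 1) >= model$frame_drop_prob)
  if (sum(keep) < 2) keep[2] <- TRUE
  list(pos = pos[keep, , drop = FALSE], frames = frames[keep],
       clipped = clipped)
}

#' Generate a synthetic multi-condition tracking dataset
#'
#' Seeded persistent-biased random walks organized as
#' condition x repeat x field-of-view, with per-track ground truth (model
#' parameters, clipping flags) attached as the `"ground_truth"` attribute.
#'
#' @param spec A [scene_spec()].
#' @return A `track_dataset`; `attr(, "ground_truth")` is a tibble with one
#'   row per track.
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("spec must be a scene_spec",
                                          call. = FALSE)
  set.seed(spec$seed)
  rows <- list(); gt <- list()
  for (cond in names(spec$conditions)) {
    model <- spec$conditions[[cond]]
    for (r in seq_len(spec$repeats)) {
      rep_name <- paste0("R", r)
      for (f in seq_len(spec$fovs_per_repeat)) {
        fov_name <- sprintf("%s_%s_fov%02d", cond, rep_name, f)
        for (k in seq_len(spec$tracks_per_fov)) {
          tr <- simulate_track(model, spec$field)
          uid <- paste0(fov_name, "::", k)
          rows[[length(rows) + 1]] <- tibble::tibble(
            unique_track_id = uid, file_name = fov_name,
            condition = cond, replicate = rep_name,
            frame = tr$frames, t = tr$frames * model$frame_interval,
            x = tr$pos[, 1], y = tr$pos[, 2]
          )
          gt[[length(gt) + 1]] <- tibble::tibble(
            unique_track_id = uid, condition = cond, replicate = rep_name,
            file_name = fov_name, source_track_id = k,
            speed_mean = model$speed_mean, speed_sd = model$speed_sd,
            persistence = model$persistence,
            bias_x = model$bias_vector[1], bias_y = model$bias_vector[2],
            frame_drop_prob = model$frame_drop_prob,
            n_frames = model$n_frames, n_spots = length(tr$frames),
            clipped = tr$clipped
          )
        }
      }
    }
  }
  fi <- spec$conditions[[1]]$frame_interval
  ds <- track_dataset(dplyr::bind_rows(rows), frame_interval = fi)
  attr(ds, "ground_truth") <- dplyr::bind_rows(gt)
  ds
}

#' Generate a leading-edge ROI scene with known approach dynamics
#'
#' A vertical edge at `x = edge_x` spans the field; a stated fraction of
#' tracks drift straight towards the edge at `approach_speed` (noise-free,
#' so their distance series is exactly linear), the rest perform an
#' uncorrelated random walk. Tracks are placed so that approachers never
#' cross the edge, keeping the unsigned distance linear in time.
#'
#' @param spec A [scene_spec()] (the motion model of each condition drives
#'   the wandering tracks).
#' @param edge_x Edge position inside the field's x-range.
#' @param approach_speed Approach speed (length per time) of approachers.
#' @param fraction_approaching Fraction of tracks per FOV that approach.
#' @return List with `$dataset` (`track_dataset`, ground truth attached),
#'   `$roi` (open polyline [roi_polygon()]).
#' @export
generate_roi_scene <- function(spec, edge_x = 100, approach_speed = 2,
                               fraction_approaching = 0.5) {
  if (!inherits(spec, "scene_spec")) stop("spec must be a scene_spec",
                                          call. = FALSE)
  if (fraction_approaching < 0 || fraction_approaching > 1) {
    stop("fraction_approaching must lie in [0, 1]", call. = FALSE)
  }
  field <- spec$field
  if (edge_x <= field[1] || edge_x >= field[2]) {
    stop("edge_x must lie inside the field", call. = FALSE)
  }
  set.seed(spec$seed)
  rows <- list(); gt <- list()
  for (cond in names(spec$conditions)) {
    model <- spec$conditions[[cond]]
    n <- model$n_frames; dt <- model$frame_interval
    duration <- (n - 1) * dt
    for (r in seq_len(spec$repeats)) {
      rep_name <- paste0("R", r)
      for (f in seq_len(spec$fovs_per_repeat)) {
        fov_name <- sprintf("%s_%s_fov%02d", cond, rep_name, f)
        n_app <- round(spec$tracks_per_fov * fraction_approaching)
        for (k in seq_len(spec$tracks_per_fov)) {
          approaching <- k <= n_app
          uid <- paste0(fov_name, "::", k)
          if (approaching) {
            # start far enough that the track never reaches the edge
            margin <- approach_speed * duration
            x0 <- stats::runif(1, edge_x + margin + 1,
                               max(field[2], edge_x + margin + 2))
            y0 <- stats::runif(1, field[3], field[4])
            frames <- 0:(n - 1)
            xs <- x0 - approach_speed * frames * dt
            ys <- rep(y0, n)
            pos <- cbind(xs, ys)
          } else {
            tr <- simulate_track(model, field)
            pos <- tr$pos; frames <- tr$frames
          }
          rows[[length(rows) + 1]] <- tibble::tibble(
            unique_track_id = uid, file_name = fov_name,
            condition = cond, replicate = rep_name,
            frame = frames, t = frames * dt,
            x = pos[, 1], y = pos[, 2]
          )
          gt[[length(gt) + 1]] <- tibble::tibble(
            unique_track_id = uid, condition = cond, replicate = rep_name,
            file_name = fov_name, approaching = approaching,
            start_distance = abs(pos[1, 1] - edge_x),
            max_distance = max(abs(pos[, 1] - edge_x)),
            approach_speed = if (approaching) approach_speed else NA_real_
          )
        }
      }
    }
  }
  fi <- spec$conditions[[1]]$frame_interval
  ds <- track_dataset(dplyr::bind_rows(rows), frame_interval = fi)
  attr(ds, "ground_truth") <- dplyr::bind_rows(gt)
  roi <- roi_polygon(cbind(c(edge_x, edge_x), c(field[3], field[4])),
                     closed = FALSE)
  list(dataset = ds, roi = roi, edge_x = edge_x)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

write_trackmate_xml_fov <- function(sp, path, frame_interval, space_unit,
                                    time_unit) {
  # stable integer spot ids within the file
  sp <- dplyr::arrange(sp, .data$unique_track_id, .data$frame)
  sp$spot_id <- seq_len(nrow(sp)) - 1L
  tids <- unique(sp$unique_track_id)
  src_id <- sub("^.*::", "", tids)
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  fmt <- function(v) formatC(v, digits = 17, format = "g", width = 1)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<TrackMate version="7.11.1">')
  w(sprintf('  <Model spatialunits="%s" timeunits="%s">',
            xml_escape(space_unit), xml_escape(time_unit)))
  w(sprintf('    <AllSpots nspots="%d">', nrow(sp)))
  for (fr in sort(unique(sp$frame))) {
    w(sprintf('      <SpotsInFrame frame="%d">', fr))
    ss <- sp[sp$frame == fr, ]
    for (i in seq_len(nrow(ss))) {
      zal <- if ("z" %in% names(ss)) fmt(ss$z[i]) else "0"
      w(sprintf(paste0('        <Spot ID="%d" name="ID%d" QUALITY="1" ',
                       'POSITION_X="%s" POSITION_Y="%s" POSITION_Z="%s" ',
                       'POSITION_T="%s" FRAME="%d" RADIUS="2.5" ',
                       'VISIBILITY="1"/>'),
                ss$spot_id[i], ss$spot_id[i], fmt(ss$x[i]), fmt(ss$y[i]),
                zal, fmt(ss$t[i]), ss$frame[i]))
    }
    w('      </SpotsInFrame>')
  }
  w('    </AllSpots>')
  w('    <AllTracks>')
  for (j in seq_along(tids)) {
    ss <- sp[sp$unique_track_id == tids[j], ]
    w(sprintf('      <Track name="Track_%s" TRACK_ID="%s" NUMBER_SPOTS="%d" NUMBER_SPLITS="0" NUMBER_MERGES="0">',
              src_id[j], src_id[j], nrow(ss)))
    if (nrow(ss) >= 2) {
      for (i in seq_len(nrow(ss) - 1)) {
        w(sprintf('        <Edge SPOT_SOURCE_ID="%d" SPOT_TARGET_ID="%d" LINK_COST="1"/>',
                  ss$spot_id[i], ss$spot_id[i + 1]))
      }
    } else {
      # single-spot track: self-edge keeps the spot assigned
      w(sprintf('        <Edge SPOT_SOURCE_ID="%d" SPOT_TARGET_ID="%d" LINK_COST="0"/>',
                ss$spot_id[1], ss$spot_id[1]))
    }
    w('      </Track>')
  }
  w('    </AllTracks>')
  w('    <FilteredTracks>')
  for (j in seq_along(tids)) {
    w(sprintf('      <TrackID TRACK_ID="%s"/>', src_id[j]))
  }
  w('    </FilteredTracks>')
  w('  </Model>')
  w('</TrackMate>')
  invisible(path)
}

write_trackmate_csv_fov <- function(sp, path) {
  sp <- dplyr::arrange(sp, .data$unique_track_id, .data$frame)
  src_id <- sub("^.*::", "", sp$unique_track_id)
  tab <- tibble::tibble(
    LABEL = paste0("ID", seq_len(nrow(sp)) - 1L),
    ID = seq_len(nrow(sp)) - 1L,
    TRACK_ID = src_id,
    QUALITY = 1,
    POSITION_X = sp$x, POSITION_Y = sp$y,
    POSITION_Z = if ("z" %in% names(sp)) sp$z else 0,
    POSITION_T = sp$t, FRAME = sp$frame
  )
  sub1 <- c("Label", "Spot ID", "Track ID", "Quality", "X", "Y", "Z", "T",
            "Frame")
  sub2 <- c("Label", "Spot ID", "Track ID", "Quality", "X", "Y", "Z", "T",
            "Frame")
  sub3 <- c("", "", "", "(quality)", "(micron)", "(micron)", "(micron)",
            "(sec)", "")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = ","), con)
  writeLines(paste(sub1, collapse = ","), con)
  writeLines(paste(sub2, collapse = ","), con)
  writeLines(paste(sub3, collapse = ","), con)
  cols <- lapply(tab, function(v) {
    if (is.numeric(v)) formatC(v, digits = 17, format = "g", width = 1)
    else as.character(v)
  })
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

write_generic_csv_fov <- function(sp, path) {
  sp <- dplyr::arrange(sp, .data$unique_track_id, .data$frame)
  tab <- tibble::tibble(
    track_id = sub("^.*::", "", sp$unique_track_id),
    frame = sp$frame, t = sp$t, x = sp$x, y = sp$y
  )
  if ("z" %in% names(sp)) tab$z <- sp$z
  extra <- setdiff(names(sp)[vapply(sp, is.numeric, logical(1))],
                   c("frame", "t", "x", "y", "z", "x_raw", "y_raw", "z_raw"))
  for (cn in extra) tab[[cn]] <- sp[[cn]]
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Column map matching [write_fixture_tree()]'s generic CSV dialect
#' @return A `column_map`.
#' @export
generic_column_map <- function() {
  column_map(track_id = "track_id", frame = "frame", x = "x", y = "y",
             t = "t", z = "z", dialect = "plain")
}

#' Write a dataset as a Condition/Repeat fixture tree
#'
#' Writes `out_dir/<condition>/<replicate>/<file>` in each requested
#' dialect (separate sub-directory per format when several are requested).
#' Reloading with [compile_dataset()] reproduces the dataset's coordinates
#' and track memberships.
#'
#' @param ds A `track_dataset`.
#' @param out_dir Output directory.
#' @param formats Subset of `c("trackmate_xml", "trackmate_csv",
#'   "generic_csv")`.
#' @return Named character vector of the per-format tree roots, invisibly.
#' @export
write_fixture_tree <- function(ds, out_dir,
                               formats = c("trackmate_xml")) {
  assert_dataset(ds)
  valid <- c("trackmate_xml", "trackmate_csv", "generic_csv")
  if (length(formats) == 0) stop("formats must be non-empty", call. = FALSE)
  bad <- setdiff(formats, valid)
  if (length(bad) > 0) {
    stop("unsupported format(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  single <- length(formats) == 1
  roots <- character(0)
  for (fmt in formats) {
    root <- if (single) out_dir else file.path(out_dir, fmt)
    groups <- split(ds$spots,
                    list(ds$spots$condition, ds$spots$replicate,
                         ds$spots$file_name), drop = TRUE)
    for (g in groups) {
      d <- file.path(root, g$condition[1], g$replicate[1])
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
      stem <- g$file_name[1]
      if (fmt == "trackmate_xml") {
        write_trackmate_xml_fov(g, file.path(d, paste0(stem, ".xml")),
                                ds$frame_interval, ds$space_unit,
                                ds$time_unit)
      } else if (fmt == "trackmate_csv") {
        write_trackmate_csv_fov(g, file.path(d, paste0(stem, ".csv")))
      } else {
        write_generic_csv_fov(g, file.path(d, paste0(stem, ".csv")))
      }
    }
    roots[fmt] <- root
  }
  invisible(roots)
}
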