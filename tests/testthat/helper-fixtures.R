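# In-code fixtures shared across test files.

# Minimal spot table for hand-constructed tracks: coords is a list of
# n x 2 matrices (one per track), frames a parallel list (default 0..n-1).
make_spots <- function(coords, frames = NULL, condition = "A",
                       replicate = "R1", file_name = "fov1",
                       frame_interval = 1) {
  rows <- lapply(seq_along(coords), function(i) {
    m <- coords[[i]]
    fr <- if (is.null(frames)) seq_len(nrow(m)) - 1L else frames[[i]]
    tibble::tibble(
      unique_track_id = paste0(file_name, "::", i),
      file_name = file_name, condition = condition, replicate = replicate,
      frame = as.integer(fr), t = fr * frame_interval,
      x = m[, 1], y = m[, 2]
    )
  })
  dplyr::bind_rows(rows)
}

make_dataset <- function(coords, ...) {
  track_dataset(make_spots(coords, ...))
}

# Small two-condition synthetic scene used by several suites.
small_scene <- function(seed = 42, n_frames = 15, tracks_per_fov = 8,
                        repeats = 2, fovs = 1,
                        speed_a = 1, speed_b = 2) {
  scene_spec(
    list(A = motion_model(speed_mean = speed_a, speed_sd = 0.2,
                          persistence = 0.5, n_frames = n_frames),
         B = motion_model(speed_mean = speed_b, speed_sd = 0.2,
                          persistence = 0.5, n_frames = n_frames)),
    repeats = repeats, fovs_per_repeat = fovs,
    tracks_per_fov = tracks_per_fov, seed = seed
  )
}

# Independent naive re-implementation of every motility metric, used as
# the oracle against the production engine. Deliberately written as a
# plain per-track loop from the definitions.
naive_track_metrics <- function(spots_one_track) {
  s <- spots_one_track[order(spots_one_track$frame), ]
  has_z <- "z" %in% names(s) && any(is.finite(s$z) & s$z != 0)
  p <- if (has_z) cbind(s$x, s$y, s$z) else cbind(s$x, s$y)
  t <- s$t
  n <- nrow(p)
  out <- list(NUMBER_SPOTS = n)
  jumps <- diff(s$frame)
  out$NUMBER_GAPS <- sum(jumps > 1)
  out$LONGEST_GAP <- if (out$NUMBER_GAPS > 0) max(jumps) - 1 else 0
  if (n == 1) {
    return(c(out, list(
      `Track Duration` = 0, `Total Distance Traveled` = 0,
      TRACK_DISPLACEMENT = 0, Directionality = 0, CONFINEMENT_RATIO = 0,
      Tortuosity = NaN, `Mean Speed` = NaN, `Median Speed` = NaN,
      `Max Speed` = NaN, `Min Speed` = NaN,
      `Speed Standard Deviation` = NaN, MEAN_STRAIGHT_LINE_SPEED = NaN,
      LINEARITY_OF_FORWARD_PROGRESSION = NaN, MAX_DISTANCE_TRAVELED = 0,
      `Total Turning Angle` = 0, MEAN_DIRECTIONAL_CHANGE_RATE = NaN,
      `Spatial Coverage` = 0)))
  }
  step_len <- numeric(n - 1)
  for (i in 1:(n - 1)) step_len[i] <- sqrt(sum((p[i + 1, ] - p[i, ])^2))
  total <- sum(step_len)
  disp <- sqrt(sum((p[n, ] - p[1, ])^2))
  dur <- t[n] - t[1]
  speeds <- step_len / diff(t)
  out$`Track Duration` <- dur
  out$`Total Distance Traveled` <- total
  out$TRACK_DISPLACEMENT <- disp
  out$Directionality <- if (total > 0) disp / total else 0
  out$CONFINEMENT_RATIO <- out$Directionality
  out$Tortuosity <- if (disp > 0) total / disp else NaN
  out$`Mean Speed` <- mean(speeds)
  out$`Median Speed` <- median(speeds)
  out$`Max Speed` <- max(speeds)
  out$`Min Speed` <- min(speeds)
  out$`Speed Standard Deviation` <- if (n > 2) sd(speeds) else
    if (n == 2) NaN else NaN
  msls <- if (dur > 0) disp / dur else NaN
  out$MEAN_STRAIGHT_LINE_SPEED <- msls
  out$LINEARITY_OF_FORWARD_PROGRESSION <-
    if (is.finite(msls) && mean(speeds) > 0) msls / mean(speeds) else NaN
  md <- 0
  for (i in 1:n) md <- max(md, sqrt(sum((p[i, ] - p[1, ])^2)))
  out$MAX_DISTANCE_TRAVELED <- md
  tta <- 0; rates <- numeric(0)
  if (n >= 3) {
    for (i in 1:(n - 2)) {
      v1 <- p[i + 1, ] - p[i, ]; v2 <- p[i + 2, ] - p[i + 1, ]
      l1 <- sqrt(sum(v1^2)); l2 <- sqrt(sum(v2^2))
      if (l1 > 0 && l2 > 0) {
        ang <- acos(min(1, max(-1, sum(v1 * v2) / (l1 * l2))))
        tta <- tta + ang
        rates <- c(rates, ang / (t[i + 1] - t[i]))
      }
    }
  }
  out$`Total Turning Angle` <- tta
  out$MEAN_DIRECTIONAL_CHANGE_RATE <- if (length(rates) > 0) mean(rates)
    else NaN
  # convex hull area via the shoelace formula on chull vertices
  pts <- unique(cbind(s$x, s$y))
  out$`Spatial Coverage` <- if (nrow(pts) < 3) 0 else {
    h <- grDevices::chull(pts)
    hx <- pts[h, 1]; hy <- pts[h, 2]
    abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  }
  out
}
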