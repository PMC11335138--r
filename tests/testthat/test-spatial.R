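test_that("Ripley estimator matches the closed form and a brute-force loop", {
  w <- rect_window(0, 1, 0, 1)
  # two points at distance 1 in a unit window, r = 1
  got <- ripley_l(rbind(c(0, 0.5), c(1, 0.5)), radii = 1, window = w)
  expect_equal(got$K, 1)
  expect_equal(got$L_minus_r, sqrt(1 / pi) - 1, tolerance = 1e-12)
  # r below the minimum pairwise distance: K = 0, L - r = -r
  got0 <- ripley_l(rbind(c(0, 0.5), c(1, 0.5)), radii = 0.5, window = w)
  expect_equal(got0$K, 0)
  expect_equal(got0$L_minus_r, -0.5)
  # brute-force double loop agrees exactly on random points
  set.seed(2)
  pts <- cbind(runif(150), runif(150))
  radii <- seq(0.02, 0.3, by = 0.02)
  got <- ripley_l(pts, radii, w)
  n <- nrow(pts)
  for (j in seq_along(radii)) {
    cnt <- 0
    for (a in 1:n) for (b in 1:n) {
      if (a != b && sqrt(sum((pts[a, ] - pts[b, ])^2)) <= radii[j]) {
        cnt <- cnt + 1
      }
    }
    expect_equal(got$K[j], w$area * cnt / (n * (n - 1)), tolerance = 1e-12)
  }
  expect_error(ripley_l(rbind(c(0, 0)), 1, w), ">= 2")
})

test_that("CSR envelope contains zero at small radii and is deterministic", {
  w <- rect_window(0, 1, 0, 1)
  radii <- seq(0.02, 0.1, by = 0.02)
  env <- csr_envelope(100, w, radii, n_simulations = 60, seed = 5)
  expect_true(all(env$envelope_low <= 0 & env$envelope_high >= 0))
  expect_true(all(env$envelope_low <= env$envelope_high))
  env2 <- csr_envelope(100, w, radii, n_simulations = 60, seed = 5)
  expect_identical(env, env2)
  expect_warning(csr_envelope(100, w, radii, n_simulations = 10),
                 "unstable")
})

test_that("clustered (Thomas) patterns break out of the CSR envelope", {
  w <- rect_window(0, 1, 0, 1)
  radii <- seq(0.02, 0.1, by = 0.02)
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    parents <- cbind(runif(5), runif(5))
    pts <- do.call(rbind, lapply(seq_len(5), function(i) {
      cbind(rnorm(20, parents[i, 1], 0.02), rnorm(20, parents[i, 2], 0.02))
    }))
    pts[, 1] <- pmin(pmax(pts[, 1], 0), 1)
    pts[, 2] <- pmin(pmax(pts[, 2], 0), 1)
    curve <- ripley_l(pts, radii, w)
    env <- csr_envelope(nrow(pts), w, radii, n_simulations = 50,
                        seed = 1000 + s)
    if (any(curve$L_minus_r > env$envelope_high)) hits <- hits + 1
  }
  expect_equal(hits, n_seeds)  # clustering this strong is always detected
})

test_that("ripley_track_analysis reduces tracks to points and rejects 3-D", {
  ds <- generate_dataset(small_scene(seed = 3, tracks_per_fov = 30))
  rip <- ripley_track_analysis(ds, radii = seq(10, 50, by = 10),
                               n_simulations = 25, seed = 2)
  expect_equal(rip$n_points, nrow(ds$tracks))
  expect_true(all(is.finite(rip$curve$L_minus_r)))
  ds3 <- ds
  ds3$spots$z <- 1
  ds3 <- track_dataset(ds3$spots, ds3$tracks, dimensionality = 3)
  expect_error(ripley_track_analysis(ds3, radii = 10), "2-D")
})

test_that("polygon distances follow plane geometry", {
  # vertical boundary at x = 100
  roi <- roi_polygon(cbind(c(100, 100), c(0, 200)), closed = FALSE)
  sp <- make_spots(list(cbind(c(40, 100, 160), c(10, 20, 30))))
  ds <- distance_to_roi(track_dataset(sp), roi)
  expect_equal(ds$spots$roi_distance, c(60, 0, 60))
  # distances are invariant under rigid translation of ROI + spots
  sh <- make_spots(list(cbind(c(40, 100, 160) + 13, c(10, 20, 30) - 7)))
  roi_sh <- roi_polygon(cbind(c(113, 113), c(-7, 193)), closed = FALSE)
  ds2 <- distance_to_roi(track_dataset(sh), roi_sh)
  expect_equal(ds2$spots$roi_distance, ds$spots$roi_distance,
               tolerance = 1e-9)
  # self-intersecting polygons are rejected
  expect_error(roi_polygon(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)),
                           closed = TRUE), "self-intersecting")
})

test_that("mask and polygon representations of the same edge agree", {
  mask <- matrix(FALSE, 50, 200)
  mask[, 1:100] <- TRUE  # region up to x = 100 (pixel units)
  roim <- roi_mask(mask, pixel_size = 1)
  roip <- roi_polygon(cbind(c(100, 100), c(0, 50)), closed = FALSE)
  set.seed(6)
  px <- runif(40, 10, 90); py <- runif(40, 5, 45)
  sp <- make_spots(list(cbind(px, py)))
  dm <- distance_to_roi(track_dataset(sp), roim)$spots$roi_distance
  dp <- distance_to_roi(track_dataset(sp), roip)$spots$roi_distance
  expect_lt(max(abs(dm - dp)), 1)  # within one pixel size
  expect_error(roi_mask(matrix(FALSE, 5, 5), 1), "empty")
})

test_that("ROI track metrics match hand values on a linear series", {
  sp <- make_spots(list(cbind(c(10, 8, 6, 4), rep(0, 4))))
  roi <- roi_polygon(cbind(c(0, 0), c(-10, 10)), closed = FALSE)
  ds <- roi_track_metrics(distance_to_roi(track_dataset(sp), roi))
  tr <- ds$tracks
  expect_equal(tr$StartDistance_edge, 10)
  expect_equal(tr$EndDistance_edge, 4)
  expect_equal(tr$DirectionMovement_edge, -6)
  expect_equal(tr$AvgRateChange_edge, -2)
  expect_equal(tr$TrendSlope_edge, -2, tolerance = 1e-12)
  expect_equal(tr$MedianDistance_edge, 7)
  expect_equal(tr$PercentageChange_edge, -60)
  expect_equal(tr$MaxDistance_edge, 10)
  expect_equal(tr$MinDistance_edge, 4)
  # constant series
  spc <- make_spots(list(cbind(rep(5, 4), 0:3)))
  roic <- roi_polygon(cbind(c(0, 0), c(-10, 10)), closed = FALSE)
  trc <- roi_track_metrics(distance_to_roi(track_dataset(spc),
                                           roic))$tracks
  expect_equal(trc$DirectionMovement_edge, 0)
  expect_equal(trc$TrendSlope_edge, 0)
  expect_equal(trc$StdDevDistance_edge, 0)
  # start exactly on the boundary: percentage change undefined
  sp0 <- make_spots(list(cbind(c(0, 5), c(0, 0))))
  tr0 <- roi_track_metrics(distance_to_roi(track_dataset(sp0),
                                           roic))$tracks
  expect_true(is.nan(tr0$PercentageChange_edge))
  expect_true(is.finite(tr0$TrendSlope_edge))
})

test_that("distance stratification applies the close-at-threshold rule", {
  sp <- make_spots(list(cbind(c(0, 74.9), c(0, 0)),
                        cbind(c(0, 75), c(0, 0)),
                        cbind(c(0, 75.1), c(0, 0))))
  roi <- roi_polygon(cbind(c(0, 0), c(-10, 10)), closed = FALSE)
  ds <- stratify_by_distance(
    roi_track_metrics(distance_to_roi(track_dataset(sp), roi)))
  got <- ds$tracks$distance_stratum[order(ds$tracks$unique_track_id)]
  expect_equal(got, c("close", "close", "far"))
  expect_error(stratify_by_distance(track_dataset(make_spots(
    list(cbind(0:1, c(0, 0)))))), "MaxDistance_edge")
})

test_that("leading-edge scene recovers designed strata and slopes exactly", {
  spec <- scene_spec(list(A = motion_model(persistence = 0,
                                           n_frames = 12)),
                     repeats = 2, tracks_per_fov = 20,
                     field = c(0, 600, 0, 400), seed = 29)
  sc <- generate_roi_scene(spec, edge_x = 100, approach_speed = 2,
                           fraction_approaching = 0.5)
  ds <- roi_track_metrics(distance_to_roi(sc$dataset, sc$roi))
  gt <- attr(sc$dataset, "ground_truth")
  j <- match(gt$unique_track_id, ds$tracks$unique_track_id)
  # approachers: TrendSlope and AvgRateChange exactly -approach_speed
  app <- gt$approaching
  expect_equal(ds$tracks$TrendSlope_edge[j][app],
               rep(-2, sum(app)), tolerance = 1e-9)
  expect_equal(ds$tracks$AvgRateChange_edge[j][app],
               rep(-2, sum(app)), tolerance = 1e-9)
  # DirectionMovement = End - Start identically
  expect_equal(ds$tracks$DirectionMovement_edge,
               ds$tracks$EndDistance_edge - ds$tracks$StartDistance_edge)
  # designed close/far membership recovered exactly from ground truth
  ds <- stratify_by_distance(ds, threshold = 75)
  want <- ifelse(gt$max_distance <= 75, "close", "far")
  expect_equal(ds$tracks$distance_stratum[j], want)
})
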