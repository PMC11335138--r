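test_that("track_dataset enforces key and column invariants", {
  sp <- make_spots(list(cbind(c(0, 1), c(0, 0))))
  ds <- track_dataset(sp)
  expect_s3_class(ds, "track_dataset")
  expect_equal(nrow(ds$tracks), 1)
  # duplicate (track, frame) pair
  bad <- dplyr::bind_rows(sp, sp[1, ])
  expect_error(track_dataset(bad), "duplicate")
  # empty condition
  sp2 <- sp; sp2$condition <- ""
  expect_error(track_dataset(sp2), "non-empty")
  # frame_interval must be positive
  expect_error(track_dataset(sp, frame_interval = 0), "positive")
  # mismatched track table
  tr <- tibble::tibble(unique_track_id = "other::1", file_name = "f",
                       condition = "A", replicate = "R1")
  expect_error(track_dataset(sp, tr), "does not match")
})

test_that("TrackMate XML loads tracks, drops untracked spots, is deterministic", {
  ds <- make_dataset(list(cbind(0:2, c(0, 1, 0)), cbind(3:5, c(1, 1, 1))))
  td <- withr::local_tempdir()
  write_fixture_tree(ds, td, formats = "trackmate_xml")
  f <- list.files(td, pattern = "\\.xml$", recursive = TRUE,
                  full.names = TRUE)
  got <- load_trackmate_xml(f, frame_interval = 1)
  expect_equal(nrow(got$tracks), 2)
  expect_equal(nrow(got$spots), 6)
  expect_equal(sort(got$spots$x), sort(ds$spots$x), tolerance = 1e-12)
  # track-level TrackMate features are imported
  expect_true("NUMBER_SPLITS" %in% names(got$tracks))
  # determinism: loading twice gives identical tables
  again <- load_trackmate_xml(f, frame_interval = 1)
  expect_identical(got$spots, again$spots)

  # inject an untracked spot: it must be dropped with a message
  doc <- readLines(f)
  extra <- '        <Spot ID="999" name="ID999" QUALITY="1" POSITION_X="7" POSITION_Y="8" POSITION_Z="0" POSITION_T="0" FRAME="0" RADIUS="2.5" VISIBILITY="1"/>'
  i <- grep("<SpotsInFrame frame=\"0\">", doc)[1]
  writeLines(append(doc, extra, after = i), f)
  expect_message(got2 <- load_trackmate_xml(f, frame_interval = 1),
                 "dropped 1")
  expect_equal(nrow(got2$spots), 6)

  # edge referencing a missing spot is an integrity error
  doc <- readLines(f)
  doc <- sub('SPOT_TARGET_ID="1"', 'SPOT_TARGET_ID="12345"', doc)
  writeLines(doc, f)
  expect_error(load_trackmate_xml(f), "integrity")
})

test_that("malformed XML errors name the offending element", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<TrackMate><NotAModel/></TrackMate>", f)
  expect_error(load_trackmate_xml(f), "Model")
})

test_that("generic CSV loading honours the column map", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tid,fr,px,py", "1,0,0,0", "1,1,1,0", "1,2,2,0", "1,3,3,0"),
             f)
  map <- column_map(track_id = "tid", frame = "fr", x = "px", y = "py")
  ds <- load_tracking_csv(f, map, frame_interval = 2)
  expect_equal(ds$spots$t, c(0, 2, 4, 6))  # t = frame * dt
  expect_equal(nrow(ds$tracks), 1)
  # missing mapping is a configuration error listing the name
  bad <- column_map(track_id = "tid", frame = "fr", x = "nope", y = "py")
  expect_error(load_tracking_csv(f, bad), "nope")
  # non-finite positions are rejected with a count
  writeLines(c("tid,fr,px,py", "1,0,0,0", "1,1,NaN,0", "1,2,2,0"), f)
  expect_message(ds2 <- load_tracking_csv(f, map), "rejected 1")
  expect_equal(nrow(ds2$spots), 2)
})

test_that("TrackMate CSV dialect equals the plain dialect on the same data", {
  ds <- make_dataset(list(cbind(c(0, 1.5, 3), c(0, 2, 1)),
                          cbind(c(5, 6), c(5, 5))))
  td <- withr::local_tempdir()
  roots <- write_fixture_tree(ds, td,
                              formats = c("trackmate_csv", "generic_csv"))
  a <- compile_dataset(roots["trackmate_csv"], "csv",
                       map = trackmate_column_map())
  b <- compile_dataset(roots["generic_csv"], "csv",
                       map = generic_column_map())
  expect_equal(a$spots$x, b$spots$x, tolerance = 1e-12)
  expect_equal(a$spots$y, b$spots$y, tolerance = 1e-12)
  expect_equal(a$spots$unique_track_id, b$spots$unique_track_id)
})

test_that("XML and CSV readers agree on the same field of view", {
  ds <- generate_dataset(small_scene(seed = 5, tracks_per_fov = 4))
  td <- withr::local_tempdir()
  roots <- write_fixture_tree(ds, td,
                              formats = c("trackmate_xml", "generic_csv"))
  a <- compile_dataset(roots["trackmate_xml"], "trackmate_xml")
  b <- compile_dataset(roots["generic_csv"], "csv",
                       map = generic_column_map())
  expect_equal(a$spots$unique_track_id, b$spots$unique_track_id)
  expect_lt(max(abs(a$spots$x - b$spots$x)), 1e-9)
  expect_lt(max(abs(a$spots$y - b$spots$y)), 1e-9)
})

test_that("compile_dataset assigns provenance from the tree and is order-independent", {
  ds <- generate_dataset(small_scene(seed = 9, tracks_per_fov = 5,
                                     repeats = 2, fovs = 1))
  td <- withr::local_tempdir()
  write_fixture_tree(ds, td, formats = "trackmate_xml")
  got <- compile_dataset(td, "trackmate_xml")
  expect_equal(sort(unique(got$tracks$condition)), c("A", "B"))
  expect_equal(sort(unique(got$tracks$replicate)), c("R1", "R2"))
  expect_equal(nrow(got$tracks), 20)  # 2 cond x 2 rep x 5 tracks
  expect_equal(
    nrow(dplyr::distinct(got$tracks, .data$condition, .data$replicate)), 4)
  # same source id in two files -> distinct unique ids
  expect_equal(anyDuplicated(got$tracks$unique_track_id), 0)
  expect_true(all(grepl("::", got$tracks$unique_track_id, fixed = TRUE)))
  # ground-truth bookkeeping matches compiled counts
  gt <- attr(ds, "ground_truth")
  expect_equal(nrow(got$tracks), nrow(gt))
  # empty tree errors
  expect_error(compile_dataset(withr::local_tempdir(), "trackmate_xml"),
               "no trackmate_xml files")
})

test_that("save/load round trip is exact, including optional z", {
  ds <- generate_dataset(small_scene(seed = 4, tracks_per_fov = 3))
  ds$spots$z <- seq_len(nrow(ds$spots)) * 0.1
  ds <- track_dataset(ds$spots, ds$tracks, frame_interval = 1,
                      dimensionality = 3)
  ds <- compute_track_metrics(ds)
  td <- withr::local_tempdir()
  save_dataset(ds, td)
  got <- load_saved_dataset(td)
  expect_equal(got$spots, ds$spots)
  expect_equal(got$tracks, ds$tracks)
  expect_equal(got$dimensionality, 3)
  # metric-free track table round-trips with key columns only
  ds0 <- generate_dataset(small_scene(seed = 4, tracks_per_fov = 2))
  td2 <- withr::local_tempdir()
  save_dataset(ds0, td2)
  expect_equal(names(load_saved_dataset(td2)$tracks),
               c("unique_track_id", "file_name", "condition", "replicate"))
})
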