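# MVNX-style XML, CSV, campos projection and resampling.

test_that("MVNX round trip is lossless and preserves label order", {
  s <- mk_fixture_series(seed = 11, duration = 0.5)
  xml <- write_mvnx(s)
  s2 <- parse_mvnx(xml)
  expect_identical(s2$keypoint_labels, mocap_keypoint_labels())
  expect_equal(s2$keypoint_labels[1], "Pelvis")
  expect_equal(s2$keypoint_labels[23], "Left toe")
  expect_equal(s2$frame_count, s$frame_count)
  expect_lt(max(abs(s2$positions - s$positions)), 1e-9)
  expect_lt(max(abs(s2$orientations - s$orientations)), 1e-9)
  expect_lt(max(abs(s2$com - s$com)), 1e-9)
  expect_identical(s2$foot_contacts, unname(s$foot_contacts))
  # a second round trip through files
  tmp <- withr::local_tempfile(fileext = ".mvnx")
  write_mvnx(s2, tmp)
  s3 <- parse_mvnx(tmp)
  expect_lt(max(abs(s3$positions - s$positions)), 1e-9)
})

test_that("parse_mvnx validates structure", {
  s <- mk_fixture_series(duration = 0.1, framerate = 30)
  xml <- write_mvnx(s)
  # drop one orientation element -> channel present in some frames only
  broken <- sub("<orientation>[^<]*</orientation>", "", xml)
  expect_error(parse_mvnx(broken), "frame-count mismatch")
  expect_error(parse_mvnx("<mvnx><subject></mvnx>"), "malformed")
  expect_error(parse_mvnx("<mvnx><subject frameRate='30'></subject></mvnx>"),
               "segments")
  # unknown frame elements are ignored with a warning
  extra <- sub("</frame>", "<sensorMagneticField>1 2 3</sensorMagneticField></frame>",
               xml)
  expect_warning(s2 <- parse_mvnx(extra), "unknown frame element")
  expect_equal(s2$frame_count, s$frame_count)
})

test_that("auxiliary derivative channels survive the round trip and are preferred", {
  s <- mk_fixture_series(duration = 0.3, framerate = 60)
  vel <- array(1.5, dim(s$positions))
  s_aux <- keypoint_series(s$positions, s$orientations, s$com, s$framerate,
                           s$keypoint_labels, s$foot_contacts,
                           velocity = vel)
  s2 <- parse_mvnx(write_mvnx(s_aux))
  expect_false(is.null(s2$velocity))
  expect_lt(max(abs(s2$velocity - vel)), 1e-9)
  # speed uses the file channel: constant (1.5,1.5,1.5) -> norm everywhere
  sp <- kin_speed(s2, "Head")
  expect_equal(sp$values, rep(sqrt(3) * 1.5, s2$frame_count))
  # ... unless recomputation is requested
  sp2 <- kin_speed(s2, "Head", prefer_file_channels = FALSE)
  expect_false(isTRUE(all.equal(sp$values, sp2$values)))
})

test_that("CSV export has the contracted shape and round-trips", {
  s <- mk_fixture_series(seed = 4, duration = 9 / 60, framerate = 60)
  expect_equal(s$frame_count, 10L)
  dir <- withr::local_tempdir()
  files <- write_series_csv(s, dir)
  expect_length(files, 8L)
  expect_setequal(basename(files),
                  c("position.csv", "orientation.csv", "velocity.csv",
                    "angular_velocity.csv", "acceleration.csv",
                    "angular_acceleration.csv", "center_of_mass.csv",
                    "foot_contacts.csv"))
  pos <- utils::read.csv(file.path(dir, "position.csv"))
  expect_equal(nrow(pos), 10L)
  expect_equal(ncol(pos), 23L * 3L)
  s2 <- read_series_csv(dir)
  expect_lt(max(abs(s2$positions - s$positions)), 1e-9)
  expect_identical(s2$keypoint_labels, s$keypoint_labels)
  expect_error(write_series_csv(s, file.path(dir, "position.csv")),
               "cannot create")
})

test_that("campos projection matches pinhole geometry", {
  cam <- camera_model(position = c(4, 0, 1.2), target = c(0, 0, 1.2),
                      fov = 50 * pi / 180, aspect = 16 / 9)
  # a point on the optical axis at 3 m
  arr <- array(0, c(2, 1, 3))
  arr[, 1, ] <- matrix(rep(c(1, 0, 1.2), each = 2), 2)
  s <- keypoint_series(arr, framerate = 60, keypoint_labels = "Pelvis")
  cp <- project_campos(s, cam, 60)
  expect_equal(unname(cp$x[1, 1]), 0.5, tolerance = 1e-12)
  expect_equal(unname(cp$y[1, 1]), 0.5, tolerance = 1e-12)
  expect_equal(unname(cp$depth[1, 1]), 3, tolerance = 1e-12)
  # displaced to the camera's left -> x < 0.5 (x = 0 is the leftmost pixel)
  arr[, 1, ] <- matrix(rep(c(1, -0.5, 1.2), each = 2), 2)
  cp2 <- project_campos(keypoint_series(arr, framerate = 60,
                                        keypoint_labels = "Pelvis"), cam, 60)
  expect_lt(cp2$x[1, 1], 0.5)
  # behind the camera: flagged with non-positive depth, not dropped
  arr[, 1, ] <- matrix(rep(c(6, 0, 1.2), each = 2), 2)
  cp3 <- project_campos(keypoint_series(arr, framerate = 60,
                                        keypoint_labels = "Pelvis"), cam, 60)
  expect_lte(cp3$depth[1, 1], 0)
  expect_equal(nrow(cp3$x), 2L)
})

test_that("projection of a planar target matches the homography oracle", {
  cam_pos <- c(3.2, 0.4, 1.5); cam_target <- c(0, -0.2, 1.1)
  fov <- 55 * pi / 180; aspect <- 16 / 9
  cam <- camera_model(cam_pos, cam_target, fov, aspect)
  corners <- rbind(c(0, -0.5, 0.7), c(0, 0.5, 0.7),
                   c(0, 0.5, 1.7), c(0, -0.5, 1.7))
  arr <- array(0, c(2, 4, 3))
  for (t in 1:2) arr[t, , ] <- corners
  s <- keypoint_series(arr, framerate = 60,
                       keypoint_labels = paste0("corner", 1:4))
  cp <- project_campos(s, cam, 60)
  for (j in 1:4) {
    o <- oracle_project(corners[j, ], cam_pos, cam_target, fov, aspect)
    expect_equal(unname(c(cp$x[1, j], cp$y[1, j], cp$depth[1, j])), o,
                 tolerance = 1e-6)
  }
})

test_that("translating the scene parallel to the image plane shifts x monotonically", {
  cam <- camera_model(position = c(5, 0, 1), target = c(0, 0, 1))
  s <- mk_fixture_series(duration = 0.2, framerate = 30)
  cp0 <- project_campos(s, cam, 30)
  shifted <- translate_series(s, c(0, -0.4, 0))  # toward the camera's left
  cp1 <- project_campos(shifted, cam, 30)
  expect_true(all(cp1$x < cp0$x))
  expect_equal(order(cp0$depth[1, ]), order(cp1$depth[1, ]))
})

test_that("campos JSON round-trips", {
  s <- mk_fixture_series(duration = 0.2, framerate = 30)
  cp <- project_campos(s, camera_model(), 30)
  path <- withr::local_tempfile(fileext = ".json")
  write_campos(cp, path)
  cp2 <- read_campos(path)
  expect_equal(cp2$landmark_names, cp$landmark_names)
  expect_equal(cp2$framerate, cp$framerate)
  expect_lt(max(abs(cp2$x - cp$x)), 1e-12)
  expect_lt(max(abs(cp2$depth - cp$depth)), 1e-12)
})

test_that("resampling preserves endpoints, constants and linear ramps", {
  s <- mk_fixture_series(duration = 0.5, framerate = 240)
  expect_identical(resample_series(s, 240), s)
  # constants stay constant at scaled length
  arr <- array(2.5, c(241, 1, 3))
  const <- keypoint_series(arr, framerate = 240, keypoint_labels = "Pelvis")
  down <- resample_series(const, 25)
  expect_equal(down$frame_count, 26L)
  expect_true(all(down$positions == 2.5))
  # linear ramp: values on the analytic line
  n <- 241
  ramp <- mk_series1(cbind(seq(0, 2, length.out = n), 0, 0), 240)
  d <- resample_series(ramp, 60)
  t_out <- seq(0, 1, length.out = d$frame_count)
  expect_lt(max(abs(d$positions[, 1, 1] - 2 * t_out)), 1e-9)
  # endpoints preserved for the interpolating scheme
  r <- resample_series(s, 25)
  expect_equal(r$positions[1, , ], s$positions[1, , ], tolerance = 1e-12)
  expect_equal(r$positions[r$frame_count, , ],
               s$positions[s$frame_count, , ], tolerance = 1e-12)
  expect_error(resample_series(s, 480), "upsample")
  up <- resample_series(s, 480, force = TRUE)
  expect_equal(up$framerate, 480)
})

test_that("orientation resampling interpolates across the Euler seam", {
  n <- 25
  ang <- seq(0, 4 * pi, length.out = n)
  wrapped <- atan2(sin(ang), cos(ang))
  s <- mk_series1(matrix(0, n, 3), 24, orientations = cbind(0, 0, wrapped))
  d <- resample_series(s, 12)
  w <- kin_angular_speed(d, "Pelvis")
  # a uniform rotation stays uniform after resampling
  expect_equal(w$values, rep(4 * pi, d$frame_count), tolerance = 1e-6)
})
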