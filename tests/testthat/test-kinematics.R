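# Kinematic features against analytic and hand-computed oracles.

test_that("finite differences recover constants, ramps and sinusoids", {
  fr <- 240
  expect_equal(finite_difference(rep(3, 50), 1, fr), rep(0, 50))
  t <- seq(0, 1, by = 1 / fr)
  d <- finite_difference(cbind(t, 0, 0), 1, fr)
  expect_equal(unname(d[, 1]), rep(1, length(t)))
  expect_true(all(d[, 2:3] == 0))
  # sinusoid: central-difference error bound (2*pi*f/fr)^2 * A * 2*pi*f
  f <- 2; A <- 0.7
  x <- A * sin(2 * pi * f * t)
  d1 <- finite_difference(x, 1, fr)
  analytic <- A * 2 * pi * f * cos(2 * pi * f * t)
  interior <- 3:(length(t) - 2)
  expect_lt(max(abs(d1 - analytic)[interior]),
            (2 * pi * f / fr)^2 * A * 2 * pi * f)
  expect_error(finite_difference(c(1, 2), 2, fr), "at least 3")
  expect_error(finite_difference(c(1, 2, 3), 3, fr), "at least 4")
})

test_that("speed matches analytic norms", {
  fr <- 240
  static <- mk_series1(matrix(1, 49, 3), fr)
  expect_equal(kin_speed(static, "Pelvis")$values, rep(0, 49))
  # uniform circular motion, radius 1 m, 1 rev/s -> 2*pi m/s
  t <- seq(0, 1, by = 1 / fr)
  circ <- mk_series1(cbind(cos(2 * pi * t), sin(2 * pi * t), 0), fr)
  v <- kin_speed(circ, "Pelvis")$values
  expect_lt(max(abs(v[3:(length(t) - 2)] - 2 * pi)), 1e-3)
  # helix with known parametrization: ||p'|| = sqrt((r*w)^2 + c^2)
  r <- 0.5; w <- 3; cl <- 0.8
  helix <- mk_series1(cbind(r * cos(w * t), r * sin(w * t), cl * t), fr)
  vh <- kin_speed(helix, "Pelvis")$values
  expect_lt(max(abs(vh - sqrt((r * w)^2 + cl^2))[3:(length(t) - 2)]),
            (w / fr)^2 * r * w)
  expect_error(kin_speed(static, "Nose"), "valid labels")
})

test_that("acceleration matches analytic norms", {
  fr <- 240
  t <- seq(0, 1, by = 1 / fr)
  lin <- mk_series1(cbind(2 * t, -t, 0.5 * t), fr)
  a <- kin_acceleration(lin, "Pelvis")$values
  expect_lt(max(a[3:(length(t) - 2)]), 1e-8)
  expect_equal(kin_acceleration(mk_series1(matrix(0, 49, 3), fr),
                                "Pelvis")$values, rep(0, 49))
  # centripetal magnitude r * Omega^2
  r <- 0.8; om <- 2 * pi
  circ <- mk_series1(cbind(r * cos(om * t), r * sin(om * t), 0), fr)
  ac <- kin_acceleration(circ, "Pelvis")$values
  expect_lt(max(abs(ac - r * om^2)[3:(length(t) - 2)]), 1e-2 * r * om^2)
})

test_that("angular speed handles rotation rates and the Euler seam", {
  fr <- 240
  n <- fr + 1
  fixed <- mk_series1(matrix(0, n, 3), fr,
                      orientations = matrix(0.7, n, 3))
  expect_equal(kin_angular_speed(fixed, "Pelvis")$values, rep(0, n))
  # one full circle per second -> 2*pi rad/s, despite +/- pi wrapping
  ang <- 2 * pi * seq(0, 1, length.out = n)
  wrapped <- atan2(sin(ang), cos(ang))
  s <- mk_series1(matrix(0, n, 3), fr, orientations = cbind(0, 0, wrapped))
  w <- kin_angular_speed(s, "Pelvis")$values
  expect_lt(max(abs(w - 2 * pi)), 1e-3)
  # 90 degrees per second about z -> pi/2 rad/s
  s2 <- mk_series1(matrix(0, n, 3), fr,
                   orientations = cbind(0, 0, pi / 2 * seq(0, 1,
                                                           length.out = n)))
  expect_equal(kin_angular_speed(s2, "Pelvis")$values, rep(pi / 2, n),
               tolerance = 1e-9)
})

test_that("angular acceleration matches analytic rates", {
  fr <- 240
  n <- fr + 1
  t <- seq(0, 1, length.out = n)
  uniform <- mk_series1(matrix(0, n, 3), fr,
                        orientations = cbind(0, 0, 3 * t))
  aa <- kin_angular_acceleration(uniform, "Pelvis")$values
  expect_lt(max(aa[3:(n - 2)]), 1e-8)
  alpha <- 1.3
  quad <- mk_series1(matrix(0, n, 3), fr,
                     orientations = cbind(0, 0, 0.5 * alpha * t^2))
  expect_equal(kin_angular_acceleration(quad, "Pelvis")$values,
               rep(alpha, n), tolerance = 1e-6)
  fixed <- mk_series1(matrix(0, n, 3), fr, orientations = matrix(1, n, 3))
  expect_equal(kin_angular_acceleration(fixed, "Pelvis")$values, rep(0, n))
})

test_that("limb contraction is the mean head-extremity distance", {
  labels <- mocap_keypoint_labels()
  pos <- matrix(0, 23, 3)
  s0 <- mk_static_body(pos)
  expect_equal(limb_contraction(s0)$values, rep(0, 5))
  # head at origin, extremities at distances 1, 2, 3, 4 -> mean 2.5
  pos[match("Right hand", labels), ] <- c(1, 0, 0)
  pos[match("Left hand", labels), ] <- c(0, 2, 0)
  pos[match("Right toe", labels), ] <- c(0, 0, 3)
  pos[match("Left toe", labels), ] <- c(0, -4, 0)
  s <- mk_static_body(pos)
  expect_equal(limb_contraction(s)$values, rep(2.5, 5))
  # rigid translation leaves it unchanged
  expect_equal(limb_contraction(translate_series(s, c(3, -2, 7)))$values,
               limb_contraction(s)$values)
})

test_that("center-of-mass distance matches hand geometry", {
  s <- mk_fixture_series(duration = 0.3, framerate = 60)
  # keypoint located at the CoM -> 0
  arr <- s$positions
  arr[, 1, ] <- s$com
  s_at <- keypoint_series(arr, s$orientations, s$com, s$framerate,
                          s$keypoint_labels)
  expect_equal(com_distance(s_at, "Pelvis")$values,
               rep(0, s$frame_count))
  # 3-4-5 triangle
  arr[, 1, ] <- s$com + matrix(rep(c(3, 4, 0), each = s$frame_count),
                               s$frame_count)
  s345 <- keypoint_series(arr, s$orientations, s$com, s$framerate,
                          s$keypoint_labels)
  expect_equal(com_distance(s345, "Pelvis")$values, rep(5, s$frame_count))
  expect_equal(com_distance(translate_series(s, c(-1, 2, 0.5)), "Head")$values,
               com_distance(s, "Head")$values, tolerance = 1e-12)
})

test_that("dimensionless jerk matches a dense independent oracle", {
  # minimum-jerk polynomial between two points
  Tdur <- 1.2; fr <- 240
  delta <- c(0.4, 0.2, 0.1)
  poly <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  jerk3 <- function(tau) (60 - 360 * tau + 360 * tau^2) / Tdur^3
  tt <- seq(0, Tdur, length.out = as.integer(Tdur * fr) + 1)
  s <- mk_series1(outer(poly(tt / Tdur), delta), fr)
  lam <- dimensionless_jerk(s, "Pelvis")
  # oracle: analytic jerk integrated on a dense grid
  td <- seq(0, Tdur, length.out = 200001)
  j2 <- jerk3(td / Tdur)^2 * sum(delta^2)
  oracle <- Tdur^5 / sum(delta^2) *
    sum(diff(td) * (j2[-1] + j2[-length(j2)]) / 2)
  expect_lt(abs(lam - oracle) / oracle, 1e-3)
  # zero for constant-velocity straight-line motion
  lin <- mk_series1(cbind(seq(0, 1, length.out = 100), 0, 0), 100)
  expect_equal(dimensionless_jerk(lin, "Pelvis"), 0, tolerance = 1e-15)
  # invariant to uniform spatial scaling
  s2 <- mk_series1(2 * outer(poly(tt / Tdur), delta), fr)
  expect_equal(dimensionless_jerk(s2, "Pelvis"), lam, tolerance = 1e-9)
  # stable under resampling a smooth trajectory at 2x framerate
  tt2 <- seq(0, Tdur, length.out = as.integer(Tdur * 2 * fr) + 1)
  lam2 <- dimensionless_jerk(mk_series1(outer(poly(tt2 / Tdur), delta),
                                        2 * fr), "Pelvis")
  expect_lt(abs(lam2 - lam) / lam, 0.01)
  # degenerate cases
  frozen <- mk_series1(matrix(1, 10, 3), 60)
  expect_equal(dimensionless_jerk(frozen, "Pelvis"), 0)
  expect_error(dimensionless_jerk(mk_series1(matrix(0, 3, 3), 60), "Pelvis"),
               "at least 4")
})

test_that("head angles match hand-computed geometry", {
  labels <- mocap_keypoint_labels()
  pos <- matrix(0, 23, 3)
  pos[match("T8", labels), ] <- c(0, 0, 1.2)
  pos[match("Neck", labels), ] <- c(0, 0, 1.4)
  pos[match("Head", labels), ] <- c(0, 0, 1.6)   # collinear, upright
  s <- mk_static_body(pos)
  expect_equal(head_angle_back(s)$values, rep(0, 5))
  expect_equal(head_angle_vertical(s)$values, rep(0, 5))
  # neck->head perpendicular to T8->neck
  pos[match("Head", labels), ] <- c(0.2, 0, 1.4)
  s2 <- mk_static_body(pos)
  expect_equal(head_angle_back(s2)$values, rep(pi / 2, 5))
  expect_equal(head_angle_vertical(s2)$values, rep(pi / 2, 5))
  # head vector at (0, 1, 1)/sqrt(2) -> pi/4 from vertical
  pos[match("Head", labels), ] <- c(0, 0, 1.4) + c(0, 1, 1) / sqrt(2) * 0.2
  expect_equal(head_angle_vertical(mk_static_body(pos))$values,
               rep(pi / 4, 5))
  # relative angle invariant under a global rotation of the body
  sdyn <- mk_fixture_series(seed = 6, duration = 0.4, framerate = 60,
                            emotion = "sadness")
  R <- random_rotation(99)
  expect_equal(head_angle_back(rotate_series(sdyn, R))$values,
               head_angle_back(sdyn)$values, tolerance = 1e-9)
  # degenerate: coincident keypoints
  pos[match("Head", labels), ] <- pos[match("Neck", labels), ]
  expect_error(head_angle_back(mk_static_body(pos)), "zero-length")
})

test_that("aggregation statistics follow their definitions", {
  expect_equal(aggregate_feature(rep(2.5, 9), "average"), 2.5)
  expect_equal(aggregate_feature(rep(2.5, 9), "mad"), 0)
  expect_equal(aggregate_feature(rep(2.5, 9), "max"), 2.5)
  # hand computation: median 3, deviations {2,1,0,1,2} -> MAD 1
  expect_equal(aggregate_feature(c(1, 2, 3, 4, 5), "mad"), 1)
  # integral: trapezoid of a ramp 0..1 over 1 s = 0.5
  fs <- feature_series(seq(0, 1, length.out = 11), "x",
                       framerate = 10)
  expect_equal(aggregate_feature(fs, "integral"), 0.5)
  expect_error(aggregate_feature(numeric(0), "average"), "empty")
  expect_error(aggregate_feature(c(1, 2), "integral"), "framerate")
  # order property on arbitrary nonnegative series
  set.seed(1)
  for (i in 1:20) {
    v <- runif(50)
    expect_gte(aggregate_feature(v, "max"), aggregate_feature(v, "average"))
  }
})

test_that("rigid translation leaves body-relative features unchanged", {
  s <- mk_fixture_series(seed = 8, duration = 0.5, framerate = 60,
                         emotion = "joy")
  tr <- translate_series(s, c(5, -3, 0.7))
  for (kp in c("Right hand", "Head")) {
    expect_equal(kin_speed(tr, kp)$values, kin_speed(s, kp)$values,
                 tolerance = 1e-9)
    expect_equal(kin_acceleration(tr, kp)$values,
                 kin_acceleration(s, kp)$values, tolerance = 1e-7)
    expect_equal(com_distance(tr, kp)$values, com_distance(s, kp)$values,
                 tolerance = 1e-12)
  }
  expect_equal(limb_contraction(tr)$values, limb_contraction(s)$values,
               tolerance = 1e-12)
  expect_equal(head_angle_back(tr)$values, head_angle_back(s)$values,
               tolerance = 1e-12)
  expect_equal(head_angle_vertical(tr)$values,
               head_angle_vertical(s)$values, tolerance = 1e-12)
  expect_equal(convex_hull_3d(tr, "per-frame")$values,
               convex_hull_3d(s, "per-frame")$values, tolerance = 1e-9)
})

test_that("time reversal leaves average, MAD and max unchanged", {
  s <- mk_fixture_series(seed = 12, duration = 0.5, framerate = 60,
                         emotion = "anger")
  rv <- reverse_series(s)
  for (build in list(function(x) kin_speed(x, "Right hand"),
                     limb_contraction,
                     function(x) com_distance(x, "Left hand"),
                     head_angle_vertical)) {
    a <- build(s); b <- build(rv)
    for (st in c("average", "mad", "max"))
      expect_equal(aggregate_feature(b, st), aggregate_feature(a, st),
                   tolerance = 1e-9)
  }
})

test_that("every feature series on fixtures is nonnegative", {
  for (emo in c("neutrality", "fear", "anger")) {
    s <- mk_fixture_series(seed = 5, duration = 0.4, framerate = 60,
                           emotion = emo)
    expect_feature_nonneg(kin_speed(s, "Right hand"))
    expect_feature_nonneg(kin_acceleration(s, "Left forearm"))
    expect_feature_nonneg(kin_angular_speed(s, "Head"))
    expect_feature_nonneg(kin_angular_acceleration(s, "T8"))
    expect_feature_nonneg(limb_contraction(s))
    expect_feature_nonneg(com_distance(s, "Pelvis"))
    expect_feature_nonneg(head_angle_back(s))
    expect_feature_nonneg(head_angle_vertical(s))
    expect_feature_nonneg(convex_hull_3d(s, "per-frame"))
    expect_gte(dimensionless_jerk(s), 0)
  }
})
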