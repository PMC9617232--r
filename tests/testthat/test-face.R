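test_that("EAR is constant on a static face and scale-invariant", {
  track <- static_track(n = 50)
  e <- ear_series(track)
  expect_equal(e$raw, rep(e$raw[1], 50))
  expect_equal(e$smoothed, e$raw)
  expect_equal(e$raw[1], 0.3, tolerance = 1e-9) # test layout: height/width = 0.03/0.1
  scaled <- transform_track(track, scale = 2)
  expect_equal(ear_series(scaled)$raw, e$raw, tolerance = 1e-12)
  expect_error(ear_series(transform_track(track, scale = 0)),
               class = "pdbiometry_degenerate_geometry")
})

test_that("a planted EAR valley appears in the smoothed series", {
  base <- test_face_base()
  n <- 120
  coords <- array(c(rep(base[, 1], each = n), rep(base[, 2], each = n)),
                  dim = c(n, nrow(base), 2L),
                  dimnames = list(NULL, rownames(base), c("x", "y")))
  # close both eyes to 20% of baseline height over frames 40..45
  for (side in c("r", "l")) {
    top <- paste0("eye_", side, "_top"); bot <- paste0("eye_", side, "_bottom")
    mid <- (base[top, 2] + base[bot, 2]) / 2
    half <- (base[bot, 2] - base[top, 2]) / 2
    coords[40:45, top, 2] <- mid - half * 0.2
    coords[40:45, bot, 2] <- mid + half * 0.2
  }
  track <- landmark_track(coords, 30, default_landmark_schema())
  e <- ear_series(track)
  expect_lt(min(e$smoothed[40:70]), 0.95 * e$raw[1]) # valley is smeared over the window
  expect_equal(which.min(e$raw), 40)
})

test_that("blink fractions are nested across the four thresholds", {
  tracks <- c(lapply(1:20, random_track),
              lapply(21:25, function(s) {
                simulate_face(list(blink_rate = 10, blink_depth = 0.9,
                                   mouth_amp = 0.01), seed = s)$track
              }))
  for (track in tracks) {
    e <- ear_series(track)
    fr <- vapply(c(30, 50, 70, 90), function(th) blink_fraction(e, th), numeric(1))
    expect_true(all(diff(fr) >= 0))
  }
  # constant EAR: no frame sits below any fraction of the mean
  e0 <- ear_series(static_track(40))
  for (th in c(30, 50, 70, 90)) expect_equal(blink_fraction(e0, th), 0)
})

test_that("motion variances vanish on a static face", {
  track <- static_track(n = 40)
  expect_equal(mouth_eye_distance_variance(track, "right"), 0)
  expect_equal(mouth_eye_distance_variance(track, "left"), 0)
  expect_equal(mouth_height_variance(track), 0)
  expect_equal(mouth_width_variance(track), 0)
  expect_equal(mouth_angle_variance(track), 0)
  expect_equal(perioral_variance(track, "right"), 0)
  expect_equal(perioral_variance(track, "left"), 0)
  feats <- extract_facial_features(track)
  num <- unlist(feats[setdiff(names(feats), "subject_id")])
  expect_true(all(num == 0))
})

test_that("variances are invariant to translation and uniform scale; angle to rotation", {
  track <- random_track(31)
  all_feats <- function(tr) {
    c(me_r = mouth_eye_distance_variance(tr, "right"),
      me_l = mouth_eye_distance_variance(tr, "left"),
      mh = mouth_height_variance(tr), mw = mouth_width_variance(tr),
      pa_r = perioral_variance(tr, "right"), pa_l = perioral_variance(tr, "left"))
  }
  f0 <- all_feats(track)
  expect_equal(all_feats(transform_track(track, dx = 0.3, dy = -0.2)), f0,
               tolerance = 1e-12)
  expect_equal(all_feats(transform_track(track, scale = 3.7)), f0,
               tolerance = 1e-12)
  a0 <- mouth_angle_variance(track)
  expect_equal(mouth_angle_variance(rotate_track(track, 0.8)), a0, tolerance = 1e-9)
  # rigid rotation of a static face keeps the crossing angle fixed
  static <- static_track(30)
  coords <- static$coords
  for (t in seq_len(30)) {
    th <- 0.02 * t
    x <- coords[t, , 1] - 0.5; y <- coords[t, , 2] - 0.5
    coords[t, , 1] <- 0.5 + cos(th) * x - sin(th) * y
    coords[t, , 2] <- 0.5 + sin(th) * x + cos(th) * y
  }
  spinning <- landmark_track(coords, 30, static$schema)
  expect_equal(mouth_angle_variance(spinning), 0, tolerance = 1e-9)
})

test_that("each variance equals the naive frame-loop oracle on random tracks", {
  for (s in 1:100) {
    track <- random_track(1000 + s, n = sample(5:40, 1))
    sc <- track$schema
    expect_equal(mouth_eye_distance_variance(track, "right"),
                 oracle_motion_variance(track, sc$eye_right$outer, sc$mouth_corner_right),
                 tolerance = 1e-12)
    expect_equal(mouth_height_variance(track),
                 oracle_motion_variance(track, sc$upper_lip, sc$lower_lip),
                 tolerance = 1e-12)
    expect_equal(mouth_width_variance(track),
                 oracle_motion_variance(track, sc$mouth_corner_right, sc$mouth_corner_left),
                 tolerance = 1e-12)
    expect_equal(mouth_angle_variance(track), oracle_angle_variance(track),
                 tolerance = 1e-12)
    expect_equal(perioral_variance(track, "left"),
                 oracle_perioral_variance(track, "left"),
                 tolerance = 1e-12)
  }
})

test_that("pure horizontal mouth stretch moves width but not height variance", {
  base <- test_face_base()
  n <- 60
  coords <- array(c(rep(base[, 1], each = n), rep(base[, 2], each = n)),
                  dim = c(n, nrow(base), 2L),
                  dimnames = list(NULL, rownames(base), c("x", "y")))
  stretch <- 0.01 * sin(2 * pi * seq_len(n) / 20)
  coords[, "mouth_r", 1] <- base["mouth_r", 1] - stretch
  coords[, "mouth_l", 1] <- base["mouth_l", 1] + stretch
  track <- landmark_track(coords, 30, default_landmark_schema())
  expect_gt(mouth_width_variance(track), 0)
  expect_equal(mouth_height_variance(track), 0)
})

test_that("swapping the left/right schema roles swaps side-specific features", {
  track <- random_track(77)
  sc <- track$schema
  swapped <- landmark_schema(
    eye_right = sc$eye_left, eye_left = sc$eye_right,
    mouth_corner_right = sc$mouth_corner_left,
    mouth_corner_left = sc$mouth_corner_right,
    upper_lip = sc$upper_lip, lower_lip = sc$lower_lip,
    nose_center = sc$nose_center,
    perioral_right = sc$perioral_left, perioral_left = sc$perioral_right,
    face_width_pair = sc$face_width_pair)
  track2 <- landmark_track(track$coords, track$fps, swapped)
  expect_identical(mouth_eye_distance_variance(track2, "right"),
                   mouth_eye_distance_variance(track, "left"))
  expect_identical(perioral_variance(track2, "left"),
                   perioral_variance(track, "right"))
})

test_that("degenerate geometry is reported with the frame", {
  track <- static_track(10)
  coords <- track$coords
  coords[4, "face_l", ] <- coords[4, "face_r", ]
  broken <- landmark_track(coords, 30, track$schema)
  expect_error(mouth_width_variance(broken), "4",
               class = "pdbiometry_degenerate_geometry")
  coords2 <- track$coords
  coords2[, "lip_lower", ] <- coords2[, "lip_upper", ]
  flat <- landmark_track(coords2, 30, track$schema)
  expect_error(mouth_angle_variance(flat), class = "pdbiometry_degenerate_geometry")
})
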