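test_that("a clean tone with no pauses extracts as silence-free monotone speech", {
  sv <- simulate_voice(list(speech_seconds = 6, pause_fraction = 0,
                            volume_drift = 0, f0 = 150, f0_jitter = 0),
                       seed = 1, sample_rate = 16000)
  f <- extract_voice_features(sv$signal)
  expect_equal(f$pause_pct, 0)
  expect_equal(f$pitch_var, 0, tolerance = 1e-9)
  expect_lt(abs(f$volume_var), 1)
  expect_equal(f$reading_time, 6)
})

test_that("planted pause fraction, F0 and drift sign are recovered", {
  for (s in 1:5) {
    sv <- simulate_voice(list(speech_seconds = 10, pause_fraction = 0.25,
                              volume_drift = 0, f0 = 160, f0_jitter = 6),
                         seed = s, sample_rate = 16000)
    f <- extract_voice_features(sv$signal)
    expect_lt(abs(f$pause_pct - 100 * sv$truth$pause_fraction), 2)
    expect_lt(abs(f$avg_pitch - 160) / 160, 0.05)
  }
  fading <- simulate_voice(list(speech_seconds = 8, pause_fraction = 0.1,
                                volume_drift = -0.3, f0 = 140, f0_jitter = 5),
                           seed = 2, sample_rate = 16000)
  expect_gt(extract_voice_features(fading$signal)$volume_var, 0)
})

test_that("a motionless face simulates to all-zero facial features", {
  sf <- simulate_face(list(blink_rate = 0, blink_depth = 0.9, mouth_amp = 0),
                      seed = 3, coord_noise = 0, drift = FALSE, seconds = 10)
  feats <- extract_facial_features(sf$track)
  num <- unlist(feats[setdiff(names(feats), "subject_id")])
  expect_true(all(num == 0))
  expect_equal(sf$truth$n_blinks, 0)
})

test_that("planted blink time is recovered within 20% at the 50% threshold", {
  total_truth <- 0
  total_est <- 0
  for (s in 1:10) {
    sf <- simulate_face(list(blink_rate = 8, blink_depth = 0.95, mouth_amp = 0.01),
                        seed = 100 + s)
    n <- dim(sf$track$coords)[1]
    est <- extract_facial_features(sf$track)$blink_50 * n
    total_truth <- total_truth + sf$truth$blink_frames_50
    total_est <- total_est + est
  }
  expect_lt(abs(total_est - total_truth) / total_truth, 0.2)
})

test_that("global zoom and translation drift barely move any facial feature", {
  p <- list(blink_rate = 6, blink_depth = 0.9, mouth_amp = 0.01)
  f_plain <- extract_facial_features(simulate_face(p, seed = 9, drift = FALSE)$track)
  f_drift <- extract_facial_features(simulate_face(p, seed = 9, drift = TRUE)$track)
  num <- setdiff(names(f_plain), "subject_id")
  expect_equal(unlist(f_drift[num]), unlist(f_plain[num]), tolerance = 1e-3)
  for (col in num) {
    expect_lt(abs(f_drift[[col]] - f_plain[[col]]), 1e-4)
  }
})

test_that("the simulated study has two disjoint, labeled, reproducible cohorts", {
  cfg <- cohort_config(n_per_group = 3, seed = 5, video_seconds = 8,
                       sample_rate = 8000)
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_named(sim1, c("train", "validation"))
  expect_length(sim1$train$audio, 6)
  expect_identical(sim1$train$audio[[1]]$samples, sim2$train$audio[[1]]$samples)
  expect_identical(sim1$validation$tracks[[3]]$coords,
                   sim2$validation$tracks[[3]]$coords)
  expect_length(intersect(sim1$train$meta$subject_id,
                          sim1$validation$meta$subject_id), 0)
  expect_setequal(unique(sim1$train$meta$label), c("control", "PD"))
  # PD training subjects are "on" phase; validation PD are off/drug-naive
  expect_true(all(sim1$train$meta$phase[sim1$train$meta$label == "PD"] == "on"))
  expect_true(all(sim1$validation$meta$phase[sim1$validation$meta$label == "PD"]
                  %in% c("off", "drug_naive")))
  # different seed, different draw
  sim3 <- simulate_cohort(cohort_config(n_per_group = 3, seed = 6,
                                        video_seconds = 8, sample_rate = 8000))
  expect_false(identical(sim1$train$audio[[1]]$samples,
                         sim3$train$audio[[1]]$samples))
})

test_that("effect_scale 0 makes the groups exchangeable in expectation", {
  cfg0 <- cohort_config(n_per_group = 12, seed = 11, effect_scale = 0,
                        video_seconds = 10, sample_rate = 8000)
  sim <- simulate_feature_table(cfg0, cohorts = "train")
  tbl <- sim$train$table
  truth <- sim$train$truth
  pd <- grepl("_PD_", truth$subject_id)
  # planted parameters come from the same distribution in both groups
  expect_lt(abs(mean(truth$pause_fraction[pd]) - mean(truth$pause_fraction[!pd])), 0.08)
  expect_lt(abs(mean(truth$blink_depth[pd]) - mean(truth$blink_depth[!pd])), 0.08)
  expect_identical(nrow(tbl), 24L)
})

test_that("cohort feature tables carry ground truth aligned by subject", {
  cfg <- cohort_config(n_per_group = 4, seed = 2, video_seconds = 10,
                       sample_rate = 8000)
  sim <- simulate_feature_table(cfg, cohorts = "train")
  expect_identical(sort(sim$train$table$subject_id), sort(sim$train$truth$subject_id))
  expect_true(all(feature_columns() %in% names(sim$train$table)))
  expect_false(anyNA(sim$train$table[feature_columns()]))
})
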