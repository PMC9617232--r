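test_that("frame volume is the per-frame mean absolute amplitude", {
  sig <- blocky_signal(c(10, 300, 10))
  v <- frame_volume(sig)
  expect_equal(v$values, c(10, 300, 10))
  expect_equal(frame_volume(blocky_signal(rep(200, 5)))$values, rep(200, 5))
  expect_equal(frame_volume(blocky_signal(rep(0, 4)))$values, rep(0, 4))
  # trailing partial frame is dropped
  sig2 <- audio_signal(rep(50, floor(44100 * 0.025) * 2 + 17))
  expect_length(frame_volume(sig2)$values, 2)
  expect_error(frame_volume(audio_signal(rep(1, 100))),
               class = "pdbiometry_input_error")
})

test_that("pause threshold follows the strict mean-volume rule", {
  mk <- function(vals) frame_series(vals, 0.025, "volume")
  expect_equal(pause_threshold(mk(c(150, 150))), 30)
  expect_equal(pause_threshold(mk(c(100, 100))), 20) # strictly 'larger than'
  expect_equal(pause_threshold(mk(c(5, 5))), 20)
  expect_equal(pause_threshold(mk(c(100.5, 100.5))), 30)
})

test_that("pause percentage counts frames below the adaptive threshold", {
  mk <- function(vals) frame_series(vals, 0.025, "volume")
  expect_equal(pause_percentage(mk(rep(200, 10))), 0)
  expect_equal(pause_percentage(mk(c(5, 5, 200, 200))), 50) # mean 102.5 -> thr 30
  expect_equal(pause_percentage(mk(rep(0, 8))), 100)
  # matches the brute-force frame count on random inputs
  for (s in 1:100) {
    set.seed(s)
    vals <- runif(sample(5:200, 1), 0, 400)
    fs <- mk(vals)
    thr <- if (mean(vals) > 100) 30 else 20
    expect_equal(pause_percentage(fs),
                 100 * oracle_pause_count(vals, thr) / length(vals),
                 tolerance = 1e-14)
  }
})

test_that("volume variance contrasts first and second half x100", {
  mk <- function(vals) frame_series(vals, 0.025, "volume")
  expect_equal(volume_variance(mk(rep(120, 9))), 0)
  expect_equal(volume_variance(mk(c(100, 100, 200, 200))), 100 * (100 - 200) / 150)
  # middle frame joins the first half on odd lengths
  expect_equal(volume_variance(mk(c(100, 100, 100, 200, 200))),
               100 * (100 - 200) / 140)
  # reversing negates for equal-length halves
  set.seed(1)
  vals <- runif(40, 10, 300)
  expect_equal(volume_variance(mk(rev(vals))), -volume_variance(mk(vals)))
  expect_equal(volume_variance(mk(vals), scale = 1),
               volume_variance(mk(vals)) / 100)
  expect_error(volume_variance(mk(rep(0, 4))), class = "pdbiometry_undefined_feature")
})

test_that("zero-crossing counts match the brute-force scan", {
  expect_true(all(zero_crossings(blocky_signal(rep(500, 4)))$values == 0))
  sig <- sine_signal(100, seconds = 1)
  expect_true(all(zero_crossings(sig)$values == 2))
  for (s in 1:100) {
    set.seed(200 + s)
    n <- sample(300:2000, 1)
    x <- round(rnorm(n, 0, 100))
    x[sample(n, n %/% 10)] <- 0 # zero plateaus exercise the sign-carry rule
    sig <- audio_signal(x, sample_rate = 8000)
    spf <- floor(8000 * 0.01)
    expect_identical(zero_crossings(sig, 0.01)$values,
                     as.double(oracle_zero_crossings(x, spf)))
  }
})

test_that("a zero touch counts as one crossing, not two", {
  # +, 0, - : one crossing; +, 0, + : none
  sig1 <- audio_signal(rep(c(5, 0, -5, 0), 25), sample_rate = 1000) # spf 10
  sig2 <- audio_signal(rep(c(5, 0, 5, 0), 25), sample_rate = 1000)
  expect_equal(sum(zero_crossings(sig1, 0.01)$values), 49)
  expect_equal(sum(zero_crossings(sig2, 0.01)$values), 0)
})

test_that("average pitch recovers pure-tone frequency and scales linearly", {
  f1 <- average_pitch(zero_crossings(sine_signal(110, 2)))
  f2 <- average_pitch(zero_crossings(sine_signal(220, 2)))
  expect_lt(abs(f1 - 110) / 110, 0.05)
  expect_lt(abs(f2 - 220) / 220, 0.05)
  expect_lt(abs(f2 / f1 - 2), 0.05)
  cz <- frame_series(c(3, 3, 3), 0.01, "crossings")
  expect_equal(average_pitch(cz), 150)
  expect_equal(average_pitch(cz, hz = FALSE), 3)
  expect_error(average_pitch(cz, voiced = rep(FALSE, 3)),
               class = "pdbiometry_undefined_feature")
})

test_that("pitch variance is the mean absolute crossing difference in Hz", {
  cz <- frame_series(c(2, 4, 2, 4), 0.01, "crossings")
  expect_equal(pitch_variance(cz), 100) # mean |diff| = 2 counts -> 100 Hz
  expect_equal(pitch_variance(frame_series(rep(3, 50), 0.01, "crossings")), 0)
  # order matters: a permutation changes the value
  cz_sorted <- frame_series(c(2, 2, 4, 4), 0.01, "crossings")
  expect_false(isTRUE(all.equal(pitch_variance(cz), pitch_variance(cz_sorted))))
  expect_error(pitch_variance(frame_series(c(2, 4), 0.01, "crossings"),
                              voiced = c(TRUE, FALSE)),
               class = "pdbiometry_undefined_feature")
})

test_that("reading time spans first to last speech frame and ignores padding", {
  vals <- rep(0, 100)
  vals[10:49] <- 200
  expect_equal(reading_time(frame_series(vals, 0.025, "volume")), 1.0)
  expect_equal(reading_time(frame_series(rep(200, 80), 0.025, "volume")), 2.0)
  padded <- c(rep(0, 30), rep(200, 80), rep(0, 15))
  expect_equal(reading_time(frame_series(padded, 0.025, "volume")), 2.0)
  expect_error(reading_time(frame_series(rep(0, 10), 0.025, "volume")),
               class = "pdbiometry_undefined_feature")
})

test_that("voiced mask maps 25 ms pause decisions onto the 10 ms grid", {
  # frames: 0.5 s speech, 0.5 s silence, 0.5 s speech at 8 kHz
  spf <- floor(8000 * 0.025)
  x <- c(rep(c(300, -300), each = 1, times = 10 * spf / 2),
         rep(0, 20 * spf),
         rep(c(300, -300), times = 10 * spf / 2))
  sig <- audio_signal(x, 8000)
  vols <- frame_volume(sig)
  cz <- zero_crossings(sig)
  mask <- voiced_mask(vols, cz)
  # 1 s total: speech 0-0.25 s, silence 0.25-0.75 s, speech 0.75-1 s;
  # interior pitch frames away from the boundaries are unambiguous
  expect_true(all(mask[2:24]))
  expect_false(any(mask[27:74]))
  expect_true(all(mask[77:99]))
})

test_that("voice features are invariant to sign flip, pitch to scaling", {
  sv <- simulate_voice(list(speech_seconds = 6, pause_fraction = 0.2,
                            volume_drift = 0.1, f0 = 140, f0_jitter = 8),
                       seed = 21, sample_rate = 16000)
  f0 <- extract_voice_features(sv$signal)
  flipped <- audio_signal(-sv$signal$samples, 16000)
  f_flip <- extract_voice_features(flipped)
  expect_equal(f_flip[-1], f0[-1], tolerance = 1e-12)
  scaled <- audio_signal(sv$signal$samples * 0.5, 16000)
  f_scaled <- extract_voice_features(scaled)
  expect_equal(f_scaled$avg_pitch, f0$avg_pitch, tolerance = 1e-12)
  expect_equal(f_scaled$pitch_var, f0$pitch_var, tolerance = 1e-12)
})
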