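#' Synthetic cohort configuration
#'
#' Defines the study conditions for the synthetic PD/control cohorts: group
#' distributions for the plantable ground-truth parameters, recording
#' geometry (sample rate, fps, video length), and an `effect_scale`
#' multiplier on the group separation (0 makes the groups exchangeable).
#'
#' Group effects are planted only in the features that separate the groups
#' in clinical cohorts — speech duration, pause fraction, volume drift,
#' pitch jitter, blink rate and depth; average pitch and all mouth-motion
#' parameters are drawn identically in both groups so the selection stage
#' has true negatives to reject.
#'
#' @param n_per_group Subjects per group per cohort (default 100).
#' @param seed Master seed.
#' @param fps Video frame rate (default 30).
#' @param video_seconds Facial recording length in seconds (default 30).
#' @param sample_rate Audio sampling rate in Hz (default 44100).
#' @param effect_scale Multiplier on the PD-vs-control mean differences
#'   (default 1; 0 = null cohort).
#' @param blink_duration_frames Length of one blink valley in frames
#'   (default 60; long relative to the 30-frame EAR smoothing window so the
#'   smoothed valley crosses the relative thresholds).
#' @param coord_noise SD of per-frame landmark jitter (default 1e-5).
#' @param groups Named list `control`/`pd`, each a named list of
#'   `c(mean, sd)` pairs for: `speech_seconds`, `pause_fraction`,
#'   `volume_drift`, `f0`, `f0_jitter`, `blink_rate` (per minute),
#'   `blink_depth` (fraction of baseline eye closure), `mouth_amp`
#'   (normalized oscillation amplitude). Defaults emulate the direction and
#'   approximate magnitude of reported clinical group differences, with
#'   speech duration scaled down for desk-size runs.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 100L, seed = 1L, fps = 30,
                          video_seconds = 30, sample_rate = 44100,
                          effect_scale = 1, blink_duration_frames = 60L,
                          coord_noise = 1e-5,
                          groups = default_group_params()) {
  if (n_per_group < 2L) pdb_stop("input_error", "n_per_group must be >= 2")
  if (!all(c("control", "pd") %in% names(groups))) {
    pdb_stop("input_error", "groups must contain 'control' and 'pd'")
  }
  for (g in groups) {
    sds <- vapply(g, `[`, numeric(1), 2L)
    if (any(sds < 0)) pdb_stop("input_error", "group parameter sds must be >= 0")
  }
  structure(list(n_per_group = as.integer(n_per_group), seed = as.integer(seed),
                 fps = fps, video_seconds = video_seconds,
                 sample_rate = sample_rate, effect_scale = effect_scale,
                 blink_duration_frames = as.integer(blink_duration_frames),
                 coord_noise = coord_noise, groups = groups),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_group_params <- function() {
  list(
    control = list(
      speech_seconds = c(12, 2),
      pause_fraction = c(0.134, 0.073),
      volume_drift   = c(0.016, 0.20),
      f0             = c(157, 32),
      f0_jitter      = c(15, 4),
      blink_rate     = c(8, 2),
      blink_depth    = c(0.95, 0.03),
      mouth_amp      = c(0.010, 0.003)
    ),
    pd = list(
      speech_seconds = c(14, 2.5),
      pause_fraction = c(0.21, 0.10),
      volume_drift   = c(0.052, 0.20),
      f0             = c(157, 32),     # not discriminative: same as control
      f0_jitter      = c(7, 3),
      blink_rate     = c(5, 2),
      blink_depth    = c(0.80, 0.08),
      mouth_amp      = c(0.010, 0.003) # not discriminative: same as control
    )
  )
}

param_bounds <- list(
  speech_seconds = c(6, 40), pause_fraction = c(0.02, 0.55),
  volume_drift = c(-0.7, 0.7), f0 = c(90, 280), f0_jitter = c(0.5, 40),
  blink_rate = c(0.5, 20), blink_depth = c(0.30, 0.99),
  mouth_amp = c(0.001, 0.05)
)

clip <- function(x, b) pmin(b[2], pmax(b[1], x))

draw_subject_params <- function(config, group, seed) {
  ctl <- config$groups$control
  grp <- config$groups[[group]]
  with_seed(seed, {
    out <- lapply(names(grp), function(p) {
      # both the mean shift and the dispersion difference are group effects,
      # so effect_scale = 0 makes the groups exactly exchangeable
      mu <- ctl[[p]][1] + config$effect_scale * (grp[[p]][1] - ctl[[p]][1])
      sd <- ctl[[p]][2] + config$effect_scale * (grp[[p]][2] - ctl[[p]][2])
      clip(stats::rnorm(1, mu, sd), param_bounds[[p]])
    })
    stats::setNames(out, names(grp))
  })
}

#' Simulate one subject's voice recording
#'
#' Alternating voiced/pause structure on the 25 ms frame grid (aligned to
#' the extractor's sample-per-frame blocking so the planted pause fraction
#' is exactly recoverable): voiced frames carry a phase-continuous sinusoid
#' whose instantaneous frequency is redrawn every 10 ms around `f0` with SD
#' `f0_jitter`, under a linear amplitude drift `volume_drift`; pause frames
#' are a near-silence floor (small positive samples, so they produce no
#' spurious zero crossings). The first and last frames are always voiced.
#'
#' @param params List with `speech_seconds`, `pause_fraction`,
#'   `volume_drift`, `f0`, `f0_jitter` (see [default_group_params()]).
#' @param seed Seed.
#' @param sample_rate Hz (default 44100).
#' @param subject_id Optional id.
#' @param amplitude Peak voiced amplitude on the 16-bit scale (default 3000).
#' @return List with `signal` (an [audio_signal()]) and `truth`: the planted
#'   `pause_fraction` (realized, on the frame grid), `reading_time`, `f0`,
#'   `f0_jitter`, `volume_drift` and the expected sign of volume variance.
#' @export
simulate_voice <- function(params, seed = 1L, sample_rate = 44100,
                           subject_id = NULL, amplitude = 3000) {
  fd <- 0.025
  spf <- as.integer(floor(sample_rate * fd))        # extractor-aligned frame
  n_frames <- max(4L, round(params$speech_seconds / fd))
  with_seed(seed, {
    pause <- rep(FALSE, n_frames)
    target_pause <- round(params$pause_fraction * n_frames)
    guard <- 0L
    while (sum(pause) < target_pause && guard < 10L * n_frames) {
      guard <- guard + 1L
      len <- min(1L + stats::rgeom(1, 1 / 8), target_pause - sum(pause),
                 n_frames - 4L)
      avail <- n_frames - len - 2L       # keep first and last frames voiced
      if (avail < 1L) break
      start <- 1L + sample.int(avail, 1L)
      idx <- start:(start + len - 1L)
      if (!any(pause[idx])) pause[idx] <- TRUE
    }
    n_samples <- n_frames * spf
    # instantaneous frequency per 10 ms block, phase-continuous
    block <- as.integer(floor(sample_rate * 0.010))
    n_blocks <- ceiling(n_samples / block)
    f_inst <- rep(pmax(60, stats::rnorm(n_blocks, params$f0, params$f0_jitter)),
                  each = block)[seq_len(n_samples)]
    # fixed phase offset keeps zero crossings off exact sample positions,
    # where floating-point sign noise would jitter the per-frame counts
    phase <- 0.7 + cumsum(2 * pi * f_inst / sample_rate)
    u <- (seq_len(n_samples) - 0.5) / n_samples
    amp <- amplitude * (1 + params$volume_drift * (u - 0.5))
    x <- amp * sin(phase)
    # near-silence floor on pause frames: positive, so zero crossings vanish
    pause_samples <- rep(pause, each = spf)
    x[pause_samples] <- stats::runif(sum(pause_samples), 0.5, 1.5)
    truth <- list(
      pause_fraction = mean(pause),
      reading_time = n_frames * fd,
      f0 = params$f0,
      f0_jitter = params$f0_jitter,
      volume_drift = params$volume_drift,
      volume_variance_sign = -sign(params$volume_drift)
    )
    list(signal = audio_signal(x, sample_rate, subject_id), truth = truth)
  })
}

## Canonical neutral landmark layout (image-normalized units, face width 0.6)
canonical_face <- function() {
  pts <- rbind(
    eye_r_outer = c(0.330, 0.380), eye_r_inner = c(0.420, 0.380),
    eye_r_top = c(0.375, 0.3665), eye_r_bottom = c(0.375, 0.3935),
    eye_l_outer = c(0.670, 0.380), eye_l_inner = c(0.580, 0.380),
    eye_l_top = c(0.625, 0.3665), eye_l_bottom = c(0.625, 0.3935),
    mouth_r = c(0.420, 0.700), mouth_l = c(0.580, 0.700),
    lip_upper = c(0.500, 0.670), lip_lower = c(0.500, 0.730),
    nose = c(0.500, 0.500),
    perioral_r1 = c(0.380, 0.640), perioral_r2 = c(0.360, 0.700),
    perioral_r3 = c(0.380, 0.760), perioral_r4 = c(0.420, 0.800),
    perioral_r5 = c(0.460, 0.820), perioral_r6 = c(0.400, 0.600),
    perioral_l1 = c(0.620, 0.640), perioral_l2 = c(0.640, 0.700),
    perioral_l3 = c(0.620, 0.760), perioral_l4 = c(0.580, 0.800),
    perioral_l5 = c(0.540, 0.820), perioral_l6 = c(0.600, 0.600),
    face_r = c(0.200, 0.500), face_l = c(0.800, 0.500)
  )
  colnames(pts) <- c("x", "y")
  pts
}

#' Simulate one subject's facial landmark track
#'
#' A canonical neutral layout animated with: raised-cosine blink valleys
#' (Poisson count at `blink_rate` per minute, closure depth `blink_depth`,
#' fixed duration), sinusoidal mouth opening/width/corner motion of
#' amplitude `mouth_amp` with matched peri-oral radial motion, small
#' landmark jitter, and a slow global translation plus zoom drift that the
#' face-width-normalized extraction must cancel.
#'
#' @param params List with `blink_rate`, `blink_depth`, `mouth_amp`.
#' @param seed Seed.
#' @param fps Frames per second (default 30).
#' @param seconds Recording length (default 30).
#' @param schema Landmark schema (default [default_landmark_schema()]).
#' @param blink_duration Blink valley length in frames (default 60).
#' @param coord_noise SD of landmark jitter (default 1e-5).
#' @param drift Include global translation/zoom drift (default TRUE).
#' @param smooth_window Trailing-mean window (frames) used to state the
#'   blink ground truth on the same smoothed scale the EAR features use
#'   (default 30).
#' @param subject_id Optional id.
#' @return List with `track` (a [landmark_track()]) and `truth`: `n_blinks`,
#'   `blink_frames_50` (frames whose noiseless, trailing-mean-smoothed eye
#'   closure exceeds 50% of baseline — the planted ground truth for the
#'   50%-threshold blink feature), `blink_depth`, `blink_rate`, `mouth_amp`.
#' @export
simulate_face <- function(params, seed = 1L, fps = 30, seconds = 30,
                          schema = default_landmark_schema(),
                          blink_duration = 60L, coord_noise = 1e-5,
                          drift = TRUE, smooth_window = 30L,
                          subject_id = NULL) {
  n <- as.integer(round(fps * seconds))
  base <- canonical_face()
  ids <- rownames(base)
  with_seed(seed, {
    # blink timing: Poisson count, non-overlapping uniform starts
    n_blinks <- stats::rpois(1, params$blink_rate * seconds / 60)
    closure <- numeric(n)        # planted eye-closure fraction per frame
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < n_blinks && tries < 200L) {
      tries <- tries + 1L
      s <- sample.int(max(1L, n - blink_duration), 1L)
      if (!any(abs(s - starts) < blink_duration + 2L)) starts <- c(starts, s)
    }
    for (s in starts) {
      k <- seq_len(blink_duration)
      w <- (1 - cos(2 * pi * (k - 0.5) / blink_duration)) / 2
      idx <- s + k - 1L
      keep <- idx <= n
      closure[idx[keep]] <- pmax(closure[idx[keep]], params$blink_depth * w[keep])
    }
    tt <- seq_len(n)
    ph <- stats::runif(6, 0, 2 * pi)
    a <- params$mouth_amp
    open_wave <- a * sin(2 * pi * 2.5 * tt / fps + ph[1])
    width_wave <- 0.5 * a * sin(2 * pi * 1.8 * tt / fps + ph[2])
    tilt_wave <- 0.4 * a * sin(2 * pi * 1.3 * tt / fps + ph[3])
    peri_wave <- 0.3 * a

    coords <- array(c(rep(base[, "x"], each = n), rep(base[, "y"], each = n)),
                    dim = c(n, nrow(base), 2L),
                    dimnames = list(NULL, ids, c("x", "y")))
    # blinks: lids move toward the eye center
    for (side in c("r", "l")) {
      top <- paste0("eye_", side, "_top"); bot <- paste0("eye_", side, "_bottom")
      mid <- (base[top, "y"] + base[bot, "y"]) / 2
      half <- (base[bot, "y"] - base[top, "y"]) / 2
      coords[, top, 2L] <- mid - half * (1 - closure)
      coords[, bot, 2L] <- mid + half * (1 - closure)
    }
    # mouth opening / width / corner tilt
    coords[, "lip_lower", 2L] <- base["lip_lower", "y"] + open_wave
    coords[, "lip_upper", 2L] <- base["lip_upper", "y"] - 0.3 * open_wave
    coords[, "mouth_r", 1L] <- base["mouth_r", "x"] - width_wave
    coords[, "mouth_l", 1L] <- base["mouth_l", "x"] + width_wave
    coords[, "mouth_r", 2L] <- base["mouth_r", "y"] + tilt_wave
    coords[, "mouth_l", 2L] <- base["mouth_l", "y"] - tilt_wave
    # peri-oral radial motion around the nose
    nose <- base["nose", ]
    peri_ids <- ids[startsWith(ids, "perioral_")]
    for (j in seq_along(peri_ids)) {
      p <- peri_ids[j]
      dir <- base[p, ] - nose
      dir <- dir / sqrt(sum(dir^2))
      wav <- peri_wave * sin(2 * pi * 2.2 * tt / fps + ph[4] + j)
      coords[, p, 1L] <- base[p, "x"] + dir["x"] * wav
      coords[, p, 2L] <- base[p, "y"] + dir["y"] * wav
    }
    if (coord_noise > 0) {
      coords <- coords + stats::rnorm(length(coords), 0, coord_noise)
    }
    if (drift) {
      u <- (tt - 1) / max(1L, n - 1L)
      scale_t <- 1 + 0.01 * sin(pi * u)
      coords[, , 1L] <- 0.5 + (coords[, , 1L] - 0.5) * scale_t + 0.02 * u
      coords[, , 2L] <- 0.5 + (coords[, , 2L] - 0.5) * scale_t + 0.01 * u
    }
    truth <- list(
      n_blinks = length(starts),
      blink_frames_50 = sum(trailing_mean(closure, smooth_window) > 0.5),
      blink_rate = params$blink_rate,
      blink_depth = params$blink_depth,
      mouth_amp = params$mouth_amp
    )
    list(track = landmark_track(coords, fps = fps, schema = schema,
                                subject_id = subject_id),
         truth = truth)
  })
}

simulate_subject <- function(config, group, index, cohort_tag) {
  sid <- sprintf("%s_%s_%03d", cohort_tag, ifelse(group == "pd", "PD", "C"), index)
  base_seed <- derive_seed(config$seed, match(cohort_tag, c("train", "validation")),
                           match(group, c("control", "pd")), index)
  params <- draw_subject_params(config, group, derive_seed(base_seed, 1L))
  voice <- simulate_voice(params, seed = derive_seed(base_seed, 2L),
                          sample_rate = config$sample_rate, subject_id = sid)
  face <- simulate_face(params, seed = derive_seed(base_seed, 3L),
                        fps = config$fps, seconds = config$video_seconds,
                        blink_duration = config$blink_duration_frames,
                        coord_noise = config$coord_noise, subject_id = sid)
  meta <- with_seed(derive_seed(base_seed, 4L), {
    stage <- if (group == "pd") {
      sample(c(1, 2, 3), 1L, prob = c(0.35, 0.45, 0.20))
    } else NA_real_
    # age shift (younger early PD, older advanced PD) is a group difference,
    # so it is scaled by effect_scale like every other planted effect
    age_shift <- if (group == "pd") -2.5 + ifelse(stage >= 3, 5, 0) else 0
    age_mu <- 68.5 + config$effect_scale * age_shift
    data.frame(
      subject_id = sid,
      age = clip(stats::rnorm(1, age_mu, 9), c(45, 90)),
      sex = ifelse(index %% 2L == 0L, "male", "female"),
      label = ifelse(group == "pd", "PD", "control"),
      stage = stage,
      phase = if (group == "pd") {
        if (cohort_tag == "train") "on" else sample(c("off", "drug_naive"), 1L, prob = c(2 / 3, 1 / 3))
      } else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  list(id = sid, params = params, voice = voice, face = face, meta = meta)
}

#' Simulate a two-cohort study
#'
#' Draws per-subject parameters from the group distributions and generates
#' audio plus landmark tracks for two independent cohorts (training and
#' validation) with distinct sub-seeds, mirroring a train-on-"on"-phase /
#' validate-on-"off"-phase design. Ground truth for every planted parameter
#' is recorded per subject.
#'
#' @param config A [cohort_config()].
#' @param cohorts Which cohorts to generate (default both).
#' @return Named list of cohorts; each cohort is a list with `audio` (named
#'   list of [audio_signal()]), `tracks` (named list of [landmark_track()]),
#'   `meta` (subject metadata `data.frame`) and `truth` (planted ground
#'   truth `data.frame`).
#' @seealso [simulate_feature_table()] for a memory-light generate-and-
#'   extract path at cohort scale.
#' @export
simulate_cohort <- function(config, cohorts = c("train", "validation")) {
  stopifnot(inherits(config, "cohort_config"))
  out <- list()
  for (tag in cohorts) {
    audio <- list(); tracks <- list(); meta <- list(); truth <- list()
    for (group in c("control", "pd")) {
      for (i in seq_len(config$n_per_group)) {
        s <- simulate_subject(config, group, i, tag)
        audio[[s$id]] <- s$voice$signal
        tracks[[s$id]] <- s$face$track
        meta[[s$id]] <- s$meta
        truth[[s$id]] <- data.frame(subject_id = s$id,
                                    as.data.frame(s$voice$truth),
                                    as.data.frame(s$face$truth),
                                    stringsAsFactors = FALSE)
      }
    }
    out[[tag]] <- list(audio = audio, tracks = tracks,
                       meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
                       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  }
  out
}

#' Simulate and extract cohort feature tables
#'
#' Streams subject-by-subject through generation and feature extraction so
#' raw waveforms and tracks are never all held in memory, and returns ready
#' feature tables plus ground truth for each cohort.
#'
#' @inheritParams simulate_cohort
#' @param feature_set Passed to [build_table()].
#' @return Named list per cohort: `table` (feature table), `meta`, `truth`.
#' @export
simulate_feature_table <- function(config,
                                   feature_set = "combined_plus_demographics",
                                   cohorts = c("train", "validation")) {
  stopifnot(inherits(config, "cohort_config"))
  out <- list()
  for (tag in cohorts) {
    voice_rows <- list(); face_rows <- list(); meta <- list(); truth <- list()
    for (group in c("control", "pd")) {
      for (i in seq_len(config$n_per_group)) {
        s <- simulate_subject(config, group, i, tag)
        voice_rows[[s$id]] <- extract_voice_features(s$voice$signal)
        face_rows[[s$id]] <- extract_facial_features(s$face$track)
        meta[[s$id]] <- s$meta
        truth[[s$id]] <- data.frame(subject_id = s$id,
                                    as.data.frame(s$voice$truth),
                                    as.data.frame(s$face$truth),
                                    stringsAsFactors = FALSE)
      }
    }
    meta_df <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
    tbl <- build_table(voice = do.call(rbind, voice_rows),
                       face = do.call(rbind, face_rows),
                       meta = meta_df, feature_set = feature_set)
    out[[tag]] <- list(table = tbl, meta = meta_df,
                       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  }
  out
}
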