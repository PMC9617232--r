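# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (frame-by-frame loops, all-pairs counts) and shares no
# code with the package internals it checks.

oracle_zero_crossings <- function(samples, spf) {
  n <- length(samples)
  nf <- n %/% spf
  counts <- numeric(nf)
  last_sign <- 0
  last_idx <- 0L
  for (i in seq_len(nf * spf)) {
    s <- sign(samples[i])
    if (s != 0) {
      if (last_sign != 0 && s != last_sign) {
        f <- ((i - 1L) %/% spf) + 1L
        # the crossing sits between last nonzero sample and i; credited to
        # the frame of the later sample of the adjacent pair (i-1, i)
        counts[f] <- counts[f] + 1L
      }
      last_sign <- s
      last_idx <- i
    }
  }
  counts
}

oracle_pause_count <- function(volumes, threshold) {
  n_pause <- 0L
  for (v in volumes) if (v < threshold) n_pause <- n_pause + 1L
  n_pause
}

oracle_auroc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  total <- 0
  for (a in sp) {
    for (b in sn) {
      if (a > b) total <- total + 1
      else if (a == b) total <- total + 0.5
    }
  }
  total / (length(sp) * length(sn))
}

# distances straight from the coordinate array, frame loop, no vectorization
track_dist <- function(track, id_a, id_b, frame) {
  a <- track$coords[frame, id_a, ]
  b <- track$coords[frame, id_b, ]
  sqrt(sum((a - b)^2))
}

oracle_motion_variance <- function(track, id_a, id_b) {
  n <- dim(track$coords)[1]
  fw <- track$schema$face_width_pair
  total <- 0
  for (t in 2:n) {
    d_now <- track_dist(track, id_a, id_b, t)
    d_prev <- track_dist(track, id_a, id_b, t - 1L)
    width <- track_dist(track, fw[1], fw[2], t)
    total <- total + abs(d_now - d_prev) / width
  }
  total / n
}

oracle_perioral_variance <- function(track, side) {
  n <- dim(track$coords)[1]
  sc <- track$schema
  pts <- if (side == "right") sc$perioral_right else sc$perioral_left
  fw <- sc$face_width_pair
  total <- 0
  for (t in 2:n) {
    width <- track_dist(track, fw[1], fw[2], t)
    for (p in pts) {
      d_now <- track_dist(track, sc$nose_center, p, t)
      d_prev <- track_dist(track, sc$nose_center, p, t - 1L)
      total <- total + abs(d_now - d_prev) / width
    }
  }
  total / n
}

oracle_angle_variance <- function(track) {
  n <- dim(track$coords)[1]
  sc <- track$schema
  ang <- numeric(n)
  for (t in seq_len(n)) {
    v1 <- track$coords[t, sc$mouth_corner_left, ] - track$coords[t, sc$mouth_corner_right, ]
    v2 <- track$coords[t, sc$lower_lip, ] - track$coords[t, sc$upper_lip, ]
    ca <- abs(sum(v1 * v2)) / sqrt(sum(v1^2) * sum(v2^2))
    ang[t] <- acos(min(1, max(0, ca))) * 180 / pi
  }
  total <- 0
  for (t in 2:n) total <- total + abs(ang[t] - ang[t - 1L])
  total / n
}

## ---- fixture builders --------------------------------------------------

# phase-offset sine so no sample lands on a machine-noise zero
sine_signal <- function(freq, seconds = 2, sample_rate = 44100, amp = 3000,
                        phase = 0.7, subject_id = NULL) {
  t <- seq_len(round(seconds * sample_rate)) / sample_rate
  audio_signal(amp * sin(2 * pi * freq * t + phase), sample_rate, subject_id)
}

# signal whose 25 ms frames have prescribed constant absolute amplitudes
blocky_signal <- function(frame_values, sample_rate = 44100, frame_duration = 0.025) {
  spf <- floor(sample_rate * frame_duration)
  audio_signal(rep(frame_values, each = spf), sample_rate)
}

# neutral face layout independent of the generator's canonical layout
test_face_base <- function() {
  rbind(
    eye_r_outer = c(0.30, 0.40), eye_r_inner = c(0.40, 0.40),
    eye_r_top = c(0.35, 0.385), eye_r_bottom = c(0.35, 0.415),
    eye_l_outer = c(0.70, 0.40), eye_l_inner = c(0.60, 0.40),
    eye_l_top = c(0.65, 0.385), eye_l_bottom = c(0.65, 0.415),
    mouth_r = c(0.40, 0.68), mouth_l = c(0.60, 0.68),
    lip_upper = c(0.50, 0.65), lip_lower = c(0.50, 0.72),
    nose = c(0.50, 0.52),
    perioral_r1 = c(0.36, 0.62), perioral_r2 = c(0.34, 0.68),
    perioral_r3 = c(0.36, 0.74), perioral_r4 = c(0.40, 0.78),
    perioral_r5 = c(0.44, 0.80), perioral_r6 = c(0.38, 0.58),
    perioral_l1 = c(0.64, 0.62), perioral_l2 = c(0.66, 0.68),
    perioral_l3 = c(0.64, 0.74), perioral_l4 = c(0.60, 0.78),
    perioral_l5 = c(0.56, 0.80), perioral_l6 = c(0.62, 0.58),
    face_r = c(0.18, 0.50), face_l = c(0.82, 0.50)
  )
}

static_track <- function(n = 60, fps = 30, base = test_face_base()) {
  ids <- rownames(base)
  coords <- array(c(rep(base[, 1], each = n), rep(base[, 2], each = n)),
                  dim = c(n, length(ids), 2L),
                  dimnames = list(NULL, ids, c("x", "y")))
  landmark_track(coords, fps = fps, schema = default_landmark_schema())
}

# smooth random motion on every landmark (random-walk low-pass), guaranteed
# non-degenerate geometry
random_track <- function(seed, n = 40, amp = 0.004) {
  set.seed(seed)
  base <- test_face_base()
  ids <- rownames(base)
  coords <- array(0, dim = c(n, length(ids), 2L),
                  dimnames = list(NULL, ids, c("x", "y")))
  for (j in seq_along(ids)) {
    for (k in 1:2) {
      wiggle <- if (n >= 8) {
        w <- stats::filter(rnorm(n, 0, amp), rep(1 / 4, 4), sides = 1)
        w[is.na(w)] <- 0
        w
      } else {
        rnorm(n, 0, amp / 2)
      }
      coords[, j, k] <- base[ids[j], k] + wiggle
    }
  }
  landmark_track(coords, fps = 30, schema = default_landmark_schema())
}

transform_track <- function(track, scale = 1, dx = 0, dy = 0) {
  coords <- track$coords
  coords[, , 1] <- coords[, , 1] * scale + dx
  coords[, , 2] <- coords[, , 2] * scale + dy
  landmark_track(coords, fps = track$fps, schema = track$schema,
                 subject_id = track$subject_id)
}

rotate_track <- function(track, theta) {
  coords <- track$coords
  x <- coords[, , 1] - 0.5
  y <- coords[, , 2] - 0.5
  coords[, , 1] <- 0.5 + cos(theta) * x - sin(theta) * y
  coords[, , 2] <- 0.5 + sin(theta) * x + cos(theta) * y
  landmark_track(coords, fps = track$fps, schema = track$schema)
}

# planted-signal classification table: one feature separates, rest is noise
planted_table <- function(seed, n = 60, p_noise = 7, informative = "signal") {
  set.seed(seed)
  label <- factor(rep(c("control", "PD"), each = n / 2), levels = c("control", "PD"))
  df <- data.frame(subject_id = sprintf("S%03d", seq_len(n)))
  df[[informative]] <- ifelse(label == "PD", 1, 0) + rnorm(n, 0, 0.1)
  for (j in seq_len(p_noise)) df[[paste0("noise", j)]] <- rnorm(n)
  df$label <- label
  df
}
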