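#' Short-time frame series
#'
#' Per-frame scalar sequence produced by frame blocking: either the frame
#' volume (mean absolute amplitude on the 16-bit scale, 25 ms frames) or the
#' zero-crossing count (10 ms frames). Trailing partial frames are dropped.
#'
#' @param values Numeric per-frame values.
#' @param frame_duration Frame length in seconds.
#' @param kind `"volume"` or `"crossings"`.
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(values, frame_duration, kind = c("volume", "crossings")) {
  kind <- match.arg(kind)
  if (!is.numeric(values) || length(values) == 0L) {
    pdb_stop("input_error", "frame series must be non-empty numeric")
  }
  if (frame_duration <= 0) pdb_stop("input_error", "frame_duration must be > 0")
  structure(list(values = as.double(values), frame_duration = frame_duration,
                 kind = kind),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series:%s> %d frames x %g ms\n", x$kind,
              length(x$values), x$frame_duration * 1000))
  invisible(x)
}

samples_per_frame <- function(signal, frame_duration) {
  spf <- floor(signal$sample_rate * frame_duration)
  if (spf < 1L || length(signal$samples) < spf) {
    pdb_stop("input_error", "signal shorter than one frame")
  }
  as.integer(spf)
}

#' Frame volume
#'
#' Blocks the signal into fixed frames (default 25 ms) and returns the volume
#' of each frame. Volume is the mean absolute amplitude on the 16-bit scale
#' (configurable to RMS); the absolute pause thresholds (30/20, mean cutoff
#' 100) are defined against this statistic.
#'
#' @param signal An [audio_signal()].
#' @param frame_duration Frame length in seconds (default 0.025).
#' @param stat `"mean_abs"` (default) or `"rms"`.
#' @return A [frame_series()] of kind `"volume"`.
#' @export
frame_volume <- function(signal, frame_duration = 0.025, stat = c("mean_abs", "rms")) {
  stat <- match.arg(stat)
  stopifnot(inherits(signal, "audio_signal"))
  spf <- samples_per_frame(signal, frame_duration)
  nf <- length(signal$samples) %/% spf
  m <- matrix(signal$samples[seq_len(nf * spf)], nrow = spf)
  v <- if (stat == "mean_abs") colMeans(abs(m)) else sqrt(colMeans(m^2))
  frame_series(v, frame_duration, "volume")
}

#' Pause threshold rule
#'
#' Adaptive two-level pause threshold: 30 when the participant's mean frame
#' volume exceeds 100 (on the 16-bit mean-absolute-amplitude scale),
#' otherwise 20. The comparison is strict ("larger than 100"), so a mean of
#' exactly 100 yields 20.
#'
#' @param volumes A volume [frame_series()].
#' @return 30 or 20.
#' @export
pause_threshold <- function(volumes) {
  stopifnot(inherits(volumes, "frame_series"), volumes$kind == "volume")
  if (mean(volumes$values) > 100) 30 else 20
}

pause_flags <- function(volumes) volumes$values < pause_threshold(volumes)

#' Pause percentage
#'
#' Percentage of frames whose volume falls below the adaptive
#' [pause_threshold()].
#'
#' @inheritParams pause_threshold
#' @return Percentage in `[0, 100]`.
#' @export
pause_percentage <- function(volumes) {
  100 * mean(pause_flags(volumes))
}

#' Volume variance (temporal drift)
#'
#' Contrast between the average volume of the first and second halves of the
#' recording, normalized by the overall average:
#' `(mean(first half) - mean(second half)) / mean(all)`, reported x100 so the
#' magnitude is a percentage-scale drift. Negative values mean the volume
#' increased over time. With an odd frame count the middle frame joins the
#' first half.
#'
#' @inheritParams pause_threshold
#' @param scale Multiplier on the raw ratio (default 100; set 1 for the raw
#'   ratio).
#' @return Signed drift statistic.
#' @export
volume_variance <- function(volumes, scale = 100) {
  stopifnot(inherits(volumes, "frame_series"), volumes$kind == "volume")
  v <- volumes$values
  n <- length(v)
  if (n < 2L) pdb_stop("input_error", "volume variance needs at least 2 frames")
  total <- mean(v)
  if (total <= 0) pdb_stop("undefined_feature", "total average volume is zero")
  cut <- ceiling(n / 2)
  scale * (mean(v[seq_len(cut)]) - mean(v[(cut + 1L):n])) / total
}

#' Zero-crossing counts per frame
#'
#' Blocks the signal into frames (default 10 ms) and counts sign changes
#' between consecutive samples within each frame. A zero sample adopts the
#' sign of the last nonzero sample, so a single touch of zero counts as one
#' crossing, not two. A crossing between samples `i-1` and `i` is credited to
#' the frame containing sample `i`, so no crossings are lost at frame
#' boundaries.
#'
#' @param signal An [audio_signal()].
#' @param frame_duration Frame length in seconds (default 0.010).
#' @return A [frame_series()] of kind `"crossings"`.
#' @export
zero_crossings <- function(signal, frame_duration = 0.010) {
  stopifnot(inherits(signal, "audio_signal"))
  spf <- samples_per_frame(signal, frame_duration)
  x <- signal$samples
  nf <- length(x) %/% spf
  x <- x[seq_len(nf * spf)]
  s <- sign(x)
  # carry the previous nonzero sign through runs of zeros
  nz <- s != 0
  if (any(nz)) {
    idx <- cumsum(nz)
    carried <- c(0, s[nz])[idx + 1L]
  } else {
    carried <- s
  }
  change <- carried[-1L] != carried[-length(carried)] &
    carried[-1L] != 0 & carried[-length(carried)] != 0
  # crossing i sits between samples i and i+1 -> frame of sample i+1
  frame_of <- ((seq_len(length(x) - 1L)) %/% spf) + 1L
  counts <- tabulate(frame_of[change], nbins = nf)
  frame_series(as.double(counts), frame_duration, "crossings")
}

#' Voiced mask on the pitch-frame grid
#'
#' Maps the 25 ms pause/voiced decision onto the 10 ms zero-crossing grid by
#' time overlap: a pitch frame is voiced when more than half of its duration
#' overlaps non-pause volume frames. Pitch frames beyond the span covered by
#' complete volume frames are treated as unvoiced.
#'
#' @param volumes Volume [frame_series()] (pause decisions).
#' @param crossings Crossings [frame_series()] (target grid).
#' @return Logical vector, one element per crossing frame.
#' @export
voiced_mask <- function(volumes, crossings) {
  stopifnot(inherits(volumes, "frame_series"), volumes$kind == "volume",
            inherits(crossings, "frame_series"), crossings$kind == "crossings")
  pauses <- pause_flags(volumes)
  vd <- volumes$frame_duration
  cd <- crossings$frame_duration
  nc <- length(crossings$values)
  starts <- (seq_len(nc) - 1L) * cd
  ends <- starts + cd
  voiced_time <- vapply(seq_len(nc), function(i) {
    j0 <- floor(starts[i] / vd) + 1
    j1 <- ceiling(ends[i] / vd)
    j <- seq(j0, j1)
    j <- j[j >= 1 & j <= length(pauses)]
    if (!length(j)) return(0)
    ov <- pmin(ends[i], j * vd) - pmax(starts[i], (j - 1) * vd)
    sum(ov[!pauses[j]])
  }, numeric(1))
  voiced_time > cd / 2
}

#' Average pitch from zero crossings
#'
#' Mean zero-crossing count over voiced frames, converted to Hz by dividing
#' by twice the frame duration (a periodic signal at f Hz crosses zero 2f
#' times per second). Set `hz = FALSE` for the raw count-per-frame scale.
#'
#' @param crossings Crossings [frame_series()].
#' @param voiced Logical mask of voiced frames (default: all frames).
#' @param hz Convert counts to Hz (default TRUE).
#' @return Estimated fundamental frequency in Hz (or mean count).
#' @export
average_pitch <- function(crossings, voiced = NULL, hz = TRUE) {
  stopifnot(inherits(crossings, "frame_series"), crossings$kind == "crossings")
  v <- if (is.null(voiced)) rep(TRUE, length(crossings$values)) else voiced
  if (!any(v)) pdb_stop("undefined_feature", "no voiced frames for average pitch")
  m <- mean(crossings$values[v])
  if (hz) m / (2 * crossings$frame_duration) else m
}

#' Pitch variance from zero crossings
#'
#' Mean absolute difference of zero-crossing counts between consecutive
#' voiced frames, on the same Hz scale as [average_pitch()]. Measures
#' frame-to-frame pitch instability (prosodic modulation); reduced values are
#' the monotone-speech signature.
#'
#' @inheritParams average_pitch
#' @return Mean absolute frame-to-frame pitch change (Hz by default).
#' @export
pitch_variance <- function(crossings, voiced = NULL, hz = TRUE) {
  stopifnot(inherits(crossings, "frame_series"), crossings$kind == "crossings")
  v <- if (is.null(voiced)) rep(TRUE, length(crossings$values)) else voiced
  cz <- crossings$values[v]
  if (length(cz) < 2L) pdb_stop("undefined_feature", "pitch variance needs >= 2 voiced frames")
  m <- mean(abs(diff(cz)))
  if (hz) m / (2 * crossings$frame_duration) else m
}

#' Reading time
#'
#' Time spanned by speech: from the first to the last non-pause volume frame,
#' inclusive, in seconds. Leading and trailing silence do not count.
#'
#' @inheritParams pause_threshold
#' @return Seconds.
#' @export
reading_time <- function(volumes) {
  stopifnot(inherits(volumes, "frame_series"), volumes$kind == "volume")
  voiced <- which(!pause_flags(volumes))
  if (!length(voiced)) pdb_stop("undefined_feature", "signal contains no speech frames")
  (voiced[length(voiced)] - voiced[1L] + 1L) * volumes$frame_duration
}

#' Extract all voice features from a recording
#'
#' Composes frame blocking, pause detection and zero-crossing pitch into the
#' per-subject voice feature vector: reading time, pause percentage, volume
#' variance, average pitch and pitch variance (plus an optional phonetic
#' score passed through unmodified). Pitch features are computed on voiced
#' frames only: the 25 ms pause decisions are resampled to the 10 ms
#' crossing grid by time overlap.
#'
#' @param signal An [audio_signal()].
#' @param frame_duration Volume frame length, seconds (default 0.025).
#' @param pitch_frame_duration Crossing frame length, seconds (default 0.010).
#' @param phonetic_score Optional externally computed score carried through.
#' @param pitch_all_frames If TRUE, pitch features use every frame instead of
#'   voiced frames only.
#' @return One-row `data.frame` with columns `subject_id`, `reading_time`,
#'   `pause_pct`, `volume_var`, `avg_pitch`, `pitch_var` (and
#'   `phonetic_score` when supplied).
#' @examples
#' t <- seq(0, 2, by = 1 / 44100)
#' sig <- audio_signal(3000 * sin(2 * pi * 150 * t), subject_id = "S1")
#' extract_voice_features(sig)
#' @export
extract_voice_features <- function(signal, frame_duration = 0.025,
                                   pitch_frame_duration = 0.010,
                                   phonetic_score = NULL,
                                   pitch_all_frames = FALSE) {
  vols <- frame_volume(signal, frame_duration)
  cz <- zero_crossings(signal, pitch_frame_duration)
  voiced <- if (pitch_all_frames) NULL else voiced_mask(vols, cz)
  out <- data.frame(
    subject_id = if (is.null(signal$subject_id)) NA_character_ else signal$subject_id,
    reading_time = reading_time(vols),
    pause_pct = pause_percentage(vols),
    volume_var = volume_variance(vols),
    avg_pitch = average_pitch(cz, voiced),
    pitch_var = pitch_variance(cz, voiced),
    stringsAsFactors = FALSE
  )
  if (!is.null(phonetic_score)) out$phonetic_score <- phonetic_score
  out
}
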