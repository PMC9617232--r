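#' Eye aspect ratio series
#'
#' Per-frame eye aspect ratio (EAR): eye height (top-to-bottom lid distance)
#' divided by eye width (outer-to-inner corner distance), averaged over both
#' eyes, together with a trailing rolling mean (default window 30 frames,
#' about one second at 30 fps). Edge frames average over the frames available
#' so far.
#'
#' @param track A [landmark_track()].
#' @param window Rolling-mean window in frames (default 30).
#' @return Object of class `ear_series` with elements `raw`, `smoothed`,
#'   `window`, `fps`.
#' @export
ear_series <- function(track, window = 30L) {
  stopifnot(inherits(track, "landmark_track"))
  if (window < 1L) pdb_stop("input_error", "window must be >= 1")
  sc <- track$schema
  one_eye <- function(eye) {
    h <- row_dist(lm_xy(track, eye$top), lm_xy(track, eye$bottom))
    w <- row_dist(lm_xy(track, eye$outer), lm_xy(track, eye$inner))
    if (any(w <= 0)) {
      pdb_stop("degenerate_geometry",
               paste0("zero eye width at frame ", which(w <= 0)[1L]))
    }
    h / w
  }
  raw <- (one_eye(sc$eye_right) + one_eye(sc$eye_left)) / 2
  smoothed <- trailing_mean(raw, window)
  structure(list(raw = raw, smoothed = smoothed, window = as.integer(window),
                 fps = track$fps),
            class = "ear_series")
}

#' @export
print.ear_series <- function(x, ...) {
  cat(sprintf("<ear_series> %d frames, window %d, mean EAR %.3f\n",
              length(x$raw), x$window, mean(x$smoothed)))
  invisible(x)
}

row_dist <- function(a, b) sqrt(rowSums((a - b)^2))

trailing_mean <- function(x, window) {
  cs <- cumsum(x)
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - window, 0L)
  (cs - c(0, cs)[lo + 1L]) / (i - lo)
}

#' Blink fraction at a relative threshold
#'
#' Fraction of frames spent in-blink: a frame is in-blink when the smoothed
#' EAR falls below `threshold_pct`% of the overall mean smoothed EAR. Lower
#' thresholds demand deeper eye closure, so fractions are non-decreasing in
#' the threshold (30% admits the fewest frames, 90% the most).
#'
#' @param ear An [ear_series()].
#' @param threshold_pct Threshold as percent of the mean (30, 50, 70 or 90).
#' @return Fraction of frames in `[0, 1]`.
#' @export
blink_fraction <- function(ear, threshold_pct) {
  stopifnot(inherits(ear, "ear_series"))
  mean(ear$smoothed < (threshold_pct / 100) * mean(ear$smoothed))
}

face_width_series <- function(track) {
  pair <- track$schema$face_width_pair
  w <- row_dist(lm_xy(track, pair[1L]), lm_xy(track, pair[2L]))
  if (any(w <= 0)) {
    pdb_stop("degenerate_geometry",
             paste0("zero face width at frame ", which(w <= 0)[1L]))
  }
  w
}

## Shared kernel for the motion-variance features: mean over frames of the
## face-width-normalized absolute frame-to-frame change of a distance series.
## The change between frames t-1 and t is normalized by the face width at
## frame t, so zoom drift cancels; the sum is divided by the total frame
## count (not the number of differences).
path_variance <- function(d, fw, n) sum(abs(diff(d)) / fw[-1L]) / n

#' Mouth-to-eye distance variance
#'
#' Mean per-frame change (normalized by face width and total frame count) in
#' the distance from the outer eye corner to the mouth corner on one side of
#' the face. Sensitive to cheek/jaw motion while speaking.
#'
#' @param track A [landmark_track()].
#' @param side `"right"` or `"left"`.
#' @return Non-negative scalar, dimensionless.
#' @export
mouth_eye_distance_variance <- function(track, side = c("right", "left")) {
  side <- match.arg(side)
  check_min_frames(track)
  sc <- track$schema
  eye <- if (side == "right") sc$eye_right$outer else sc$eye_left$outer
  mouth <- if (side == "right") sc$mouth_corner_right else sc$mouth_corner_left
  d <- row_dist(lm_xy(track, eye), lm_xy(track, mouth))
  path_variance(d, face_width_series(track), n_frames(track))
}

#' Mouth opening variances
#'
#' Mean per-frame change (normalized by face width and total frame count) in
#' the upper-to-lower-lip distance (`mouth_height_variance`) or the
#' mouth-corner-to-mouth-corner distance (`mouth_width_variance`).
#'
#' @param track A [landmark_track()].
#' @return Non-negative scalar, dimensionless.
#' @export
mouth_height_variance <- function(track) {
  check_min_frames(track)
  sc <- track$schema
  d <- row_dist(lm_xy(track, sc$upper_lip), lm_xy(track, sc$lower_lip))
  path_variance(d, face_width_series(track), n_frames(track))
}

#' @rdname mouth_height_variance
#' @export
mouth_width_variance <- function(track) {
  check_min_frames(track)
  sc <- track$schema
  d <- row_dist(lm_xy(track, sc$mouth_corner_right), lm_xy(track, sc$mouth_corner_left))
  path_variance(d, face_width_series(track), n_frames(track))
}

#' Mouth angle variance
#'
#' Per frame, the acute crossing angle (degrees, in `[0, 90]`) between the
#' line through the two mouth corners and the line from the upper to the
#' lower lip; returned is the summed absolute frame-to-frame angle change
#' divided by the total frame count. No face-width normalization (angles are
#' already scale-free); invariant to rigid rotation of the whole face.
#'
#' @param track A [landmark_track()].
#' @return Degrees per frame.
#' @export
mouth_angle_variance <- function(track) {
  check_min_frames(track)
  sc <- track$schema
  v1 <- lm_xy(track, sc$mouth_corner_left) - lm_xy(track, sc$mouth_corner_right)
  v2 <- lm_xy(track, sc$lower_lip) - lm_xy(track, sc$upper_lip)
  n1 <- sqrt(rowSums(v1^2))
  n2 <- sqrt(rowSums(v2^2))
  if (any(n1 <= 0) || any(n2 <= 0)) {
    pdb_stop("degenerate_geometry",
             paste0("degenerate mouth line at frame ",
                    which(n1 <= 0 | n2 <= 0)[1L]))
  }
  cosang <- abs(rowSums(v1 * v2)) / (n1 * n2)
  ang <- acos(pmin(1, pmax(0, cosang))) * 180 / pi
  sum(abs(diff(ang))) / n_frames(track)
}

#' Peri-oral area movement variance
#'
#' Six points near the mouth and jaw on one side; per frame, the distance
#' from the nose center to each point. Returned is the summed absolute
#' frame-to-frame change of those six distances, each change normalized by
#' the face width, divided by the total frame count. Whole-face translation
#' leaves the feature at zero since nose and points move together.
#'
#' @param track A [landmark_track()].
#' @param side `"right"` or `"left"`.
#' @return Non-negative scalar, dimensionless.
#' @export
perioral_variance <- function(track, side = c("right", "left")) {
  side <- match.arg(side)
  check_min_frames(track)
  sc <- track$schema
  pts <- if (side == "right") sc$perioral_right else sc$perioral_left
  nose <- lm_xy(track, sc$nose_center)
  fw <- face_width_series(track)
  n <- n_frames(track)
  total <- 0
  for (p in pts) {
    d <- row_dist(nose, lm_xy(track, p))
    total <- total + sum(abs(diff(d)) / fw[-1L])
  }
  total / n
}

check_min_frames <- function(track, min = 2L) {
  if (n_frames(track) < min) {
    pdb_stop("input_error", "variance features need at least 2 frames")
  }
}

#' Extract all facial features from a landmark track
#'
#' Composes the blink and motion-variance features into the per-subject
#' facial feature vector: blink fractions at the 30/50/70/90% thresholds,
#' mouth-to-eye distance variance (right/left), mouth height/width/angle
#' variances, and peri-oral variance (right/left).
#'
#' @param track A [landmark_track()].
#' @param window EAR rolling-mean window in frames (default 30).
#' @return One-row `data.frame` with columns `subject_id`, `blink_30`,
#'   `blink_50`, `blink_70`, `blink_90`, `mouth_eye_var_r`,
#'   `mouth_eye_var_l`, `mouth_height_var`, `mouth_width_var`,
#'   `mouth_angle_var`, `perioral_var_r`, `perioral_var_l`.
#' @export
extract_facial_features <- function(track, window = 30L) {
  ear <- ear_series(track, window)
  data.frame(
    subject_id = if (is.null(track$subject_id)) NA_character_ else track$subject_id,
    blink_30 = blink_fraction(ear, 30),
    blink_50 = blink_fraction(ear, 50),
    blink_70 = blink_fraction(ear, 70),
    blink_90 = blink_fraction(ear, 90),
    mouth_eye_var_r = mouth_eye_distance_variance(track, "right"),
    mouth_eye_var_l = mouth_eye_distance_variance(track, "left"),
    mouth_height_var = mouth_height_variance(track),
    mouth_width_var = mouth_width_variance(track),
    mouth_angle_var = mouth_angle_variance(track),
    perioral_var_r = perioral_variance(track, "right"),
    perioral_var_l = perioral_variance(track, "left"),
    stringsAsFactors = FALSE
  )
}
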