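#' Facial landmark schema
#'
#' Names the semantic roles the facial features need and maps each role to a
#' landmark id as it appears in the track file. Coordinates are assumed
#' image-normalized; all distances are later divided by the per-frame face
#' width, so absolute units never matter.
#'
#' @param eye_right,eye_left Named lists with ids `outer`, `inner`, `top`,
#'   `bottom` (eye corners and lids).
#' @param mouth_corner_right,mouth_corner_left,upper_lip,lower_lip,nose_center
#'   Single landmark ids.
#' @param perioral_right,perioral_left Exactly six landmark ids each, near the
#'   mouth and jaw on that side; peri-oral motion is measured as distance
#'   changes from the nose center to each of these points.
#' @param face_width_pair Two distinct landmark ids spanning the face outline;
#'   their per-frame distance is the scale normalizer.
#' @return An object of class `landmark_schema`.
#' @seealso [default_landmark_schema()] for the canonical synthetic layout.
#' @export
landmark_schema <- function(eye_right, eye_left,
                            mouth_corner_right, mouth_corner_left,
                            upper_lip, lower_lip, nose_center,
                            perioral_right, perioral_left,
                            face_width_pair) {
  eye_roles <- c("outer", "inner", "top", "bottom")
  for (eye in list(eye_right = eye_right, eye_left = eye_left)) {
    if (!all(eye_roles %in% names(eye))) {
      pdb_stop("schema_error", "each eye needs ids named outer, inner, top, bottom")
    }
  }
  for (side in list(perioral_right = perioral_right, perioral_left = perioral_left)) {
    if (length(side) != 6L || anyDuplicated(side)) {
      pdb_stop("schema_error", "perioral point sets must contain exactly 6 distinct ids")
    }
  }
  if (length(face_width_pair) != 2L || face_width_pair[1] == face_width_pair[2]) {
    pdb_stop("schema_error", "face_width_pair must be two distinct ids")
  }
  structure(
    list(eye_right = lapply(eye_right[eye_roles], as.character),
         eye_left = lapply(eye_left[eye_roles], as.character),
         mouth_corner_right = as.character(mouth_corner_right),
         mouth_corner_left = as.character(mouth_corner_left),
         upper_lip = as.character(upper_lip),
         lower_lip = as.character(lower_lip),
         nose_center = as.character(nose_center),
         perioral_right = as.character(perioral_right),
         perioral_left = as.character(perioral_left),
         face_width_pair = as.character(face_width_pair)),
    class = "landmark_schema"
  )
}

#' @rdname landmark_schema
#' @export
default_landmark_schema <- function() {
  landmark_schema(
    eye_right = list(outer = "eye_r_outer", inner = "eye_r_inner",
                     top = "eye_r_top", bottom = "eye_r_bottom"),
    eye_left = list(outer = "eye_l_outer", inner = "eye_l_inner",
                    top = "eye_l_top", bottom = "eye_l_bottom"),
    mouth_corner_right = "mouth_r", mouth_corner_left = "mouth_l",
    upper_lip = "lip_upper", lower_lip = "lip_lower",
    nose_center = "nose",
    perioral_right = paste0("perioral_r", 1:6),
    perioral_left = paste0("perioral_l", 1:6),
    face_width_pair = c("face_r", "face_l")
  )
}

#' All landmark ids a schema requires
#' @param schema A [landmark_schema()].
#' @return Character vector of distinct ids.
#' @export
required_landmarks <- function(schema) {
  stopifnot(inherits(schema, "landmark_schema"))
  unique(unlist(schema, use.names = FALSE))
}

#' Landmark track container
#'
#' Time-indexed 2-D facial landmark coordinates, stored as an
#' `n_frames x n_landmarks x 2` array with landmark ids as column names.
#'
#' @param coords Numeric array `frames x landmarks x 2` (x, y), with landmark
#'   ids as `dimnames[[2]]`.
#' @param fps Frames per second (> 0). The video frame rate is recording-
#'   specific and therefore always supplied, never defaulted.
#' @param schema A [landmark_schema()]; every required id must be present.
#' @param subject_id Optional identifier.
#' @return An object of class `landmark_track`.
#' @export
landmark_track <- function(coords, fps, schema, subject_id = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 2L) {
    pdb_stop("input_error", "`coords` must be a frames x landmarks x 2 array")
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    pdb_stop("input_error", "`fps` must be a single positive number")
  }
  ids <- dimnames(coords)[[2]]
  missing_ids <- setdiff(required_landmarks(schema), ids)
  if (length(missing_ids)) {
    pdb_stop("schema_error",
             paste0("track is missing required landmarks: ",
                    paste(missing_ids, collapse = ", ")))
  }
  if (anyNA(coords)) pdb_stop("input_error", "landmark coordinates contain NA")
  structure(
    list(coords = coords, fps = as.double(fps), schema = schema,
         subject_id = subject_id),
    class = "landmark_track"
  )
}

#' @export
print.landmark_track <- function(x, ...) {
  cat(sprintf("<landmark_track> %s: %d frames, %d landmarks @ %g fps\n",
              if (is.null(x$subject_id)) "?" else x$subject_id,
              n_frames(x), dim(x$coords)[2], x$fps))
  invisible(x)
}

n_frames <- function(track) dim(track$coords)[1]

## coordinates of one landmark over time: n_frames x 2 matrix
lm_xy <- function(track, id) {
  m <- track$coords[, id, , drop = FALSE]
  dim(m) <- c(dim(m)[1L], 2L)
  m
}

#' Read / write landmark tracks
#'
#' Long CSV with columns `frame`, `landmark_id`, `x`, `y` (or the JSON
#' equivalent: an array of per-frame objects mapping ids to `[x, y]`).
#' Frames are sorted by index and the schema is validated against the
#' ids present in every frame.
#'
#' @param path CSV or JSON file path (format chosen by extension).
#' @param schema A [landmark_schema()].
#' @param fps Frames per second of the source video (required; the recording
#'   frame rate is not stored in the track file).
#' @param subject_id Optional identifier.
#' @return A [landmark_track()].
#' @export
read_landmark_track <- function(path, schema, fps, subject_id = NULL) {
  if (!file.exists(path)) pdb_stop("format_error", paste0("landmark file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    frames <- jsonlite::read_json(path, simplifyVector = FALSE)
    df <- do.call(rbind, lapply(seq_along(frames), function(i) {
      fr <- frames[[i]]
      if (is.null(names(fr))) {
        pdb_stop("format_error",
                 paste0("JSON frame ", i, " is not a landmark-id map: ", path))
      }
      data.frame(frame = i - 1L, landmark_id = names(fr),
                 x = vapply(fr, function(p) as.numeric(p[[1L]]), numeric(1)),
                 y = vapply(fr, function(p) as.numeric(p[[2L]]), numeric(1)))
    }))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("frame", "landmark_id", "x", "y")
  if (!all(need %in% names(df))) {
    pdb_stop("format_error",
             paste0("landmark file must have columns frame, landmark_id, x, y: ", path))
  }
  frame_ids <- sort(unique(df$frame))
  ids <- sort(unique(df$landmark_id))
  req <- required_landmarks(schema)
  coords <- array(NA_real_, dim = c(length(frame_ids), length(ids), 2L),
                  dimnames = list(NULL, ids, c("x", "y")))
  fi <- match(df$frame, frame_ids)
  li <- match(df$landmark_id, ids)
  coords[cbind(fi, li, 1L)] <- df$x
  coords[cbind(fi, li, 2L)] <- df$y
  for (role_id in req) {
    if (!role_id %in% ids) {
      pdb_stop("schema_error", paste0("landmark '", role_id, "' absent from ", path))
    }
    bad <- which(is.na(coords[, role_id, 1L]) | is.na(coords[, role_id, 2L]))
    if (length(bad)) {
      pdb_stop("schema_error",
               paste0("landmark '", role_id, "' missing in frame(s) ",
                      paste(frame_ids[utils::head(bad, 5L)], collapse = ", "),
                      " of ", path))
    }
  }
  landmark_track(coords[, req, , drop = FALSE], fps = fps, schema = schema,
                 subject_id = subject_id)
}

#' @rdname read_landmark_track
#' @param track A [landmark_track()].
#' @export
write_landmark_track <- function(track, path) {
  stopifnot(inherits(track, "landmark_track"))
  ids <- dimnames(track$coords)[[2]]
  nf <- n_frames(track)
  df <- data.frame(
    frame = rep(seq_len(nf) - 1L, times = length(ids)),
    landmark_id = rep(ids, each = nf),
    x = as.vector(track$coords[, , 1L]),
    y = as.vector(track$coords[, , 2L])
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
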