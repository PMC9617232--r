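## Canonical column orders. Fixed once: file layout, tie-breaking in feature
## selection, and coverage ranking all depend on this ordering.
facial_feature_names <- function() {
  c("blink_30", "blink_50", "blink_70", "blink_90",
    "mouth_eye_var_r", "mouth_eye_var_l",
    "mouth_height_var", "mouth_width_var", "mouth_angle_var",
    "perioral_var_r", "perioral_var_l")
}

voice_feature_names <- function() {
  c("reading_time", "pause_pct", "volume_var", "avg_pitch", "pitch_var")
}

#' Feature columns of a feature set
#'
#' @param feature_set One of `"face_only"`, `"voice_only"`, `"combined"`,
#'   `"combined_plus_demographics"`.
#' @return Character vector of model feature column names, in canonical order.
#' @export
feature_columns <- function(feature_set = c("combined_plus_demographics",
                                            "face_only", "voice_only", "combined")) {
  feature_set <- match.arg(feature_set)
  switch(feature_set,
    face_only = facial_feature_names(),
    voice_only = voice_feature_names(),
    combined = c(facial_feature_names(), voice_feature_names()),
    combined_plus_demographics = c(facial_feature_names(), voice_feature_names(),
                                   "age", "sex"))
}

#' Build the subjects-by-features table
#'
#' Joins per-subject facial features, voice features and metadata into the
#' classifier input table. Sex is encoded male = 1, female = 0; labels are a
#' factor with levels `control`, `PD` (PD is the positive class).
#'
#' @param voice `data.frame` of [extract_voice_features()] rows (one per
#'   subject), or NULL for `face_only`.
#' @param face `data.frame` of [extract_facial_features()] rows, or NULL for
#'   `voice_only`.
#' @param meta `data.frame` with columns `subject_id`, `age`, `sex`
#'   (`"male"`/`"female"`), `label` (`"PD"`/`"control"`); optional `stage`,
#'   `phase`.
#' @param feature_set Which feature block(s) to assemble; see
#'   [feature_columns()].
#' @return A `data.frame` with `subject_id`, the feature columns in canonical
#'   order, and `label`.
#' @export
build_table <- function(voice = NULL, face = NULL, meta,
                        feature_set = c("combined_plus_demographics",
                                        "face_only", "voice_only", "combined")) {
  feature_set <- match.arg(feature_set)
  cols <- feature_columns(feature_set)
  need <- c("subject_id", "label")
  if (!all(need %in% names(meta))) {
    pdb_stop("assembly_error", "meta must contain subject_id and label")
  }
  if (anyDuplicated(meta$subject_id)) {
    pdb_stop("integrity_error", "duplicate subject_id in metadata")
  }
  out <- data.frame(subject_id = as.character(meta$subject_id),
                    stringsAsFactors = FALSE)

  join_block <- function(block, what) {
    if (is.null(block)) {
      pdb_stop("assembly_error", paste0(what, " features required for feature set '",
                                        feature_set, "'"))
    }
    missing_ids <- setdiff(out$subject_id, block$subject_id)
    if (length(missing_ids)) {
      pdb_stop("assembly_error",
               paste0("subjects missing ", what, " features: ",
                      paste(utils::head(missing_ids, 5L), collapse = ", ")))
    }
    block[match(out$subject_id, block$subject_id), , drop = FALSE]
  }

  if (any(facial_feature_names() %in% cols)) {
    fb <- join_block(face, "facial")
    out <- cbind(out, fb[, facial_feature_names(), drop = FALSE])
  }
  if (any(voice_feature_names() %in% cols)) {
    vb <- join_block(voice, "voice")
    out <- cbind(out, vb[, voice_feature_names(), drop = FALSE])
  }
  if ("age" %in% cols) {
    if (!all(c("age", "sex") %in% names(meta))) {
      pdb_stop("assembly_error", "meta must contain age and sex for demographics")
    }
    out$age <- as.double(meta$age)
    out$sex <- ifelse(meta$sex == "male", 1, 0)
  }
  out$label <- factor(as.character(meta$label), levels = c("control", "PD"))
  rownames(out) <- NULL
  validate_feature_table(out, cols)
  out
}

validate_feature_table <- function(table, cols = NULL) {
  if (is.null(cols)) cols <- setdiff(names(table), c("subject_id", "label"))
  if (!"label" %in% names(table) || anyNA(table$label)) {
    pdb_stop("integrity_error", "feature table has missing or undefined labels")
  }
  if (anyDuplicated(table$subject_id)) {
    pdb_stop("integrity_error", "duplicate subject_id in feature table")
  }
  num <- table[, cols, drop = FALSE]
  if (anyNA(num) || !all(vapply(num, is.numeric, logical(1)))) {
    pdb_stop("integrity_error", "feature columns must be numeric with no missing values")
  }
  invisible(table)
}

#' Write / read a feature table as CSV
#'
#' Fixed column order (`subject_id`, features in canonical order, `label`),
#' values formatted to 15 significant digits so a round trip is lossless well
#' beyond 12 digits.
#'
#' @param table A feature table from [build_table()].
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  cols <- intersect(c("subject_id", feature_columns("combined_plus_demographics"),
                      "phonetic_score", "label"),
                    names(table))
  out <- table[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) pdb_stop("format_error", paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) pdb_stop("integrity_error", "feature table CSV lacks a label column")
  df$label <- factor(df$label, levels = c("control", "PD"))
  df$subject_id <- as.character(df$subject_id)
  validate_feature_table(df)
  df
}
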