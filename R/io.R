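# CSV dialect: comma-separated, "." decimal, mandatory header, UTF-8.
# Report files carry a "# manifest: <hash>" comment line when written by
# the pipeline; readers skip leading comment lines.

vm_read_csv <- function(path) {
  if (!file.exists(path)) {
    vm_stop("file not found: %s", path, class = "voicemod_io_error")
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}

vm_require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    vm_stop("%s: missing column(s) %s", path, paste(miss, collapse = ", "),
            class = "voicemod_validation_error")
  }
}

#' Read and validate a long-format ratings CSV
#'
#' Required columns: `listener_id`, `speaker_id`, `condition`, `scale`,
#' `rating`. Condition and scale labels are casefolded to the canonical
#' lowercase set; out-of-range or non-integer ratings and duplicate
#' (listener, speaker, condition, scale) keys are rejected with their row
#' numbers (1-based, excluding the header).
#'
#' @param path CSV path.
#' @param likert_min,likert_max allowed rating bounds.
#' @return Validated ratings data.frame.
#' @export
read_ratings <- function(path, likert_min = 1, likert_max = 7) {
  df <- vm_read_csv(path)
  vm_require_columns(df, c("listener_id", "speaker_id", "condition", "scale",
                           "rating"), path)
  df$condition <- vm_normalize_label(df$condition, VM_CONDITIONS)
  df$scale <- vm_normalize_label(df$scale, VM_SOCIAL_TRAITS)
  bad <- which(is.na(df$rating) | df$rating != round(df$rating) |
                 df$rating < likert_min | df$rating > likert_max)
  if (length(bad) > 0) {
    vm_stop("%s: rating out of [%d,%d] or non-integer on row(s) %s", path,
            likert_min, likert_max,
            paste(utils::head(bad, 10), collapse = ", "),
            class = "voicemod_validation_error")
  }
  key <- paste(df$listener_id, df$speaker_id, df$condition, df$scale)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    vm_stop("%s: duplicate (listener, speaker, condition, scale) on row(s) %s",
            path, paste(utils::head(dup, 10), collapse = ", "),
            class = "voicemod_validation_error")
  }
  df
}

#' Write a table as CSV, optionally stamped with a manifest hash
#'
#' @param obj data.frame.
#' @param path output path.
#' @param manifest_hash optional hash recorded as a leading comment.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path, manifest_hash = NULL) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(manifest_hash)) {
    writeLines(sprintf("# manifest: %s", manifest_hash), con)
  }
  utils::write.csv(obj, con, row.names = FALSE)
  invisible(path)
}

#' Read a questionnaire items CSV
#' @param path CSV with columns `speaker_id`, `instrument`, `item`,
#'   `response`.
#' @return Validated data.frame.
#' @export
read_items <- function(path) {
  df <- vm_read_csv(path)
  vm_require_columns(df, c("speaker_id", "instrument", "item", "response"), path)
  df$instrument <- vm_normalize_label(df$instrument, c("qcae", "sd3"))
  df
}

#' Read a speaker demographics CSV
#' @param path CSV with columns `speaker_id`, `age`, `sex`.
#' @return Validated data.frame.
#' @export
read_speakers <- function(path) {
  df <- vm_read_csv(path)
  vm_require_columns(df, c("speaker_id", "age", "sex"), path)
  df$sex <- vm_normalize_label(df$sex, c("female", "male"))
  df
}

#' Read a per-speaker performance CSV
#' @param path CSV produced by the index stage.
#' @return data.frame.
#' @export
read_performance <- function(path) {
  df <- vm_read_csv(path)
  vm_require_columns(df, c("speaker_id", "ed"), path)
  df
}

#' Read a reactivity profiles CSV
#' @param path CSV produced by the score stage.
#' @return data.frame.
#' @export
read_profiles <- function(path) {
  df <- vm_read_csv(path)
  vm_require_columns(df, c("speaker_id", "cognitive_empathy",
                           "affective_empathy", "machiavellianism",
                           "psychopathy", "age", "sex"), path)
  df
}
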