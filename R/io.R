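## CSV round-trip for the study tables. Human-readable CSV is the right
## store at this scale (~4.6k trials); missing values are the literal token
## NA, quoting is RFC-4180 via base R, columns are matched by name on read.

.trial_cols <- c("subject_id", "session_index", "stim_condition",
                 "trial_index", "opponent_id", "opponent_class",
                 "opponent_policy", "decision_order", "subject_choice",
                 "opponent_choice", "subject_rt_s", "opponent_rt_s",
                 "points_subject", "cumulative_points", "valid")

.profile_cols <- c("subject_id", "age", "sex", "neo_neuroticism",
                   "neo_extraversion", "neo_openness", "neo_agreeableness",
                   "neo_conscientiousness", "believed_live",
                   "panas_positive_tvns", "panas_positive_sham",
                   "panas_negative_tvns", "panas_negative_sham",
                   "disease_duration", "time_since_last_seizure",
                   "affected_hemisphere", "medicated", "latent_drift_offset")

.likability_cols <- c("subject_id", "session_index", "opponent_id",
                      "opponent_class", "sam_likability")

check_schema <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " table is missing required column(s): ",
         paste(missing, collapse = ", "))
  df[, cols, drop = FALSE]
}

#' Write / read the trial log
#'
#' Lossless CSV round trip of the trial-log table (fixed header order on
#' write; columns matched by name on read, so reordered files are
#' accepted). Missing choices/RTs are written as the literal token `NA`.
#'
#' @param trials trial-log data frame.
#' @param path file path.
#' @return `write_trials` returns the path invisibly; `read_trials` the
#'   table.
#' @export
write_trials <- function(trials, path) {
  trials <- check_schema(trials, .trial_cols, "trial-log")
  utils::write.csv(trials, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df <- check_schema(df, .trial_cols, "trial-log")
  df$valid <- as.logical(df$valid)
  df
}

#' Write / read the subject profiles
#' @param profiles profile data frame.
#' @param path file path.
#' @export
write_profiles <- function(profiles, path) {
  profiles <- check_schema(profiles, .profile_cols, "profiles")
  utils::write.csv(profiles, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df <- check_schema(df, .profile_cols, "profiles")
  df$believed_live <- as.logical(df$believed_live)
  df$medicated <- as.logical(df$medicated)
  df
}

#' Write / read the likability ratings
#' @param likability likability data frame.
#' @param path file path.
#' @export
write_likability <- function(likability, path) {
  likability <- check_schema(likability, .likability_cols, "likability")
  utils::write.csv(likability, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_likability
#' @export
read_likability <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_schema(df, .likability_cols, "likability")
}
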