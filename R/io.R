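# Plain-text interchange: trial, rating and score CSVs with fixed column
# order, and YAML/JSON configuration. Missing numeric fields serialize as
# empty strings; numerics are written at full double precision so files
# round-trip without loss.

.trial_cols <- c("participant_id", "group", "run", "block_index", "condition",
                 "trial_index", "trial_type", "response", "correct",
                 "rt_seconds", "missing")

.fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write / read trial records
#'
#' Trial CSVs use the fixed column order `participant_id, group, run,
#' block_index, condition, trial_index, trial_type, response, correct,
#' rt_seconds, missing`; undefined numeric and logical fields are empty.
#'
#' @param trials data.frame of trial records.
#' @param path File path.
#' @return `write_trials` invisibly returns the path; `read_trials` a
#'   data.frame with typed columns.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(.trial_cols, names(trials))
  if (length(miss)) stop("trials table lacks columns: ", paste(miss, collapse = ", "))
  df <- trials[, .trial_cols]
  df$rt_seconds <- .fmt_num(df$rt_seconds)
  df$correct <- ifelse(is.na(df$correct), "", ifelse(df$correct, "TRUE", "FALSE"))
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character",
                                       group = "character", run = "integer",
                                       block_index = "integer",
                                       condition = "character",
                                       trial_index = "integer",
                                       trial_type = "character",
                                       response = "character",
                                       correct = "character",
                                       rt_seconds = "numeric",
                                       missing = "logical"))
  df$correct <- ifelse(df$correct == "" | is.na(df$correct), NA, df$correct == "TRUE")
  df[, .trial_cols]
}

#' Write / read rating and score tables
#'
#' Ratings use columns `participant_id, group, condition, question, rating`;
#' scores use `participant_id, group, instrument, score`.
#'
#' @param ratings,scores Tables to write.
#' @param path File path.
#' @export
write_ratings <- function(ratings, path) {
  cols <- c("participant_id", "group", "condition", "question", "rating")
  df <- ratings[, cols]
  df$rating <- .fmt_num(df$rating)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character", group = "character",
                                 condition = "character", question = "character",
                                 rating = "numeric"))
}

#' @rdname write_ratings
#' @export
write_scores <- function(scores, path) {
  cols <- c("participant_id", "group", "instrument", "score")
  df <- scores[, cols]
  df$score <- .fmt_num(df$score)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_scores <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character", group = "character",
                                 instrument = "character", score = "numeric"))
}

#' Write posterior draws and diagnostics
#'
#' Draws persist as a tidy CSV (`chain, iter, parameter, value`) plus a JSON
#' sidecar with R-hat values and sampler settings.
#'
#' @param draws An `lba_draws` object (see [sample_posterior()]).
#' @param csv_path,json_path Output paths.
#' @export
write_draws <- function(draws, csv_path, json_path) {
  df <- as.data.frame(draws)
  df$value <- sprintf("%.17g", df$value)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(rhat = as.list(draws$rhat),
                            settings = draws$settings),
                       json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv_path)
}
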