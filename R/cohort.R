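#' Answer-record cohorts
#'
#' A cohort is a data.frame with one row per respondent record: columns
#' `record_id`, `sex` (`"male"`/`"female"`), optional `inquiry_seconds`, and
#' one column `q<id>` per question holding the categorical answer
#' `A`/`B`/`C`/`D` (`NA` for questions not applicable to the record's sex).
#'
#' @name cohort
NULL

question_columns <- function(cohort) {
  grep("^q[0-9]+$", names(cohort), value = TRUE)
}

#' Validate a cohort data.frame
#'
#' Checks the column layout, answer labels, and that every applicable
#' question (per `questionnaire`) is answered exactly once.
#'
#' @param cohort Cohort data.frame (see [cohort]).
#' @param questionnaire Optional questionnaire layout; when supplied,
#'   applicability per sex is enforced.
#' @return The cohort, invisibly; errors describe the first violation.
#' @export
validate_cohort <- function(cohort, questionnaire = NULL) {
  need <- c("record_id", "sex")
  if (!all(need %in% names(cohort))) {
    stop("cohort needs columns record_id and sex", call. = FALSE)
  }
  if (anyDuplicated(cohort$record_id)) {
    stop("duplicate record_id in cohort", call. = FALSE)
  }
  if (!all(cohort$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  qcols <- question_columns(cohort)
  if (length(qcols) == 0L) stop("cohort has no question columns", call. = FALSE)
  ans <- as.matrix(cohort[, qcols, drop = FALSE])
  bad <- !is.na(ans) & !(ans %in% c("A", "B", "C", "D"))
  if (any(bad)) {
    stop("invalid answer label(s): ", paste(unique(ans[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(questionnaire)) {
    qid <- as.integer(sub("^q", "", qcols))
    for (s in c("male", "female")) {
      rows <- which(cohort$sex == s)
      if (!length(rows)) next
      applicable <- qid %in% questionnaire_ids(questionnaire, s)
      sub <- ans[rows, , drop = FALSE]
      if (anyNA(sub[, applicable, drop = FALSE])) {
        stop("unanswered applicable question(s) for sex ", s, call. = FALSE)
      }
      if (any(!is.na(sub[, !applicable, drop = FALSE]))) {
        stop("answers present for questions not applicable to sex ", s,
             call. = FALSE)
      }
    }
  }
  invisible(cohort)
}

#' Read / write an answer cohort as CSV
#'
#' One row per record; question columns `q<id>` hold `A`/`B`/`C`/`D`, blank
#' cells read as `NA` (question not applicable).
#'
#' @param path CSV path.
#' @return `read_cohort`: the cohort data.frame. `write_cohort`: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = c("", "NA"))
  df$record_id <- as.character(df$record_id)
  if ("inquiry_seconds" %in% names(df)) {
    df$inquiry_seconds <- as.numeric(df$inquiry_seconds)
  }
  validate_cohort(df)
  df
}

#' @rdname read_cohort
#' @param cohort Cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
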