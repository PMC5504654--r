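#' Severity filter for quantification
#'
#' Quantification can use all answered symptoms (the overall health state) or
#' only severe ones (the major health state). Severity is defined by answer
#' level: by default only level A ("severe / always") counts as severe;
#' level B may be admitted via `severe_levels`.
#'
#' @param mode `"all_symptoms"` or `"severe_only"`.
#' @param severe_levels Subset of `c("A", "B")` used when
#'   `mode = "severe_only"`.
#' @return A `severity_filter` list.
#' @export
severity_filter <- function(mode = c("all_symptoms", "severe_only"),
                            severe_levels = "A") {
  mode <- match.arg(mode)
  if (mode == "severe_only") {
    if (length(severe_levels) == 0L || !all(severe_levels %in% c("A", "B"))) {
      stop("severe_levels must be a non-empty subset of c('A','B')",
           call. = FALSE)
    }
  }
  structure(list(mode = mode, severe_levels = severe_levels),
            class = "severity_filter")
}

# Answer labels -> filtered weight vector for one record.
filtered_answer_weights <- function(labels, filter) {
  w <- answer_weight(labels)
  if (filter$mode == "severe_only") {
    w[is.na(labels) | !(labels %in% filter$severe_levels)] <- 0
  }
  w
}

#' Quantify one answer record into syndrome-element values
#'
#' The value of element e is the weighted sum, over answered questions q that
#' pass the severity filter, of `answer_weight(q) * matrix_weight(q, e)` —
#' i.e. the product of the record's answer-weight vector with the mapping
#' matrix. No normalisation is applied; downstream value-order assignment is
#' scale-free within each group.
#'
#' @param answers Named character vector of answer labels; names are question
#'   ids matching the matrix's row names. `NA` answers (not-applicable
#'   questions) contribute nothing.
#' @param matrix A [mapping_matrix()].
#' @param filter A [severity_filter()].
#' @return Named numeric vector of element values (names = matrix columns).
#' @examples
#' m <- matrix(0, 1, 47, dimnames = list("1", paste0("e", 1:47)))
#' m[1, "e28"] <- 40
#' mm <- mapping_matrix(m, "original")
#' compute_element_values(c(`1` = "A"), mm)  # e28 = 40
#' @export
compute_element_values <- function(answers, matrix,
                                   filter = severity_filter()) {
  qid <- names(answers)
  if (is.null(qid)) stop("`answers` must be named by question id", call. = FALSE)
  missing <- setdiff(qid, rownames(matrix))
  if (length(missing)) {
    stop("question id(s) absent from mapping matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  w <- filtered_answer_weights(answers, filter)
  v <- as.numeric(w %*% unclass(matrix)[qid, , drop = FALSE])
  names(v) <- colnames(matrix)
  v
}

#' Quantify a cohort of answer records
#'
#' Order-preserving batch version of [compute_element_values()]. Under a
#' severe-only filter, records containing no severe answer are flagged: they
#' carry no information about the major health state and are dropped from
#' severe-mode evaluation (mirroring the restriction of a cohort to its
#' records with severe symptoms).
#'
#' @param cohort Cohort data.frame (see [cohort]).
#' @param matrix A [mapping_matrix()].
#' @param filter A [severity_filter()].
#' @return A list with `values` (numeric matrix, records x elements, rownames
#'   = record ids) and `flagged` (logical vector; TRUE where no answer passed
#'   a severe-only filter).
#' @export
batch_quantify <- function(cohort, matrix, filter = severity_filter()) {
  qcols <- question_columns(cohort)
  qid <- sub("^q", "", qcols)
  missing <- setdiff(qid, rownames(matrix))
  if (length(missing)) {
    stop("question id(s) absent from mapping matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ans <- as.matrix(cohort[, qcols, drop = FALSE])
  n <- nrow(ans)
  if (n == 0L) {
    return(list(
      values = matrix(0, 0, ncol(matrix), dimnames = list(NULL, colnames(matrix))),
      flagged = logical(0)
    ))
  }
  W <- vapply(seq_len(n), function(i) {
    filtered_answer_weights(ans[i, ], filter)
  }, numeric(length(qcols)))
  W <- t(W)  # records x questions
  values <- W %*% unclass(matrix)[qid, , drop = FALSE]
  rownames(values) <- cohort$record_id
  flagged <- if (filter$mode == "severe_only") {
    vapply(seq_len(n), function(i) {
      !any(ans[i, ] %in% filter$severe_levels)
    }, logical(1))
  } else {
    rep(FALSE, n)
  }
  names(flagged) <- cohort$record_id
  list(values = values, flagged = flagged)
}
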