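#' Synthetic mapping-matrix specification
#'
#' Parameters for simulating a sparse symptom-to-element mapping matrix of
#' the shape the quantification model expects: each question maps to a
#' handful of elements with positive weights on the (0, 100) scale, every
#' evaluable element is reachable from at least one question, and the
#' composite elements 7 and 8 carry no direct mapping.
#'
#' @param n_questions Number of questionnaire rows (default 194, the full
#'   two-sex questionnaire; 177 gives the male-only layout).
#' @param links_per_question Integer range (length-2) of elements mapped per
#'   question.
#' @param weight_range Range of original weights, inside (0, 100).
#' @param seed Integer RNG seed; the matrix is reproducible from it.
#' @param registry Element registry.
#' @return A `matrix_spec` list.
#' @export
matrix_spec <- function(n_questions = 194L, links_per_question = c(2L, 6L),
                        weight_range = c(0.5, 99.5), seed = 1L,
                        registry = load_registry()) {
  stopifnot(n_questions >= 1L, length(links_per_question) == 2L,
            links_per_question[1] >= 1L,
            links_per_question[2] >= links_per_question[1],
            weight_range[1] > 0, weight_range[2] < 100,
            weight_range[1] < weight_range[2])
  n_eval <- sum(registry$evaluable)
  if (links_per_question[2] > n_eval) {
    stop("links_per_question exceeds the number of evaluable elements",
         call. = FALSE)
  }
  structure(list(n_questions = as.integer(n_questions),
                 links_per_question = as.integer(links_per_question),
                 weight_range = weight_range, seed = as.integer(seed),
                 registry = registry),
            class = "matrix_spec")
}

#' Simulate a mapping matrix
#'
#' @param spec A [matrix_spec()].
#' @return A [mapping_matrix()] with scale `"original"`; columns e7 and e8
#'   are all-zero, every other element column has at least one positive
#'   weight.
#' @examples
#' m <- generate_matrix(matrix_spec(n_questions = 20, seed = 7))
#' identical(unclass(m), unclass(generate_matrix(matrix_spec(n_questions = 20, seed = 7))))
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "matrix_spec"))
  reg <- spec$registry
  ev_idx <- reg$index[reg$evaluable]
  with_seed(spec$seed, {
    w <- matrix(0, spec$n_questions, nrow(reg),
                dimnames = list(as.character(seq_len(spec$n_questions)),
                                reg$label))
    for (q in seq_len(spec$n_questions)) {
      k <- sample(seq(spec$links_per_question[1], spec$links_per_question[2]), 1L)
      els <- sample(ev_idx, k)
      w[q, reg$label[els]] <- stats::runif(k, spec$weight_range[1],
                                           spec$weight_range[2])
    }
    # guarantee every evaluable element at least one mapped question
    orphan <- ev_idx[colSums(w[, reg$label[ev_idx], drop = FALSE] > 0) == 0]
    for (e in orphan) {
      q <- sample(spec$n_questions, 1L)
      w[q, reg$label[e]] <- stats::runif(1, spec$weight_range[1],
                                         spec$weight_range[2])
    }
    mapping_matrix(w, "original")
  })
}

#' Synthetic cohort specification
#'
#' Parameters for simulating questionnaire answer records. The default
#' answer-level distribution makes symptomatic answers sparse (most
#' questions answered D, "none/never") while giving roughly 80% of records
#' at least one severe (A) answer over a 177-question form — so that a
#' severe-only analysis retains the bulk of the cohort, as in a general
#' health-screening population.
#'
#' @param n_records Cohort size (default 670).
#' @param sex_ratio Probability a record is male (default 301/670).
#' @param answer_probs Named probabilities over `c(A,B,C,D)`, summing to 1.
#' @param inquiry_time_mean,inquiry_time_sd Gaussian inquiry-duration model
#'   in seconds (truncated at 0).
#' @param seed Integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_records = 670L, sex_ratio = 301 / 670,
                        answer_probs = c(A = 0.009, B = 0.06, C = 0.15, D = 0.781),
                        inquiry_time_mean = 900, inquiry_time_sd = 300,
                        seed = 1L) {
  stopifnot(n_records >= 0L, sex_ratio >= 0, sex_ratio <= 1)
  if (!identical(sort(names(answer_probs)), c("A", "B", "C", "D")) ||
      abs(sum(answer_probs) - 1) > 1e-9 || any(answer_probs < 0)) {
    stop("answer_probs must be non-negative, named A..D and sum to 1",
         call. = FALSE)
  }
  structure(list(n_records = as.integer(n_records), sex_ratio = sex_ratio,
                 answer_probs = answer_probs[c("A", "B", "C", "D")],
                 inquiry_time_mean = inquiry_time_mean,
                 inquiry_time_sd = inquiry_time_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate an answer cohort
#'
#' Draws each record's sex, its answers to all sex-applicable questions
#' (i.i.d. from the spec's answer-level distribution) and its inquiry
#' duration. Questions not applicable to the record's sex are `NA`.
#'
#' @param spec A [cohort_spec()].
#' @param questionnaire Questionnaire layout (default
#'   [default_questionnaire()]).
#' @return A cohort data.frame (see [cohort]), reproducible from the seed.
#' @export
generate_cohort <- function(spec, questionnaire = default_questionnaire()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_records
  qids <- questionnaire$question_id
  with_seed(spec$seed, {
    sex <- ifelse(stats::runif(n) < spec$sex_ratio, "male", "female")
    ans <- matrix(NA_character_, n, length(qids),
                  dimnames = list(NULL, paste0("q", qids)))
    for (i in seq_len(n)) {
      appl <- qids %in% questionnaire_ids(questionnaire, sex[i])
      ans[i, appl] <- sample(c("A", "B", "C", "D"), sum(appl), replace = TRUE,
                             prob = spec$answer_probs)
    }
    secs <- pmax(stats::rnorm(n, spec$inquiry_time_mean, spec$inquiry_time_sd), 0)
    cohort <- data.frame(
      record_id = sprintf("r%04d", seq_len(n)),
      sex = sex,
      inquiry_seconds = round(secs, 1),
      ans,
      check.names = FALSE,
      stringsAsFactors = FALSE
    )
    cohort
  })
}

#' Screen a cohort by the three exclusion criteria
#'
#' Excludes (a) records without any symptoms (every answered question D),
#' (b) records whose inquiry time falls below the supplied minimum, and
#' (c) records whose answers to all applicable questions are identical.
#' Criteria are tested in order a, b, c and each excluded record carries the
#' first reason that applies (an all-D record is tagged `a` even though `c`
#' also holds; an all-A record is tagged `c`). Kept and excluded records
#' partition the input.
#'
#' @param cohort Cohort data.frame.
#' @param min_inquiry_seconds Minimum acceptable inquiry duration in
#'   seconds. No default exists: the normal inquiry-time standard is
#'   deployment-specific and must be supplied.
#' @return A list with `kept` (cohort subset) and `excluded` (data.frame
#'   with `record_id` and `reason` in `c("a","b","c")`).
#' @export
screen_cohort <- function(cohort, min_inquiry_seconds) {
  if (missing(min_inquiry_seconds)) {
    stop("min_inquiry_seconds must be supplied (no standard default exists)",
         call. = FALSE)
  }
  qcols <- question_columns(cohort)
  ans <- as.matrix(cohort[, qcols, drop = FALSE])
  reason <- rep(NA_character_, nrow(cohort))
  all_d <- apply(ans, 1, function(a) all(is.na(a) | a == "D") )
  reason[all_d] <- "a"
  if ("inquiry_seconds" %in% names(cohort)) {
    short <- !is.na(cohort$inquiry_seconds) &
      cohort$inquiry_seconds < min_inquiry_seconds
    reason[is.na(reason) & short] <- "b"
  }
  uniform <- apply(ans, 1, function(a) length(unique(a[!is.na(a)])) == 1L)
  reason[is.na(reason) & uniform] <- "c"
  keep <- is.na(reason)
  list(
    kept = cohort[keep, , drop = FALSE],
    excluded = data.frame(record_id = cohort$record_id[!keep],
                          reason = reason[!keep],
                          stringsAsFactors = FALSE)
  )
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
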