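#' Construct a mapping-weight matrix
#'
#' A mapping matrix links inquiry questions (rows) to syndrome elements
#' (columns). A zero entry means "no mapping"; positive entries are mapping
#' weights. Two weight scales exist: `"original"` weights are reals in the
#' open interval (0, 100); `"condensed"` weights live on the small ordinal
#' scale `{2,3,4,5,6,8,10}` produced by the condensation rules.
#'
#' @param weights Numeric matrix, questions x elements. Row names must be
#'   question ids (coerced to character), column names element labels
#'   `e1..e47`; if `weights` is unnamed they are filled in as `1..nrow` and
#'   `e1..e47` (requiring 47 columns).
#' @param scale `"original"` or `"condensed"`.
#' @return An object of class `mapping_matrix` (a numeric matrix with a
#'   `scale` attribute).
#' @examples
#' m <- matrix(0, 2, 47, dimnames = list(1:2, paste0("e", 1:47)))
#' m[1, "e28"] <- 40
#' mm <- mapping_matrix(m, "original")
#' matrix_scale(mm)
#' @export
mapping_matrix <- function(weights, scale = c("original", "condensed")) {
  scale <- match.arg(scale)
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(weights))) rownames(weights) <- as.character(seq_len(nrow(weights)))
  if (is.null(colnames(weights))) {
    if (ncol(weights) != 47L) {
      stop("unnamed weight matrices must have 47 element columns", call. = FALSE)
    }
    colnames(weights) <- paste0("e", 1:47)
  }
  validate_mapping_weights(weights, scale)
  structure(weights, scale = scale, class = c("mapping_matrix", class(weights)))
}

validate_mapping_weights <- function(weights, scale) {
  if (anyNA(weights)) stop("mapping weights contain NA", call. = FALSE)
  if (any(weights < 0)) stop("mapping weights must be non-negative", call. = FALSE)
  pos <- weights[weights > 0]
  if (scale == "original") {
    if (any(pos >= 100)) {
      stop("original-scale weights must lie in (0, 100); found ",
           max(pos), call. = FALSE)
    }
  } else {
    ok <- pos %in% c(2, 3, 4, 5, 6, 8, 10)
    if (!all(ok)) {
      stop("condensed-scale weights must be in {2,3,4,5,6,8,10}; found ",
           paste(unique(pos[!ok]), collapse = ", "), call. = FALSE)
    }
  }
  if (anyDuplicated(rownames(weights))) {
    stop("duplicate question ids in mapping matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(weights))) {
    stop("duplicate element columns in mapping matrix", call. = FALSE)
  }
  invisible(weights)
}

#' @rdname mapping_matrix
#' @param x A `mapping_matrix`.
#' @export
matrix_scale <- function(x) attr(x, "scale")

#' @export
print.mapping_matrix <- function(x, ...) {
  nz <- sum(x > 0)
  cat(sprintf(
    "<mapping_matrix> %d questions x %d elements, scale = %s, %d mapped pairs (density %.1f%%)\n",
    nrow(x), ncol(x), matrix_scale(x), nz, 100 * nz / length(x)
  ))
  invisible(x)
}

#' Read a mapping matrix from CSV
#'
#' Two dialects are supported. `"wide"`: one row per question, first column
#' `question_id`, remaining columns named `e<index>`; cells are weights
#' (0 or empty = no mapping). `"long"`: columns `question_id`,
#' `element_index`, `weight`, one row per mapped pair.
#'
#' @param path CSV file path.
#' @param dialect `"wide"` or `"long"`.
#' @param scale Weight scale of the stored matrix (`"original"` or
#'   `"condensed"`); values outside the declared scale's domain are rejected.
#' @param n_elements Number of element columns for long-dialect expansion
#'   (default 47).
#' @return A [mapping_matrix()].
#' @export
read_matrix <- function(path, dialect = c("wide", "long"),
                        scale = c("original", "condensed"),
                        n_elements = 47L) {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "wide") {
    if (names(df)[1] != "question_id") {
      stop("wide matrix CSV must start with a question_id column: ", path,
           call. = FALSE)
    }
    qid <- as.character(df$question_id)
    w <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(w)) stop("non-numeric weight cells in ", path, call. = FALSE)
    w[is.na(w)] <- 0
    rownames(w) <- qid
  } else {
    need <- c("question_id", "element_index", "weight")
    if (!all(need %in% names(df))) {
      stop("long matrix CSV needs columns question_id, element_index, weight",
           call. = FALSE)
    }
    key <- paste(df$question_id, df$element_index)
    if (anyDuplicated(key)) {
      dup <- which(duplicated(key))[1]
      stop(sprintf("duplicate (question, element) pair at data row %d of %s",
                   dup, path), call. = FALSE)
    }
    qid <- as.character(sort(unique(df$question_id)))
    w <- matrix(0, length(qid), n_elements,
                dimnames = list(qid, paste0("e", seq_len(n_elements))))
    ei <- as.integer(df$element_index)
    if (any(is.na(ei)) || any(ei < 1L) || any(ei > n_elements)) {
      stop("element_index out of range 1..", n_elements, " in ", path,
           call. = FALSE)
    }
    w[cbind(as.character(df$question_id), paste0("e", ei))] <- df$weight
  }
  mapping_matrix(w, scale)
}

#' Write a mapping matrix to CSV
#'
#' @param x A [mapping_matrix()].
#' @param path Output CSV path.
#' @param dialect `"wide"` or `"long"` (see [read_matrix()]).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    df <- data.frame(question_id = rownames(x), unclass(x)[, , drop = FALSE],
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    idx <- which(x > 0, arr.ind = TRUE)
    df <- data.frame(
      question_id = rownames(x)[idx[, 1]],
      element_index = as.integer(sub("^e", "", colnames(x)[idx[, 2]])),
      weight = x[idx],
      stringsAsFactors = FALSE
    )
    df <- df[order(as.integer(df$question_id), df$element_index), ]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
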