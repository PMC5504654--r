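#' Condensation rules
#'
#' Four rules condense original real-valued mapping weights in (0, 100) onto
#' a small ordinal scale, named by their basis and granularity:
#' Symptom_Normal and Symptom_Fuzzy quantize each weight value directly;
#' Element_Normal and Element_Fuzzy quantize each weight's ratio to the
#' maximum weight of its element column. Normal granularity outputs
#' `{2,4,6,10}`; fuzzy granularity adds secondary weights near interval
#' boundaries, outputting `{2,3,4,5,6,8,10}`.
#'
#' @param basis `"symptom"` (quantize the value) or `"element"` (quantize the
#'   ratio to the element-column maximum).
#' @param granularity `"normal"` or `"fuzzy"`.
#' @return A `condense_rule` list with a `name` field such as
#'   `"Symptom_Normal"`.
#' @examples
#' condense_rule("symptom", "normal")$name
#' @export
condense_rule <- function(basis = c("symptom", "element"),
                          granularity = c("normal", "fuzzy")) {
  basis <- match.arg(basis)
  granularity <- match.arg(granularity)
  name <- paste0(tools::toTitleCase(basis), "_", tools::toTitleCase(granularity))
  structure(list(basis = basis, granularity = granularity, name = name),
            class = "condense_rule")
}

#' Parse a rule name like "symptom_normal"
#' @param name One of `"symptom_normal"`, `"symptom_fuzzy"`,
#'   `"element_normal"`, `"element_fuzzy"` (case-insensitive).
#' @return A [condense_rule()].
#' @export
parse_rule <- function(name) {
  parts <- strsplit(tolower(name), "_", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("unknown rule name: ", name, call. = FALSE)
  condense_rule(parts[1], parts[2])
}

# Interval tables. Each row: lower, upper, lower-closed, upper-closed, weight.
# Intervals are pairwise disjoint and cover the stated domain exactly.
value_intervals <- function(granularity) {
  if (granularity == "normal") {
    # the printed normal brackets double-cover the value 10 ([10,25) and
    # (0,10]); the left-closed band wins, so 10 -> 4 and the bottom band is
    # effectively (0,10)
    rbind(
      c(40, 100, 1, 0, 10),
      c(25, 40, 1, 0, 6),
      c(10, 25, 1, 0, 4),
      c(0, 10, 0, 0, 2)
    )
  } else {
    rbind(
      c(45, 100, 1, 0, 10),
      c(40, 45, 1, 0, 8),
      c(35, 40, 1, 0, 8),
      c(30, 35, 1, 0, 6),
      c(25, 30, 1, 0, 5),
      c(20, 25, 1, 0, 5),
      c(12, 20, 1, 0, 4),
      c(10, 12, 0, 0, 3),
      c(8, 10, 0, 1, 3),
      c(0, 8, 0, 1, 2)
    )
  }
}

ratio_intervals <- function(granularity) {
  if (granularity == "normal") {
    rbind(
      c(0.6, 1, 1, 1, 10),
      c(0.4, 0.6, 1, 0, 6),
      c(0.2, 0.4, 1, 0, 4),
      c(0, 0.2, 0, 0, 2)
    )
  } else {
    rbind(
      c(0.65, 1, 1, 1, 10),
      c(0.6, 0.65, 1, 0, 8),
      c(0.55, 0.6, 1, 0, 8),
      c(0.45, 0.55, 1, 0, 6),
      c(0.4, 0.45, 1, 0, 5),
      c(0.35, 0.4, 1, 0, 5),
      c(0.25, 0.35, 1, 0, 4),
      c(0.2, 0.25, 0, 0, 3),
      c(0.15, 0.2, 0, 1, 3),
      c(0, 0.15, 0, 1, 2)
    )
  }
}

interval_lookup <- function(x, tab) {
  out <- rep(NA_real_, length(x))
  for (i in seq_len(nrow(tab))) {
    lo <- tab[i, 1]; hi <- tab[i, 2]
    inlo <- if (tab[i, 3] == 1) x >= lo else x > lo
    inhi <- if (tab[i, 4] == 1) x <= hi else x < hi
    hit <- is.na(out) & inlo & inhi
    out[hit] <- tab[i, 5]
  }
  out
}

#' Quantize an original weight value
#'
#' Symptom-basis condensation: maps a weight in (0, 100) to its condensed
#' weight. Normal intervals: \[40,100)->10, \[25,40)->6, \[10,25)->4,
#' (0,10\]->2. Fuzzy intervals add secondary weights near boundaries:
#' \[45,100)->10, \[40,45)->8, \[35,40)->8, \[30,35)->6, \[25,30)->5,
#' \[20,25)->5, \[12,20)->4, (10,12)->3, (8,10\]->3, (0,8\]->2.
#'
#' @param v Numeric vector of original weights, each in (0, 100).
#' @param granularity `"normal"` or `"fuzzy"`.
#' @return Numeric vector of condensed weights.
#' @examples
#' quantize_value(50, "normal")  # 10
#' quantize_value(42, "fuzzy")   # 8
#' @export
quantize_value <- function(v, granularity = c("normal", "fuzzy")) {
  granularity <- match.arg(granularity)
  if (anyNA(v) || any(v <= 0) || any(v >= 100)) {
    stop("original weights must lie in the open interval (0, 100)",
         call. = FALSE)
  }
  interval_lookup(v, value_intervals(granularity))
}

#' Quantize a weight-to-element-maximum ratio
#'
#' Element-basis condensation: maps a ratio in (0, 1\] to its condensed
#' weight. Normal intervals: \[0.6,1\]->10, \[0.4,0.6)->6, \[0.2,0.4)->4,
#' (0,0.2)->2. Fuzzy intervals: \[0.65,1\]->10, \[0.6,0.65)->8,
#' \[0.55,0.6)->8, \[0.45,0.55)->6, \[0.4,0.45)->5, \[0.35,0.4)->5,
#' \[0.25,0.35)->4, (0.2,0.25)->3, (0.15,0.2\]->3, (0,0.15\]->2.
#'
#' @param r Numeric vector of ratios, each in (0, 1\].
#' @param granularity `"normal"` or `"fuzzy"`.
#' @return Numeric vector of condensed weights.
#' @examples
#' quantize_ratio(0.65, "normal")  # 10
#' quantize_ratio(0.2, "fuzzy")    # 3
#' @export
quantize_ratio <- function(r, granularity = c("normal", "fuzzy")) {
  granularity <- match.arg(granularity)
  if (anyNA(r) || any(r <= 0) || any(r > 1)) {
    stop("ratios must lie in (0, 1]", call. = FALSE)
  }
  interval_lookup(r, ratio_intervals(granularity))
}

#' Condense a mapping matrix
#'
#' Applies one of the four condensation rules to every positive entry of an
#' original-scale mapping matrix; zeros (no mapping) are preserved, as are
#' dimensions and dimnames. Under element basis, each entry is first divided
#' by the maximum weight of its element column (computed over the whole
#' matrix); columns with no positive entry are skipped with a warning, since
#' no maximum exists.
#'
#' @param matrix A [mapping_matrix()] with scale `"original"`.
#' @param rule A [condense_rule()] or a rule name accepted by [parse_rule()].
#' @return A [mapping_matrix()] with scale `"condensed"`.
#' @examples
#' m <- matrix(0, 3, 47, dimnames = list(1:3, paste0("e", 1:47)))
#' m[, "e28"] <- c(80, 40, 8)
#' cm <- condense_matrix(mapping_matrix(m, "original"), "element_normal")
#' cm[, "e28"]  # 10 6 2
#' @export
condense_matrix <- function(matrix, rule) {
  if (is.character(rule)) rule <- parse_rule(rule)
  if (!inherits(matrix, "mapping_matrix") || matrix_scale(matrix) != "original") {
    stop("`matrix` must be a mapping_matrix with scale 'original'",
         call. = FALSE)
  }
  w <- unclass(matrix)
  attr(w, "scale") <- NULL
  out <- w
  if (rule$basis == "symptom") {
    pos <- w > 0
    out[pos] <- quantize_value(w[pos], rule$granularity)
  } else {
    for (j in seq_len(ncol(w))) {
      col <- w[, j]
      pos <- col > 0
      if (!any(pos)) {
        next
      }
      mx <- max(col[pos])
      out[pos, j] <- quantize_ratio(col[pos] / mx, rule$granularity)
    }
    empty <- colSums(w > 0) == 0
    # warn once for evaluable-style columns that carry no mapping at all;
    # e7/e8 columns are expected to be empty and are not warned about
    unexpected <- setdiff(colnames(w)[empty], c("e7", "e8"))
    if (length(unexpected)) {
      warning("element column(s) with no positive weight skipped: ",
              paste(unexpected, collapse = ", "), call. = FALSE)
    }
  }
  mapping_matrix(out, "condensed")
}
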