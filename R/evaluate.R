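#' Value-order rules
#'
#' An element's value order is an ordinal rank of its quantitative value
#' relative to the maximum value within its differentiation group:
#' ratio r = value / group maximum, with orders
#' \[0.95,1\]->8, \[0.9,0.95)->7, \[0.85,0.9)->6, \[0.8,0.85)->5,
#' \[0.6,0.8)->4, \[0.4,0.6)->3, \[0.2,0.4)->2, (0,0.2)->1, and order 0 for
#' value 0. Each order carries a weight used by the matched-degree statistic:
#' orders 8..1 weigh 1, 0.95, 0.9, 0.8, 0.7, 0.6, 0.4, 0.2; order 0 weighs 0.
#'
#' @name value_orders
NULL

order_ratio_breaks <- function() {
  # lower bound (closed) of each order 1..8 band; order 1 band is open at 0
  c(0, 0.2, 0.4, 0.6, 0.8, 0.85, 0.9, 0.95)
}

#' Weight attached to a value order
#' @param order Integer vector of orders in 0..8.
#' @return Numeric vector of order weights.
#' @export
order_weight <- function(order) {
  w <- c(0, 0.2, 0.4, 0.6, 0.7, 0.8, 0.9, 0.95, 1)
  if (any(is.na(order)) || any(order < 0L) || any(order > 8L)) {
    stop("value orders must be integers in 0..8", call. = FALSE)
  }
  w[order + 1L]
}

ratio_to_order <- function(r) {
  # r in (0, 1]; bands are left-closed (ratio exactly 0.2 -> order 2)
  findInterval(r, order_ratio_breaks())
}

#' Assign per-group value orders to element values
#'
#' For each differentiation group, the maximum value among the group's
#' evaluable elements defines the reference; every evaluable element's value
#' is converted to a ratio and mapped to an order (see [value_orders]).
#' Elements with value 0 — and entire groups whose maximum is 0 — receive
#' order 0. Elements 7 and 8 are not evaluable and are never assigned an
#' order.
#'
#' @param values Named numeric vector of element values (names `e1..e47`),
#'   e.g. one row of [batch_quantify()] output or the result of
#'   [compute_element_values()].
#' @param registry Element registry from [load_registry()].
#' @return A data.frame with one row per evaluable element: `index`, `label`,
#'   `group`, `value`, `ratio` (NA for zero values), `order` (0..8) and
#'   `weight` (the order's weight).
#' @examples
#' reg <- load_registry()
#' v <- setNames(numeric(47), reg$label)
#' v["e28"] <- 40; v["e26"] <- 20
#' vo <- assign_value_orders(v, reg)
#' vo[vo$label %in% c("e28", "e26"), c("label", "order")]  # 8 and 3
#' @export
assign_value_orders <- function(values, registry = load_registry()) {
  ev <- registry[registry$evaluable, ]
  miss <- setdiff(ev$label, names(values))
  if (length(miss)) {
    stop("values missing for evaluable element(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  v <- values[ev$label]
  if (any(v < 0)) stop("element values must be non-negative", call. = FALSE)
  ratio <- rep(NA_real_, nrow(ev))
  ord <- integer(nrow(ev))
  for (g in levels(ev$group)) {
    sel <- ev$group == g
    mx <- max(v[sel])
    if (mx > 0) {
      pos <- sel & v > 0
      ratio[pos] <- v[pos] / mx
      ord[pos] <- ratio_to_order(ratio[pos])
    }
  }
  data.frame(
    index = ev$index, label = ev$label, group = ev$group,
    value = unname(v), ratio = ratio, order = ord,
    weight = order_weight(ord),
    stringsAsFactors = FALSE
  )
}

#' Matched degree of one differentiation group
#'
#' Agreement between two value-order assignments over one group's evaluable
#' elements: MDG = (CG - sum of SE_W over mismatched elements) / CG, where
#' CG is the group's evaluable element count, an element is mismatched when
#' its order differs between the reference and test assignments, and SE_W is
#' the order weight of the mismatched element (taken from the reference
#' order by default; see `se_w_source`).
#'
#' @param ref,test Value-order data.frames from [assign_value_orders()]; the
#'   reference is conventionally the original-weight assignment.
#' @param group Group id (a level of the registry's `group` factor).
#' @param se_w_source Where the mismatch weight SE_W comes from:
#'   `"reference"` (default), `"test"`, or `"max"` (the larger of the two).
#' @return A list with `group`, `cg`, `n_mismatch`, `mismatch_sum` and `mdg`.
#' @examples
#' reg <- load_registry()
#' v <- setNames(numeric(47), reg$label); v["e1"] <- 10; v["e2"] <- 7
#' a <- assign_value_orders(v, reg)
#' b <- a; b$order[b$label == "e2"] <- 3; b$weight <- order_weight(b$order)
#' group_matched_degree(a, b, "eight_principle")$mdg  # (6 - 0.7) / 6
#' @export
group_matched_degree <- function(ref, test, group,
                                 se_w_source = c("reference", "test", "max")) {
  se_w_source <- match.arg(se_w_source)
  r <- ref[ref$group == group, ]
  t <- test[test$group == group, ]
  if (nrow(r) == 0L) stop("unknown group: ", group, call. = FALSE)
  if (!identical(r$label, t$label)) {
    stop("reference and test cover different elements for group ", group,
         call. = FALSE)
  }
  cg <- nrow(r)
  mis <- r$order != t$order
  sew <- switch(se_w_source,
    reference = order_weight(r$order),
    test = order_weight(t$order),
    max = pmax(order_weight(r$order), order_weight(t$order))
  )
  msum <- sum(sew[mis])
  list(group = group, cg = cg, n_mismatch = sum(mis),
       mismatch_sum = msum, mdg = (cg - msum) / cg)
}

#' Integrated matched degree
#'
#' Weighted mean of the four group matched degrees:
#' MD = sum over groups of MDG * CG / CT, with CT the total evaluable element
#' count (45).
#'
#' @param groups List of four results from [group_matched_degree()].
#' @param ct Total evaluable count; group sizes must sum to it.
#' @return MD as a single number in \[0, 1\].
#' @export
integrated_matched_degree <- function(groups, ct = 45L) {
  cg <- vapply(groups, `[[`, numeric(1), "cg")
  if (sum(cg) != ct) {
    stop("group element counts sum to ", sum(cg), ", expected ", ct,
         call. = FALSE)
  }
  mdg <- vapply(groups, `[[`, numeric(1), "mdg")
  sum(mdg * cg) / ct
}

#' Matched-degree distribution bins
#'
#' Cohort matched degrees are summarised, on the percent scale, over the
#' bins \[95,100\], \[90,95), \[85,90), \[80,85), \[75,80), \[70,75),
#' \[65,70), \[60,65), \[0,60) — left-closed except the top bin, which is
#' closed on both sides.
#'
#' @param md_percent Numeric vector of matched degrees in percent (0..100).
#' @return A named integer vector of counts over the nine bins, in the order
#'   listed above; counts sum to `length(md_percent)`.
#' @export
md_histogram <- function(md_percent) {
  if (any(md_percent < 0 | md_percent > 100)) {
    stop("matched degrees in percent must lie in [0, 100]", call. = FALSE)
  }
  labels <- md_bin_labels()
  lower <- c(95, 90, 85, 80, 75, 70, 65, 60, 0)
  counts <- integer(9L)
  for (i in seq_along(lower)) {
    hit <- md_percent >= lower[i]
    counts[i] <- sum(hit)
    md_percent <- md_percent[!hit]
  }
  stats::setNames(counts, labels)
}

md_bin_labels <- function() {
  c("[95,100]", "[90,95)", "[85,90)", "[80,85)", "[75,80)", "[70,75)",
    "[65,70)", "[60,65)", "[0,60)")
}

#' Evaluate condensed weights against original weights over a cohort
#'
#' The full evaluation pipeline for one condensation rule: each record is
#' quantified under both matrices, value orders are assigned under both, and
#' the original-matrix orders serve as the standard against which the
#' condensed-matrix orders are scored. Under a severe-only filter, records
#' with no severe answer are excluded (they carry no major-health-state
#' signal). Cohort-level distributions over the matched-degree bins are
#' reported per group and for the integrated matched degree.
#'
#' @param cohort Cohort data.frame (see [cohort]).
#' @param original_matrix,condensed_matrix [mapping_matrix()] objects with
#'   identical dimensions (scales `"original"` and `"condensed"`).
#' @param filter A [severity_filter()].
#' @param registry Element registry.
#' @param se_w_source Passed to [group_matched_degree()].
#' @return A `match_report` list: `records` (data.frame with `record_id`,
#'   one `mdg_<group>` column per group, and `md`, all in \[0,1\]),
#'   `histograms` (named list: one counts vector per group plus
#'   `"integrated"`, percent-scale bins), `n_evaluated`, `n_excluded`,
#'   and `filter`.
#' @export
evaluate_condensed <- function(cohort, original_matrix, condensed_matrix,
                               filter = severity_filter(),
                               registry = load_registry(),
                               se_w_source = "reference") {
  if (!identical(dim(original_matrix), dim(condensed_matrix)) ||
      !identical(rownames(original_matrix), rownames(condensed_matrix))) {
    stop("original and condensed matrices must share dimensions and question ids",
         call. = FALSE)
  }
  q_ref <- batch_quantify(cohort, original_matrix, filter)
  q_tst <- batch_quantify(cohort, condensed_matrix, filter)
  keep <- !q_ref$flagged
  ids <- cohort$record_id[keep]
  groups <- levels(registry$group)
  rec <- data.frame(record_id = ids, stringsAsFactors = FALSE)
  for (g in groups) rec[[paste0("mdg_", g)]] <- numeric(length(ids))
  rec$md <- numeric(length(ids))
  for (i in seq_along(ids)) {
    vo_ref <- assign_value_orders(q_ref$values[ids[i], ], registry)
    vo_tst <- assign_value_orders(q_tst$values[ids[i], ], registry)
    gms <- lapply(groups, function(g) {
      group_matched_degree(vo_ref, vo_tst, g, se_w_source)
    })
    for (k in seq_along(groups)) {
      rec[[paste0("mdg_", groups[k])]][i] <- gms[[k]]$mdg
    }
    rec$md[i] <- integrated_matched_degree(gms, ct = sum(registry$evaluable))
  }
  hist <- lapply(groups, function(g) {
    md_histogram(100 * rec[[paste0("mdg_", g)]])
  })
  names(hist) <- groups
  hist$integrated <- md_histogram(100 * rec$md)
  structure(
    list(records = rec, histograms = hist,
         n_evaluated = length(ids), n_excluded = sum(!keep),
         filter = filter),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report> %d records evaluated (%d excluded), mode = %s\n",
    x$n_evaluated, x$n_excluded, x$filter$mode
  ))
  cat(sprintf("  median integrated MD = %.3f\n", stats::median(x$records$md)))
  invisible(x)
}
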