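reg <- load_registry()

zero_values <- function() stats::setNames(numeric(47), reg$label)

test_that("value orders follow the per-group ratio table", {
  v <- zero_values()
  v["e28"] <- 50          # disease-cause maximum
  v["e26"] <- 25          # ratio 0.5 -> order 3
  v["e30"] <- 50 * 0.92   # ratio 0.92 -> order 7
  v["e9"]  <- 10          # qi-blood maximum (only positive member)
  vo <- assign_value_orders(v, reg)
  get <- function(lab, col) vo[[col]][vo$label == lab]
  expect_equal(get("e28", "order"), 8)   # ratio 1
  expect_equal(get("e28", "weight"), 1)
  expect_equal(get("e26", "order"), 3)
  expect_equal(get("e26", "weight"), 0.6)
  expect_equal(get("e30", "order"), 7)
  expect_equal(get("e9", "order"), 8)
  # untouched groups are fully zero
  expect_true(all(vo$order[vo$group == "visceral"] == 0))
  expect_true(all(vo$weight[vo$group == "visceral"] == 0))
  # elements 7 and 8 are never assigned an order
  expect_false(any(vo$index %in% c(7, 8)))
  expect_equal(nrow(vo), 45L)
})

test_that("value-order boundaries match the printed brackets", {
  # per-band probes on the ratio scale: lower edges are closed, order 1 band
  # is the open interval (0, 0.2)
  band <- function(r) {
    v <- zero_values(); v["e28"] <- 100; v["e26"] <- 100 * r
    vo <- assign_value_orders(v, reg)
    vo$order[vo$label == "e26"]
  }
  expect_equal(band(0.95), 8)
  expect_equal(band(0.95 - 1e-9), 7)
  expect_equal(band(0.9), 7)
  expect_equal(band(0.85), 6)
  expect_equal(band(0.8), 5)
  expect_equal(band(0.6), 4)
  expect_equal(band(0.4), 3)
  expect_equal(band(0.2), 2)
  expect_equal(band(0.2 - 1e-9), 1)
  expect_equal(band(1e-9), 1)
})

test_that("value orders are invariant to scaling all values", {
  set.seed(33)
  for (i in 1:20) {
    v <- zero_values()
    idx <- sample(which(reg$evaluable), 12)
    v[reg$label[idx]] <- stats::runif(12, 0.1, 100)
    base <- assign_value_orders(v, reg)$order
    for (c_ in c(0.01, 3, 1000)) {
      expect_equal(assign_value_orders(v * c_, reg)$order, base)
    }
    # every non-degenerate group carries an order-8 element
    vo <- assign_value_orders(v, reg)
    for (g in unique(vo$group[vo$value > 0])) {
      expect_true(8 %in% vo$order[vo$group == g])
    }
  }
})

test_that("group matched degree implements the weighted-mismatch formula", {
  v <- zero_values()
  v[reg$label[1:6]] <- c(10, 7, 3, 1.5, 9.6, 4.5)  # eight-principle values
  ref <- assign_value_orders(v, reg)

  # self-comparison: no mismatch
  gm <- group_matched_degree(ref, ref, "eight_principle")
  expect_equal(gm$mdg, 1)
  expect_equal(gm$cg, 6L)

  # one mismatched element whose reference order is 4 (weight 0.7)
  expect_equal(ref$order[ref$label == "e2"], 4)  # ratio 0.7
  test <- ref
  test$order[test$label == "e2"] <- 3
  test$weight <- order_weight(test$order)
  gm <- group_matched_degree(ref, test, "eight_principle")
  expect_equal(gm$n_mismatch, 1L)
  expect_equal(gm$mdg, (6 - 0.7) / 6)

  # all six mismatched at reference order 8 -> maximal penalty
  v8 <- zero_values(); v8[reg$label[1:6]] <- 100
  ref8 <- assign_value_orders(v8, reg)
  t8 <- ref8; t8$order <- ifelse(t8$group == "eight_principle", 1L, t8$order)
  expect_equal(group_matched_degree(ref8, t8, "eight_principle")$mdg, 0)

  # SE_W source is configurable
  gm_t <- group_matched_degree(ref, test, "eight_principle", "test")
  expect_equal(gm_t$mdg, (6 - 0.6) / 6)  # test order 3 weighs 0.6
  gm_m <- group_matched_degree(ref, test, "eight_principle", "max")
  expect_equal(gm_m$mdg, (6 - 0.7) / 6)
})

test_that("integrated matched degree is the CG-weighted mean over CT = 45", {
  mk <- function(mdg, cg, g) list(group = g, cg = cg, n_mismatch = 0L,
                                  mismatch_sum = 0, mdg = mdg)
  gs <- list(mk(1, 6L, "eight_principle"), mk(1, 7L, "disease_cause"),
             mk(1, 16L, "qi_blood_fluid_humor"), mk(0, 16L, "visceral"))
  expect_equal(integrated_matched_degree(gs), 29 / 45)
  gs1 <- lapply(gs, function(g) { g$mdg <- 1; g })
  expect_equal(integrated_matched_degree(gs1), 1)
  gs0 <- lapply(gs, function(g) { g$mdg <- 0; g })
  expect_equal(integrated_matched_degree(gs0), 0)
  gs_bad <- gs; gs_bad[[1]]$cg <- 7L
  expect_error(integrated_matched_degree(gs_bad), "sum to 46")
})

test_that("matched-degree histogram bins partition the percent scale", {
  md <- c(100, 95, 94.999, 90, 87, 80, 79.9, 70, 65, 64.9, 60, 59.9, 0)
  h <- md_histogram(md)
  expect_equal(sum(h), length(md))
  expect_equal(unname(h["[95,100]"]), 2L)
  expect_equal(unname(h["[90,95)"]), 2L)
  expect_equal(unname(h["[85,90)"]), 1L)
  expect_equal(unname(h["[80,85)"]), 1L)
  expect_equal(unname(h["[75,80)"]), 1L)
  expect_equal(unname(h["[70,75)"]), 1L)
  expect_equal(unname(h["[65,70)"]), 1L)
  expect_equal(unname(h["[60,65)"]), 2L)
  expect_equal(unname(h["[0,60)"]), 2L)
  expect_error(md_histogram(101), "\\[0, 100\\]")
})

test_that("evaluating a matrix against itself yields MD = 1 everywhere", {
  m <- generate_matrix(matrix_spec(n_questions = 40, seed = 5))
  ch <- generate_cohort(cohort_spec(n_records = 25, seed = 6),
                        questionnaire = data.frame(
                          question_id = 1:40,
                          sex_applicability = "both"))
  rep <- evaluate_condensed(ch, m, m)
  expect_equal(rep$n_evaluated, 25L)
  expect_true(all(rep$records$md == 1))
  expect_equal(unname(rep$histograms$integrated["[95,100]"]), 25L)
  expect_equal(sum(rep$histograms$integrated), 25L)
})

test_that("evaluation histograms agree with an independent per-record recount", {
  m <- generate_matrix(matrix_spec(n_questions = 30, seed = 7))
  ch <- generate_cohort(cohort_spec(n_records = 50, seed = 8),
                        questionnaire = data.frame(
                          question_id = 1:30,
                          sex_applicability = "both"))
  cm <- condense_matrix(m, "symptom_fuzzy")
  rep <- evaluate_condensed(ch, m, cm)

  # independent recount: per record, recompute MD from scratch and bin by a
  # plain cut()-style rule
  md2 <- vapply(seq_len(nrow(ch)), function(i) {
    ans <- unlist(ch[i, grep("^q", names(ch))])
    names(ans) <- sub("^q", "", names(ans))
    vo_r <- assign_value_orders(compute_element_values(ans, m), reg)
    vo_t <- assign_value_orders(compute_element_values(ans, cm), reg)
    mism <- vo_r$order != vo_t$order
    md <- 0
    for (g in levels(reg$group)) {
      sel <- vo_r$group == g
      mdg <- (sum(sel) - sum(order_weight(vo_r$order)[mism & sel])) / sum(sel)
      md <- md + mdg * sum(sel) / 45
    }
    md
  }, numeric(1))
  expect_equal(rep$records$md, md2, tolerance = 1e-12)

  edges <- c(0, 60, 65, 70, 75, 80, 85, 90, 95, 100.000001)
  recount <- rev(as.integer(table(cut(100 * rep$records$md, edges,
                                      right = FALSE))))
  expect_equal(unname(rep$histograms$integrated), recount)
  expect_equal(sum(rep$histograms$integrated), 50L)
})

test_that("severe-only evaluation restricts to records with severe symptoms", {
  m <- tiny_matrix()
  base <- stats::setNames(rep("D", 4), paste0("q", 1:4))
  recs <- list(replace(base, 1, "A"), replace(base, 2, "B"), base,
               replace(base, 3, "A"), replace(base, 2, "C"),
               replace(base, 4, "B"), base, replace(base, 1, "C"),
               replace(base, 2, "A"), replace(base, 3, "C"))
  ch <- make_cohort(recs)
  cm <- condense_matrix(m, "symptom_normal")
  rep <- evaluate_condensed(ch, m, cm, severity_filter("severe_only", "A"))
  expect_equal(rep$n_evaluated, 3L)
  expect_equal(rep$n_excluded, 7L)
  expect_equal(rep$records$record_id, c("r001", "r004", "r009"))
})
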