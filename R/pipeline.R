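#' Pipeline run configuration
#'
#' Bundles every input and parameter of the end-to-end run: where the
#' mapping matrix and answer records come from (files, or simulation specs),
#' which condensation rules to evaluate, the severity mode, screening
#' threshold, and APOSD extraction settings.
#'
#' @param matrix A [mapping_matrix()], a path to a wide-dialect matrix CSV,
#'   or a [matrix_spec()] to simulate one.
#' @param records A cohort data.frame, a path to a cohort CSV, or a
#'   [cohort_spec()] to simulate one.
#' @param rules Character vector of condensation rule names (any of
#'   `"symptom_normal"`, `"symptom_fuzzy"`, `"element_normal"`,
#'   `"element_fuzzy"`).
#' @param mode `"all_symptoms"` or `"severe_only"`.
#' @param severe_levels Severe answer levels for `"severe_only"` mode.
#' @param min_inquiry_seconds Screening threshold in seconds; `NULL` skips
#'   screening.
#' @param aposd_depth,aposd_min_support Combination extraction settings.
#' @param out_dir Output directory; `NULL` produces in-memory results only.
#' @param seed Seed used for any simulation specs that do not carry one.
#' @return A `run_config` list.
#' @export
run_config <- function(matrix, records,
                       rules = c("symptom_normal", "symptom_fuzzy",
                                 "element_normal", "element_fuzzy"),
                       mode = "all_symptoms", severe_levels = "A",
                       min_inquiry_seconds = NULL,
                       aposd_depth = 4L, aposd_min_support = 1L,
                       out_dir = NULL, seed = 1L) {
  rules <- vapply(rules, function(r) parse_rule(r)$name, character(1))
  structure(
    list(matrix = matrix, records = records, rules = unname(rules),
         mode = mode, severe_levels = severe_levels,
         min_inquiry_seconds = min_inquiry_seconds,
         aposd_depth = as.integer(aposd_depth),
         aposd_min_support = as.integer(aposd_min_support),
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

resolve_matrix <- function(x, seed) {
  if (inherits(x, "mapping_matrix")) return(x)
  if (inherits(x, "matrix_spec")) return(generate_matrix(x))
  if (is.character(x) && length(x) == 1L) return(read_matrix(x, "wide", "original"))
  stop("cannot resolve mapping matrix input", call. = FALSE)
}

resolve_records <- function(x, seed) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, "cohort_spec")) return(generate_cohort(x))
  if (is.character(x) && length(x) == 1L) return(read_cohort(x))
  stop("cannot resolve records input", call. = FALSE)
}

#' Run the full evaluation pipeline
#'
#' Orchestrates the end-to-end flow: resolve (or simulate) the mapping
#' matrix and the answer cohort, optionally screen the cohort, quantify
#' records under the original matrix, condense it under each configured
#' rule, evaluate matched degrees per rule, build the formal context from
#' the original-weight value orders and generate the APOSD with extracted
#' combinations. When `out_dir` is set, every artifact is written (CSV/JSON/
#' DOT) together with a manifest recording parameters and md5 checksums.
#'
#' @param config A [run_config()].
#' @return A list with `matrix`, `cohort` (post-screening), `screening`,
#'   `values` (original-matrix quantification), `condensed` (named list of
#'   matrices), `reports` (named list of match reports), `context`, `tree`,
#'   `combinations`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  registry <- load_registry()
  filter <- severity_filter(config$mode, config$severe_levels)

  m0 <- resolve_matrix(config$matrix, config$seed)
  cohort <- resolve_records(config$records, config$seed)
  message(sprintf("pipeline: %d records in, %d-question matrix",
                  nrow(cohort), nrow(m0)))

  screening <- NULL
  if (!is.null(config$min_inquiry_seconds)) {
    screening <- screen_cohort(cohort, config$min_inquiry_seconds)
    cohort <- screening$kept
    message(sprintf("screening: %d kept, %d excluded",
                    nrow(cohort), nrow(screening$excluded)))
  }

  quant <- batch_quantify(cohort, m0, filter)

  condensed <- lapply(config$rules, function(r) condense_matrix(m0, r))
  names(condensed) <- config$rules
  reports <- lapply(condensed, function(cm) {
    evaluate_condensed(cohort, m0, cm, filter, registry)
  })
  for (r in names(reports)) {
    message(sprintf("evaluate[%s]: %d records, median MD %.3f", r,
                    reports[[r]]$n_evaluated,
                    stats::median(reports[[r]]$records$md)))
  }

  keep <- !quant$flagged
  orders <- t(vapply(which(keep), function(i) {
    vo <- assign_value_orders(quant$values[i, ], registry)
    stats::setNames(vo$order, vo$label)
  }, numeric(sum(registry$evaluable))))
  rownames(orders) <- cohort$record_id[keep]
  context <- build_context(orders)
  tree <- generate_aposd(context)
  combinations <- extract_combinations(tree, config$aposd_depth,
                                       config$aposd_min_support)

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    manifest <- write_pipeline_outputs(
      config, m0, cohort, screening, quant, condensed, reports,
      context, tree, combinations
    )
  }

  list(matrix = m0, cohort = cohort, screening = screening,
       values = quant$values, condensed = condensed, reports = reports,
       context = context, tree = tree, combinations = combinations,
       manifest = manifest)
}

report_to_list <- function(report) {
  list(
    n_evaluated = report$n_evaluated,
    n_excluded = report$n_excluded,
    mode = report$filter$mode,
    records = report$records,
    histograms = lapply(report$histograms, as.list)
  )
}

write_pipeline_outputs <- function(config, m0, cohort, screening, quant,
                                   condensed, reports, context, tree,
                                   combinations) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$out_dir, ...)

  write_matrix(m0, p("matrix_original.csv"), "wide")
  write_cohort(cohort, p("records.csv"))
  if (!is.null(screening)) {
    utils::write.csv(screening$excluded, p("excluded.csv"), row.names = FALSE)
  }
  vals <- data.frame(record_id = rownames(quant$values), quant$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(vals, p("values.csv"), row.names = FALSE)
  for (r in names(condensed)) {
    write_matrix(condensed[[r]], p(sprintf("matrix_%s.csv", tolower(r))), "wide")
  }
  jsonlite::write_json(lapply(reports, report_to_list), p("report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_context(context, p("context.csv"), "cross")
  writeLines(export_diagram(tree, "json"), p("tree.json"))
  writeLines(export_diagram(tree, "dot"), p("tree.dot"))
  utils::write.csv(combinations, p("combinations.csv"), row.names = FALSE)

  files <- c("matrix_original.csv", "records.csv",
             if (!is.null(screening)) "excluded.csv",
             "values.csv",
             sprintf("matrix_%s.csv", tolower(names(condensed))),
             "report.json", "context.csv", "tree.json", "tree.dot",
             "combinations.csv")
  manifest <- list(
    parameters = list(
      rules = config$rules, mode = config$mode,
      severe_levels = config$severe_levels,
      min_inquiry_seconds = config$min_inquiry_seconds,
      aposd_depth = config$aposd_depth,
      aposd_min_support = config$aposd_min_support,
      seed = config$seed
    ),
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(p(f))))
    })
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest
}
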