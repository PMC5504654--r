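# Shared fixture builders. All fixtures are generated in code; no files.

# Empty 47-column weight matrix with question ids 1..n.
empty_weights <- function(n_questions) {
  matrix(0, n_questions, 47,
         dimnames = list(as.character(seq_len(n_questions)), paste0("e", 1:47)))
}

# A tiny hand-set original matrix: 4 questions touching a few elements in
# each group.
tiny_matrix <- function() {
  w <- empty_weights(4)
  w["1", "e28"] <- 40  # dampness, disease cause
  w["1", "e1"]  <- 20  # yang deficiency, eight principle
  w["2", "e9"]  <- 60  # qi deficiency, qi-blood
  w["2", "e36"] <- 35  # spleen, visceral
  w["3", "e28"] <- 10
  w["3", "e14"] <- 25  # blood deficiency
  w["4", "e32"] <- 55  # liver
  mapping_matrix(w, "original")
}

# Cohort data.frame from a list of named answer vectors (names q<id>).
make_cohort <- function(answers_list, sex = "male", inquiry_seconds = 600) {
  qcols <- names(answers_list[[1]])
  rows <- lapply(seq_along(answers_list), function(i) {
    a <- answers_list[[i]]
    stopifnot(identical(names(a), qcols))
    c(record_id = sprintf("r%03d", i), sex = sex,
      inquiry_seconds = as.character(inquiry_seconds), a)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  df$inquiry_seconds <- as.numeric(df$inquiry_seconds)
  df
}

# Independent brute-force oracle for quantification: explicit double loop
# over (question, element) pairs with the answer-weight table inlined.
oracle_element_values <- function(answers, weights, mode = "all_symptoms",
                                  severe_levels = "A") {
  tab <- c(A = 1, B = 0.618, C = 0.382, D = 0)
  v <- stats::setNames(numeric(ncol(weights)), colnames(weights))
  for (q in names(answers)) {
    lab <- answers[[q]]
    if (is.na(lab)) next
    w <- tab[[lab]]
    if (mode == "severe_only" && !(lab %in% severe_levels)) w <- 0
    for (e in colnames(weights)) {
      v[e] <- v[e] + w * weights[q, e]
    }
  }
  v
}

# Random small formal context (logical incidence, no empty object intents).
random_context <- function(n_obj, n_att, p = 0.35) {
  inc <- matrix(stats::runif(n_obj * n_att) < p, n_obj, n_att,
                dimnames = list(sprintf("o%d", seq_len(n_obj)),
                                sprintf("a%d", seq_len(n_att))))
  empty <- rowSums(inc) == 0
  for (i in which(empty)) inc[i, sample(n_att, 1)] <- TRUE
  bare <- colSums(inc) == 0
  for (j in which(bare)) inc[sample(n_obj, 1), j] <- TRUE
  formal_context(inc)
}

# Independent realization of the greedy layered partition, written as an
# iterative worklist over explicit object-id sets (structure deliberately
# different from the package's recursive builder). Returns a flat table of
# nodes: path (collapsed), support, layer, and terminating objects.
oracle_partition <- function(context) {
  inc <- context$incidence
  atts <- colnames(inc)
  out <- list()
  work <- list(list(objs = rownames(inc), path = character(0)))
  while (length(work)) {
    item <- work[[1]]; work <- work[-1]
    active <- item$objs
    while (length(active)) {
      remaining <- setdiff(atts, item$path)
      counts <- vapply(remaining, function(a) sum(inc[active, a]), numeric(1))
      if (max(counts) == 0) break
      best <- remaining[counts == max(counts)][1]  # first in column order
      covered <- active[inc[active, best]]
      newpath <- c(item$path, best)
      intents <- lapply(covered, function(o) atts[inc[o, ]])
      done <- vapply(intents, function(s) all(s %in% newpath), logical(1))
      out[[length(out) + 1L]] <- list(
        path = paste(newpath, collapse = "-"),
        support = length(covered), layer = length(newpath),
        terminal = sort(covered[done])
      )
      if (any(!done)) {
        work[[length(work) + 1L]] <- list(objs = covered[!done], path = newpath)
      }
      active <- setdiff(active, covered)
    }
  }
  out
}

# Flatten a package aposd tree into the same node-table shape.
flatten_aposd <- function(tree) {
  out <- list()
  recurse <- function(node, path) {
    path <- c(path, node$attribute)
    out[[length(out) + 1L]] <<- list(
      path = paste(path, collapse = "-"),
      support = node$support, layer = node$layer,
      terminal = sort(node$objects)
    )
    for (ch in node$children) recurse(ch, path)
  }
  for (ch in tree$children) recurse(ch, character(0))
  out
}

# Canonical ordering of a flat node table for comparison.
sort_nodes <- function(nodes) {
  key <- vapply(nodes, `[[`, character(1), "path")
  nodes[order(key)]
}
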