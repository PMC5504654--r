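#' Formal contexts
#'
#' A formal context K = (U, M, I) has a set of objects U, a set of
#' attributes M, and a binary incidence relation I between them. It is the
#' input of attribute partial-ordered structure diagram (APOSD) generation.
#'
#' @param incidence Logical (or 0/1) matrix, objects x attributes, with
#'   dimnames (object ids, attribute ids).
#' @return An object of class `formal_context`: a list with `objects`,
#'   `attributes` and the logical `incidence` matrix.
#' @export
formal_context <- function(incidence) {
  if (!is.matrix(incidence)) stop("`incidence` must be a matrix", call. = FALSE)
  mode(incidence) <- "logical"
  if (anyNA(incidence)) stop("incidence has NA cells", call. = FALSE)
  if (is.null(rownames(incidence))) {
    rownames(incidence) <- paste0("o", seq_len(nrow(incidence)))
  }
  if (is.null(colnames(incidence))) {
    colnames(incidence) <- paste0("a", seq_len(ncol(incidence)))
  }
  if (anyDuplicated(rownames(incidence))) stop("duplicate object ids", call. = FALSE)
  if (anyDuplicated(colnames(incidence))) stop("duplicate attribute ids", call. = FALSE)
  structure(
    list(objects = rownames(incidence), attributes = colnames(incidence),
         incidence = incidence),
    class = "formal_context"
  )
}

#' @export
print.formal_context <- function(x, ...) {
  cat(sprintf("<formal_context> %d objects x %d attributes, %d incidences\n",
              length(x$objects), length(x$attributes), sum(x$incidence)))
  invisible(x)
}

#' Build a formal context from cohort value orders
#'
#' Knowledge-discovery step 1: for each record, the syndrome elements whose
#' value order is at the record's highest attained level become the record's
#' attributes (all ties included). Records are objects; element labels are
#' attributes. Records whose orders are all zero carry no attribute and are
#' excluded with a warning.
#'
#' @param cohort_orders Named list of value-order data.frames (one per
#'   record, from [assign_value_orders()]); names are record ids. A numeric
#'   matrix of orders (records x elements, dimnames set) is also accepted.
#' @return A [formal_context()] whose attributes are the element labels that
#'   occur at top level in at least one record, ordered by element index.
#' @export
build_context <- function(cohort_orders) {
  if (is.matrix(cohort_orders)) {
    om <- cohort_orders
  } else {
    if (length(cohort_orders) == 0L) stop("empty cohort", call. = FALSE)
    labs <- cohort_orders[[1]]$label
    om <- t(vapply(cohort_orders, function(vo) {
      stats::setNames(vo$order, vo$label)[labs]
    }, numeric(length(labs))))
    colnames(om) <- labs
    rownames(om) <- names(cohort_orders)
  }
  if (nrow(om) == 0L) stop("empty cohort", call. = FALSE)
  top <- apply(om, 1, max)
  dead <- top == 0
  if (any(dead)) {
    warning(sum(dead), " record(s) with all-zero orders excluded from context",
            call. = FALSE)
    om <- om[!dead, , drop = FALSE]
    top <- top[!dead]
    if (nrow(om) == 0L) stop("no record attains a positive order", call. = FALSE)
  }
  inc <- om == top  # row-wise: element attains the record's max order
  used <- colSums(inc) > 0
  inc <- inc[, used, drop = FALSE]
  # deterministic attribute order: ascending element index where labels are
  # e<index>, otherwise the incoming column order
  idx <- suppressWarnings(as.integer(sub("^e", "", colnames(inc))))
  if (!anyNA(idx)) inc <- inc[, order(idx), drop = FALSE]
  formal_context(inc)
}

#' Generate an attribute partial-ordered structure diagram
#'
#' Recursive greedy partition of a formal context into a layered tree: at
#' each node, among the objects reaching it, the attribute (not yet on the
#' path) covering the most of them is selected; objects possessing it
#' descend under a child labelled with it, and the remaining objects are
#' re-partitioned as sibling branches. An object stops when its attributes
#' are exhausted. Attributes nearer the root therefore cover more objects
#' ("innermost layer" in the annular rendering). Ties in coverage are broken
#' by `tie_break` order (default: the context's attribute order, i.e.
#' ascending element index for contexts from [build_context()]).
#'
#' @param context A [formal_context()].
#' @param tie_break Character vector giving the attribute priority order used
#'   to break coverage ties; defaults to `context$attributes`.
#' @return An object of class `aposd`: a list with `children` (list of root
#'   branches; each node is a list with `attribute`, `support`, `layer`,
#'   `objects` — the ids terminating at that node — and `children`) and
#'   `n_objects`.
#' @export
generate_aposd <- function(context, tie_break = context$attributes) {
  if (!inherits(context, "formal_context")) {
    stop("`context` must be a formal_context", call. = FALSE)
  }
  inc <- context$incidence
  if (nrow(inc) == 0L) stop("context has no objects", call. = FALSE)
  prio <- match(colnames(inc), tie_break)
  if (anyNA(prio)) stop("tie_break must cover every attribute", call. = FALSE)

  partition <- function(objs, path, layer) {
    # objs: character ids reaching this point; path: attributes already used
    branches <- list()
    active <- objs
    repeat {
      if (!length(active)) break
      remaining <- setdiff(colnames(inc), path)
      sub <- inc[active, remaining, drop = FALSE]
      cover <- colSums(sub)
      if (all(cover == 0)) break  # all active objects exhausted (shouldn't occur)
      best <- remaining[order(-cover, prio[match(remaining, colnames(inc))])][1]
      covered <- active[inc[active, best]]
      child_path <- c(path, best)
      # objects whose whole intent lies on the path terminate here
      extent <- inc[covered, , drop = FALSE]
      done <- rowSums(extent[, setdiff(colnames(inc), child_path), drop = FALSE]) == 0
      node <- list(
        attribute = best,
        support = length(covered),
        layer = layer,
        objects = covered[done],
        children = partition(covered[!done], child_path, layer + 1L)
      )
      branches[[length(branches) + 1L]] <- node
      active <- setdiff(active, covered)
    }
    branches
  }

  structure(
    list(children = partition(context$objects, character(0), 1L),
         n_objects = nrow(inc)),
    class = "aposd"
  )
}

aposd_walk <- function(tree, fn) {
  recurse <- function(node, path) {
    fn(node, path)
    for (ch in node$children) recurse(ch, c(path, node$attribute))
  }
  for (ch in tree$children) recurse(ch, character(0))
  invisible(NULL)
}

#' @export
print.aposd <- function(x, ...) {
  n_nodes <- 0L; max_layer <- 0L
  aposd_walk(x, function(node, path) {
    n_nodes <<- n_nodes + 1L
    max_layer <<- max(max_layer, node$layer)
  })
  cat(sprintf("<aposd> %d objects, %d nodes, %d layers\n",
              x$n_objects, n_nodes, max_layer))
  invisible(x)
}

#' Extract frequent syndrome-element combinations from an APOSD
#'
#' Walks the tree and reports every root-to-node chain of exactly `depth`
#' layers on which every node's support is at least `min_support`, labelled
#' `a1-a2-...-ak` with the terminal node's support.
#'
#' @param tree An `aposd` from [generate_aposd()].
#' @param depth Chain length (number of layers), >= 1.
#' @param min_support Minimum object support required of every node on the
#'   chain.
#' @return A data.frame with columns `combination` and `support`, ordered by
#'   decreasing support then label.
#' @export
extract_combinations <- function(tree, depth, min_support = 1L) {
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  out_comb <- character(0)
  out_sup <- integer(0)
  recurse <- function(node, path) {
    if (node$support < min_support) return(invisible(NULL))
    path <- c(path, node$attribute)
    if (length(path) == depth) {
      out_comb <<- c(out_comb, paste(path, collapse = "-"))
      out_sup <<- c(out_sup, node$support)
      return(invisible(NULL))
    }
    for (ch in node$children) recurse(ch, path)
  }
  for (ch in tree$children) recurse(ch, character(0))
  ord <- order(-out_sup, out_comb)
  data.frame(combination = out_comb[ord], support = out_sup[ord],
             stringsAsFactors = FALSE)
}

#' Export an APOSD as DOT or JSON
#'
#' Serialises the tree with deterministic node ordering (pre-order). The
#' JSON form round-trips losslessly through [aposd_from_json()].
#'
#' @param tree An `aposd`.
#' @param format `"dot"` or `"json"`.
#' @return A single character string (DOT source or JSON text).
#' @export
export_diagram <- function(tree, format = c("dot", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    strip <- function(node) {
      list(attribute = node$attribute,
           support = node$support,
           layer = node$layer,
           objects = as.list(node$objects),
           children = lapply(node$children, strip))
    }
    body <- list(n_objects = tree$n_objects,
                 children = lapply(tree$children, strip))
    return(as.character(jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA)))
  }
  lines <- c("digraph aposd {", "  node [shape=box];")
  counter <- 0L
  emit <- function(node, parent_id) {
    counter <<- counter + 1L
    id <- sprintf("n%d", counter)
    lines <<- c(lines, sprintf(
      '  %s [label="%s\\nsupport=%d", rank=%d];',
      id, node$attribute, node$support, node$layer
    ))
    if (!is.null(parent_id)) {
      lines <<- c(lines, sprintf("  %s -> %s;", parent_id, id))
    }
    for (ch in node$children) emit(ch, id)
  }
  for (ch in tree$children) emit(ch, NULL)
  paste(c(lines, "}"), collapse = "\n")
}

#' @rdname export_diagram
#' @param json JSON text produced by `export_diagram(tree, "json")`.
#' @export
aposd_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  rebuild <- function(node) {
    list(attribute = node$attribute,
         support = as.integer(node$support),
         layer = as.integer(node$layer),
         objects = as.character(unlist(node$objects)),
         children = lapply(node$children, rebuild))
  }
  structure(
    list(children = lapply(x$children, rebuild),
         n_objects = as.integer(x$n_objects)),
    class = "aposd"
  )
}

#' Read / write a formal context as cross-table CSV
#'
#' The cross-table layout mirrors the conventional formal-context grid: the
#' first column holds object ids, the header row attribute ids, and cells
#' are 1 (incidence) or blank/0. A long form with columns
#' `object`, `attribute` (one row per incidence) is also supported.
#'
#' @param path CSV path.
#' @param dialect `"cross"` or `"long"`.
#' @return `read_context`: a [formal_context()].
#' @export
read_context <- function(path, dialect = c("cross", "long")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "cross") {
    obj <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    m[is.na(m)] <- 0
    mode(m) <- "numeric"
    if (!all(m %in% c(0, 1))) {
      stop("cross-table cells must be 1 or blank/0: ", path, call. = FALSE)
    }
    rownames(m) <- obj
    formal_context(m == 1)
  } else {
    if (!all(c("object", "attribute") %in% names(df))) {
      stop("long context CSV needs columns object and attribute", call. = FALSE)
    }
    obj <- unique(as.character(df$object))
    att <- unique(as.character(df$attribute))
    m <- matrix(FALSE, length(obj), length(att), dimnames = list(obj, att))
    m[cbind(as.character(df$object), as.character(df$attribute))] <- TRUE
    formal_context(m)
  }
}

#' @rdname read_context
#' @param context A [formal_context()].
#' @export
write_context <- function(context, path, dialect = c("cross", "long")) {
  dialect <- match.arg(dialect)
  if (dialect == "cross") {
    m <- ifelse(context$incidence, "1", "")
    df <- data.frame(object = context$objects, m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    idx <- which(context$incidence, arr.ind = TRUE)
    df <- data.frame(object = context$objects[idx[, 1]],
                     attribute = context$attributes[idx[, 2]],
                     stringsAsFactors = FALSE)
    df <- df[order(df$object, df$attribute), ]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
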