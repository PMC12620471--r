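#' Indiscernibility partition
#'
#' Partitions the object set \eqn{U} into the equivalence classes of the
#' indiscernibility relation \eqn{IND(B)}: two objects fall in the same block
#' iff they agree on every attribute in `attrs`. The empty attribute set
#' discerns nothing and yields the single block \eqn{U}.
#'
#' @param table A [decision_table()].
#' @param attrs Character vector of attribute names (conditions and/or the
#'   decision attribute). May be empty.
#' @return An object of class `rs_partition`: a list of integer vectors (row
#'   indices into `table`), blocks ordered by first occurrence, members
#'   ascending; attribute `generated_by` records `attrs`.
#' @export
indiscernibility <- function(table, attrs = conditions_of(table)) {
  stopifnot(inherits(table, "decision_table"))
  check_attrs(table, attrs, allow_decision = TRUE)
  n <- nrow(table)
  if (length(attrs) == 0L) {
    blocks <- list(seq_len(n))
  } else {
    key <- do.call(paste, c(unname(as.data.frame(table)[attrs]), sep = "\r"))
    blocks <- split(seq_len(n), factor(key, levels = unique(key)))
    names(blocks) <- NULL
  }
  structure(blocks, generated_by = attrs, n_objects = n,
            class = "rs_partition")
}

#' @export
print.rs_partition <- function(x, ...) {
  cat(sprintf("Indiscernibility partition on {%s}: %d blocks over %d objects\n",
              paste(attr(x, "generated_by"), collapse = ", "),
              length(x), attr(x, "n_objects")))
  invisible(x)
}

check_attrs <- function(table, attrs, allow_decision = FALSE) {
  ok <- conditions_of(table)
  if (allow_decision) ok <- c(ok, decision_of(table))
  bad <- setdiff(attrs, ok)
  if (length(bad)) {
    stop("unknown attribute(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Lower and upper approximation of a target set
#'
#' For a target \eqn{X \subseteq U}, the lower approximation is the union of
#' indiscernibility blocks fully contained in \eqn{X} (objects certainly in
#' the concept), the upper approximation the union of blocks intersecting
#' \eqn{X} (objects possibly in the concept). Accuracy is
#' \eqn{|\underline{B}X| / |\overline{B}X|}; the empty target is vacuously
#' exact (accuracy 1).
#'
#' @inheritParams indiscernibility
#' @param target Integer vector of object (row) indices.
#' @return A list of class `rs_approximation` with components `target`,
#'   `lower`, `upper`, `boundary` (all ascending integer vectors) and
#'   `accuracy`.
#' @export
approximate <- function(table, attrs, target) {
  stopifnot(inherits(table, "decision_table"))
  n <- nrow(table)
  target <- as.integer(target)
  if (length(target) && (anyNA(target) || any(target < 1L | target > n))) {
    stop("target contains unknown objects", call. = FALSE)
  }
  target <- sort(unique(target))
  part <- indiscernibility(table, attrs)
  in_target <- logical(n)
  in_target[target] <- TRUE
  lower <- integer(0)
  upper <- integer(0)
  for (blk in part) {
    hits <- sum(in_target[blk])
    if (hits == length(blk)) lower <- c(lower, blk)
    if (hits > 0L) upper <- c(upper, blk)
  }
  lower <- sort(lower)
  upper <- sort(upper)
  acc <- if (length(upper) == 0L) 1 else length(lower) / length(upper)
  structure(list(target = target, lower = lower, upper = upper,
                 boundary = setdiff(upper, lower), accuracy = acc),
            class = "rs_approximation")
}

#' @export
print.rs_approximation <- function(x, ...) {
  cat(sprintf(
    "Rough approximation: |target|=%d |lower|=%d |upper|=%d accuracy=%.4f\n",
    length(x$target), length(x$lower), length(x$upper), x$accuracy))
  invisible(x)
}

#' Dependency degree of the decision on a condition subset
#'
#' \eqn{\gamma_B(D) = \sum_k |\underline{B} D_k| / |U|}: the fraction of
#' objects that some decision class's lower approximation (under `attrs`)
#' accounts for, i.e. the fraction classifiable without ambiguity. 1 means the
#' table is consistent under `attrs` (quality of classification 1); 0 means no
#' object can be certainly classified.
#'
#' @inheritParams indiscernibility
#' @param attrs Character vector of condition attribute names (may be empty).
#' @return A list of class `rs_dependency`: `attrs`, `gamma`,
#'   `per_class_lower_sizes` (named integer vector, one entry per decision
#'   class in order of first appearance).
#' @export
dependency_degree <- function(table, attrs = conditions_of(table)) {
  stopifnot(inherits(table, "decision_table"))
  check_attrs(table, attrs, allow_decision = FALSE)
  dvals <- table[[decision_of(table)]]
  classes <- unique(dvals)
  part <- indiscernibility(table, attrs)
  lower_sizes <- stats::setNames(integer(length(classes)), as.character(classes))
  for (blk in part) {
    dv <- unique(dvals[blk])
    if (length(dv) == 1L) {
      k <- as.character(dv)
      lower_sizes[k] <- lower_sizes[k] + length(blk)
    }
  }
  structure(list(attrs = attrs, gamma = sum(lower_sizes) / nrow(table),
                 per_class_lower_sizes = lower_sizes),
            class = "rs_dependency")
}

#' @export
print.rs_dependency <- function(x, ...) {
  cat(sprintf("gamma_{%s}(D) = %.4f\n",
              paste(x$attrs, collapse = ","), x$gamma))
  invisible(x)
}

#' All reducts and the core of a decision table
#'
#' A reduct is a minimal condition subset \eqn{R} preserving the full
#' dependency degree, \eqn{\gamma_R(D) = \gamma_C(D)}; the core is the
#' intersection of all reducts (the indispensable attributes; possibly
#' empty). The search enumerates the subset lattice by increasing size,
#' pruning supersets of found reducts, which is exact but exponential: it is
#' refused above `max_exhaustive` condition attributes unless
#' `heuristic = TRUE`, in which case a greedy backward elimination returns a
#' single (not necessarily minimum, clearly labelled non-exhaustive) reduct.
#'
#' @inheritParams indiscernibility
#' @param max_exhaustive Largest |C| for which exhaustive search is attempted
#'   (default 20).
#' @param heuristic If `TRUE`, use greedy backward elimination regardless of
#'   size; the result then holds a single reduct and `exhaustive = FALSE`.
#' @return A list of class `rs_reducts`: `reducts` (list of character
#'   vectors, attribute order preserved), `core` (character vector),
#'   `gamma` (the full-table dependency), `exhaustive` (logical).
#' @export
find_reducts <- function(table, max_exhaustive = 20L, heuristic = FALSE) {
  stopifnot(inherits(table, "decision_table"))
  conds <- conditions_of(table)
  gamma_full <- dependency_degree(table, conds)$gamma
  if (!heuristic && length(conds) > max_exhaustive) {
    stop(sprintf(
      "find_reducts: %d condition attributes exceed the exhaustive bound (%d); rerun with heuristic = TRUE for a greedy (non-exhaustive) reduct",
      length(conds), max_exhaustive), call. = FALSE)
  }
  if (heuristic) {
    red <- conds
    for (a in rev(conds)) {   # try dropping later attributes first
      cand <- setdiff(red, a)
      if (length(cand) &&
          dependency_degree(table, cand)$gamma == gamma_full) {
        red <- cand
      }
    }
    out <- list(reducts = list(red), core = red, gamma = gamma_full,
                exhaustive = FALSE)
    class(out) <- "rs_reducts"
    return(out)
  }
  reducts <- list()
  for (k in seq_along(conds)) {
    for (idx in utils::combn(length(conds), k, simplify = FALSE)) {
      sub <- conds[idx]
      if (any(vapply(reducts, function(r) all(r %in% sub), TRUE))) next
      if (dependency_degree(table, sub)$gamma == gamma_full) {
        reducts[[length(reducts) + 1L]] <- sub
      }
    }
  }
  core <- if (length(reducts)) Reduce(intersect, reducts) else character(0)
  structure(list(reducts = reducts, core = core, gamma = gamma_full,
                 exhaustive = TRUE),
            class = "rs_reducts")
}

#' @export
print.rs_reducts <- function(x, ...) {
  cat(sprintf("%s reduct search: gamma_C(D) = %.4f\n",
              if (x$exhaustive) "Exhaustive" else "Greedy (non-exhaustive)",
              x$gamma))
  for (r in x$reducts) cat("  reduct: {", paste(r, collapse = ", "), "}\n")
  cat("  core:   {", paste(x$core, collapse = ", "), "}\n")
  invisible(x)
}

#' Per-class approximation quality report
#'
#' The classification-quality summary for a decision table: one row per
#' decision class with object count, lower/upper approximation sizes and
#' accuracy under the full condition set, plus the overall quality of
#' classification \eqn{\gamma_C(D)}.
#'
#' @inheritParams indiscernibility
#' @return A list of class `rs_quality`: `per_class` data frame (`class`,
#'   `n_objects`, `lower`, `upper`, `accuracy`) and `quality` (gamma).
#' @export
classification_quality <- function(table) {
  stopifnot(inherits(table, "decision_table"))
  dvals <- table[[decision_of(table)]]
  classes <- unique(dvals)
  conds <- conditions_of(table)
  rows <- lapply(classes, function(k) {
    ap <- approximate(table, conds, which(dvals == k))
    data.frame(class = k, n_objects = length(ap$target),
               lower = length(ap$lower), upper = length(ap$upper),
               accuracy = ap$accuracy, stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(per_class = per_class,
                 quality = dependency_degree(table, conds)$gamma),
            class = "rs_quality")
}

#' @export
print.rs_quality <- function(x, ...) {
  cat(sprintf("Quality of classification: %.4f\n", x$quality))
  print.data.frame(x$per_class, row.names = FALSE)
  invisible(x)
}
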