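#' Construct a decision table
#'
#' A decision table is the information system \eqn{S = (U, A = C \cup \{D\},
#' V, f)}: a finite set of objects described by categorical condition
#' attributes \eqn{C} and one decision attribute \eqn{D}. Values are compared
#' by equality only (classical indiscernibility); ordinal Likert codes are
#' treated as categories. The description function must be total: any missing
#' cell is rejected at construction.
#'
#' @param data A data frame; every column categorical (integer codes,
#'   character or factor), no `NA`s.
#' @param decision Name of the decision column. Defaults to the last column.
#' @return An object of class `decision_table` (a data frame with attributes
#'   `conditions` and `decision`).
#' @examples
#' dt <- decision_table(data.frame(a = c(1, 1, 2, 2), b = c(1, 2, 1, 2),
#'                                 d = c(1, 1, 2, 2)))
#' @export
decision_table <- function(data, decision = NULL) {
  if (!is.data.frame(data) || nrow(data) == 0L || ncol(data) < 2L) {
    stop("decision_table: need a nonempty data frame with >= 2 columns",
         call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(decision)) decision <- names(data)[ncol(data)]
  if (!decision %in% names(data)) {
    stop(sprintf("decision attribute '%s' not found", decision), call. = FALSE)
  }
  if (anyNA(data)) {
    bad <- which(rowSums(is.na(data)) > 0)
    stop("decision_table: incomplete rows rejected (missing cells in rows ",
         paste(utils::head(bad, 20L), collapse = ", "), ")", call. = FALSE)
  }
  for (cn in names(data)) {
    if (is.factor(data[[cn]])) data[[cn]] <- as.character(data[[cn]])
    if (is.double(data[[cn]])) {
      if (any(data[[cn]] != round(data[[cn]]))) {
        stop(sprintf("decision_table: column '%s' is not categorical (non-integer values)",
                     cn), call. = FALSE)
      }
      data[[cn]] <- as.integer(data[[cn]])
    }
  }
  structure(data,
            conditions = setdiff(names(data), decision),
            decision = decision,
            class = c("decision_table", "data.frame"))
}

#' @export
print.decision_table <- function(x, ...) {
  cat(sprintf("Decision table: %d objects, %d condition attributes, decision '%s'\n",
              nrow(x), length(conditions_of(x)), decision_of(x)))
  cat(sprintf("  conditions: %s\n", paste(conditions_of(x), collapse = ", ")))
  tab <- table(x[[decision_of(x)]])
  cat(sprintf("  decision classes: %s\n",
              paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Condition / decision attribute accessors
#' @param table A `decision_table`.
#' @return Character vector of condition attribute names, or the decision
#'   attribute name.
#' @export
conditions_of <- function(table) attr(table, "conditions")

#' @rdname conditions_of
#' @export
decision_of <- function(table) attr(table, "decision")

#' Read a decision table from CSV
#'
#' Header row of attribute names; integer-coded categories; by convention the
#' last column is the decision attribute unless `decision` names another.
#'
#' @param path CSV file path.
#' @param decision Decision attribute name (default: last column).
#' @return A `decision_table`.
#' @export
read_decision_table <- function(path, decision = NULL) {
  decision_table(utils::read.csv(path, stringsAsFactors = FALSE,
                                 check.names = FALSE),
                 decision = decision)
}

#' Write a decision table to CSV
#' @param table A `decision_table`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_decision_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read / write the ISF decision-table dialect
#'
#' A minimal reader/writer for the ISF format used by classical rough-set
#' tools: an `**ATTRIBUTES` block declaring each attribute and its value
#' domain, a `**DECISION` (or trailing-position convention) marker, and an
#' `**EXAMPLES` block with one object per line. Only nominal attributes are
#' supported.
#'
#' @param path File path.
#' @return `read_isf()` returns a `decision_table`.
#' @export
read_isf <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  a_at <- grep("^\\*\\*ATTRIBUTES", lines, ignore.case = TRUE)
  e_at <- grep("^\\*\\*EXAMPLES", lines, ignore.case = TRUE)
  end_at <- grep("^\\*\\*END", lines, ignore.case = TRUE)
  if (length(a_at) != 1L || length(e_at) != 1L) {
    stop("read_isf: need exactly one **ATTRIBUTES and one **EXAMPLES block",
         call. = FALSE)
  }
  d_at <- grep("^\\*\\*DECISION", lines, ignore.case = TRUE)
  attr_lines <- lines[(a_at + 1L):(e_at - 1L)]
  attr_lines <- attr_lines[!grepl("^\\*\\*", attr_lines)]
  # each: "+ name: [v1, v2, ...]" or "+ name: (nominal)"
  names_ <- sub("^\\+?\\s*([^:]+):.*$", "\\1", attr_lines)
  names_ <- trimws(names_)
  stop_at <- if (length(end_at)) min(end_at[end_at > e_at]) else length(lines) + 1L
  ex_lines <- lines[(e_at + 1L):(stop_at - 1L)]
  rows <- lapply(ex_lines, function(l) strsplit(l, "[,[:space:]]+")[[1]])
  n_attr <- length(names_)
  if (any(vapply(rows, length, 1L) != n_attr)) {
    stop("read_isf: example row length does not match attribute count",
         call. = FALSE)
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- names_
  for (cn in names(df)) {
    v <- suppressWarnings(as.integer(df[[cn]]))
    if (!anyNA(v)) df[[cn]] <- v
  }
  decision <- names_[length(names_)]
  if (length(d_at) == 1L && d_at < e_at) {
    dec_line <- lines[d_at]
    dec_name <- trimws(sub("^\\*\\*DECISION:?", "", dec_line, ignore.case = TRUE))
    if (nzchar(dec_name)) decision <- dec_name
  }
  decision_table(df, decision = decision)
}

#' @rdname read_isf
#' @param table A `decision_table` to write.
#' @export
write_isf <- function(table, path) {
  stopifnot(inherits(table, "decision_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("**ATTRIBUTES", con)
  for (cn in names(table)) {
    dom <- sort(unique(table[[cn]]))
    writeLines(sprintf("+ %s: [%s]", cn, paste(dom, collapse = ", ")), con)
  }
  writeLines(sprintf("**DECISION: %s", decision_of(table)), con)
  writeLines("**EXAMPLES", con)
  apply(as.data.frame(table), 1L, function(r) {
    writeLines(paste(trimws(r), collapse = " "), con)
  })
  writeLines("**END", con)
  invisible(path)
}
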