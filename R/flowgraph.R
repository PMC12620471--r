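#' Decision flow graph of a rule set
#'
#' Projects a rule set onto a layered bipartite graph: one node per distinct
#' (attribute, value) literal, one node per decision class present in the
#' rules, and one edge per (rule, literal) pair linking the literal to the
#' rule's decision, annotated with the rule id, support and coverage. Two
#' rules sharing a literal share its node, so the graph exposes which
#' conditions participate in several satisfaction or dissatisfaction
#' pathways. Node order is deterministic: attribute order of the inducing
#' table, then value; decision nodes in order of first appearance in the
#' rule set.
#'
#' @param rules A nonempty `rule_set`.
#' @return A list of class `flow_graph`: `condition_nodes` (data frame
#'   `id`, `attribute`, `value`), `decision_nodes` (data frame `id`,
#'   `class`), `edges` (data frame `from`, `to`, `rule_id`, `support`,
#'   `coverage`).
#' @export
build_flow_graph <- function(rules) {
  stopifnot(inherits(rules, "rule_set"))
  if (length(rules$rules) == 0L) {
    stop("build_flow_graph: empty rule set", call. = FALSE)
  }
  lit <- do.call(rbind, lapply(seq_along(rules$rules), function(i) {
    r <- rules$rules[[i]]
    data.frame(rule_id = i,
               attribute = names(r$conditions),
               value = as.character(r$conditions),
               decision = as.character(r$decision),
               support = r$support, coverage = r$coverage,
               stringsAsFactors = FALSE)
  }))
  attr_order <- rules$table_ref$conditions
  nodes <- unique(lit[, c("attribute", "value")])
  nodes <- nodes[order(match(nodes$attribute, attr_order), nodes$value), ,
                 drop = FALSE]
  nodes$id <- sprintf("%s = %s", nodes$attribute, nodes$value)
  rownames(nodes) <- NULL
  dec <- data.frame(class = unique(lit$decision), stringsAsFactors = FALSE)
  dec$id <- sprintf("%s = %s", rules$table_ref$decision, dec$class)
  edges <- data.frame(
    from = sprintf("%s = %s", lit$attribute, lit$value),
    to = sprintf("%s = %s", rules$table_ref$decision, lit$decision),
    rule_id = lit$rule_id, support = lit$support, coverage = lit$coverage,
    stringsAsFactors = FALSE)
  structure(list(condition_nodes = nodes[, c("id", "attribute", "value")],
                 decision_nodes = dec[, c("id", "class")],
                 edges = edges),
            class = "flow_graph")
}

#' @export
print.flow_graph <- function(x, ...) {
  cat(sprintf("Decision flow graph: %d condition nodes, %d decision nodes, %d edges\n",
              nrow(x$condition_nodes), nrow(x$decision_nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a flow graph in DOT format
#'
#' Emits a layered (left-to-right) Graphviz DOT digraph: condition literals
#' as boxes in the first rank, decision classes as ellipses in the second,
#' and one labelled edge per (rule, literal) pair.
#'
#' @param graph A [build_flow_graph()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_flow_graph_dot <- function(graph, path) {
  stopifnot(inherits(graph, "flow_graph"))
  q <- function(x) sprintf("\"%s\"", gsub("\"", "\\\\\"", x))
  lines <- c(
    "digraph decision_flow {",
    "  rankdir=LR;",
    "  node [fontname=\"Helvetica\"];",
    "  { rank=same;",
    sprintf("    %s [shape=box];", q(graph$condition_nodes$id)),
    "  }",
    "  { rank=same;",
    sprintf("    %s [shape=ellipse, style=filled, fillcolor=lightgrey];",
            q(graph$decision_nodes$id)),
    "  }",
    sprintf("  %s -> %s [label=\"r%d (%.2f%%)\"];",
            q(graph$edges$from), q(graph$edges$to),
            graph$edges$rule_id, 100 * graph$edges$coverage),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}
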