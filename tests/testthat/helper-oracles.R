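# Independent brute-force oracles, deliberately naive: they re-derive every
# rough-set quantity straight from its definition so the package's optimized
# implementations can be checked against them on small random tables.

# O(n^2) pairwise indiscernibility: blocks by direct pair comparison.
oracle_partition <- function(table, attrs) {
  n <- nrow(table)
  vals <- as.data.frame(table)[, attrs, drop = FALSE]
  agree <- function(i, j) {
    all(vapply(attrs, function(a) vals[[a]][i] == vals[[a]][j], TRUE))
  }
  block_of <- rep(NA_integer_, n)
  blocks <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (b in seq_along(blocks)) {
      if (length(attrs) == 0L || agree(i, blocks[[b]][1L])) {
        blocks[[b]] <- c(blocks[[b]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) blocks[[length(blocks) + 1L]] <- i
  }
  blocks
}

oracle_lower <- function(blocks, target) {
  v <- unlist(lapply(blocks, function(b) if (all(b %in% target)) b else NULL))
  if (is.null(v)) integer(0) else as.integer(v)
}

oracle_upper <- function(blocks, target) {
  v <- unlist(lapply(blocks, function(b) if (any(b %in% target)) b else NULL))
  if (is.null(v)) integer(0) else as.integer(v)
}

oracle_gamma <- function(table, attrs) {
  blocks <- oracle_partition(table, attrs)
  dvals <- table[[decision_of(table)]]
  total <- 0L
  for (k in unique(dvals)) {
    total <- total + length(oracle_lower(blocks, which(dvals == k)))
  }
  total / nrow(table)
}

# All minimal subsets preserving gamma, by filtering the full power set.
oracle_reducts <- function(table) {
  conds <- conditions_of(table)
  g_full <- oracle_gamma(table, conds)
  subsets <- unlist(lapply(seq_along(conds), function(k) {
    utils::combn(conds, k, simplify = FALSE)
  }), recursive = FALSE)
  preserving <- Filter(function(s) oracle_gamma(table, s) == g_full, subsets)
  Filter(function(s) {
    !any(vapply(preserving, function(p) {
      length(p) < length(s) && all(p %in% s)
    }, TRUE))
  }, preserving)
}

# All condition-minimal certain conjunctions up to max_len literals, by
# exhaustive enumeration over attribute subsets and realized value tuples.
oracle_minimal_certain_rules <- function(table, max_len = 3L) {
  conds <- conditions_of(table)
  dvals <- as.character(table[[decision_of(table)]])
  df <- as.data.frame(table)
  certain <- list()
  for (L in seq_len(min(max_len, length(conds)))) {
    for (attrs in utils::combn(conds, L, simplify = FALSE)) {
      tuples <- unique(df[, attrs, drop = FALSE])
      for (ti in seq_len(nrow(tuples))) {
        m <- rep(TRUE, nrow(df))
        for (a in attrs) m <- m & (df[[a]] == tuples[ti, a])
        if (!any(m)) next
        dv <- unique(dvals[m])
        if (length(dv) == 1L) {
          certain[[length(certain) + 1L]] <- list(
            attrs = attrs,
            vals = vapply(attrs, function(a) as.character(tuples[ti, a]),
                          character(1)),
            decision = dv)
        }
      }
    }
  }
  is_sub <- function(small, big) {
    all(small$attrs %in% big$attrs) &&
      all(small$vals == big$vals[match(small$attrs, big$attrs)])
  }
  keep <- vapply(seq_along(certain), function(i) {
    !any(vapply(seq_along(certain), function(j) {
      j != i && length(certain[[j]]$attrs) < length(certain[[i]]$attrs) &&
        is_sub(certain[[j]], certain[[i]])
    }, TRUE))
  }, TRUE)
  certain[keep]
}

rule_key <- function(attrs, vals, decision) {
  o <- order(attrs)
  paste0(paste(attrs[o], vals[o], sep = "=", collapse = "|"),
         "->", decision)
}

ruleset_keys <- function(rs) {
  vapply(rs$rules, function(r) {
    rule_key(names(r$conditions), as.character(r$conditions),
             as.character(r$decision))
  }, character(1))
}

# Random small decision table (possibly inconsistent) for property tests.
random_table <- function(n_objects, n_attrs, n_values = 3L, n_classes = 2L) {
  df <- as.data.frame(lapply(seq_len(n_attrs), function(i) {
    sample.int(n_values, n_objects, replace = TRUE)
  }))
  names(df) <- paste0("a", seq_len(n_attrs))
  df$d <- sample.int(n_classes, n_objects, replace = TRUE)
  decision_table(df, decision = "d")
}

# Minimal DOT reader for round-trip checks: node and edge counts.
parse_dot_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  edge_lines <- grep("->", lines, fixed = TRUE, value = TRUE)
  node_lines <- grep("^\\s*\".+\"\\s*\\[shape", lines, value = TRUE)
  list(n_nodes = length(node_lines), n_edges = length(edge_lines))
}

table2x2 <- function() {
  decision_table(data.frame(a = c(1, 1, 2, 2), b = c(1, 2, 1, 2),
                            d = c(1, 1, 2, 2)))
}
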