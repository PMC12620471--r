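#' Induce certain decision rules (LEM2-style minimal covering)
#'
#' For each decision class, induces a minimal-covering set of certain rules
#' "if \eqn{\Phi} then \eqn{\psi}" from the class's lower approximation under
#' the full condition set. Literals are selected greedily: maximize the number
#' of still-uncovered goal objects matched, ties broken by fewer matches
#' overall (i.e. fewer matches outside the goal), then by attribute order,
#' then by value order. Each finished conjunction is pruned to be
#' condition-minimal (dropping any literal would break certainty), and
#' redundant rules whose matches are covered by the remaining rules are
#' removed. On an inconsistent table the rules cover exactly the lower
#' approximations, never boundary objects.
#'
#' @param table A [decision_table()].
#' @param classes Decision values to induce for (default: all, in order of
#'   first appearance).
#' @param method `"covering"` (default): LEM2-style minimal covering, the
#'   compact rule set used for reporting and classification. `"all"`:
#'   exhaustive enumeration of every condition-minimal certain rule up to
#'   `max_length` literals (Apriori-style over the value tuples realized in
#'   each class). The covering mode emits only enough rules to cover each
#'   lower approximation, so low-support regularities inside an
#'   already-covered class do not surface there; the exhaustive mode is the
#'   one that provably contains every certain conjunction present in the
#'   data, e.g. for parameter-recovery checks against planted rules.
#' @param max_length Maximum literals per rule for `method = "all"`
#'   (default 3).
#' @return An object of class `rule_set`: a list with `rules` (list of rules,
#'   each a list with `conditions` named vector, `decision`, `support`,
#'   `coverage`, `certainty`) and `table_ref` (dimensions + attribute names).
#' @export
induce_rules <- function(table, classes = NULL,
                         method = c("covering", "all"), max_length = 3L) {
  stopifnot(inherits(table, "decision_table"))
  method <- match.arg(method)
  conds <- conditions_of(table)
  dvals <- table[[decision_of(table)]]
  if (is.null(classes)) classes <- unique(dvals)
  if (method == "all") {
    rules <- list()
    for (k in classes) {
      rules <- c(rules, all_minimal_certain(table, k, max_length))
    }
    return(new_rule_set(rules, table))
  }
  # literal blocks: for each condition attribute, row indices per value
  literal_rows <- lapply(conds, function(a) {
    split(seq_len(nrow(table)), factor(table[[a]],
                                       levels = sort(unique(table[[a]]))))
  })
  names(literal_rows) <- conds
  rules <- list()
  for (k in classes) {
    lower <- approximate(table, conds, which(dvals == k))$lower
    rules <- c(rules, lem2_cover(table, literal_rows, lower, k))
  }
  new_rule_set(rules, table)
}

# LEM2 covering of goal set B (indices) for decision value k.
lem2_cover <- function(table, literal_rows, B, k) {
  conds <- names(literal_rows)
  n <- nrow(table)
  G <- B
  rules <- list()
  covered_by <- list()
  while (length(G) > 0L) {
    T_attrs <- character(0)
    T_vals <- list()
    T_block <- seq_len(n)
    G_local <- G
    repeat {
      if (length(T_attrs) > 0L && all(T_block %in% B)) break
      best <- NULL
      for (a in conds) {
        if (a %in% T_attrs) next
        for (v in names(literal_rows[[a]])) {
          blk <- literal_rows[[a]][[v]]
          ng <- length(intersect(blk, G_local))
          if (ng == 0L) next
          cand <- list(a = a, v = v, ng = ng, nb = length(blk))
          if (is.null(best) || ng > best$ng ||
              (ng == best$ng && cand$nb < best$nb)) {
            best <- cand
          }
        }
      }
      if (is.null(best)) {
        stop("lem2: no literal extends the current conjunction (inconsistent goal)",
             call. = FALSE)
      }
      T_attrs <- c(T_attrs, best$a)
      T_vals[[best$a]] <- best$v
      T_block <- intersect(T_block, literal_rows[[best$a]][[best$v]])
      G_local <- intersect(G_local, T_block)
    }
    # condition minimality: drop literals whose removal keeps the block certain
    for (a in T_attrs) {
      if (length(T_attrs) == 1L) break
      rest <- setdiff(T_attrs, a)
      blk <- Reduce(intersect,
                    lapply(rest, function(b) literal_rows[[b]][[T_vals[[b]]]]))
      if (all(blk %in% B)) {
        T_attrs <- rest
        T_vals[[a]] <- NULL
        T_block <- blk
      }
    }
    rules[[length(rules) + 1L]] <- list(
      conditions = vapply(T_attrs, function(a) T_vals[[a]], character(1)),
      decision = k)
    covered_by[[length(rules)]] <- T_block
    G <- setdiff(G, T_block)
  }
  # drop rules made redundant by later ones (classic final LEM2 pass)
  if (length(rules) > 1L) {
    keep <- rep(TRUE, length(rules))
    for (i in seq_along(rules)) {
      others <- unlist(covered_by[setdiff(which(keep), i)])
      if (all(covered_by[[i]] %in% others)) keep[i] <- FALSE
    }
    rules <- rules[keep]
  }
  rules
}

# Every condition-minimal certain conjunction (<= max_length literals) for
# decision value k, enumerated from the value tuples its class realizes.
all_minimal_certain <- function(table, k, max_length) {
  conds <- conditions_of(table)
  dvals <- table[[decision_of(table)]]
  in_class <- as.character(dvals) == as.character(k)
  if (!any(in_class)) return(list())
  mat <- vapply(conds, function(a) as.character(table[[a]]),
                character(nrow(table)))
  found <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  lit_key <- function(attrs, vals) {
    paste(attrs, vals, sep = "=", collapse = "|")  # attrs in canonical order
  }
  max_length <- min(max_length, length(conds))
  for (L in seq_len(max_length)) {
    for (attrs in utils::combn(conds, L, simplify = FALSE)) {
      key <- do.call(paste, c(lapply(attrs, function(a) mat[, a]),
                              sep = "\r"))
      pure <- tapply(in_class, key, all)
      present <- tapply(in_class, key, any)
      certain_keys <- names(pure)[pure & present]
      if (length(certain_keys) == 0L) next
      for (ck in certain_keys) {
        vals <- strsplit(ck, "\r", fixed = TRUE)[[1L]]
        # minimal iff no proper sub-conjunction was already certain
        minimal <- TRUE
        if (L > 1L) {
          for (drop in seq_len(L)) {
            if (!is.null(seen[[lit_key(attrs[-drop], vals[-drop])]])) {
              minimal <- FALSE
              break
            }
          }
          # subsets smaller than L-1 are covered transitively: a certain
          # sub-sub-conjunction makes some (L-1)-subset certain too
        }
        seen[[lit_key(attrs, vals)]] <- TRUE
        if (minimal) {
          found[[length(found) + 1L]] <-
            list(conditions = stats::setNames(vals, attrs), decision = k)
        }
      }
    }
  }
  found
}

new_rule_set <- function(rules, table, filter_spec = NULL) {
  rules <- lapply(rules, function(r) {
    st <- rule_stats(r, table)
    r$support <- st$support
    r$coverage <- st$coverage
    r$certainty <- st$certainty
    r
  })
  structure(list(rules = rules,
                 table_ref = list(n_objects = nrow(table),
                                  conditions = conditions_of(table),
                                  decision = decision_of(table)),
                 filter_spec = filter_spec),
            class = "rule_set")
}

#' Support, coverage and certainty of a rule
#'
#' `support` counts objects satisfying both premise \eqn{\Phi} and conclusion
#' \eqn{\psi}; `coverage` divides support by the size of the decision class
#' (how much of the class the premise explains); `certainty` divides support
#' by the number of objects matching the premise (1 for certain rules). An
#' empty premise matches every object.
#'
#' @param rule A list with `conditions` (named character/numeric vector:
#'   names are attributes, elements values) and `decision`.
#' @param table A [decision_table()].
#' @return List with `support`, `coverage`, `certainty`.
#' @export
rule_stats <- function(rule, table) {
  stopifnot(inherits(table, "decision_table"))
  conds <- conditions_of(table)
  lits <- rule$conditions
  if (length(lits)) {
    if (anyDuplicated(names(lits))) {
      stop("rule_stats: an attribute appears twice in the conditions",
           call. = FALSE)
    }
    check_attrs(table, names(lits), allow_decision = FALSE)
  }
  match_phi <- rep(TRUE, nrow(table))
  for (a in names(lits)) {
    match_phi <- match_phi & (as.character(table[[a]]) == as.character(lits[[a]]))
  }
  in_class <- as.character(table[[decision_of(table)]]) == as.character(rule$decision)
  class_n <- sum(in_class)
  if (class_n == 0L) {
    stop(sprintf("rule_stats: decision class '%s' is empty, coverage undefined",
                 rule$decision), call. = FALSE)
  }
  support <- sum(match_phi & in_class)
  n_phi <- sum(match_phi)
  list(support = support,
       coverage = support / class_n,
       certainty = if (n_phi == 0L) NA_real_ else support / n_phi)
}

#' Build a rule set from explicit conjunctions
#'
#' Wraps user-supplied (or planted) condition/decision pairs into a
#' `rule_set` with statistics computed against `table`. Useful for evaluating
#' published rule tables against a data set.
#'
#' @param rules List of lists with `conditions` (named vector) and `decision`.
#' @param table A [decision_table()].
#' @return A `rule_set`.
#' @export
rule_set_from_conditions <- function(rules, table) {
  new_rule_set(rules, table)
}

#' Filter rules by coverage and decision class
#'
#' Keeps rules with `coverage >= min_coverage` (boundary kept) whose decision
#' value lies in `keep_classes`; order is preserved. Raising `min_coverage`
#' never adds rules.
#'
#' @param rules A `rule_set`.
#' @param min_coverage Fraction in \[0, 1\].
#' @param keep_classes Decision values to keep (default: all).
#' @return A filtered `rule_set` with `filter_spec` recorded.
#' @export
filter_rules <- function(rules, min_coverage = 0.10, keep_classes = NULL) {
  stopifnot(inherits(rules, "rule_set"))
  if (!is.numeric(min_coverage) || min_coverage < 0 || min_coverage > 1) {
    stop("filter_rules: min_coverage must lie in [0, 1]", call. = FALSE)
  }
  keep <- vapply(rules$rules, function(r) {
    r$coverage >= min_coverage &&
      (is.null(keep_classes) ||
         as.character(r$decision) %in% as.character(keep_classes))
  }, TRUE)
  out <- rules
  out$rules <- rules$rules[keep]
  out$filter_spec <- list(min_coverage = min_coverage,
                          keep_classes = keep_classes)
  out
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("Rule set: %d rules (table: %d objects)\n",
              length(x$rules), x$table_ref$n_objects))
  if (!is.null(x$filter_spec)) {
    cat(sprintf("  filtered: coverage >= %.2f, classes {%s}\n",
                x$filter_spec$min_coverage,
                paste(x$filter_spec$keep_classes, collapse = ", ")))
  }
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    cat(sprintf("  %2d. (%s) => %s = %s  [support %d, coverage %.2f%%, certainty %.2f]\n",
                i,
                paste(sprintf("%s = %s", names(r$conditions), r$conditions),
                      collapse = ") and ("),
                x$table_ref$decision, r$decision,
                r$support, 100 * r$coverage, r$certainty))
  }
  invisible(x)
}

#' Rule set as a data frame
#'
#' @param x A `rule_set`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return Data frame with one row per rule: `rule_id`, `conditions` (literal
#'   conjunction as text), `decision`, `support`, `coverage`, `certainty`.
#' @export
as.data.frame.rule_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (length(x$rules) == 0L) {
    return(data.frame(rule_id = integer(), conditions = character(),
                      decision = character(), support = integer(),
                      coverage = numeric(), certainty = numeric(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    rule_id = seq_along(x$rules),
    conditions = vapply(x$rules, function(r) {
      paste(sprintf("(%s = %s)", names(r$conditions), r$conditions),
            collapse = " and ")
    }, character(1)),
    decision = vapply(x$rules, function(r) as.character(r$decision), character(1)),
    support = vapply(x$rules, function(r) as.integer(r$support), integer(1)),
    coverage = vapply(x$rules, function(r) r$coverage, numeric(1)),
    certainty = vapply(x$rules, function(r) r$certainty, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Classify condition profiles with a rule set
#'
#' Exact-matching rules vote with weight equal to their support; the class
#' with the largest summed support wins (ties by first rule in set order).
#' When no rule matches exactly, the best partially matching rule decides:
#' largest fraction of satisfied literals, ties by larger support, then by
#' rule order. Deterministic given the rule order; total (never abstains when
#' the rule set is nonempty).
#'
#' @param newdata Data frame of condition values (one row per object).
#' @param rules A nonempty `rule_set`.
#' @return Character vector of predicted decision values.
#' @export
classify_objects <- function(newdata, rules) {
  stopifnot(inherits(rules, "rule_set"))
  if (length(rules$rules) == 0L) {
    stop("classify_objects: empty rule set", call. = FALSE)
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    row <- newdata[i, , drop = FALSE]
    frac <- vapply(rules$rules, function(r) {
      hit <- vapply(names(r$conditions), function(a) {
        a %in% names(row) &&
          as.character(row[[a]]) == as.character(r$conditions[[a]])
      }, TRUE)
      if (length(hit) == 0L) 1 else mean(hit)
    }, numeric(1))
    exact <- which(frac == 1)
    if (length(exact)) {
      votes <- tapply(
        vapply(rules$rules[exact], function(r) r$support, numeric(1)),
        vapply(rules$rules[exact], function(r) as.character(r$decision),
               character(1)),
        sum)
      # ties: first class reached by rule order among the top-voted
      top <- names(votes)[votes == max(votes)]
      if (length(top) > 1L) {
        ord <- vapply(rules$rules[exact], function(r) as.character(r$decision),
                      character(1))
        top <- ord[ord %in% top][1L]
      }
      return(top[1L])
    }
    supp <- vapply(rules$rules, function(r) r$support, numeric(1))
    best <- order(-frac, -supp)[1L]
    as.character(rules$rules[[best]]$decision)
  }, character(1))
}

#' Stratified k-fold cross-validation of rule induction
#'
#' Splits objects into `n_folds` folds stratified by decision class (seeded
#' shuffle within each class, round-robin assignment), induces certain rules
#' on each training portion and classifies the held-out rows with
#' [classify_objects()]. If some fold's training portion would lose a decision
#' class entirely, that fold is merged into the next one with a warning.
#'
#' @param table A [decision_table()].
#' @param n_folds Number of folds, default 10.
#' @param seed Integer seed for the stratified shuffle.
#' @param min_coverage,keep_classes Optional filter applied to each fold's
#'   induced rules before classification (defaults: no filter, mirroring the
#'   common practice of validating the full induced set).
#' @return List of class `rs_cv`: `n_folds` (effective), `per_fold_accuracy`,
#'   `mean_accuracy`, `seed`.
#' @export
cross_validate <- function(table, n_folds = 10L, seed = 1L,
                           min_coverage = 0, keep_classes = NULL) {
  stopifnot(inherits(table, "decision_table"))
  n <- nrow(table)
  if (n_folds < 2L || n < n_folds) {
    stop("cross_validate: need n_folds >= 2 and at least n_folds objects",
         call. = FALSE)
  }
  dvals <- as.character(table[[decision_of(table)]])
  fold <- integer(n)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  for (k in unique(dvals)) {
    idx <- which(dvals == k)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  # merge folds whose training portion would miss a class
  repeat {
    bad <- NULL
    for (f in sort(unique(fold))) {
      if (!all(unique(dvals) %in% dvals[fold != f])) { bad <- f; break }
    }
    if (is.null(bad) || length(unique(fold)) <= 2L) break
    warning(sprintf("fold %d left a training class empty; merging with the next fold", bad))
    others <- sort(unique(fold))
    nxt <- others[others != bad][1L]
    fold[fold == bad] <- nxt
  }
  fold_ids <- sort(unique(fold))
  acc <- vapply(fold_ids, function(f) {
    train <- decision_table(as.data.frame(table)[fold != f, , drop = FALSE],
                            decision = decision_of(table))
    rules <- induce_rules(train)
    if (min_coverage > 0 || !is.null(keep_classes)) {
      rules <- filter_rules(rules, min_coverage, keep_classes)
    }
    test <- as.data.frame(table)[fold == f, , drop = FALSE]
    pred <- classify_objects(test[, conditions_of(table), drop = FALSE], rules)
    mean(pred == as.character(test[[decision_of(table)]]))
  }, numeric(1))
  structure(list(n_folds = length(fold_ids), per_fold_accuracy = acc,
                 mean_accuracy = mean(acc), seed = seed),
            class = "rs_cv")
}

#' @export
print.rs_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d): mean accuracy %.2f%%\n",
              x$n_folds, x$seed, 100 * x$mean_accuracy))
  cat("  per fold:", paste(sprintf("%.3f", x$per_fold_accuracy), collapse = " "),
      "\n")
  invisible(x)
}

#' Write a rule set to CSV and JSON
#'
#' @param rules A `rule_set`.
#' @param dir Output directory.
#' @param stem File-name stem (default `"rules"`).
#' @return Invisibly, the paths written.
#' @export
write_rules <- function(rules, dir, stem = "rules") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(rules)
  df$coverage <- round(df$coverage, 4)
  df$certainty <- round(df$certainty, 4)
  csv_path <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(df, csv_path, row.names = FALSE)
  json_path <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(list(
    filter_spec = rules$filter_spec,
    table_ref = rules$table_ref,
    rules = lapply(rules$rules, function(r) {
      list(conditions = as.list(r$conditions),
           decision = as.character(r$decision),
           support = r$support, coverage = round(r$coverage, 4),
           certainty = round(r$certainty, 4))
    })
  ), json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv_path, json_path))
}

# Seed hygiene: set a seed locally, restoring the caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
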