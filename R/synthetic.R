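#' Specification for a synthetic Likert survey with planted rules
#'
#' Describes a decision table to generate: object count, condition schema,
#' decision-class sizes, and a set of planted conjunction rules. A planted
#' rule demands that exactly `count` members of its decision class satisfy
#' its literal conjunction; with `exclusive = TRUE` (default) no object
#' outside that class may satisfy the full conjunction, so the planted rule
#' is certain (certainty 1) with coverage `count / class size` by
#' construction. Planted rules of the same class may share objects when their
#' literals are compatible (no attribute demanded at two different values),
#' which is how planted counts may legitimately sum beyond the class size.
#'
#' @param conditions Character vector of condition attribute names.
#' @param class_sizes Named integer vector: decision value -> class size.
#' @param planted_rules List of lists, each with `conditions` (named vector
#'   attribute -> value) and `decision` and `count`.
#' @param domain Integer vector of allowed condition values (default `1:5`).
#' @param noise Probability of re-randomizing a non-planted cell after the
#'   class-conditional draw (default 0).
#' @param class_probs Optional named list: decision value -> probability
#'   vector over `domain` for free cells. Defaults: low-skewed for the first
#'   class, mid for the second, high-skewed for the third when the domain is
#'   1..5 and there are three classes; uniform otherwise.
#' @param exclusive Enforce that no object outside a rule's class satisfies
#'   its conjunction (default `TRUE`).
#' @param blockers For each planted rule with >= 2 literals, plant one
#'   object in another class per literal that satisfies all literals but
#'   that one (default `TRUE`). This makes every proper sub-conjunction of a
#'   planted rule uncertain, so minimal-covering induction cannot shorten
#'   the planted conjunction away.
#' @return A list of class `survey_spec`.
#' @export
survey_spec <- function(conditions, class_sizes, planted_rules = list(),
                        domain = 1:5, noise = 0, class_probs = NULL,
                        exclusive = TRUE, blockers = TRUE) {
  stopifnot(is.character(conditions), length(conditions) >= 1L,
            is.numeric(class_sizes), !is.null(names(class_sizes)),
            all(class_sizes >= 1), noise >= 0, noise <= 1)
  spec <- list(conditions = conditions,
               class_sizes = stats::setNames(as.integer(class_sizes),
                                             names(class_sizes)),
               planted_rules = planted_rules,
               domain = as.integer(domain), noise = noise,
               class_probs = class_probs,
               exclusive = isTRUE(exclusive), blockers = isTRUE(blockers))
  class(spec) <- "survey_spec"
  validate_survey_spec(spec)
  spec
}

validate_survey_spec <- function(spec) {
  classes <- names(spec$class_sizes)
  pats <- character(0)
  for (i in seq_along(spec$planted_rules)) {
    r <- spec$planted_rules[[i]]
    if (is.null(r$conditions) || is.null(r$decision) || is.null(r$count)) {
      stop("survey_spec: each planted rule needs conditions, decision, count",
           call. = FALSE)
    }
    if (!as.character(r$decision) %in% classes) {
      stop(sprintf("survey_spec: rule %d decision '%s' is not a class", i,
                   r$decision), call. = FALSE)
    }
    bad <- setdiff(names(r$conditions), spec$conditions)
    if (length(bad)) {
      stop(sprintf("survey_spec: rule %d uses unknown attribute(s) %s", i,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (!all(as.integer(r$conditions) %in% spec$domain)) {
      stop(sprintf("survey_spec: rule %d uses values outside the domain", i),
           call. = FALSE)
    }
    if (r$count > spec$class_sizes[[as.character(r$decision)]]) {
      stop(sprintf("survey_spec: rule %d count %d exceeds class size %d", i,
                   r$count, spec$class_sizes[[as.character(r$decision)]]),
           call. = FALSE)
    }
    pat <- paste(sort(paste(names(r$conditions), r$conditions, sep = "=")),
                 collapse = ",")
    if (spec$exclusive && pat %in% pats) {
      stop(sprintf("survey_spec: rule %d duplicates an exclusive planted pattern (%s)",
                   i, pat), call. = FALSE)
    }
    pats <- c(pats, pat)
  }
  invisible(spec)
}

default_class_probs <- function(spec) {
  classes <- names(spec$class_sizes)
  if (!is.null(spec$class_probs)) {
    return(lapply(spec$class_probs, function(p) p / sum(p)))
  }
  m <- length(spec$domain)
  probs <- if (m == 5L && length(classes) == 3L) {
    # dissatisfied skews low, neutral centers, satisfied skews high
    list(c(0.35, 0.35, 0.15, 0.10, 0.05),
         c(0.10, 0.20, 0.40, 0.20, 0.10),
         c(0.05, 0.10, 0.15, 0.35, 0.35))
  } else {
    rep(list(rep(1 / m, m)), length(classes))
  }
  stats::setNames(probs, classes)
}

#' Generate a survey decision table with planted conjunction rules
#'
#' Deterministically (under `seed`) builds a decision table realizing a
#' [survey_spec()]: exact class sizes; for every planted rule, exactly
#' `count` members of its class satisfy the conjunction, and (when
#' `exclusive`) no outside object does. Rules are assigned to objects
#' greedily (unassigned objects first, then already-assigned objects with
#' compatible pinned values); free cells are drawn from the class-conditional
#' categorical distribution, optionally noise-perturbed, then repaired so
#' that no accidental full-pattern match or cross-class duplicate profile
#' survives.
#'
#' @param spec A [survey_spec()].
#' @param seed Integer seed.
#' @param ensure_consistent Repair duplicate condition profiles across
#'   decision classes so the table is consistent (gamma = 1); default `TRUE`.
#' @return A [decision_table()] with attribute `planted` (the spec).
#' @export
generate_survey <- function(spec, seed = 1L, ensure_consistent = TRUE) {
  stopifnot(inherits(spec, "survey_spec"))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  classes <- names(spec$class_sizes)
  n <- sum(spec$class_sizes)
  p <- length(spec$conditions)
  dvals <- rep(classes, times = spec$class_sizes)
  cells <- matrix(NA_integer_, nrow = n, ncol = p,
                  dimnames = list(NULL, spec$conditions))
  pinned <- matrix(FALSE, nrow = n, ncol = p,
                   dimnames = list(NULL, spec$conditions))
  assigned <- vector("list", n)  # per object: list of rule indices
  class_rows <- split(seq_len(n), factor(dvals, levels = classes))

  # --- plant rules: greedy fresh-first assignment within each class
  rule_order <- order(-vapply(spec$planted_rules, function(r) r$count, 1))
  for (ri in rule_order) {
    r <- spec$planted_rules[[ri]]
    rows <- class_rows[[as.character(r$decision)]]
    lits <- stats::setNames(as.integer(r$conditions), names(r$conditions))
    compatible <- function(i) {
      if (!all(is.na(cells[i, names(lits)]) | cells[i, names(lits)] == lits)) {
        return(FALSE)
      }
      # the combined pinned cells must not fully match some third pattern
      pin2 <- pinned[i, ]
      pin2[names(lits)] <- TRUE
      row2 <- cells[i, ]
      row2[names(lits)] <- lits
      !any(vapply(seq_along(spec$planted_rules), function(rj) {
        if (rj == ri || rj %in% assigned[[i]]) return(FALSE)
        l2 <- stats::setNames(as.integer(spec$planted_rules[[rj]]$conditions),
                              names(spec$planted_rules[[rj]]$conditions))
        all(pin2[names(l2)]) && all(row2[names(l2)] == l2)
      }, TRUE))
    }
    fresh <- rows[vapply(rows, function(i) length(assigned[[i]]) == 0L, TRUE)]
    used <- rows[vapply(rows, function(i) length(assigned[[i]]) > 0L, TRUE)]
    pick <- fresh[seq_len(min(r$count, length(fresh)))]
    need <- r$count - length(pick)
    if (need > 0L) {
      ok <- used[vapply(used, compatible, TRUE)]
      if (length(ok) < need) {
        stop(sprintf(
          "generate_survey: infeasible planting for rule %d (%s -> %s, count %d): only %d compatible objects available in its class",
          ri, paste(names(lits), lits, sep = "=", collapse = " & "),
          r$decision, r$count, length(pick) + length(ok)), call. = FALSE)
      }
      pick <- c(pick, ok[seq_len(need)])
    }
    for (i in pick) {
      cells[i, names(lits)] <- lits
      pinned[i, names(lits)] <- TRUE
      assigned[[i]] <- c(assigned[[i]], ri)
    }
  }

  # --- blockers: for each multi-literal rule and each literal, one object in
  # another class matching all literals but that one
  if (spec$blockers && length(spec$planted_rules)) {
    for (ri in seq_along(spec$planted_rules)) {
      r <- spec$planted_rules[[ri]]
      lits <- stats::setNames(as.integer(r$conditions), names(r$conditions))
      if (length(lits) < 2L) next
      other_rows <- setdiff(seq_len(n), class_rows[[as.character(r$decision)]])
      for (j in seq_along(lits)) {
        part <- lits[-j]
        blocked_val <- pick_other_value(spec$domain, lits[[j]])
        want <- c(part, stats::setNames(blocked_val, names(lits)[j]))
        cand <- other_rows[vapply(other_rows, function(i) {
          if (!all(is.na(cells[i, names(want)]) | cells[i, names(want)] == want)) {
            return(FALSE)
          }
          # the blocker's pinned cells must not complete any other planted
          # pattern on this object (that would be unrepairable later)
          pin2 <- pinned[i, ]
          pin2[names(want)] <- TRUE
          row2 <- cells[i, ]
          row2[names(want)] <- want
          !any(vapply(spec$planted_rules, function(r2) {
            l2 <- stats::setNames(as.integer(r2$conditions),
                                  names(r2$conditions))
            all(pin2[names(l2)]) && all(row2[names(l2)] == l2)
          }, TRUE))
        }, TRUE)]
        if (length(cand) == 0L) next  # best effort; repair keeps counts exact
        i <- cand[[1L]]
        cells[i, names(want)] <- want
        pinned[i, names(want)] <- TRUE
      }
    }
  }

  # --- fill free cells from class-conditional categorical distributions
  probs <- default_class_probs(spec)
  for (k in classes) {
    for (i in class_rows[[k]]) {
      free <- which(!pinned[i, ])
      if (length(free)) {
        cells[i, free] <- sample(spec$domain, length(free), replace = TRUE,
                                 prob = probs[[k]])
      }
    }
  }

  # --- noise: re-randomize non-planted cells uniformly
  if (spec$noise > 0) {
    for (i in seq_len(n)) {
      free <- which(!pinned[i, ])
      hit <- free[stats::runif(length(free)) < spec$noise]
      if (length(hit)) {
        cells[i, hit] <- sample(spec$domain, length(hit), replace = TRUE)
      }
    }
  }

  # --- repair accidental pattern matches and cross-class duplicates
  for (pass in seq_len(200L)) {
    changed <- FALSE
    for (ri in seq_along(spec$planted_rules)) {
      r <- spec$planted_rules[[ri]]
      lits <- stats::setNames(as.integer(r$conditions), names(r$conditions))
      match_full <- which(apply(cells[, names(lits), drop = FALSE], 1L,
                                function(x) all(x == lits)))
      intended <- which(vapply(assigned, function(a) ri %in% a, TRUE))
      stray <- setdiff(match_full, intended)
      if (spec$exclusive) {
        bad <- stray
      } else {
        bad <- intersect(stray, class_rows[[as.character(r$decision)]])
      }
      for (i in bad) {
        free <- names(lits)[!pinned[i, names(lits)]]
        if (length(free) == 0L) {
          stop(sprintf(
            "generate_survey: planted patterns conflict on object %d (rule %d fully pinned but not assigned)",
            i, ri), call. = FALSE)
        }
        cells <- repair_cell(cells, i, free, spec, assigned, dvals)
        changed <- TRUE
      }
    }
    if (ensure_consistent) {
      key <- apply(cells, 1L, paste, collapse = "\r")
      for (dup_key in unique(key[duplicated(key)])) {
        idx <- which(key == dup_key)
        if (length(unique(dvals[idx])) > 1L) {
          i <- idx[[length(idx)]]
          free <- colnames(cells)[!pinned[i, ]]
          if (length(free) == 0L) {
            stop("generate_survey: cannot repair an inconsistent fully-pinned object",
                 call. = FALSE)
          }
          cells <- repair_cell(cells, i, free, spec, assigned, dvals)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
    if (pass == 200L) {
      stop("generate_survey: repair did not converge; the spec is likely infeasible",
           call. = FALSE)
    }
  }

  df <- as.data.frame(cells)
  df$D <- if (all(!is.na(suppressWarnings(as.integer(classes))))) {
    as.integer(dvals)
  } else dvals
  tab <- decision_table(df, decision = "D")
  attr(tab, "planted") <- spec
  tab
}

pick_other_value <- function(domain, v) {
  alts <- domain[domain != v]
  alts[[1L]]
}

# Change one free cell of object i (choosing among `free` attributes) to a
# value that leaves the object matching no planted pattern it is not assigned
# to; falls back to the first alternative value if no clean choice exists.
repair_cell <- function(cells, i, free, spec, assigned, dvals) {
  strays <- function(row) {
    sum(vapply(seq_along(spec$planted_rules), function(ri) {
      if (ri %in% assigned[[i]]) return(FALSE)
      r <- spec$planted_rules[[ri]]
      if (!spec$exclusive &&
          as.character(dvals[[i]]) != as.character(r$decision)) return(FALSE)
      lits <- stats::setNames(as.integer(r$conditions), names(r$conditions))
      all(row[names(lits)] == lits)
    }, TRUE))
  }
  fallback <- NULL
  for (a in free) {
    for (v in spec$domain[spec$domain != cells[i, a]]) {
      row <- cells[i, ]
      row[[a]] <- v
      if (is.null(fallback)) fallback <- list(a = a, v = v)
      if (strays(row) == 0L) {
        cells[i, a] <- v
        return(cells)
      }
    }
  }
  cells[i, fallback$a] <- fallback$v
  cells
}

#' Planted rules of a generated table as a rule set
#'
#' Evaluates the planted conjunctions of a [generate_survey()] table against
#' the table itself, returning them (in spec order) with support, coverage
#' and certainty computed from the data.
#'
#' @param table A decision table carrying a `planted` attribute.
#' @return A `rule_set`.
#' @export
planted_rule_set <- function(table) {
  spec <- attr(table, "planted")
  if (is.null(spec)) {
    stop("planted_rule_set: table carries no planted-rule spec", call. = FALSE)
  }
  rules <- lapply(spec$planted_rules, function(r) {
    list(conditions = stats::setNames(as.character(r$conditions),
                                      names(r$conditions)),
         decision = r$decision)
  })
  rule_set_from_conditions(rules, table)
}

#' Read a survey spec from YAML
#'
#' @param path YAML file with fields `conditions`, `class_sizes`,
#'   `planted_rules` (each with `conditions`, `decision`, `count`), and
#'   optionally `domain`, `noise`, `class_probs`, `exclusive`, `blockers`.
#' @return A [survey_spec()].
#' @export
read_survey_spec <- function(path) {
  y <- yaml::read_yaml(path)
  survey_spec(
    conditions = unlist(y$conditions),
    class_sizes = stats::setNames(unlist(y$class_sizes),
                                  names(y$class_sizes)),
    planted_rules = lapply(y$planted_rules, function(r) {
      list(conditions = stats::setNames(unlist(r$conditions),
                                        names(r$conditions)),
           decision = r$decision, count = r$count)
    }),
    domain = if (is.null(y$domain)) 1:5 else unlist(y$domain),
    noise = if (is.null(y$noise)) 0 else y$noise,
    class_probs = y$class_probs,
    exclusive = if (is.null(y$exclusive)) TRUE else y$exclusive,
    blockers = if (is.null(y$blockers)) TRUE else y$blockers
  )
}

#' The bundled satisfaction-survey fixture spec
#'
#' The packaged 163-object fixture: nine Likert conditions, decision classes
#' of sizes 14 / 41 / 108, and ten exclusive planted conjunctions (five per
#' outer class) whose designed counts give coverages of 35.71/35.71/14.29/
#' 14.29/14.29 percent over the dissatisfied class and 45.37/11.11/17.59/
#' 20.37/13.89 percent over the satisfied class. The neutral class is left
#' unplanted (class-conditional noise only).
#'
#' @return A [survey_spec()].
#' @export
satisfaction_fixture_spec <- function() {
  read_survey_spec(system.file("extdata", "satisfaction_fixture.yaml",
                               package = "roughdelphi", mustWork = TRUE))
}

#' Generate a consistent survey table
#'
#' Draws condition profiles from the class-conditional distributions and then
#' sets the decision as a deterministic function of the profile (mean Likert
#' score cut at 2.6 and 3.4), so the table is consistent by construction:
#' quality of classification 1 and per-class approximation accuracy 1.
#'
#' @param n_objects Number of rows (default 163).
#' @param conditions Condition attribute names (default: the nine names of
#'   [satisfaction_fixture_spec()]).
#' @param seed Integer seed.
#' @return A [decision_table()].
#' @export
generate_consistent_survey <- function(n_objects = 163L,
                                       conditions = satisfaction_fixture_spec()$conditions,
                                       seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  probs <- list(c(0.35, 0.35, 0.15, 0.10, 0.05),
                c(0.10, 0.20, 0.40, 0.20, 0.10),
                c(0.05, 0.10, 0.15, 0.35, 0.35))
  mix <- sample(1:3, n_objects, replace = TRUE,
                prob = c(14, 41, 108) / 163)
  cells <- t(vapply(mix, function(k) {
    sample(1:5, length(conditions), replace = TRUE, prob = probs[[k]])
  }, integer(length(conditions))))
  colnames(cells) <- conditions
  m <- rowMeans(cells)
  d <- ifelse(m <= 2.6, 1L, ifelse(m >= 3.4, 3L, 2L))
  df <- as.data.frame(cells)
  df$D <- d
  decision_table(df, decision = "D")
}

#' Specification for a synthetic expert panel
#'
#' @param n_experts Number of experts (default 18, a typical validated panel
#'   size for Delphi studies).
#' @param criteria Data frame with columns `criterion_id` and `importance`
#'   (true central tendency on the 1--10 scale).
#' @param interval_width Mean optimistic-minus-conservative gap (default 2).
#' @param score_sd Standard deviation of individual expert scores around
#'   their center (default 1).
#' @param outlier_rate Probability that an expert x criterion response is
#'   aberrant (both scores near the opposite end of the scale), exercising
#'   the two-standard-deviation trim (default 0).
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_experts = 18L, criteria,
                       interval_width = 2, score_sd = 1,
                       outlier_rate = 0) {
  stopifnot(n_experts >= 2L, is.data.frame(criteria),
            all(c("criterion_id", "importance") %in% names(criteria)),
            outlier_rate >= 0, outlier_rate <= 1)
  structure(list(n_experts = as.integer(n_experts), criteria = criteria,
                 interval_width = interval_width, score_sd = score_sd,
                 outlier_rate = outlier_rate),
            class = "panel_spec")
}

#' Generate an expert panel
#'
#' Per expert and criterion, a conservative and an optimistic score are drawn
#' around `importance -/+ interval_width/2` (normal, `score_sd`), rounded to
#' the 1--10 integer scale, clamped, and ordered (conservative <=
#' optimistic). With probability `outlier_rate` the response is aberrant:
#' both scores land near the end of the scale opposite the criterion's
#' importance, which places them beyond two standard deviations of the
#' panel's series and exercises [trim_outliers()].
#'
#' @param spec A [panel_spec()].
#' @param seed Integer seed.
#' @return A panel data frame (`expert_id`, `criterion_id`, `conservative`,
#'   `optimistic`) suitable for [screen_criteria()].
#' @export
generate_panel <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "panel_spec"))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  clamp <- function(x) pmin(10L, pmax(1L, as.integer(round(x))))
  rows <- list()
  for (ci in seq_len(nrow(spec$criteria))) {
    cr <- spec$criteria$criterion_id[[ci]]
    imp <- spec$criteria$importance[[ci]]
    cons <- clamp(stats::rnorm(spec$n_experts, imp - spec$interval_width / 2,
                               spec$score_sd))
    opti <- clamp(stats::rnorm(spec$n_experts, imp + spec$interval_width / 2,
                               spec$score_sd))
    swap <- cons > opti
    tmp <- cons[swap]; cons[swap] <- opti[swap]; opti[swap] <- tmp
    aberr <- stats::runif(spec$n_experts) < spec$outlier_rate
    if (any(aberr)) {
      if (imp >= 5.5) {
        cons[aberr] <- 1L
        opti[aberr] <- 2L
      } else {
        cons[aberr] <- 9L
        opti[aberr] <- 10L
      }
    }
    rows[[ci]] <- data.frame(
      expert_id = sprintf("E%02d", seq_len(spec$n_experts)),
      criterion_id = cr, conservative = cons, optimistic = opti,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "spec") <- spec
  out
}

#' Read a panel spec from YAML
#'
#' @param path YAML file with `n_experts`, `criteria` (list of
#'   `criterion_id`/`importance` pairs), `interval_width`, `score_sd`,
#'   `outlier_rate`.
#' @return A [panel_spec()].
#' @export
read_panel_spec <- function(path) {
  y <- yaml::read_yaml(path)
  crit <- do.call(rbind, lapply(y$criteria, function(cr) {
    data.frame(criterion_id = cr$criterion_id, importance = cr$importance,
               stringsAsFactors = FALSE)
  }))
  panel_spec(
    n_experts = if (is.null(y$n_experts)) 18L else y$n_experts,
    criteria = crit,
    interval_width = if (is.null(y$interval_width)) 2 else y$interval_width,
    score_sd = if (is.null(y$score_sd)) 1 else y$score_sd,
    outlier_rate = if (is.null(y$outlier_rate)) 0 else y$outlier_rate
  )
}

#' The bundled default expert-panel spec
#'
#' Twelve candidate criteria (the four-dimension evaluation framework:
#' device features, user needs, environment, policy) scored by 18 experts;
#' nine criteria carry high true importance and three moderate, so that a
#' threshold-7 screen typically retains nine conditions.
#'
#' @return A [panel_spec()].
#' @export
default_panel_spec <- function() {
  read_panel_spec(system.file("extdata", "panel_default.yaml",
                              package = "roughdelphi", mustWork = TRUE))
}
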