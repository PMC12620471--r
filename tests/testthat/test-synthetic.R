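# Synthetic-data generator: determinism, exact planted structure,
# feasibility checking, and panel generation.

test_that("survey generation is deterministic under seed and varies across seeds", {
  spec <- satisfaction_fixture_spec()
  t1 <- generate_survey(spec, seed = 13)
  t2 <- generate_survey(spec, seed = 13)
  t3 <- generate_survey(spec, seed = 14)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
  # byte-identical files under the same seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_decision_table(t1, p1)
  write_decision_table(t2, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("class sizes are exact and survive noise", {
  spec <- satisfaction_fixture_spec()
  noisy <- survey_spec(spec$conditions, spec$class_sizes, spec$planted_rules,
                       noise = 0.3)
  for (s in c(2, 5)) {
    tab <- generate_survey(noisy, seed = s)
    counts <- table(tab[[decision_of(tab)]])
    expect_equal(as.integer(counts[c("1", "2", "3")]), c(14L, 41L, 108L))
  }
})

test_that("planted conjunctions hit their designed counts exclusively", {
  spec <- satisfaction_fixture_spec()
  for (s in c(1, 4, 8)) {
    tab <- generate_survey(spec, seed = s)
    rs <- planted_rule_set(tab)
    expect_equal(vapply(rs$rules, function(r) r$support, integer(1)),
                 vapply(spec$planted_rules, function(r) as.integer(r$count),
                        integer(1)))
    # exclusivity: nobody outside the class matches, so certainty is 1
    expect_true(all(vapply(rs$rules, function(r) r$certainty, numeric(1)) == 1))
  }
})

test_that("the bundled fixture reproduces the designed coverage percentages", {
  tab <- generate_survey(satisfaction_fixture_spec(), seed = 1)
  rs <- planted_rule_set(tab)
  cov_pct <- round(100 * vapply(rs$rules, function(r) r$coverage, numeric(1)),
                   2)
  expect_equal(cov_pct, c(35.71, 35.71, 14.29, 14.29, 14.29,
                          45.37, 11.11, 17.59, 20.37, 13.89))
  expect_equal(classification_quality(tab)$quality, 1)
})

test_that("fully planting a class yields a coverage-1 rule", {
  spec <- survey_spec(conditions = c("x", "y", "z"),
                      class_sizes = c("1" = 6, "2" = 8),
                      planted_rules = list(
                        list(conditions = c(x = 5, y = 5), decision = 1,
                             count = 6)),
                      noise = 0)
  tab <- generate_survey(spec, seed = 2)
  rs <- planted_rule_set(tab)
  expect_equal(rs$rules[[1]]$coverage, 1)
  # and covering induction finds a rule matching exactly that block
  ind <- induce_rules(tab, classes = 1)
  expect_true(any(vapply(ind$rules, function(r) r$support == 6, TRUE)))
})

test_that("infeasible planting specs are rejected with an explanation", {
  # count exceeding class size
  expect_error(survey_spec(c("x", "y"), c("1" = 3, "2" = 3),
                           list(list(conditions = c(x = 1), decision = 1,
                                     count = 5))),
               "exceeds class size")
  # duplicate exclusive pattern
  expect_error(survey_spec(c("x", "y"), c("1" = 5, "2" = 5),
                           list(list(conditions = c(x = 1), decision = 1,
                                     count = 2),
                                list(conditions = c(x = 1), decision = 2,
                                     count = 2))),
               "duplicates an exclusive planted pattern")
  # incompatible overlapping rules that cannot share enough objects
  spec <- survey_spec(c("x", "y"), c("1" = 4, "2" = 4),
                      list(list(conditions = c(x = 1, y = 1), decision = 1,
                                count = 3),
                           list(conditions = c(x = 2, y = 2), decision = 1,
                                count = 3)))
  expect_error(generate_survey(spec, seed = 1), "infeasible planting")
})

test_that("exhaustive induction recovers planted conjunctions with designed support", {
  spec <- satisfaction_fixture_spec()   # noise 0, exclusive planting
  for (s in 1:3) {
    tab <- generate_survey(spec, seed = s)
    rules <- induce_rules(tab, method = "all", max_length = 3)
    keys <- ruleset_keys(rules)
    for (p in spec$planted_rules) {
      hit <- vapply(rules$rules, function(r) {
        as.character(r$decision) == as.character(p$decision) &&
          all(paste(names(r$conditions), r$conditions, sep = "=") %in%
                paste(names(p$conditions), p$conditions, sep = "=")) &&
          r$support == p$count
      }, TRUE)
      expect_true(any(hit),
                  label = sprintf("seed %d: planted (%s) recovered", s,
                                  paste(names(p$conditions), p$conditions,
                                        sep = "=", collapse = " & ")))
    }
  }
})

test_that("the consistent generator always yields quality 1", {
  for (s in c(3, 17)) {
    tab <- generate_consistent_survey(seed = s)
    expect_equal(nrow(tab), 163)
    expect_equal(length(conditions_of(tab)), 9)
    q <- classification_quality(tab)
    expect_equal(q$quality, 1)
    expect_true(all(q$per_class$accuracy == 1))
  }
})

test_that("panel generation respects the score invariants and seed", {
  spec <- default_panel_spec()
  p1 <- generate_panel(spec, seed = 5)
  p2 <- generate_panel(spec, seed = 5)
  expect_identical(p1$conservative, p2$conservative)
  expect_true(all(p1$conservative >= 1 & p1$optimistic <= 10))
  expect_true(all(p1$conservative <= p1$optimistic))
  expect_equal(nrow(p1), 18 * 12)
  # constant panel: zero spread, no outliers
  const_spec <- panel_spec(n_experts = 6,
                           criteria = data.frame(criterion_id = "c",
                                                 importance = 8),
                           interval_width = 2, score_sd = 0,
                           outlier_rate = 0)
  cp <- generate_panel(const_spec, seed = 1)
  expect_equal(unique(cp$conservative), 7)
  expect_equal(unique(cp$optimistic), 9)
  scr <- screen_criteria(cp)
  expect_equal(scr$G, 8)  # degenerate TFNs: non-overlap midpoint
  expect_true(scr$retained)
})

test_that("a high-importance criterion is nearly always retained", {
  spec <- panel_spec(n_experts = 18,
                     criteria = data.frame(criterion_id = "hi",
                                           importance = 8.5),
                     interval_width = 2, score_sd = 1, outlier_rate = 0)
  kept <- vapply(1:200, function(s) {
    scr <- screen_criteria(generate_panel(spec, seed = s), threshold = 7)
    scr$retained[[1]]
  }, TRUE)
  expect_gte(mean(kept), 0.95)
})

test_that("injected aberrant responses are trimmed at about their rate", {
  spec <- panel_spec(n_experts = 18,
                     criteria = data.frame(
                       criterion_id = c("c1", "c2"),
                       importance = c(7.5, 8.2)),
                     interval_width = 2, score_sd = 1, outlier_rate = 0.1)
  trimmed <- unlist(lapply(1:200, function(s) {
    panel <- generate_panel(spec, seed = s)
    scr <- screen_criteria(panel)
    n <- 18
    c(1 - scr$n_used_conservative / n, 1 - scr$n_used_optimistic / n)
  }))
  expect_gte(mean(trimmed), 0.07)
  expect_lte(mean(trimmed), 0.13)
})

test_that("survey and panel specs round-trip through YAML", {
  spec <- satisfaction_fixture_spec()
  expect_s3_class(spec, "survey_spec")
  expect_equal(length(spec$conditions), 9)
  expect_equal(sum(spec$class_sizes), 163)
  expect_equal(length(spec$planted_rules), 10)
  ps <- default_panel_spec()
  expect_s3_class(ps, "panel_spec")
  expect_equal(ps$n_experts, 18)
  expect_equal(nrow(ps$criteria), 12)
})
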