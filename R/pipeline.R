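#' Pipeline run configuration
#'
#' Bundles and validates every setting of the end-to-end analysis. Either
#' `panel` / `panel_spec` feeds the Fuzzy Delphi stage (optional), and either
#' `table`, `table_path` or `survey_spec` provides the decision table for the
#' rough-set stage. The configuration is serialized into the output
#' directory for provenance.
#'
#' @param out_dir Output directory for run artifacts.
#' @param table A [decision_table()], or `NULL`.
#' @param table_path CSV path for the decision table, or `NULL`.
#' @param survey_spec A [survey_spec()] used to generate the table when no
#'   table is supplied (default: the bundled satisfaction fixture).
#' @param panel Expert-panel data frame for the FDM stage, or `NULL`.
#' @param panel_spec A [panel_spec()] used to generate a panel when
#'   `run_fdm = TRUE` and no panel is given.
#' @param run_fdm Run the Fuzzy Delphi screening stage (default: `TRUE` when
#'   a panel or panel spec is available).
#' @param decision Decision attribute name for `table_path` (default: last
#'   column).
#' @param fdm_threshold Consensus retention threshold (default 7).
#' @param central Central statistic for TFNs, see [build_tfn()].
#' @param min_coverage Rule-filter coverage threshold (default 0.10).
#' @param keep_classes Decision classes kept by the rule filter (default:
#'   the lowest and highest decision value in the table).
#' @param n_folds Cross-validation folds (default 10).
#' @param cv_filtered Cross-validate with the filtered rule set instead of
#'   the full induced set (default `FALSE`).
#' @param seed Integer seed governing generation, folding, everything random.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       table = NULL, table_path = NULL, survey_spec = NULL,
                       panel = NULL, panel_spec = NULL, run_fdm = NULL,
                       decision = NULL, fdm_threshold = 7,
                       central = c("geometric", "arithmetic"),
                       min_coverage = 0.10, keep_classes = NULL,
                       n_folds = 10L, cv_filtered = FALSE, seed = 1L) {
  central <- match.arg(central)
  if (!is.numeric(min_coverage) || min_coverage < 0 || min_coverage > 1) {
    stop("run_config: min_coverage must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(fdm_threshold) || fdm_threshold < 1 || fdm_threshold > 10) {
    stop("run_config: fdm_threshold must lie in [1, 10]", call. = FALSE)
  }
  if (!is.numeric(n_folds) || n_folds < 2) {
    stop("run_config: n_folds must be >= 2", call. = FALSE)
  }
  if (is.null(run_fdm)) run_fdm <- !is.null(panel) || !is.null(panel_spec)
  structure(list(out_dir = out_dir, table = table, table_path = table_path,
                 survey_spec = survey_spec, panel = panel,
                 panel_spec = panel_spec, run_fdm = isTRUE(run_fdm),
                 decision = decision, fdm_threshold = fdm_threshold,
                 central = central, min_coverage = min_coverage,
                 keep_classes = keep_classes, n_folds = as.integer(n_folds),
                 cv_filtered = isTRUE(cv_filtered), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full configurational analysis pipeline
#'
#' Executes, in order: (optional) Fuzzy Delphi screening of the expert
#' panel; loading or seeded generation of the survey decision table; the
#' rough-set quality report (per-class approximations, quality of
#' classification, reducts and core); LEM2 rule induction with support and
#' coverage; coverage filtering; stratified cross-validation; and the
#' decision flow graph of the filtered rules. Every artifact is written to
#' `config$out_dir` along with a run log and a `MANIFEST.json` holding an
#' md5 hash per file, so identical configurations and seeds produce
#' byte-identical manifests. Stage failures abort the run with the stage
#' name; artifacts already written are kept and the manifest is marked
#' incomplete.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`screen`, `table`,
#'   `quality`, `reducts`, `rules`, `filtered`, `cv`, `graph`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  results <- list()
  artifacts <- character(0)
  complete <- FALSE
  finish <- function() {
    writeLines(log_lines, log_path)
    manifest <- list(
      complete = complete,
      seed = config$seed,
      files = as.list(tools::md5sum(sort(artifacts)))
    )
    names(manifest$files) <- basename(sort(artifacts))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("stage '%s' FAILED: %s", name, conditionMessage(e))
      finish()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_out <- config[c("run_fdm", "fdm_threshold", "central", "min_coverage",
                      "keep_classes", "n_folds", "cv_filtered", "seed",
                      "decision", "table_path")]
  jsonlite::write_json(cfg_out, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  artifacts <- c(artifacts, cfg_path)

  if (config$run_fdm) {
    results$screen <- stage("fdm_screen", {
      panel <- config$panel
      if (is.null(panel)) {
        spec <- if (is.null(config$panel_spec)) default_panel_spec() else config$panel_spec
        panel <- generate_panel(spec, seed = config$seed)
      }
      scr <- screen_criteria(panel, threshold = config$fdm_threshold,
                             central = config$central)
      artifacts <- c(artifacts, write_consensus_report(scr, config$out_dir))
      say("FDM screen: %d/%d criteria retained at threshold %.4g",
          sum(scr$retained), nrow(scr), config$fdm_threshold)
      scr
    })
  }

  results$table <- stage("decision_table", {
    tab <- config$table
    if (is.null(tab) && !is.null(config$table_path)) {
      tab <- read_decision_table(config$table_path, decision = config$decision)
    }
    if (is.null(tab)) {
      spec <- if (is.null(config$survey_spec)) satisfaction_fixture_spec() else config$survey_spec
      tab <- generate_survey(spec, seed = config$seed)
    }
    p <- file.path(config$out_dir, "decision_table.csv")
    write_decision_table(tab, p)
    artifacts <- c(artifacts, p)
    say("decision table: %d objects, %d conditions", nrow(tab),
        length(conditions_of(tab)))
    tab
  })
  tab <- results$table
  if (is.null(config$keep_classes)) {
    dv <- sort(unique(as.character(tab[[decision_of(tab)]])))
    config$keep_classes <- c(dv[[1L]], dv[[length(dv)]])
  }

  results$quality <- stage("quality", {
    qual <- classification_quality(tab)
    per <- qual$per_class
    per$accuracy <- round(per$accuracy, 4)
    per$quality <- c(round(qual$quality, 4), rep(NA, nrow(per) - 1L))
    p <- file.path(config$out_dir, "quality.csv")
    utils::write.csv(per, p, row.names = FALSE, na = "")
    artifacts <- c(artifacts, p)
    say("quality of classification: %.4f", qual$quality)
    qual
  })

  results$reducts <- stage("reducts", {
    red <- find_reducts(tab)
    p <- file.path(config$out_dir, "reducts.json")
    jsonlite::write_json(list(gamma = red$gamma, exhaustive = red$exhaustive,
                              reducts = red$reducts, core = red$core),
                         p, auto_unbox = TRUE, pretty = TRUE)
    artifacts <- c(artifacts, p)
    say("reducts: %d found; core = {%s}", length(red$reducts),
        paste(red$core, collapse = ", "))
    red
  })

  results$rules <- stage("rule_induction", {
    rules <- induce_rules(tab)
    artifacts <- c(artifacts, write_rules(rules, config$out_dir, "rules_full"))
    say("induced %d certain rules", length(rules$rules))
    rules
  })

  results$filtered <- stage("rule_filter", {
    filt <- filter_rules(results$rules, config$min_coverage,
                         config$keep_classes)
    artifacts <- c(artifacts, write_rules(filt, config$out_dir,
                                           "rules_filtered"))
    say("filter (coverage >= %.2f, classes {%s}): %d rules kept",
        config$min_coverage, paste(config$keep_classes, collapse = ","),
        length(filt$rules))
    filt
  })

  results$cv <- stage("cross_validation", {
    cv <- cross_validate(tab, n_folds = config$n_folds, seed = config$seed,
                         min_coverage = if (config$cv_filtered) config$min_coverage else 0,
                         keep_classes = if (config$cv_filtered) config$keep_classes else NULL)
    p <- file.path(config$out_dir, "cv.csv")
    utils::write.csv(data.frame(fold = seq_along(cv$per_fold_accuracy),
                                accuracy = round(cv$per_fold_accuracy, 4)),
                     p, row.names = FALSE)
    pj <- file.path(config$out_dir, "cv.json")
    jsonlite::write_json(list(n_folds = cv$n_folds, seed = cv$seed,
                              mean_accuracy = round(cv$mean_accuracy, 4),
                              per_fold = round(cv$per_fold_accuracy, 4)),
                         pj, auto_unbox = TRUE, pretty = TRUE)
    artifacts <- c(artifacts, p, pj)
    say("%d-fold CV mean accuracy: %.2f%%", cv$n_folds, 100 * cv$mean_accuracy)
    cv
  })

  results$graph <- stage("flow_graph", {
    src <- if (length(results$filtered$rules)) results$filtered else results$rules
    g <- build_flow_graph(src)
    p <- file.path(config$out_dir, "flow_graph.dot")
    write_flow_graph_dot(g, p)
    artifacts <- c(artifacts, p)
    say("flow graph: %d condition nodes, %d decision nodes, %d edges",
        nrow(g$condition_nodes), nrow(g$decision_nodes), nrow(g$edges))
    g
  })

  complete <- TRUE
  say("run complete: %d artifacts in %s", length(artifacts), config$out_dir)
  results$manifest <- finish()
  invisible(results)
}
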