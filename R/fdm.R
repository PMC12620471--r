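#' Drop expert scores beyond two standard deviations
#'
#' Single-pass outlier exclusion used before building triangular fuzzy
#' numbers: scores with \eqn{|x - \bar x| > 2 s} (sample standard deviation,
#' \eqn{n-1} denominator) are removed. The pass is applied once; survivors are
#' not re-tested, which avoids cascade removal on small expert panels. When
#' all scores are identical (\eqn{s = 0}) nothing is removed.
#'
#' @param scores Numeric vector of at least two expert scores.
#' @return Numeric vector, the retained scores in their original order.
#' @examples
#' trim_outliers(c(1, rep(8, 9)))  # drops the 1
#' @export
trim_outliers <- function(scores) {
  if (!is.numeric(scores) || length(scores) < 2L) {
    stop("invalid panel: need at least 2 scores to trim", call. = FALSE)
  }
  s <- stats::sd(scores)
  if (s == 0) return(scores)
  keep <- abs(scores - mean(scores)) <= 2 * s
  scores[keep]
}

#' Triangular fuzzy number from a score series
#'
#' Aggregates one criterion's (trimmed) expert scores into a triangular fuzzy
#' number (low, mode, high) = (minimum, central statistic, maximum). The
#' default central statistic is the geometric mean \eqn{(\prod x_i)^{1/n}};
#' the arithmetic mean is available as an alternative since published
#' consensus tables are sometimes computed either way.
#'
#' @param scores Positive numeric vector (strictly positive: the geometric
#'   mean is undefined otherwise).
#' @param central `"geometric"` (default) or `"arithmetic"` central statistic.
#' @return An object of class `tfn`: numeric vector `c(low, mode, high)`.
#' @examples
#' build_tfn(c(4, 6, 9))  # (4, 6, 9): (4*6*9)^(1/3) = 6
#' @export
build_tfn <- function(scores, central = c("geometric", "arithmetic")) {
  central <- match.arg(central)
  if (!is.numeric(scores) || length(scores) == 0L) {
    stop("build_tfn: need a nonempty numeric score vector", call. = FALSE)
  }
  if (any(scores <= 0)) {
    stop("build_tfn: all scores must be positive", call. = FALSE)
  }
  mode <- if (central == "geometric") exp(mean(log(scores))) else mean(scores)
  tfn(min(scores), mode, max(scores))
}

#' Construct a triangular fuzzy number
#'
#' @param low,mode,high Numbers with `low <= mode <= high`.
#' @return An object of class `tfn`.
#' @export
tfn <- function(low, mode, high) {
  stopifnot(is.numeric(low), is.numeric(mode), is.numeric(high))
  if (!(low <= mode + 1e-12 && mode <= high + 1e-12)) {
    stop("tfn: requires low <= mode <= high", call. = FALSE)
  }
  structure(c(low = low, mode = mode, high = high), class = "tfn")
}

#' @export
print.tfn <- function(x, ...) {
  cat(sprintf("TFN(%.4f, %.4f, %.4f)\n", x[["low"]], x[["mode"]], x[["high"]]))
  invisible(x)
}

#' Gray-zone convergence test and consensus value
#'
#' Given the conservative TFN \eqn{(C_L, C_M, C_U)} and the optimistic TFN
#' \eqn{(O_L, O_M, O_U)} for one criterion, tests expert convergence and, when
#' convergent, defuzzifies a consensus value \eqn{G}:
#'
#' * If \eqn{C_U < O_L} the two fuzzy numbers do not overlap and opinions
#'   converge trivially; \eqn{G = (C_M + O_M)/2}.
#' * Otherwise the gray zone \eqn{Z = C_U - O_L} is compared with the gap
#'   between the modes \eqn{M = O_M - C_M}. If \eqn{Z \le M} opinions still
#'   converge and
#'   \deqn{G = \frac{C_U O_M - O_L C_M}{(C_U - C_M) + (O_M - O_L)},}
#'   the abscissa of the crossing point of the two membership functions.
#'   When \eqn{C_U = O_L = k} this reduces algebraically to \eqn{k}.
#' * If \eqn{Z > M} the criterion is flagged non-convergent (re-survey
#'   needed) and \eqn{G} is `NA`.
#'
#' @param conservative_tfn,optimistic_tfn Objects of class [tfn()] (or numeric
#'   length-3 vectors `(low, mode, high)`).
#' @return A list with components `gray_zone` (Z), `mode_gap` (M), `converged`
#'   (logical) and `consensus` (G, `NA` when not converged).
#' @examples
#' # reproduces a published consensus value:
#' fdm_consensus(tfn(4, 6.0666, 8), tfn(6, 8.4, 9))$consensus  # 7.1077
#' @export
fdm_consensus <- function(conservative_tfn, optimistic_tfn) {
  ct <- as_tfn(conservative_tfn)
  ot <- as_tfn(optimistic_tfn)
  c_m <- ct[["mode"]]; c_u <- ct[["high"]]
  o_l <- ot[["low"]];  o_m <- ot[["mode"]]
  z <- c_u - o_l
  m <- o_m - c_m
  if (c_u < o_l) {
    return(list(gray_zone = z, mode_gap = m, converged = TRUE,
                consensus = (c_m + o_m) / 2))
  }
  if (z <= m) {
    denom <- (c_u - c_m) + (o_m - o_l)
    if (denom == 0) {
      stop("degenerate panel: C_U = C_M and O_M = O_L leave the consensus undefined",
           call. = FALSE)
    }
    g <- (c_u * o_m - o_l * c_m) / denom
    return(list(gray_zone = z, mode_gap = m, converged = TRUE, consensus = g))
  }
  list(gray_zone = z, mode_gap = m, converged = FALSE, consensus = NA_real_)
}

as_tfn <- function(x) {
  if (inherits(x, "tfn")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(tfn(x[[1L]], x[[2L]], x[[3L]]))
  stop("expected a tfn or a numeric (low, mode, high) triple", call. = FALSE)
}

#' Screen candidate criteria with the Fuzzy Delphi Method
#'
#' Runs the full FDM screen over an expert panel: per criterion, the
#' conservative and optimistic score series are separately trimmed of
#' two-standard-deviation outliers ([trim_outliers()]), aggregated into
#' triangular fuzzy numbers ([build_tfn()]), tested for gray-zone convergence
#' and defuzzified ([fdm_consensus()]). A criterion is retained when it
#' converges and its consensus value reaches the threshold (`>=` comparison,
#' so a criterion exactly at the threshold is kept). Non-convergent criteria
#' are never dropped silently: they appear in the output with
#' `converged = FALSE` and `needs_resurvey = TRUE`.
#'
#' @param panel A data frame with columns `expert_id`, `criterion_id`,
#'   `conservative`, `optimistic` (one row per expert x criterion), e.g. from
#'   [read_panel()] or [generate_panel()].
#' @param threshold Retention threshold on the consensus value, default 7 on
#'   the 1--10 scale.
#' @param central Central statistic for the TFN mode, see [build_tfn()].
#' @return A data frame of class `fdm_screen` with one row per criterion in
#'   input order: the six TFN parameters `C_L, C_M, C_U, O_L, O_M, O_U`, the
#'   gray zone `Z`, mode gap `M`, `converged`, consensus `G`, `retained`,
#'   `needs_resurvey`, and the post-trim counts `n_used_conservative`,
#'   `n_used_optimistic`.
#' @export
screen_criteria <- function(panel, threshold = 7,
                            central = c("geometric", "arithmetic")) {
  central <- match.arg(central)
  panel <- validate_panel(panel)
  crits <- unique(panel$criterion_id)
  rows <- lapply(crits, function(cr) {
    sub <- panel[panel$criterion_id == cr, , drop = FALSE]
    if (nrow(sub) < 2L) {
      stop(sprintf("invalid panel: criterion '%s' has fewer than 2 experts", cr),
           call. = FALSE)
    }
    cons <- trim_outliers(sub$conservative)
    opti <- trim_outliers(sub$optimistic)
    ct <- build_tfn(cons, central = central)
    ot <- build_tfn(opti, central = central)
    res <- fdm_consensus(ct, ot)
    data.frame(
      criterion_id = cr,
      C_L = ct[["low"]], C_M = ct[["mode"]], C_U = ct[["high"]],
      O_L = ot[["low"]], O_M = ot[["mode"]], O_U = ot[["high"]],
      Z = res$gray_zone, M = res$mode_gap,
      converged = res$converged,
      G = res$consensus,
      # >= with a machine tolerance: G values that equal the threshold
      # algebraically (e.g. the C_U = O_L boundary) must be retained
      retained = isTRUE(res$converged) && !is.na(res$consensus) &&
        res$consensus >= threshold - 1e-9,
      needs_resurvey = !res$converged,
      n_used_conservative = length(cons),
      n_used_optimistic = length(opti),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(criterion_id = character(), C_L = numeric(),
                      C_M = numeric(), C_U = numeric(), O_L = numeric(),
                      O_M = numeric(), O_U = numeric(), Z = numeric(),
                      M = numeric(), converged = logical(), G = numeric(),
                      retained = logical(), needs_resurvey = logical(),
                      n_used_conservative = integer(),
                      n_used_optimistic = integer(),
                      stringsAsFactors = FALSE)
  }
  attr(out, "threshold") <- threshold
  attr(out, "central") <- central
  class(out) <- c("fdm_screen", "data.frame")
  out
}

#' @export
print.fdm_screen <- function(x, ...) {
  cat(sprintf("Fuzzy Delphi screen: %d criteria, threshold %.4g (%s mean)\n",
              nrow(x), attr(x, "threshold"), attr(x, "central")))
  kept <- x$criterion_id[x$retained]
  drop <- x$criterion_id[!x$retained & x$converged]
  resv <- x$criterion_id[!x$converged]
  cat(sprintf("  retained (%d): %s\n", length(kept), paste(kept, collapse = ", ")))
  if (length(drop)) {
    cat(sprintf("  excluded (%d): %s\n", length(drop), paste(drop, collapse = ", ")))
  }
  if (length(resv)) {
    cat(sprintf("  non-convergent, re-survey (%d): %s\n",
                length(resv), paste(resv, collapse = ", ")))
  }
  print.data.frame(cbind(x[, "criterion_id", drop = FALSE],
                         round(x[, c("C_M", "C_U", "O_L", "O_M", "Z", "M", "G")], 4),
                         x[, c("converged", "retained")]),
                   row.names = FALSE)
  invisible(x)
}

validate_panel <- function(panel) {
  need <- c("expert_id", "criterion_id", "conservative", "optimistic")
  if (!is.data.frame(panel) || !all(need %in% names(panel))) {
    stop("panel must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  bad_range <- !is.finite(panel$conservative) | !is.finite(panel$optimistic) |
    panel$conservative < 1 | panel$conservative > 10 |
    panel$optimistic < 1 | panel$optimistic > 10
  bad_order <- !bad_range & panel$conservative > panel$optimistic
  if (any(bad_range) || any(bad_order)) {
    idx <- which(bad_range | bad_order)
    stop(sprintf(
      "invalid panel rows (scores must lie in [1,10] with conservative <= optimistic): %s",
      paste(utils::head(idx, 20L), collapse = ", ")), call. = FALSE)
  }
  panel
}

#' Read an expert panel from CSV
#'
#' Expects the header `expert_id,criterion_id,conservative,optimistic`. Rows
#' violating the score invariants (scores in \[1,10\],
#' conservative <= optimistic) are rejected with a report of the offending
#' row numbers.
#'
#' @param path CSV file path.
#' @return A validated panel data frame.
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_panel(panel)
}

#' Bundled published Fuzzy Delphi reference parameters
#'
#' Loads the packaged reference table of twelve candidate criteria for home
#' treatment devices with their published double-triangular-fuzzy-number
#' parameters (`C_U`, `O_L`, `C_M`, `O_M` on the 1--10 scale). Applying
#' [fdm_consensus()] row-wise reproduces the published consensus values and
#' the 9-of-12 retention verdict at threshold 7, which is how the package
#' validates its consensus arithmetic.
#'
#' @return Data frame with columns `criterion_id`, `C_U`, `O_L`, `C_M`, `O_M`.
#' @export
fdm_reference <- function() {
  utils::read.csv(system.file("extdata", "fdm_reference.csv",
                              package = "roughdelphi", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Consensus from summary fuzzy-number parameters
#'
#' Convenience wrapper for [fdm_consensus()] when only the four parameters
#' that the convergence test and defuzzification use are available (as in
#' published consensus tables): the conservative mode and maximum and the
#' optimistic minimum and mode.
#'
#' @param C_U,O_L,C_M,O_M Numeric scalars (or equal-length vectors).
#' @return For scalars, the [fdm_consensus()] list; for vectors, a data frame
#'   with columns `gray_zone`, `mode_gap`, `converged`, `consensus`.
#' @export
fdm_consensus_params <- function(C_U, O_L, C_M, O_M) {
  one <- function(cu, ol, cm, om) {
    fdm_consensus(tfn(min(cm, cu), cm, cu), tfn(ol, max(ol, om), max(ol, om)))
  }
  if (length(C_U) == 1L) return(one(C_U, O_L, C_M, O_M))
  res <- Map(one, C_U, O_L, C_M, O_M)
  data.frame(gray_zone = vapply(res, `[[`, 0, "gray_zone"),
             mode_gap = vapply(res, `[[`, 0, "mode_gap"),
             converged = vapply(res, `[[`, TRUE, "converged"),
             consensus = vapply(res, `[[`, 0, "consensus"))
}

#' Write the FDM consensus report
#'
#' Writes the per-criterion consensus table as CSV (numeric columns formatted
#' to 4 decimals) plus a JSON summary of retained/excluded/non-convergent
#' criteria.
#'
#' @param screen An `fdm_screen` result from [screen_criteria()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_consensus_report <- function(screen, dir) {
  stopifnot(inherits(screen, "fdm_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(dir, "fdm_consensus.csv")
  out <- screen
  num <- c("C_L", "C_M", "C_U", "O_L", "O_M", "O_U", "Z", "M", "G")
  for (cn in num) out[[cn]] <- ifelse(is.na(out[[cn]]), "",
                                      formatC(out[[cn]], format = "f", digits = 4))
  cols <- c("criterion_id", "C_L", "C_M", "C_U", "O_L", "O_M", "O_U",
            "Z", "M", "converged", "G", "retained")
  utils::write.csv(out[, cols], csv_path, row.names = FALSE)
  json_path <- file.path(dir, "fdm_summary.json")
  jsonlite::write_json(list(
    threshold = attr(screen, "threshold"),
    central = attr(screen, "central"),
    n_criteria = nrow(screen),
    retained = screen$criterion_id[screen$retained],
    excluded = screen$criterion_id[!screen$retained & screen$converged],
    needs_resurvey = screen$criterion_id[!screen$converged]
  ), json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv_path, json_path))
}
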