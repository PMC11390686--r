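# End-to-end two-stage workflow: yearly super-SBM scores, efficiency
# summaries and growth rates, the Malmquist tables, and the optional
# censored-regression determinants stage.

#' Percentage growth between two periods of a score series
#'
#' \code{100 * (score_last / score_first - 1)}, the "grew by x%" number
#' quoted for efficiency series.
#'
#' @param scores named numeric vector (names = period labels) or a data
#'   frame with \code{period} and \code{score} columns.
#' @param first,last period labels.
#' @return percentage (numeric scalar).
#' @export
growth_rate <- function(scores, first, last) {
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$score, scores$period)
  first <- as.character(first); last <- as.character(last)
  if (!first %in% names(scores) || !last %in% names(scores))
    stop("period not present in the score series")
  s0 <- scores[[first]]; s1 <- scores[[last]]
  if (is.na(s0) || is.na(s1)) stop("score missing for requested period")
  if (s0 <= 0) stop("first-period score must be positive")
  100 * (s1 / s0 - 1)
}

#' Efficient-DMU counts per period
#'
#' @param score_tables data frame with \code{period}, \code{score} (and
#'   optionally \code{status}) columns covering one or more periods —
#'   e.g. rbind-ed \code{score_cross_section} tables.
#' @param tau classification threshold: efficient means
#'   \code{score >= 1 - tau}.
#' @return data frame: period, n_efficient, n.
#' @export
efficient_counts <- function(score_tables, tau = 1e-6) {
  stopifnot(all(c("period", "score") %in% names(score_tables)))
  periods <- unique(score_tables$period)
  out <- data.frame(period = periods,
                    n_efficient = NA_integer_, n = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(periods)) {
    s <- score_tables$score[score_tables$period == periods[i]]
    out$n[i] <- length(s)
    out$n_efficient[i] <- sum(!is.na(s) & s >= 1 - tau)
    if (!length(s)) warning("no scores for period ", periods[i])
  }
  out
}

#' Run the full two-stage efficiency study on a panel
#'
#' Pipeline: validate the panel, score every period's cross-section with
#' the configured DEA model (per-year frontiers), summarise (yearly mean
#' scores, efficient counts, first-to-last growth rates), compute the
#' adjacent-period Malmquist table with per-DMU and per-pair aggregations,
#' and — when covariates are supplied — regress the per-(dmu, period)
#' scores on them with a Tobit second stage.
#'
#' @param panel a \code{\link{panel_dataset}} (or path to a panel CSV).
#' @param covariates optional covariate data frame (\code{dmu},
#'   \code{period}, covariate columns) or CSV path; enables the Tobit
#'   stage.
#' @param cfg a \code{\link{dea_config}} for the yearly scores (default
#'   non-oriented CRS super-SBM).
#' @param agg \code{"arithmetic"} (default) or \code{"geometric"}
#'   Malmquist aggregation.
#' @param epsilon_substitute passed to \code{\link{validate_panel}}.
#' @param tobit_lower,tobit_upper censoring bounds for the second stage.
#' @param out_dir optional directory; when given, score tables, Malmquist
#'   tables and the report are also written as CSV/JSON files.
#' @param precision decimal places used when serialising report tables
#'   (internal objects keep full precision).
#'
#' @return object of class \code{study_report}: list with
#'   \code{score_table} (all periods stacked), \code{yearly} (period,
#'   mean_score, n_efficient), \code{growth} (per-DMU first-to-last
#'   growth rate and the growth of the yearly mean), \code{malmquist}
#'   (pair-level table), \code{malmquist_by_dmu},
#'   \code{malmquist_by_pair}, \code{tobit} (fit or NULL), \code{config}
#'   metadata.
#' @export
run_pipeline <- function(panel, covariates = NULL,
                         cfg = dea_config("sesbm"),
                         agg = c("arithmetic", "geometric"),
                         epsilon_substitute = FALSE,
                         tobit_lower = 0, tobit_upper = Inf,
                         out_dir = NULL, precision = 3L) {
  agg <- match.arg(agg)
  if (is.character(panel)) panel <- load_panel(panel)
  stopifnot(inherits(panel, "panel_dataset"), precision >= 1L)
  if (is.character(covariates)) covariates <- load_covariates(covariates, panel)
  panel <- validate_panel(panel, epsilon_substitute)

  # stage 1: per-year cross-sectional frontiers
  score_rows <- lapply(panel$periods, function(p)
    score_cross_section(cross_section(panel, p), cfg)$table)
  score_table <- do.call(rbind, score_rows)
  yearly <- data.frame(
    period = panel$periods,
    mean_score = vapply(score_rows, function(t) mean(t$score, na.rm = TRUE),
                        numeric(1)),
    n_efficient = vapply(score_rows, function(t)
      sum(t$efficient, na.rm = TRUE), integer(1)))
  first <- panel$periods[1L]; last <- panel$periods[length(panel$periods)]
  per_dmu_growth <- vapply(panel$dmu_ids, function(d) {
    s <- score_table[score_table$dmu == d, ]
    tryCatch(growth_rate(stats::setNames(s$score, s$period), first, last),
             error = function(e) NA_real_)
  }, numeric(1))
  growth <- list(
    per_dmu = data.frame(dmu = panel$dmu_ids,
                         growth_pct = unname(per_dmu_growth)),
    mean_score = growth_rate(stats::setNames(yearly$mean_score,
                                             yearly$period), first, last),
    first = first, last = last)

  # stage 1b: productivity change
  mal <- malmquist_table(panel)
  by_dmu <- aggregate_malmquist(mal, by = "dmu", method = agg)
  by_pair <- aggregate_malmquist(mal, by = "pair", method = agg)

  # stage 2: determinants
  tob <- NULL
  if (!is.null(covariates)) {
    stopifnot(all(c("dmu", "period") %in% names(covariates)))
    merged <- merge(score_table[, c("dmu", "period", "score")], covariates,
                    by = c("dmu", "period"))
    if (!nrow(merged)) stop("covariates do not match any (dmu, period) score")
    covs <- as.matrix(merged[, setdiff(names(merged),
                                       c("dmu", "period", "score")),
                             drop = FALSE])
    tob <- fit_tobit(merged$score, covs, lower = tobit_lower,
                     upper = tobit_upper)
  }

  report <- structure(
    list(score_table = score_table, yearly = yearly, growth = growth,
         malmquist = mal, malmquist_by_dmu = by_dmu,
         malmquist_by_pair = by_pair, tobit = tob,
         validation = attr(panel, "validation"),
         config = list(model = cfg$model, rts = cfg$rts,
                       orientation = cfg$orientation, tau = cfg$tau,
                       aggregation = agg, precision = precision)),
    class = "study_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n")
  cat(sprintf("  model: %s/%s/%s, aggregation %s\n", toupper(x$config$model),
              toupper(x$config$rts), x$config$orientation,
              x$config$aggregation))
  cat("  yearly mean scores:\n")
  print(transform(x$yearly, mean_score = round(mean_score,
                                               x$config$precision)))
  cat(sprintf("  mean-score growth %s-%s: %.2f%%\n", x$growth$first,
              x$growth$last, x$growth$mean_score))
  cat("  Malmquist means (per DMU, trailing Mean row):\n")
  tail_row <- x$malmquist_by_dmu[nrow(x$malmquist_by_dmu), ]
  print(transform(tail_row,
                  effch = round(effch, 3), techch = round(techch, 3),
                  pech = round(pech, 3), sech = round(sech, 3),
                  tfpch = round(tfpch, 3)))
  if (!is.null(x$tobit)) { cat("  tobit stage:\n"); print(x$tobit) }
  invisible(x)
}

#' Serialise a study report to CSV/JSON files
#'
#' Writes \code{scores_<period>.csv} per period, \code{malmquist.csv},
#' \code{summary_by_dmu.csv}, \code{summary_by_pair.csv},
#' \code{yearly.csv}, optionally \code{tobit.json}, and
#' \code{report.json} with config and summary numbers. Numeric table
#' cells are rounded to the report's configured precision at
#' serialisation time only.
#'
#' @param report a \code{study_report}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pr <- report$config$precision
  rnd <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = pr)
    df
  }
  for (p in unique(report$score_table$period))
    utils::write.csv(rnd(report$score_table[report$score_table$period == p, ]),
                     file.path(out_dir, paste0("scores_", p, ".csv")),
                     row.names = FALSE)
  utils::write.csv(rnd(report$malmquist),
                   file.path(out_dir, "malmquist.csv"), row.names = FALSE)
  utils::write.csv(rnd(report$malmquist_by_dmu),
                   file.path(out_dir, "summary_by_dmu.csv"),
                   row.names = FALSE)
  utils::write.csv(rnd(report$malmquist_by_pair),
                   file.path(out_dir, "summary_by_pair.csv"),
                   row.names = FALSE)
  utils::write.csv(rnd(report$yearly), file.path(out_dir, "yearly.csv"),
                   row.names = FALSE)
  if (!is.null(report$tobit)) {
    tj <- list(bounds = c(report$tobit$lower, report$tobit$upper),
               counts = c(left = report$tobit$n_left,
                          uncensored = report$tobit$n_uncensored,
                          right = report$tobit$n_right),
               loglik = report$tobit$loglik,
               converged = report$tobit$converged,
               coefficients = tobit_report(report$tobit,
                                           check_convergence = FALSE))
    jsonlite::write_json(tj, file.path(out_dir, "tobit.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  jsonlite::write_json(
    list(config = report$config,
         growth_mean_pct = report$growth$mean_score,
         yearly = report$yearly),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(out_dir)
}
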