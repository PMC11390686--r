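# Balanced DMU x period panels of positive input/output quantities.
#
# Storage: two 3-d arrays X (dmu x period x input) and Y (dmu x period x
# output) with dimnames, so slicing a cross-section is a single `[` call.

#' Construct a balanced DMU panel
#'
#' A \code{panel_dataset} holds a balanced panel of decision-making units
#' (DMUs) observed over periods, with \code{m >= 1} input and \code{q >= 1}
#' output quantities per cell. All quantities must be finite; positivity is
#' checked by \code{\link{validate_panel}} (DEA requires strictly positive
#' data).
#'
#' @param X numeric array \code{n x T x m} of inputs (dimnames optional).
#' @param Y numeric array \code{n x T x q} of outputs.
#' @param dmu_ids character vector of unique DMU labels (length n).
#' @param periods character vector of unique period labels (length T).
#' @param input_names,output_names variable names (lengths m, q).
#'
#' @return an object of class \code{panel_dataset}.
#' @seealso \code{\link{load_panel}}, \code{\link{cross_section}},
#'   \code{\link{descriptive_totals}}
#' @export
panel_dataset <- function(X, Y, dmu_ids, periods, input_names, output_names) {
  dmu_ids <- as.character(dmu_ids)
  periods <- as.character(periods)
  input_names <- as.character(input_names)
  output_names <- as.character(output_names)
  if (anyDuplicated(dmu_ids)) stop("duplicate DMU ids")
  if (anyDuplicated(periods)) stop("duplicate period labels")
  if (anyDuplicated(c(input_names, output_names)))
    stop("duplicate variable names")
  if (length(input_names) < 1L || length(output_names) < 1L)
    stop("need at least one input and one output variable")
  dm <- c(length(dmu_ids), length(periods))
  X <- array(as.numeric(X), dim = c(dm, length(input_names)),
             dimnames = list(dmu_ids, periods, input_names))
  Y <- array(as.numeric(Y), dim = c(dm, length(output_names)),
             dimnames = list(dmu_ids, periods, output_names))
  if (anyNA(X) || anyNA(Y) || any(!is.finite(X)) || any(!is.finite(Y)))
    stop("panel values must all be finite (unbalanced panel?)")
  structure(list(dmu_ids = dmu_ids, periods = periods,
                 input_names = input_names, output_names = output_names,
                 X = X, Y = Y),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("panel_dataset: %d DMUs x %d periods, %d inputs, %d outputs\n",
              length(x$dmu_ids), length(x$periods),
              length(x$input_names), length(x$output_names)))
  cat("  DMUs:    ", paste(utils::head(x$dmu_ids, 8L), collapse = ", "),
      if (length(x$dmu_ids) > 8L) ", ..." else "", "\n", sep = "")
  cat("  periods: ", paste(x$periods, collapse = ", "), "\n", sep = "")
  cat("  inputs:  ", paste(x$input_names, collapse = ", "), "\n", sep = "")
  cat("  outputs: ", paste(x$output_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# strip thousands separators ("4,376") before numeric conversion
.parse_numeric <- function(v, what, rows) {
  out <- suppressWarnings(as.numeric(gsub(",", "", v, fixed = TRUE)))
  bad <- which(is.na(out) & !is.na(v))
  if (length(bad))
    stop(sprintf("non-numeric value %s in column '%s', data row %d",
                 dQuote(v[bad[1L]]), what, rows[bad[1L]]))
  out
}

#' Read a DMU panel from a wide CSV file
#'
#' The expected layout is one row per (dmu, period): a \code{dmu} column, a
#' \code{period} column, then variable columns whose names carry an
#' \code{input:} or \code{output:} prefix, e.g. \code{input:beds},
#' \code{output:visits}. Thousands separators (\code{","}) inside numbers
#' are tolerated. The panel must be balanced: every DMU observed in every
#' period.
#'
#' @param path CSV file path.
#' @param period_order optional character vector giving the period ordering;
#'   default is lexicographic (year labels sort chronologically).
#'
#' @return a \code{\link{panel_dataset}}.
#' @export
load_panel <- function(path, period_order = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("dmu", "period")
  if (!all(need %in% names(raw)))
    stop("panel CSV must have 'dmu' and 'period' columns")
  vars <- setdiff(names(raw), need)
  in_cols <- vars[startsWith(vars, "input:")]
  out_cols <- vars[startsWith(vars, "output:")]
  if (length(in_cols) < 1L || length(out_cols) < 1L)
    stop("panel CSV needs at least one 'input:' and one 'output:' column")
  unknown <- setdiff(vars, c(in_cols, out_cols))
  if (length(unknown))
    stop("columns without input:/output: prefix: ",
         paste(unknown, collapse = ", "))

  dmu_ids <- unique(raw$dmu)
  periods <- unique(raw$period)
  periods <- if (is.null(period_order)) sort(periods) else {
    if (!setequal(period_order, periods))
      stop("period_order does not match the periods present in the file")
    period_order
  }
  key <- paste(raw$dmu, raw$period, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (dmu, period) row: ",
         sub("\r", "/", key[duplicated(key)][1L], fixed = TRUE))
  full <- expand.grid(dmu = dmu_ids, period = periods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(paste(full$dmu, full$period, sep = "\r"), key)
  if (length(missing))
    stop("unbalanced panel: missing (dmu, period) cell ",
         sub("\r", "/", missing[1L], fixed = TRUE))

  idx <- matrix(NA_integer_, length(dmu_ids), length(periods))
  idx[cbind(match(raw$dmu, dmu_ids), match(raw$period, periods))] <-
    seq_len(nrow(raw))
  grab <- function(cols) {
    vapply(cols, function(cl) {
      v <- .parse_numeric(raw[[cl]], cl, seq_len(nrow(raw)))
      matrix(v[idx], length(dmu_ids), length(periods))
    }, matrix(0, length(dmu_ids), length(periods)))
  }
  panel_dataset(grab(in_cols), grab(out_cols), dmu_ids, periods,
                sub("^input:", "", in_cols), sub("^output:", "", out_cols))
}

#' Write a DMU panel to a wide CSV file
#'
#' Inverse of \code{\link{load_panel}}: values round-trip at full precision.
#'
#' @param p a \code{\link{panel_dataset}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(p, path) {
  stopifnot(inherits(p, "panel_dataset"))
  rows <- expand.grid(dmu = p$dmu_ids, period = p$periods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(rows, check.names = FALSE)
  for (v in p$input_names)
    out[[paste0("input:", v)]] <-
      p$X[cbind(rows$dmu, rows$period, v)]
  for (v in p$output_names)
    out[[paste0("output:", v)]] <-
      p$Y[cbind(rows$dmu, rows$period, v)]
  utils::write.csv(format(out, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a panel for DEA use
#'
#' DEA models require strictly positive data. With
#' \code{epsilon_substitute = FALSE} (the default) any non-positive cell is
#' an error; with \code{TRUE} zero cells are replaced by \code{1e-6} times
#' the column (variable) maximum and each substitution is listed in the
#' attached report. Negative values are always an error. The report also
#' notes whether the discrimination rule of thumb n > 2(m + q) holds; a
#' violation is a warning in the report, not an error.
#'
#' @param p a \code{\link{panel_dataset}}.
#' @param epsilon_substitute replace zeros by 1e-6 x column max?
#'
#' @return the (possibly adjusted) panel, with a \code{"validation"}
#'   attribute: list with \code{substitutions} (data frame) and
#'   \code{warnings} (character).
#' @export
validate_panel <- function(p, epsilon_substitute = FALSE) {
  stopifnot(inherits(p, "panel_dataset"))
  subs <- list()
  fix <- function(A, kind) {
    for (v in dimnames(A)[[3]]) {
      slab <- A[, , v, drop = FALSE]
      if (any(slab < 0))
        stop(sprintf("negative value for %s '%s'", kind, v))
      zero <- which(slab == 0, arr.ind = TRUE)
      if (nrow(zero)) {
        if (!epsilon_substitute) {
          z <- zero[1L, ]
          stop(sprintf(
            "non-positive value for %s '%s' at DMU %s, period %s (set epsilon_substitute = TRUE to substitute)",
            kind, v, dimnames(A)[[1]][z[1L]], dimnames(A)[[2]][z[2L]]))
        }
        repl <- 1e-6 * max(slab)
        if (repl <= 0)
          stop(sprintf("%s '%s' is identically zero; cannot substitute", kind, v))
        for (r in seq_len(nrow(zero))) {
          A[zero[r, 1L], zero[r, 2L], v] <- repl
          subs[[length(subs) + 1L]] <<- data.frame(
            dmu = dimnames(A)[[1]][zero[r, 1L]],
            period = dimnames(A)[[2]][zero[r, 2L]],
            variable = v, replacement = repl)
        }
      }
    }
    A
  }
  p$X <- fix(p$X, "input")
  p$Y <- fix(p$Y, "output")
  n <- length(p$dmu_ids)
  mq <- length(p$input_names) + length(p$output_names)
  warns <- character(0)
  if (n <= 2L * mq)
    warns <- sprintf(
      "only %d DMUs for %d variables; discrimination rule of thumb wants n > 2(m+q) = %d",
      n, mq, 2L * mq)
  attr(p, "validation") <- list(
    substitutions = if (length(subs)) do.call(rbind, subs) else
      data.frame(dmu = character(0), period = character(0),
                 variable = character(0), replacement = numeric(0)),
    warnings = warns)
  p
}

#' Extract one period's cross-section
#'
#' @param p a \code{\link{panel_dataset}}.
#' @param period a period label present in \code{p$periods}.
#'
#' @return an object of class \code{cross_section}: list with \code{period},
#'   input matrix \code{X} (n x m), output matrix \code{Y} (n x q), and
#'   \code{dmu_ids} in stored order.
#' @export
cross_section <- function(p, period) {
  stopifnot(inherits(p, "panel_dataset"))
  period <- as.character(period)
  if (!period %in% p$periods)
    stop("unknown period: ", period)
  X <- p$X[, period, , drop = TRUE]
  Y <- p$Y[, period, , drop = TRUE]
  # drop = TRUE collapses n = 1 or m = 1 to vectors; restore matrix shape
  X <- matrix(X, length(p$dmu_ids), length(p$input_names),
              dimnames = list(p$dmu_ids, p$input_names))
  Y <- matrix(Y, length(p$dmu_ids), length(p$output_names),
              dimnames = list(p$dmu_ids, p$output_names))
  structure(list(period = period, X = X, Y = Y, dmu_ids = p$dmu_ids),
            class = "cross_section")
}

#' Per-period column totals
#'
#' Sums every input and output variable over DMUs within each period —
#' the descriptive aggregates usually reported alongside an efficiency
#' analysis.
#'
#' @param p a \code{\link{panel_dataset}}.
#' @return data frame: one row per period, one column per variable
#'   (inputs first), plus a leading \code{period} column.
#' @export
descriptive_totals <- function(p) {
  stopifnot(inherits(p, "panel_dataset"))
  tx <- apply(p$X, c(2, 3), sum)
  ty <- apply(p$Y, c(2, 3), sum)
  out <- data.frame(period = p$periods,
                    matrix(cbind(tx, ty), nrow = length(p$periods)),
                    check.names = FALSE, row.names = NULL)
  names(out)[-1L] <- c(p$input_names, p$output_names)
  out
}

#' Read a covariate table for the determinants stage
#'
#' Layout: \code{dmu}, \code{period}, then named numeric covariate columns.
#' Keys must be a subset of the panel's (dmu, period) pairs when a panel is
#' supplied.
#'
#' @param path CSV path.
#' @param panel optional \code{\link{panel_dataset}} to check keys against.
#' @return data frame with \code{dmu}, \code{period}, covariates.
#' @export
load_covariates <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("dmu", "period") %in% names(raw)))
    stop("covariate CSV must have 'dmu' and 'period' columns")
  out <- data.frame(dmu = raw$dmu, period = raw$period,
                    stringsAsFactors = FALSE)
  for (cl in setdiff(names(raw), c("dmu", "period")))
    out[[cl]] <- .parse_numeric(raw[[cl]], cl, seq_len(nrow(raw)))
  if (anyNA(out[-(1:2)]))
    stop("missing covariate values")
  if (!is.null(panel)) {
    ok <- paste(out$dmu, out$period) %in%
      paste(rep(panel$dmu_ids, times = length(panel$periods)),
            rep(panel$periods, each = length(panel$dmu_ids)))
    if (!all(ok))
      stop("covariate keys not present in panel: ",
           paste(paste(out$dmu, out$period)[!ok][1:min(3, sum(!ok))],
                 collapse = "; "))
  }
  out
}
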