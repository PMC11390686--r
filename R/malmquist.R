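# Adjacent-period Malmquist productivity index and its decomposition.
#
# Core distances are radial, output-oriented, CRS (the DEAP convention);
# PECH uses within-period VRS distances only and SECH falls out as
# EFFCH / PECH, so cross-period VRS solves — the infeasibility-prone ones —
# are never needed.

#' Farrell distance of a data point against a period's frontier
#'
#' Radial efficiency of the (x, y) bundle of \code{point_dmu} taken from
#' the cross-section \code{point_data}, measured against the frontier
#' built from all DMUs of \code{tech} (the evaluated unit is not excluded
#' — the standard Malmquist convention). Output orientation (the default)
#' returns \eqn{D = 1/\phi} where \eqn{\phi} is the maximal feasible
#' output expansion. Within its own technology period a CRS distance lies
#' in (0, 1]; cross-period distances may exceed 1.
#'
#' @param tech \code{\link{cross_section}} defining the technology.
#' @param point_dmu DMU label, looked up in \code{point_data}.
#' @param point_data \code{\link{cross_section}} the evaluated bundle is
#'   taken from (defaults to \code{tech}).
#' @param rts \code{"crs"} or \code{"vrs"}.
#' @param orientation \code{"output"} (default) or \code{"input"}.
#'
#' @return list with \code{value} (the distance D), \code{tech_period},
#'   \code{data_period}, \code{dmu}, \code{rts}, \code{orientation},
#'   \code{status}.
#' @export
dea_distance <- function(tech, point_dmu, point_data = tech,
                         rts = c("crs", "vrs"),
                         orientation = c("output", "input")) {
  stopifnot(inherits(tech, "cross_section"),
            inherits(point_data, "cross_section"))
  rts <- match.arg(rts); orientation <- match.arg(orientation)
  k <- .cs_index(point_data, point_dmu)
  X <- t(tech$X); Y <- t(tech$Y)
  m <- nrow(X); q <- nrow(Y); n <- ncol(X)
  xk <- point_data$X[k, ]; yk <- point_data$Y[k, ]
  vrs <- rts == "vrs"
  eqA <- if (vrs) matrix(c(0, rep(1, n)), 1) else NULL
  eqb <- if (vrs) 1 else NULL
  out <- list(tech_period = tech$period, data_period = point_data$period,
              dmu = as.character(point_dmu), rts = rts,
              orientation = orientation)
  if (orientation == "output") {
    sol <- solve_lp(c(1, rep(0, n)),
                    A_le = cbind(0, X), b_le = xk,
                    A_ge = cbind(-yk, Y), b_ge = rep(0, q),
                    A_eq = eqA, b_eq = eqb, maximize = TRUE)
    out$value <- if (sol$status == "optimal") 1 / sol$value else NA_real_
  } else {
    sol <- solve_lp(c(1, rep(0, n)),
                    A_le = cbind(-xk, X), b_le = rep(0, m),
                    A_ge = cbind(0, Y), b_ge = yk,
                    A_eq = eqA, b_eq = eqb, maximize = FALSE)
    out$value <- if (sol$status == "optimal") sol$value else NA_real_
  }
  out$status <- sol$status
  out
}

#' Malmquist index for one DMU over one adjacent period pair
#'
#' Computes the total factor productivity change between periods t and
#' t+1 and its full decomposition
#' \deqn{TFPCH = EFFCH \times TECHCH = PECH \times SECH \times TECHCH}
#' from four CRS distances (within- and cross-period) and two
#' within-period VRS distances:
#' \itemize{
#'   \item \code{effch} \eqn{= D^{t+1}(t+1) / D^t(t)} (CRS catch-up)
#'   \item \code{techch} \eqn{= \sqrt{\frac{D^t(t+1)}{D^{t+1}(t+1)}
#'     \cdot \frac{D^t(t)}{D^{t+1}(t)}}} (frontier shift)
#'   \item \code{pech} \eqn{= D^{t+1}_{vrs}(t+1) / D^t_{vrs}(t)}
#'   \item \code{sech} \eqn{= effch / pech}
#'   \item \code{tfpch} \eqn{= effch \times techch}
#' }
#'
#' @param panel a \code{\link{panel_dataset}}.
#' @param dmu DMU label.
#' @param t,t1 adjacent period labels, \code{t1} immediately after
#'   \code{t} in \code{panel$periods}.
#' @param orientation passed to \code{\link{dea_distance}}.
#'
#' @return list of class \code{malmquist_result} with the five indices,
#'   the six underlying distances, and \code{status} ("ok" or "failed").
#' @export
malmquist_pair <- function(panel, dmu, t, t1, orientation = "output") {
  stopifnot(inherits(panel, "panel_dataset"))
  t <- as.character(t); t1 <- as.character(t1)
  it <- match(t, panel$periods); it1 <- match(t1, panel$periods)
  if (is.na(it) || is.na(it1) || it1 != it + 1L)
    stop("periods must be adjacent in the panel: ", t, ", ", t1)
  cs_t <- cross_section(panel, t)
  cs_t1 <- cross_section(panel, t1)
  d <- list(
    crs_t_t   = dea_distance(cs_t,  dmu, cs_t,  "crs", orientation),
    crs_t_t1  = dea_distance(cs_t,  dmu, cs_t1, "crs", orientation),
    crs_t1_t  = dea_distance(cs_t1, dmu, cs_t,  "crs", orientation),
    crs_t1_t1 = dea_distance(cs_t1, dmu, cs_t1, "crs", orientation),
    vrs_t_t   = dea_distance(cs_t,  dmu, cs_t,  "vrs", orientation),
    vrs_t1_t1 = dea_distance(cs_t1, dmu, cs_t1, "vrs", orientation))
  vals <- vapply(d, function(z) z$value, numeric(1))
  res <- list(dmu = as.character(dmu), t = t, t1 = t1,
              distances = vals, status = "ok",
              effch = NA_real_, techch = NA_real_, pech = NA_real_,
              sech = NA_real_, tfpch = NA_real_)
  if (anyNA(vals) || any(vals <= 0)) {
    res$status <- "failed"
    class(res) <- "malmquist_result"
    return(res)
  }
  res$effch <- vals["crs_t1_t1"] / vals["crs_t_t"]
  res$techch <- sqrt((vals["crs_t_t1"] / vals["crs_t1_t1"]) *
                     (vals["crs_t_t"] / vals["crs_t1_t"]))
  res$tfpch <- res$effch * res$techch
  res$pech <- vals["vrs_t1_t1"] / vals["vrs_t_t"]
  res$sech <- res$effch / res$pech
  res <- lapply(res, unname)
  res$distances <- vals
  class(res) <- "malmquist_result"
  res
}

#' @export
print.malmquist_result <- function(x, ...) {
  cat(sprintf("malmquist %s %s-%s: tfpch %.4f = effch %.4f x techch %.4f (pech %.4f, sech %.4f) [%s]\n",
              x$dmu, x$t, x$t1, x$tfpch, x$effch, x$techch, x$pech, x$sech,
              x$status))
  invisible(x)
}

#' Malmquist indices for every DMU over every adjacent period pair
#'
#' @param panel a \code{\link{panel_dataset}} with at least two periods.
#' @param orientation passed to \code{\link{dea_distance}}.
#'
#' @return data frame with columns \code{dmu}, \code{t}, \code{t1},
#'   \code{pair} ("t-t1"), \code{effch}, \code{techch}, \code{pech},
#'   \code{sech}, \code{tfpch}, \code{status}; attribute
#'   \code{"results"} keeps the full \code{malmquist_result} objects.
#' @export
malmquist_table <- function(panel, orientation = "output") {
  stopifnot(inherits(panel, "panel_dataset"))
  Tn <- length(panel$periods)
  if (Tn < 2L) stop("need at least two periods")
  grid <- expand.grid(dmu = panel$dmu_ids, i = seq_len(Tn - 1L),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  results <- lapply(seq_len(nrow(grid)), function(r)
    malmquist_pair(panel, grid$dmu[r], panel$periods[grid$i[r]],
                   panel$periods[grid$i[r] + 1L], orientation))
  tab <- data.frame(
    dmu = grid$dmu,
    t = panel$periods[grid$i],
    t1 = panel$periods[grid$i + 1L],
    pair = paste(panel$periods[grid$i], panel$periods[grid$i + 1L], sep = "-"),
    effch = vapply(results, `[[`, numeric(1), "effch"),
    techch = vapply(results, `[[`, numeric(1), "techch"),
    pech = vapply(results, `[[`, numeric(1), "pech"),
    sech = vapply(results, `[[`, numeric(1), "sech"),
    tfpch = vapply(results, `[[`, numeric(1), "tfpch"),
    status = vapply(results, `[[`, character(1), "status"),
    stringsAsFactors = FALSE)
  attr(tab, "results") <- results
  tab
}

.index_cols <- c("effch", "techch", "pech", "sech", "tfpch")

#' Aggregate Malmquist results
#'
#' Averages the five indices over period pairs (\code{by = "dmu"},
#' one row per DMU — the usual per-unit table) or over DMUs
#' (\code{by = "pair"}, one row per adjacent pair — the usual time
#' profile). Arithmetic averaging is the default, matching the common
#' reporting convention of applied efficiency studies; the geometric mean
#' (the index-theoretically consistent choice) is available via
#' \code{method}. Failed rows are dropped and counted in the
#' \code{"dropped"} attribute.
#'
#' @param results data frame from \code{\link{malmquist_table}}.
#' @param by \code{"dmu"} or \code{"pair"}.
#' @param method \code{"arithmetic"} or \code{"geometric"}.
#'
#' @return data frame of group means with a trailing \code{"Mean"} row
#'   (cross-group mean of each index column).
#' @export
aggregate_malmquist <- function(results, by = c("dmu", "pair"),
                                method = c("arithmetic", "geometric")) {
  by <- match.arg(by); method <- match.arg(method)
  stopifnot(all(c(.index_cols, "status") %in% names(results)))
  keep <- results$status == "ok"
  dropped <- sum(!keep)
  results <- results[keep, , drop = FALSE]
  if (!nrow(results)) stop("no usable Malmquist results")
  avg <- if (method == "arithmetic") mean else function(v) exp(mean(log(v)))
  key <- results[[by]]
  groups <- unique(key)
  out <- data.frame(group = groups, stringsAsFactors = FALSE)
  names(out) <- by
  for (cl in .index_cols)
    out[[cl]] <- vapply(groups, function(g) avg(results[[cl]][key == g]),
                        numeric(1))
  total <- stats::setNames(data.frame("Mean", stringsAsFactors = FALSE), by)
  for (cl in .index_cols) total[[cl]] <- avg(out[[cl]])
  out <- rbind(out, total)
  attr(out, "dropped") <- dropped
  attr(out, "method") <- method
  out
}

#' Summarise a per-unit index table the way applied studies print it
#'
#' Takes a table with one row per DMU and the five index columns
#' (\code{effch}, \code{techch}, \code{pech}, \code{sech}, \code{tfpch}),
#' appends a trailing \code{row_mean} column (mean of the five indices in
#' that row) and a final \code{Mean} row (column means). Used both for the
#' package's own Malmquist output and for re-aggregating published
#' per-unit index tables.
#'
#' @param index_table data frame; first column identifies the unit,
#'   remaining index columns are matched case-insensitively.
#' @param method \code{"arithmetic"} (default) or \code{"geometric"}.
#' @return data frame with the added column and row.
#' @export
index_summary <- function(index_table, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  avg <- if (method == "arithmetic") function(v) mean(v) else
    function(v) exp(mean(log(v)))
  nm <- tolower(names(index_table))
  idx <- match(.index_cols, nm)
  if (anyNA(idx))
    stop("index table must contain columns: ",
         paste(.index_cols, collapse = ", "))
  vals <- as.matrix(index_table[, idx])
  out <- index_table
  out$row_mean <- apply(vals, 1, avg)
  total <- out[1, , drop = FALSE]
  total[1, 1] <- "Mean"
  for (j in seq_along(idx)) total[[idx[j]]] <- avg(vals[, j])
  total$row_mean <- avg(out$row_mean[seq_len(nrow(vals))])
  rbind(out, total)
}
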