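# Cross-sectional DEA solvers.
#
# All models are solved in envelopment form via solve_lp(); the fractional
# SBM and super-SBM programs are linearised with the Charnes-Cooper
# transformation (scale variable t with t * denominator = 1, all lambdas
# and slacks multiplied by t, back-transformed before reporting).

#' DEA model configuration
#'
#' @param model one of \code{"ccr"}, \code{"bcc"}, \code{"sbm"},
#'   \code{"sesbm"}. CCR implies constant returns to scale, BCC variable;
#'   SBM/SE-SBM take \code{rts} as given.
#' @param rts returns to scale, \code{"crs"} or \code{"vrs"}.
#' @param orientation \code{"input"}, \code{"output"}, or \code{"non"}
#'   (non-oriented; only meaningful for SBM-family models, which default
#'   to it).
#' @param tol LP solver pivot tolerance.
#' @param tau efficiency classification threshold: a DMU is called
#'   efficient when its score is at least \code{1 - tau}.
#'
#' @return a \code{dea_config} list.
#' @export
dea_config <- function(model = c("sesbm", "sbm", "ccr", "bcc"),
                       rts = c("crs", "vrs"),
                       orientation = NULL,
                       tol = 1e-9, tau = 1e-6) {
  model <- match.arg(model)
  rts <- match.arg(rts)
  if (model == "ccr") rts <- "crs"
  if (model == "bcc") rts <- "vrs"
  if (is.null(orientation))
    orientation <- if (model %in% c("sbm", "sesbm")) "non" else "input"
  orientation <- match.arg(orientation, c("input", "output", "non"))
  if (model %in% c("ccr", "bcc") && orientation == "non")
    stop("radial models are input- or output-oriented")
  structure(list(model = model, rts = rts, orientation = orientation,
                 tol = tol, tau = tau), class = "dea_config")
}

.dea_result <- function(dmu, cfg, score = NA_real_, lambda = NULL,
                        slack_in = NULL, slack_out = NULL,
                        projection_x = NULL, projection_y = NULL,
                        status = "optimal") {
  structure(list(dmu = dmu, model = cfg$model, rts = cfg$rts,
                 orientation = cfg$orientation, score = score,
                 lambda = lambda, slack_in = slack_in, slack_out = slack_out,
                 projection_x = projection_x, projection_y = projection_y,
                 status = status,
                 efficient = !is.na(score) && score >= 1 - cfg$tau),
            class = "dea_result")
}

#' @export
print.dea_result <- function(x, ...) {
  cat(sprintf("dea_result [%s/%s/%s] DMU %s: score %s (%s)%s\n",
              toupper(x$model), toupper(x$rts), x$orientation, x$dmu,
              if (is.na(x$score)) "NA" else formatC(x$score, digits = 4,
                                                   format = "f"),
              x$status, if (isTRUE(x$efficient)) ", efficient" else ""))
  invisible(x)
}

.cs_index <- function(cs, dmu) {
  k <- match(as.character(dmu), cs$dmu_ids)
  if (is.na(k)) stop("DMU not in cross-section: ", dmu)
  k
}

#' Radial (CCR / BCC) efficiency of one DMU
#'
#' Solves the envelopment-form LP. Input orientation: minimise the radial
#' contraction theta with X'lambda <= theta x_k, Y'lambda >= y_k (plus
#' sum(lambda) = 1 under VRS); output orientation: maximise the expansion
#' phi, with the reported score 1/phi. A second-phase solve maximises the
#' (normalised) slack sum at the optimal radial factor so the reported
#' slacks identify the projection max-slack style; remaining ties among
#' alternate optima are not resolved further.
#'
#' @param cs a \code{\link{cross_section}}.
#' @param dmu DMU label.
#' @param cfg a \code{\link{dea_config}} with \code{model} "ccr" or "bcc".
#'
#' @return a \code{dea_result}.
#' @export
radial_efficiency <- function(cs, dmu, cfg = dea_config("ccr")) {
  stopifnot(inherits(cs, "cross_section"),
            cfg$model %in% c("ccr", "bcc"))
  k <- .cs_index(cs, dmu)
  X <- t(cs$X); Y <- t(cs$Y)                # m x n, q x n
  m <- nrow(X); q <- nrow(Y); n <- ncol(X)
  xk <- X[, k]; yk <- Y[, k]
  vrs <- cfg$rts == "vrs"
  eqA <- if (vrs) matrix(c(0, rep(1, n)), 1) else NULL
  eqb <- if (vrs) 1 else NULL

  if (cfg$orientation == "input") {
    # vars: theta, lambda
    sol <- solve_lp(c(1, rep(0, n)),
                    A_le = cbind(-xk, X), b_le = rep(0, m),
                    A_ge = cbind(0, Y), b_ge = yk,
                    A_eq = eqA, b_eq = eqb,
                    maximize = FALSE, eps = cfg$tol)
    if (sol$status != "optimal")
      return(.dea_result(dmu, cfg, status = sol$status))
    theta <- sol$value
    score <- theta
    tgt_x <- theta * xk; tgt_y <- yk
  } else {
    sol <- solve_lp(c(1, rep(0, n)),
                    A_le = cbind(0, X), b_le = xk,
                    A_ge = cbind(-yk, Y), b_ge = rep(0, q),
                    A_eq = eqA, b_eq = eqb,
                    maximize = TRUE, eps = cfg$tol)
    if (sol$status != "optimal")
      return(.dea_result(dmu, cfg, status = sol$status))
    phi <- sol$value
    score <- 1 / phi
    tgt_x <- xk; tgt_y <- phi * yk
  }

  # phase 2: max normalised slacks with the radial factor fixed
  # vars: lambda (n), s- (m), s+ (q)
  obj <- c(rep(0, n), 1 / xk, 1 / yk)
  A_eq2 <- rbind(cbind(X, diag(m), matrix(0, m, q)),
                 cbind(Y, matrix(0, q, m), -diag(q)))
  b_eq2 <- c(tgt_x, tgt_y)
  if (vrs) {
    A_eq2 <- rbind(A_eq2, c(rep(1, n), rep(0, m + q)))
    b_eq2 <- c(b_eq2, 1)
  }
  p2 <- solve_lp(obj, A_eq = A_eq2, b_eq = b_eq2, maximize = TRUE,
                 eps = cfg$tol)
  if (p2$status == "optimal") {
    lambda <- p2$x[seq_len(n)]
    s_in <- p2$x[n + seq_len(m)]
    s_out <- p2$x[n + m + seq_len(q)]
  } else {                                   # degenerate phase 2; fall back
    lambda <- rep(NA_real_, n); s_in <- rep(NA_real_, m)
    s_out <- rep(NA_real_, q)
  }
  .dea_result(dmu, cfg, score = score,
              lambda = stats::setNames(lambda, cs$dmu_ids),
              slack_in = stats::setNames(s_in, colnames(cs$X)),
              slack_out = stats::setNames(s_out, colnames(cs$Y)),
              projection_x = stats::setNames(tgt_x - s_in, colnames(cs$X)),
              projection_y = stats::setNames(tgt_y + s_out, colnames(cs$Y)))
}

#' Slack-based measure (SBM) efficiency of one DMU
#'
#' Non-oriented SBM (the default) minimises
#' \deqn{\rho = \frac{1 - \frac1m \sum_i s^-_i / x_{ik}}
#'                  {1 + \frac1q \sum_r s^+_r / y_{rk}}}
#' subject to \eqn{x_k = X\lambda + s^-}, \eqn{y_k = Y\lambda - s^+},
#' \eqn{\lambda, s \ge 0} (and \eqn{\sum\lambda = 1} under VRS), linearised
#' by the Charnes-Cooper transformation. \eqn{\rho \in (0, 1]} with
#' \eqn{\rho = 1} iff all slacks vanish. Oriented variants drop the output
#' (input) slack term from the objective.
#'
#' @inheritParams radial_efficiency
#' @return a \code{dea_result}.
#' @export
sbm_efficiency <- function(cs, dmu, cfg = dea_config("sbm")) {
  stopifnot(inherits(cs, "cross_section"), cfg$model %in% c("sbm", "sesbm"))
  k <- .cs_index(cs, dmu)
  X <- t(cs$X); Y <- t(cs$Y)
  m <- nrow(X); q <- nrow(Y); n <- ncol(X)
  xk <- X[, k]; yk <- Y[, k]
  vrs <- cfg$rts == "vrs"

  # vars: t, Lambda (n), S- (m), S+ (q)   [capitalised = t-scaled]
  nv <- 1 + n + m + q
  i_t <- 1; i_l <- 1 + seq_len(n); i_sm <- 1 + n + seq_len(m)
  i_sp <- 1 + n + m + seq_len(q)
  balance <- rbind(
    cbind(xk, -X, -diag(m), matrix(0, m, q)),     # t x_k - X L - S- = 0
    cbind(yk, -Y, matrix(0, q, m), diag(q)))      # t y_k - Y L + S+ = 0
  b_bal <- rep(0, m + q)
  A_eq <- balance; b_eq <- b_bal
  if (vrs) {
    r <- numeric(nv); r[i_t] <- -1; r[i_l] <- 1   # sum(L) = t
    A_eq <- rbind(A_eq, r); b_eq <- c(b_eq, 0)
  }
  obj <- numeric(nv)
  if (cfg$orientation == "output") {
    # max 1 + (1/q) sum S+/y  with t = 1 fixed via normalisation row
    norm <- numeric(nv); norm[i_t] <- 1
    obj[i_sp] <- 1 / (q * yk)
    sol <- solve_lp(obj, A_eq = rbind(A_eq, norm), b_eq = c(b_eq, 1),
                    maximize = TRUE, eps = cfg$tol)
    if (sol$status != "optimal") return(.dea_result(dmu, cfg, status = sol$status))
    t_val <- 1
    score <- 1 / (1 + sol$value)
  } else {
    norm <- numeric(nv)
    if (cfg$orientation == "input") {
      norm[i_t] <- 1                               # t = 1 (no denominator)
    } else {
      norm[i_t] <- 1; norm[i_sp] <- 1 / (q * yk)   # t + (1/q) sum S+/y = 1
    }
    obj[i_t] <- 1; obj[i_sm] <- -1 / (m * xk)      # t - (1/m) sum S-/x
    sol <- solve_lp(obj, A_eq = rbind(A_eq, norm), b_eq = c(b_eq, 1),
                    maximize = FALSE, eps = cfg$tol)
    if (sol$status != "optimal") return(.dea_result(dmu, cfg, status = sol$status))
    t_val <- sol$x[i_t]
    score <- sol$value
  }
  if (t_val <= cfg$tol)
    return(.dea_result(dmu, cfg, status = "infeasible"))
  lambda <- sol$x[i_l] / t_val
  s_in <- sol$x[i_sm] / t_val
  s_out <- sol$x[i_sp] / t_val
  .dea_result(dmu, cfg, score = score,
              lambda = stats::setNames(lambda, cs$dmu_ids),
              slack_in = stats::setNames(s_in, colnames(cs$X)),
              slack_out = stats::setNames(s_out, colnames(cs$Y)),
              projection_x = stats::setNames(xk - s_in, colnames(cs$X)),
              projection_y = stats::setNames(yk + s_out, colnames(cs$Y)))
}

#' Super-efficiency SBM of one DMU
#'
#' For an SBM-inefficient DMU (SBM score below \code{1 - tau}) the plain
#' SBM result is returned unchanged — the usual reporting convention, so a
#' full cross-section mixes super-efficiency scores above 1 with SBM scores
#' below 1. For an SBM-efficient DMU the unit is removed from the reference
#' set and the program
#' \deqn{\min \rho = \frac{\frac1m \sum_i \bar x_i / x_{ik}}
#'                        {\frac1q \sum_r \bar y_r / y_{rk}}}
#' subject to \eqn{\bar x \ge \sum_{j \ne k} \lambda_j x_j},
#' \eqn{\bar y \le \sum_{j \ne k} \lambda_j y_j}, \eqn{\bar x \ge x_k},
#' \eqn{0 < \bar y \le y_k}, \eqn{\lambda \ge 0} (plus
#' \eqn{\sum_{j \ne k} \lambda_j = 1} under VRS) is solved after
#' Charnes-Cooper linearisation; its optimum is at least 1.
#'
#' Under VRS the program can be infeasible (no convex reference excluding
#' the unit); that is surfaced as \code{status = "infeasible"}, never
#' replaced by a large number. A cross-section with a single DMU scores 1
#' with a warning.
#'
#' @inheritParams radial_efficiency
#' @return a \code{dea_result}.
#' @export
super_sbm_efficiency <- function(cs, dmu, cfg = dea_config("sesbm")) {
  stopifnot(inherits(cs, "cross_section"))
  k <- .cs_index(cs, dmu)
  n <- nrow(cs$X)
  if (n == 1L) {
    warning("single-DMU cross-section: super-efficiency defined as 1")
    res <- .dea_result(dmu, cfg, score = 1,
                       lambda = stats::setNames(0, cs$dmu_ids),
                       slack_in = stats::setNames(rep(0, ncol(cs$X)), colnames(cs$X)),
                       slack_out = stats::setNames(rep(0, ncol(cs$Y)), colnames(cs$Y)),
                       projection_x = cs$X[1, ], projection_y = cs$Y[1, ])
    return(res)
  }
  base <- sbm_efficiency(cs, dmu, cfg)
  if (base$status != "optimal" || base$score < 1 - cfg$tau)
    return(base)

  X <- t(cs$X); Y <- t(cs$Y)
  m <- nrow(X); q <- nrow(Y)
  xk <- X[, k]; yk <- Y[, k]
  Xr <- X[, -k, drop = FALSE]; Yr <- Y[, -k, drop = FALSE]
  nr <- n - 1L
  vrs <- cfg$rts == "vrs"

  # vars: t, Lambda (nr), Xbar~ (m), Ybar~ (q)  [all t-scaled]
  nv <- 1 + nr + m + q
  i_t <- 1; i_l <- 1 + seq_len(nr); i_x <- 1 + nr + seq_len(m)
  i_y <- 1 + nr + m + seq_len(q)
  zl <- function(cols, vals) { v <- numeric(nv); v[cols] <- vals; v }

  A_ge <- rbind(
    t(vapply(seq_len(m), function(i)                    # Xb_i - sum L x_ij >= 0
      zl(c(i_x[i], i_l), c(1, -Xr[i, ])), numeric(nv))),
    t(vapply(seq_len(m), function(i)                    # Xb_i - t x_ik >= 0
      zl(c(i_x[i], i_t), c(1, -xk[i])), numeric(nv))))
  b_ge <- rep(0, 2 * m)
  A_le <- rbind(
    t(vapply(seq_len(q), function(r)                    # Yb_r - sum L y_rj <= 0
      zl(c(i_y[r], i_l), c(1, -Yr[r, ])), numeric(nv))),
    t(vapply(seq_len(q), function(r)                    # Yb_r - t y_rk <= 0
      zl(c(i_y[r], i_t), c(1, -yk[r])), numeric(nv))))
  b_le <- rep(0, 2 * q)
  A_eq <- matrix(zl(i_y, 1 / (q * yk)), 1)              # (1/q) sum Yb/y = 1
  b_eq <- 1
  if (vrs) {
    A_eq <- rbind(A_eq, zl(c(i_t, i_l), c(-1, rep(1, nr))))
    b_eq <- c(b_eq, 0)
  }
  obj <- zl(i_x, 1 / (m * xk))
  sol <- solve_lp(obj, A_le = A_le, b_le = b_le, A_ge = A_ge, b_ge = b_ge,
                  A_eq = A_eq, b_eq = b_eq, maximize = FALSE, eps = cfg$tol)
  if (sol$status != "optimal")
    return(.dea_result(dmu, cfg, status = sol$status))
  t_val <- sol$x[i_t]
  if (t_val <= cfg$tol)
    return(.dea_result(dmu, cfg, status = "infeasible"))
  lambda <- numeric(n); lambda[-k] <- sol$x[i_l] / t_val
  proj_x <- sol$x[i_x] / t_val
  proj_y <- sol$x[i_y] / t_val
  .dea_result(dmu, cfg, score = sol$value,
              lambda = stats::setNames(lambda, cs$dmu_ids),
              slack_in = stats::setNames(pmax(proj_x - xk, 0), colnames(cs$X)),
              slack_out = stats::setNames(pmax(yk - proj_y, 0), colnames(cs$Y)),
              projection_x = stats::setNames(proj_x, colnames(cs$X)),
              projection_y = stats::setNames(proj_y, colnames(cs$Y)))
}

#' Multiplier-form radial score (independent check)
#'
#' Solves the dual (multiplier) LP of the radial envelopment program:
#' input orientation maximises \eqn{u'y_k} subject to \eqn{v'x_k = 1} and
#' \eqn{u'y_j - v'x_j \le 0} for every DMU (BCC adds a free intercept). By
#' LP duality its optimum equals the envelopment score, which makes it a
#' useful independent verification route.
#'
#' @inheritParams radial_efficiency
#' @return the optimal score (numeric scalar), or \code{NA} with a warning
#'   if the solve fails.
#' @export
multiplier_oracle <- function(cs, dmu, cfg = dea_config("ccr")) {
  stopifnot(inherits(cs, "cross_section"), cfg$model %in% c("ccr", "bcc"))
  k <- .cs_index(cs, dmu)
  X <- t(cs$X); Y <- t(cs$Y)
  m <- nrow(X); q <- nrow(Y); n <- ncol(X)
  xk <- X[, k]; yk <- Y[, k]
  vrs <- cfg$rts == "vrs"
  # vars: v (m), u (q), [w+ , w- free intercept under VRS]
  nv <- m + q + if (vrs) 2L else 0L
  w <- if (vrs) c(1, -1) else numeric(0)
  if (cfg$orientation == "input") {
    obj <- c(rep(0, m), yk, w)
    A_le <- cbind(-t(X), t(Y), if (vrs) matrix(w, n, 2, byrow = TRUE))
    sol <- solve_lp(obj,
                    A_le = A_le, b_le = rep(0, n),
                    A_eq = matrix(c(xk, rep(0, q), rep(0, length(w))), 1),
                    b_eq = 1, maximize = TRUE, eps = cfg$tol)
  } else {
    # min v'x_k (+ intercept) s.t. u'y_k = 1, v'x_j - u'y_j (+w) >= 0
    obj <- c(xk, rep(0, q), w)
    A_ge <- cbind(t(X), -t(Y), if (vrs) matrix(w, n, 2, byrow = TRUE))
    sol <- solve_lp(obj,
                    A_ge = A_ge, b_ge = rep(0, n),
                    A_eq = matrix(c(rep(0, m), yk, rep(0, length(w))), 1),
                    b_eq = 1, maximize = FALSE, eps = cfg$tol)
    if (sol$status == "optimal") sol$value <- 1 / sol$value
  }
  if (sol$status != "optimal") {
    warning("multiplier LP not optimal: ", sol$status)
    return(NA_real_)
  }
  sol$value
}

#' Score every DMU of a cross-section
#'
#' @param cs a \code{\link{cross_section}}.
#' @param cfg a \code{\link{dea_config}}; dispatches to the radial, SBM or
#'   super-SBM solver.
#'
#' @return object of class \code{dea_scores}: list with \code{results}
#'   (one \code{dea_result} per DMU, stored order), \code{table} (data
#'   frame: dmu, period, model, rts, orientation, score, efficient,
#'   status), \code{mean_score} and \code{n_efficient} (over DMUs with an
#'   optimal solve).
#' @export
score_cross_section <- function(cs, cfg = dea_config("sesbm")) {
  stopifnot(inherits(cs, "cross_section"))
  fn <- switch(cfg$model,
               ccr = radial_efficiency, bcc = radial_efficiency,
               sbm = sbm_efficiency, sesbm = super_sbm_efficiency)
  results <- lapply(cs$dmu_ids, function(d) fn(cs, d, cfg))
  scores <- vapply(results, function(r) r$score, numeric(1))
  tab <- data.frame(dmu = cs$dmu_ids, period = cs$period,
                    model = cfg$model, rts = cfg$rts,
                    orientation = cfg$orientation,
                    score = scores,
                    efficient = vapply(results, function(r) isTRUE(r$efficient),
                                       logical(1)),
                    status = vapply(results, function(r) r$status, character(1)),
                    stringsAsFactors = FALSE)
  structure(list(results = results, table = tab,
                 mean_score = mean(scores, na.rm = TRUE),
                 n_efficient = sum(tab$efficient, na.rm = TRUE)),
            class = "dea_scores")
}

#' @export
print.dea_scores <- function(x, ...) {
  cat(sprintf("dea_scores (%s): %d DMUs, mean %.3f, %d efficient\n",
              toupper(x$table$model[1]), nrow(x$table),
              x$mean_score, x$n_efficient))
  print(utils::head(x$table[, c("dmu", "score", "efficient", "status")], 10L))
  invisible(x)
}
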