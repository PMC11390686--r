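# Two-limit censored-normal (Tobit) regression by maximum likelihood.
#
# Parameterised as (beta, log sigma) so sigma stays positive; optimised
# with BFGS from the least-squares start using the analytic gradient.
# Standard errors come from the inverse observed information at the
# optimum, with the sigma row delta-transformed back from the log scale.

.tobit_loglik_parts <- function(par, y, X, L, U) {
  k <- ncol(X)
  beta <- par[seq_len(k)]
  sigma <- exp(par[k + 1L])
  xb <- drop(X %*% beta)
  left <- if (is.finite(L)) y <= L else rep(FALSE, length(y))
  right <- if (is.finite(U)) y >= U else rep(FALSE, length(y))
  mid <- !left & !right
  ll <- numeric(length(y))
  if (any(mid)) {
    z <- (y[mid] - xb[mid]) / sigma
    ll[mid] <- stats::dnorm(z, log = TRUE) - log(sigma)
  }
  if (any(left)) {
    zl <- (L - xb[left]) / sigma
    ll[left] <- stats::pnorm(zl, log.p = TRUE)
  }
  if (any(right)) {
    zu <- (U - xb[right]) / sigma
    ll[right] <- stats::pnorm(zu, lower.tail = FALSE, log.p = TRUE)
  }
  list(ll = ll, beta = beta, sigma = sigma, xb = xb,
       left = left, right = right, mid = mid)
}

.tobit_negll <- function(par, y, X, L, U) {
  -sum(.tobit_loglik_parts(par, y, X, L, U)$ll)
}

.tobit_neggrad <- function(par, y, X, L, U) {
  -colSums(.tobit_scores(par, y, X, L, U))
}

#' Fit a two-limit Tobit (censored-normal) regression
#'
#' Maximises the censored-normal log-likelihood
#' \deqn{\sum_{L<y<U} \log\frac{\phi((y - x\beta)/\sigma)}{\sigma}
#'   + \sum_{y \le L} \log\Phi\!\Big(\frac{L - x\beta}{\sigma}\Big)
#'   + \sum_{y \ge U} \log\Big[1 - \Phi\!\Big(\frac{U - x\beta}{\sigma}\Big)\Big]}
#' over \eqn{(\beta, \log\sigma)} by BFGS with analytic gradient, starting
#' from the least-squares estimates. Observations at (or beyond) a finite
#' bound count as censored. Intended for second-stage efficiency
#' regressions, where DEA scores are bounded below and the usual choice is
#' \code{lower = 0}, \code{upper = Inf} (super-efficiency scores exceed 1,
#' so censoring at 1 would discard real variation).
#'
#' @param y numeric response within \code{[lower, upper]}.
#' @param X numeric covariate matrix or data frame (n x k), without
#'   intercept column.
#' @param lower,upper censoring bounds (defaults 0, +Inf); at least the
#'   set of uncensored observations must be non-empty.
#' @param intercept include an intercept (default TRUE).
#' @param cluster optional factor for cluster-robust standard errors
#'   (sandwich with cluster-summed scores); default NULL = conventional
#'   observed-information SEs.
#' @param max_iter,gr_tol optimiser iteration cap and gradient-norm
#'   convergence tolerance.
#'
#' @return object of class \code{tobit_fit}: list with \code{coefficients}
#'   (named beta), \code{sigma}, \code{se} (incl. \code{sigma} row),
#'   \code{z}, \code{p_value}, \code{loglik}, \code{loglik_start},
#'   \code{n_left}, \code{n_uncensored}, \code{n_right}, \code{converged},
#'   \code{lower}, \code{upper}, \code{vcov}.
#' @export
fit_tobit <- function(y, X, lower = 0, upper = Inf, intercept = TRUE,
                      cluster = NULL, max_iter = 500L, gr_tol = 1e-8) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  n <- nrow(X); k <- ncol(X)
  if (k < 1L) stop("need at least one regressor or an intercept")
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (!lower < upper) stop("lower bound must be below upper bound")
  if (any(y < lower - 1e-12) || any(y > upper + 1e-12))
    stop("response values outside the censoring bounds")
  if (n <= k + 1L) stop("need n > number of regressors + 1")
  qr_x <- qr(X)
  if (qr_x$rank < k) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):k]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  left <- if (is.finite(lower)) y <= lower else rep(FALSE, n)
  right <- if (is.finite(upper)) y >= upper else rep(FALSE, n)
  if (!any(!left & !right))
    stop("all observations censored; model not identifiable")

  ols <- qr.coef(qr_x, y)
  res <- y - drop(X %*% ols)
  s0 <- max(sqrt(sum(res^2) / max(n - k, 1L)), 1e-6)
  par0 <- c(ols, log(s0))
  ll_start <- -.tobit_negll(par0, y, X, lower, upper)

  opt <- stats::optim(par0, .tobit_negll, .tobit_neggrad,
                      y = y, X = X, L = lower, U = upper,
                      method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  # Newton polish with the observed information to drive the gradient to
  # the requested tolerance (BFGS alone stalls a few orders above it)
  par <- opt$par; val <- opt$value
  for (it in 1:50) {
    g <- .tobit_neggrad(par, y, X, lower, upper)
    if (sqrt(sum(g^2)) < gr_tol * (1 + abs(val))) break
    H <- stats::optimHess(par, .tobit_negll, .tobit_neggrad,
                          y = y, X = X, L = lower, U = upper)
    step <- tryCatch(solve(H, g), error = function(e) g)
    ok <- FALSE
    for (h in 2^-(0:20)) {
      cand <- par - h * step
      cv <- .tobit_negll(cand, y, X, lower, upper)
      if (is.finite(cv) && cv <= val) { par <- cand; val <- cv; ok <- TRUE; break }
    }
    if (!ok) break
  }
  opt$par <- par; opt$value <- val
  gnorm <- sqrt(sum(.tobit_neggrad(opt$par, y, X, lower, upper)^2))
  converged <- opt$convergence == 0L && gnorm < gr_tol * (1 + abs(opt$value))

  beta <- stats::setNames(opt$par[seq_len(k)], colnames(X))
  sigma <- unname(exp(opt$par[k + 1L]))
  H <- stats::optimHess(opt$par, .tobit_negll, .tobit_neggrad,
                        y = y, X = X, L = lower, U = upper)
  V_ls <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k + 1L, k + 1L))
  if (!is.null(cluster)) {
    cluster <- as.factor(cluster)
    stopifnot(length(cluster) == n)
    # per-observation score of (beta, log sigma), summed within clusters
    sc <- .tobit_scores(opt$par, y, X, lower, upper)
    G <- rowsum(sc, cluster)
    meat <- crossprod(G)
    nc <- nlevels(droplevels(cluster))
    V_ls <- V_ls %*% (meat * nc / (nc - 1L)) %*% V_ls
  }
  # delta method: sigma row back from the log scale
  J <- diag(k + 1L); J[k + 1L, k + 1L] <- sigma
  V <- J %*% V_ls %*% J
  se <- sqrt(pmax(diag(V), 0))
  est <- c(beta, sigma = sigma)
  z <- est / se
  z[k + 1L] <- NA_real_                    # no H0: sigma = 0 test
  pv <- 2 * stats::pnorm(-abs(z))
  structure(list(coefficients = beta, sigma = sigma,
                 se = stats::setNames(se, names(est)),
                 z = stats::setNames(z, names(est)),
                 p_value = stats::setNames(pv, names(est)),
                 loglik = -opt$value, loglik_start = ll_start,
                 n_left = sum(left), n_uncensored = sum(!left & !right),
                 n_right = sum(right), n = n,
                 converged = converged, gradient_norm = gnorm,
                 lower = lower, upper = upper, vcov = V,
                 cluster = !is.null(cluster)),
            class = "tobit_fit")
}

.tobit_scores <- function(par, y, X, L, U) {
  p <- .tobit_loglik_parts(par, y, X, L, U)
  sigma <- p$sigma
  n <- length(y)
  w <- numeric(n); g_ls <- numeric(n)
  if (any(p$mid)) {
    z <- (y[p$mid] - p$xb[p$mid]) / sigma
    w[p$mid] <- z / sigma; g_ls[p$mid] <- z^2 - 1
  }
  if (any(p$left)) {
    zl <- (L - p$xb[p$left]) / sigma
    lam <- exp(stats::dnorm(zl, log = TRUE) - stats::pnorm(zl, log.p = TRUE))
    w[p$left] <- -lam / sigma; g_ls[p$left] <- -zl * lam
  }
  if (any(p$right)) {
    zu <- (U - p$xb[p$right]) / sigma
    lam <- exp(stats::dnorm(zu, log = TRUE) -
                 stats::pnorm(zu, lower.tail = FALSE, log.p = TRUE))
    w[p$right] <- lam / sigma; g_ls[p$right] <- zu * lam
  }
  cbind(X * w, log_sigma = g_ls)
}

#' @export
print.tobit_fit <- function(x, ...) {
  cat(sprintf("tobit_fit: n = %d (%d left-censored, %d uncensored, %d right-censored)\n",
              x$n, x$n_left, x$n_uncensored, x$n_right))
  cat(sprintf("  bounds [%g, %g], logLik %.3f, %s\n", x$lower, x$upper,
              x$loglik, if (x$converged) "converged" else "NOT CONVERGED"))
  print(tobit_report(x, check_convergence = FALSE))
  invisible(x)
}

#' Coefficient table for a Tobit fit
#'
#' One row per coefficient plus a trailing \code{sigma} row, with
#' asymptotic-normal z statistics, two-sided p values and significance
#' stars at the 0.05 (*) and 0.01 (**) levels. Estimation is pooled over
#' all rows (no panel random effects); pass \code{cluster} to
#' \code{\link{fit_tobit}} for cluster-robust standard errors.
#'
#' @param fit a \code{\link{fit_tobit}} result.
#' @param check_convergence refuse to summarise an unconverged fit
#'   (default TRUE).
#' @return data frame: term, estimate, se, z, p_value, stars.
#' @export
tobit_report <- function(fit, check_convergence = TRUE) {
  stopifnot(inherits(fit, "tobit_fit"))
  if (check_convergence && !fit$converged)
    stop("fit did not converge (gradient norm ", format(fit$gradient_norm),
         "); inspect the data or raise max_iter")
  est <- c(fit$coefficients, sigma = fit$sigma)
  stars <- ifelse(is.na(fit$p_value), "",
                  ifelse(fit$p_value < 0.01, "**",
                         ifelse(fit$p_value < 0.05, "*", "")))
  data.frame(term = names(est), estimate = unname(est),
             se = unname(fit$se), z = unname(fit$z),
             p_value = unname(fit$p_value), stars = unname(stars),
             stringsAsFactors = FALSE, row.names = NULL)
}
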