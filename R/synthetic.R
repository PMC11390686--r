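# Synthetic panel generators with known ground truth.
#
# Two kinds of fixture:
#   * Cobb-Douglas frontier panels where the true technology, its growth
#     rate, and every unit's inefficiency draw are recorded, so solver and
#     Malmquist output can be checked against generator truth.
#   * Luohu-calibrated panels whose per-period column totals exactly match
#     the published aggregates (CHC case) or a fixed multiple of them
#     (regional case, where district totals are not published).

.default_seed <- 20150401L   # fixed so bundled fixtures are byte-stable

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Specification for a Cobb-Douglas frontier panel
#'
#' Describes the data-generating process used by
#' \code{\link{generate_frontier_panel}}: inputs are log-normal, the
#' frontier output level is \eqn{A_0 (1+g)^{t-1} \prod_i x_i^{\alpha_i}}
#' (constant returns when the exponents sum to 1, the default), total
#' output is split over the q outputs by a per-DMU share vector, and
#' realised outputs are scaled by \eqn{e^{-u}} with half-normal
#' inefficiency \eqn{u \sim |N(0, \sigma_u)|}.
#'
#' @param n_dmus number of DMUs.
#' @param periods period labels (default \code{"2015".."2021"}).
#' @param m,q numbers of inputs and outputs.
#' @param alpha Cobb-Douglas input exponents (default equal shares
#'   summing to 1).
#' @param output_shares mean output share vector (default equal).
#' @param sigma_u half-normal inefficiency scale (>= 0).
#' @param growth technology growth rate g per period.
#' @param persistent_u logical: draw inefficiency once per DMU (TRUE,
#'   default) or redraw every period.
#' @param A0 frontier scale constant.
#' @param input_meanlog,input_sdlog log-normal input parameters.
#' @param share_concentration Dirichlet concentration for the per-DMU
#'   perturbation of \code{output_shares}; larger = more homogeneous.
#' @param seed RNG seed (integer).
#'
#' @return a \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_dmus = 20L, periods = as.character(2015:2021),
                           m = 2L, q = 2L,
                           alpha = rep(1 / m, m),
                           output_shares = rep(1 / q, q),
                           sigma_u = 0.2, growth = 0,
                           persistent_u = TRUE,
                           A0 = 1, input_meanlog = log(100),
                           input_sdlog = 0.4,
                           share_concentration = 50,
                           seed = .default_seed) {
  stopifnot(n_dmus >= 1L, m >= 1L, q >= 1L,
            length(alpha) == m, all(alpha > 0),
            length(output_shares) == q, all(output_shares > 0),
            sigma_u >= 0, growth > -1)
  structure(list(n_dmus = as.integer(n_dmus),
                 periods = as.character(periods),
                 m = as.integer(m), q = as.integer(q),
                 alpha = alpha, output_shares = output_shares / sum(output_shares),
                 sigma_u = sigma_u, growth = growth,
                 persistent_u = isTRUE(persistent_u),
                 A0 = A0, input_meanlog = input_meanlog,
                 input_sdlog = input_sdlog,
                 share_concentration = share_concentration,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a frontier panel with known inefficiency
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with \code{panel} (a \code{\link{panel_dataset}}) and
#'   \code{truth}: the inefficiency draws \code{u} (DMU x period), the
#'   true efficiency \code{exp(-u)}, and the frontier parameters.
#' @export
generate_frontier_panel <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_dmus; Tn <- length(spec$periods)
  dmus <- sprintf("D%02d", seq_len(n))
  X <- array(stats::rlnorm(n * Tn * spec$m, spec$input_meanlog,
                           spec$input_sdlog),
             dim = c(n, Tn, spec$m))
  shares <- .rdirichlet(n, spec$share_concentration * spec$output_shares)
  u <- if (spec$persistent_u)
    matrix(abs(stats::rnorm(n, 0, spec$sigma_u)), n, Tn)
  else matrix(abs(stats::rnorm(n * Tn, 0, spec$sigma_u)), n, Tn)
  if (spec$sigma_u == 0) u[] <- 0
  Y <- array(0, dim = c(n, Tn, spec$q))
  for (t in seq_len(Tn)) {
    lvl <- spec$A0 * (1 + spec$growth)^(t - 1)
    front <- lvl * apply(X[, t, , drop = FALSE], 1, function(x)
      prod(x^spec$alpha))
    real <- front * exp(-u[, t])
    Y[, t, ] <- real * shares
  }
  panel <- panel_dataset(X, Y, dmus, spec$periods,
                         sprintf("x%d", seq_len(spec$m)),
                         sprintf("y%d", seq_len(spec$q)))
  truth <- list(u = matrix(u, n, Tn, dimnames = list(dmus, spec$periods)),
                efficiency = exp(-matrix(u, n, Tn,
                                         dimnames = list(dmus, spec$periods))),
                alpha = spec$alpha, growth = spec$growth, A0 = spec$A0,
                shares = shares, spec = spec)
  list(panel = panel, truth = truth)
}

# save/restore the global RNG state so generators are pure functions of
# their seed without clobbering a caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) return(invisible())
  assign(".Random.seed", old, envir = globalenv())
}

# split `total` into length(shares) integer parts proportional to shares,
# preserving the total exactly (largest-remainder), every part >= 1
.integer_apportion <- function(total, shares) {
  stopifnot(total >= length(shares))
  f <- shares / sum(shares) * total
  base <- floor(f)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(f - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  while (any(base == 0)) {
    i <- which.max(base); j <- which(base == 0)[1L]
    base[i] <- base[i] - 1; base[j] <- 1
  }
  stopifnot(sum(base) == total)
  base
}

#' Generate a Luohu-calibrated fixture panel
#'
#' Builds a panel whose shape matches the Luohu Hospital Group study
#' design and whose per-period column totals are exactly calibrated:
#' \describe{
#'   \item{\code{"chc"}}{20 community health centers x 7 years, 4 inputs
#'     and 5 outputs; every column total equals the published total for
#'     that (period, variable) — see \code{\link{luohu_chc_totals}}.}
#'   \item{\code{"regional"}}{10 regions x 7 years, 2 inputs and 2
#'     outputs. District-level totals are not published, so column totals
#'     are a fixed plausible multiple (8x) of the published group totals;
#'     the fixture is shape-compatible, not value-calibrated.}
#' }
#' Within each column the total is split over DMUs by stable random
#' shares: a per-DMU size weight drawn once, times a small per-cell
#' jitter, normalised; integer cells are reconciled by largest-remainder
#' rounding so totals stay exact and every cell stays >= 1.
#'
#' @param which \code{"chc"} or \code{"regional"}.
#' @param seed RNG seed (default a fixed documented constant, so the
#'   fixture is byte-stable).
#' @return a \code{\link{panel_dataset}} with a \code{"calibration"}
#'   attribute (targets used, notes).
#' @export
generate_luohu_fixture <- function(which = c("chc", "regional"),
                                   seed = .default_seed) {
  which <- match.arg(which)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (which == "chc") {
    totals <- luohu_chc_totals()
    n <- 20L; dmus <- sprintf("C%d", 1:20)
    scale_mult <- 1
    notes <- paste("2021 health_education total is an order of magnitude",
                   "above earlier years; calibrated to the published value",
                   "as printed")
  } else {
    totals <- luohu_group_totals()
    n <- 10L; dmus <- sprintf("R%02d", 1:10)
    scale_mult <- 8
    notes <- paste("district-level totals are not published; column totals",
                   "are 8x the published group totals (shape-compatible,",
                   "not value-calibrated)")
  }
  periods <- sort(unique(totals$period))
  in_vars <- unique(totals$variable[totals$kind == "input"])
  out_vars <- unique(totals$variable[totals$kind == "output"])
  size <- stats::rgamma(n, shape = 5)           # stable DMU size weights
  fill <- function(vars, kind) {
    A <- array(0, dim = c(n, length(periods), length(vars)))
    for (vi in seq_along(vars)) for (ti in seq_along(periods)) {
      tot <- totals$total[totals$kind == kind &
                            totals$variable == vars[vi] &
                            totals$period == periods[ti]]
      stopifnot(length(tot) == 1L)
      jitter <- stats::rgamma(n, shape = 50)    # ~14% cv around size
      A[, ti, vi] <- .integer_apportion(tot * scale_mult, size * jitter)
    }
    A
  }
  X <- fill(in_vars, "input")
  Y <- fill(out_vars, "output")
  panel <- panel_dataset(X, Y, dmus, as.character(periods), in_vars, out_vars)
  attr(panel, "calibration") <- list(which = which, seed = seed,
                                     scale_mult = scale_mult,
                                     targets = totals, notes = notes)
  panel
}

#' Generate left-censored regression data
#'
#' Simulates \eqn{y^* = X\beta + \epsilon}, \eqn{\epsilon \sim N(0,
#' \sigma)}, observed as \eqn{y = \max(y^*, L)} — the testbed for
#' \code{\link{fit_tobit}}.
#'
#' @param n sample size.
#' @param beta coefficient vector; the first element is the intercept.
#' @param sigma error scale.
#' @param lower censoring bound L (use \code{-Inf} for none).
#' @param seed RNG seed.
#' @return list with \code{y}, \code{X} (covariates excluding intercept,
#'   standard normal), and \code{truth} (beta, sigma, lower,
#'   censored_fraction).
#' @export
generate_censored_data <- function(n, beta = c(1, 2), sigma = 1,
                                   lower = 0, seed = .default_seed) {
  stopifnot(n > 0, sigma > 0, length(beta) >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  k <- length(beta) - 1L
  X <- matrix(stats::rnorm(n * k), n, k,
              dimnames = list(NULL, if (k) paste0("x", seq_len(k))))
  ystar <- drop(cbind(1, X) %*% beta) + stats::rnorm(n, 0, sigma)
  y <- pmax(ystar, lower)
  list(y = y, X = X,
       truth = list(beta = beta, sigma = sigma, lower = lower,
                    censored_fraction = mean(y <= lower)))
}
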