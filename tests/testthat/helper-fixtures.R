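# Shared fixtures and independent oracles.

# build a cross_section directly from matrices
make_cs <- function(X, Y, ids = NULL, period = "t") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(ids)) ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("d", seq_len(nrow(X)))
  rownames(X) <- rownames(Y) <- ids
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  structure(list(period = period, X = X, Y = Y, dmu_ids = ids),
            class = "cross_section")
}

random_cs <- function(n, m, q, lo = 1, hi = 10) {
  make_cs(matrix(stats::runif(n * m, lo, hi), n, m),
          matrix(stats::runif(n * q, lo, hi), n, q))
}

# brute-force lambda-grid oracle for single-input/single-output CRS models.
# Searches reference bundles (Xbar, Ybar) = lam1 * p1 + lam2 * p2 over all
# DMU pairs on a lambda grid; model = "ccr" minimises the input contraction
# Xbar / x_k subject to Ybar >= y_k, model = "sbm" minimises
# (Xbar / x_k) / (Ybar / y_k) subject to Xbar <= x_k, Ybar >= y_k.
grid_oracle <- function(cs, dmu, model = c("ccr", "sbm"), step = 1e-3) {
  model <- match.arg(model)
  k <- match(dmu, cs$dmu_ids)
  x <- cs$X[, 1]; y <- cs$Y[, 1]
  xk <- x[k]; yk <- y[k]
  lam_max <- 2 * max(yk / y, xk / x)
  n <- length(x)
  best <- Inf
  score_of <- function(xb, yb) {
    if (model == "ccr") {
      ok <- yb >= yk
      if (any(ok)) min(xb[ok] / xk) else Inf
    } else {
      ok <- yb >= yk & xb <= xk
      if (any(ok)) min((xb[ok] / xk) / (yb[ok] / yk)) else Inf
    }
  }
  fine <- seq(0, lam_max, by = step)
  for (j in seq_len(n))
    best <- min(best, score_of(fine * x[j], fine * y[j]))
  coarse <- seq(0, lam_max, by = max(step, lam_max / 150))
  for (j1 in seq_len(n)) for (j2 in j1:n) for (l2 in coarse)
    best <- min(best, score_of(coarse * x[j1] + l2 * x[j2],
                               coarse * y[j1] + l2 * y[j2]))
  best
}
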