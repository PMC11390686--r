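test_that("within-period distances lie in (0, 1] and hit 1 on the frontier", {
  set.seed(5)
  fp <- generate_frontier_panel(synthetic_spec(n_dmus = 10, m = 2, q = 2,
                                               periods = c("t1", "t2"),
                                               sigma_u = 0.3, seed = 5))
  cs <- cross_section(fp$panel, "t1")
  d_all <- vapply(fp$panel$dmu_ids, function(d)
    dea_distance(cs, d)$value, numeric(1))
  expect_true(all(d_all > 0 & d_all <= 1 + 1e-9))
  expect_equal(max(d_all), 1, tolerance = 1e-9)   # someone spans the frontier
})

test_that("cross-period distance of a doubled-output point is 2 under CRS", {
  p <- panel_dataset(array(c(1, 1), c(1, 2, 1)), array(c(3, 6), c(1, 2, 1)),
                     "A", c("t1", "t2"), "x", "y")
  d <- dea_distance(cross_section(p, "t1"), "A", cross_section(p, "t2"))
  expect_equal(d$value, 2, tolerance = 1e-9)
  r <- malmquist_pair(p, "A", "t1", "t2")
  expect_equal(r$tfpch, 2, tolerance = 1e-9)
  expect_equal(r$effch, 1, tolerance = 1e-9)
  expect_equal(r$techch, 2, tolerance = 1e-9)
  expect_equal(unname(r$distances),
               c(1, 2, 0.5, 1, 1, 1), tolerance = 1e-9)
})

test_that("identical data in adjacent periods gives all components 1", {
  set.seed(9)
  X <- matrix(runif(4, 1, 5), 4, 1)
  Y <- matrix(runif(4, 2, 9), 4, 1)
  p <- panel_dataset(array(cbind(X, X), c(4, 2, 1)),
                     array(cbind(Y, Y), c(4, 2, 1)),
                     paste0("d", 1:4), c("t1", "t2"), "x", "y")
  tab <- malmquist_table(p)
  for (cl in c("effch", "techch", "pech", "sech", "tfpch"))
    expect_equal(tab[[cl]], rep(1, 4), tolerance = 1e-9)
})

test_that("decomposition identities and reversal hold on random panels", {
  set.seed(23)
  for (rep in 1:3) {
    n <- sample(4:7, 1); m <- sample(1:2, 1); q <- sample(1:2, 1)
    p <- panel_dataset(array(runif(n * 3 * m, 1, 9), c(n, 3, m)),
                       array(runif(n * 3 * q, 1, 9), c(n, 3, q)),
                       paste0("d", 1:n), c("t1", "t2", "t3"),
                       paste0("x", 1:m), paste0("y", 1:q))
    tab <- malmquist_table(p)
    expect_true(all(tab$status == "ok"))
    expect_equal(tab$tfpch, tab$effch * tab$techch, tolerance = 1e-9)
    expect_equal(tab$effch, tab$pech * tab$sech, tolerance = 1e-9)
    expect_true(all(tab[c("effch", "techch", "pech", "sech", "tfpch")] > 0))
    # reversal: swapping the two periods inverts every component
    pr <- panel_dataset(p$X[, c(2, 1, 3), , drop = FALSE],
                        p$Y[, c(2, 1, 3), , drop = FALSE],
                        p$dmu_ids, c("t1", "t2", "t3"),
                        p$input_names, p$output_names)
    fwd <- malmquist_pair(p, "d1", "t1", "t2")
    rev <- malmquist_pair(pr, "d1", "t1", "t2")
    for (cl in c("effch", "techch", "pech", "sech", "tfpch"))
      expect_equal(fwd[[cl]] * rev[[cl]], 1, tolerance = 1e-9)
  }
})

test_that("malmquist_table covers all adjacent pairs and no more", {
  fp <- generate_frontier_panel(synthetic_spec(n_dmus = 5, m = 1, q = 1,
                                               seed = 3))
  tab <- malmquist_table(fp$panel)   # 7 periods -> 6 pairs
  expect_equal(nrow(tab), 5 * 6)
  expect_equal(sort(unique(tab$pair)),
               sort(paste(2015:2020, 2016:2021, sep = "-")))
  expect_error(malmquist_pair(fp$panel, "D01", "2015", "2017"), "adjacent")
})

test_that("synthetic technology growth is recovered by mean TECHCH", {
  fp0 <- generate_frontier_panel(synthetic_spec(n_dmus = 30, m = 2, q = 2,
                                                periods = as.character(2015:2018),
                                                sigma_u = 0.2, growth = 0,
                                                seed = 102))
  tab0 <- malmquist_table(fp0$panel)
  expect_equal(exp(mean(log(tab0$techch))), 1, tolerance = 0.02)
  fp5 <- generate_frontier_panel(synthetic_spec(n_dmus = 30, m = 2, q = 2,
                                                periods = as.character(2015:2018),
                                                sigma_u = 0.2, growth = 0.05,
                                                seed = 103))
  tab5 <- malmquist_table(fp5$panel)
  expect_equal(exp(mean(log(tab5$techch))), 1.05, tolerance = 0.02)
})

test_that("aggregation reproduces the published per-unit means", {
  chc <- luohu_chc_mpi()
  s <- index_summary(chc)
  mean_row <- s[s$chc == "Mean", ]
  expect_equal(round(mean_row$effch, 3), 1.020)
  expect_equal(round(mean_row$techch, 3), 1.092)
  expect_equal(round(mean_row$tfpch, 3), 1.078)
  reg <- shenzhen_region_mpi()
  s2 <- index_summary(reg)
  expect_equal(round(s2$tfpch[s2$region == "Mean"], 3), 0.990)
  expect_equal(round(s2$row_mean[s2$region == "Luohu Hospital Group"], 3),
               1.025)
})

test_that("aggregate_malmquist means by dmu and pair, dropping failed rows", {
  tab <- data.frame(dmu = rep(c("a", "b"), each = 2),
                    pair = rep(c("p1", "p2"), 2),
                    effch = c(1, 4, 2, 2), techch = c(2, 1, 2, 2),
                    pech = 1, sech = c(1, 4, 2, 2), tfpch = c(2, 4, 4, 4),
                    status = c("ok", "ok", "ok", "failed"))
  a <- aggregate_malmquist(tab, by = "dmu", method = "arithmetic")
  expect_equal(a$effch[a$dmu == "a"], 2.5)
  expect_equal(a$effch[a$dmu == "b"], 2)       # failed row dropped
  expect_equal(attr(a, "dropped"), 1L)
  g <- aggregate_malmquist(tab, by = "dmu", method = "geometric")
  expect_equal(g$effch[g$dmu == "a"], 2)       # sqrt(1*4)
  p <- aggregate_malmquist(tab, by = "pair")
  expect_equal(p$pair, c("p1", "p2", "Mean"))
  # single result: mean equals itself under both methods
  one <- tab[1, ]
  for (mth in c("arithmetic", "geometric"))
    expect_equal(aggregate_malmquist(one, method = mth)$effch[1], 1)
})
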