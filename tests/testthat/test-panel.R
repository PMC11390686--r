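test_that("wide CSV load: minimal file, prefixes, thousands separators", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dmu,period,input:beds,output:visits",
               "A,2015,10,\"1,200\"",
               "A,2016,12,1400"), f)
  p <- load_panel(f)
  expect_s3_class(p, "panel_dataset")
  expect_equal(p$dmu_ids, "A")
  expect_equal(p$periods, c("2015", "2016"))
  expect_equal(length(p$input_names), 1L)
  expect_equal(length(p$output_names), 1L)
  expect_equal(p$Y["A", "2015", "visits"], 1200)  # separator stripped
})

test_that("unbalanced panels and bad numbers are rejected with context", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dmu,period,input:x,output:y",
               "C6,2018,1,2", "C7,2017,1,2", "C6,2017,1,2"), f)
  expect_error(load_panel(f), "C7/2018")
  writeLines(c("dmu,period,input:x,output:y", "A,2015,oops,2"), f)
  expect_error(load_panel(f), "input:x")
})

test_that("write_panel / load_panel round-trips values at full precision", {
  p <- generate_luohu_fixture("chc")
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f)
  p2 <- load_panel(f)
  expect_equal(p2$dmu_ids, p$dmu_ids)
  expect_equal(p2$periods, p$periods)
  expect_identical(as.numeric(p2$X), as.numeric(p$X))
  expect_identical(as.numeric(p2$Y), as.numeric(p$Y))
  # non-integer values round-trip too
  q <- generate_frontier_panel(synthetic_spec(n_dmus = 3, periods = c("a", "b"),
                                              seed = 8))$panel
  write_panel(q, f)
  q2 <- load_panel(f)
  expect_equal(as.numeric(q2$X), as.numeric(q$X), tolerance = 1e-15)
  expect_equal(as.numeric(q2$Y), as.numeric(q$Y), tolerance = 1e-15)
})

test_that("validate_panel enforces positivity and applies epsilon substitution", {
  p <- generate_luohu_fixture("chc")
  v <- validate_panel(p)
  expect_identical(v$X, p$X)                     # untouched when all positive
  expect_equal(nrow(attr(v, "validation")$substitutions), 0L)
  expect_length(attr(v, "validation")$warnings, 0L)  # 20 > 2*(4+5)

  p$X["C3", "2016", "home_beds"] <- 0
  expect_error(validate_panel(p), "C3")
  v2 <- validate_panel(p, epsilon_substitute = TRUE)
  expect_equal(nrow(attr(v2, "validation")$substitutions), 1L)
  expect_equal(v2$X["C3", "2016", "home_beds"],
               1e-6 * max(p$X[, , "home_beds"]))

  # discrimination warning when n <= 2(m+q)
  small <- generate_frontier_panel(synthetic_spec(n_dmus = 6, m = 2, q = 2,
                                                  periods = "2015",
                                                  seed = 2))$panel
  expect_match(attr(validate_panel(small), "validation")$warnings,
               "rule of thumb")
})

test_that("cross_section slices in stored order and fails on unknown period", {
  p <- generate_luohu_fixture("chc")
  cs <- cross_section(p, "2017")
  expect_equal(nrow(cs$X), 20L)
  expect_equal(cs$dmu_ids, p$dmu_ids)
  expect_equal(unname(cs$X[, "equipment"]), unname(p$X[, "2017", "equipment"]))
  expect_error(cross_section(p, "2014"), "unknown period")
})

test_that("descriptive_totals equals a naive summation and is DMU-order invariant", {
  fp <- generate_frontier_panel(synthetic_spec(n_dmus = 7, m = 2, q = 3,
                                               periods = c("p1", "p2"),
                                               seed = 31))
  p <- fp$panel
  dt <- descriptive_totals(p)
  for (t in p$periods) for (v in p$output_names) {
    naive <- 0
    for (d in p$dmu_ids) naive <- naive + p$Y[d, t, v]
    expect_equal(dt[dt$period == t, v], naive)
  }
  # permute DMUs
  perm <- rev(seq_along(p$dmu_ids))
  p2 <- panel_dataset(p$X[perm, , , drop = FALSE], p$Y[perm, , , drop = FALSE],
                      p$dmu_ids[perm], p$periods, p$input_names,
                      p$output_names)
  expect_equal(descriptive_totals(p2), dt)
  # cross-section column sums match the totals row
  cs <- cross_section(p, "p2")
  expect_equal(unname(colSums(cs$X)),
               unname(unlist(dt[dt$period == "p2", p$input_names])))
})

test_that("covariate tables load and are key-checked against the panel", {
  p <- generate_luohu_fixture("chc")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dmu,period,gp_share", "C1,2015,0.31", "C2,2015,0.44"), f)
  cv <- load_covariates(f, p)
  expect_equal(cv$gp_share, c(0.31, 0.44))
  writeLines(c("dmu,period,gp_share", "C99,2015,0.31"), f)
  expect_error(load_covariates(f, p), "C99")
})
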