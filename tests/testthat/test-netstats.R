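cent_table <- function(vals, mode = "HSN",
                       ids = sprintf("s%02d", seq_along(vals))) {
  tibble::tibble(store_id = ids, mode = mode, raw_degree = vals,
                 normalized_pct = vals)
}

test_that("identical centrality tables give t = 0, p = 1", {
  a <- cent_table(c(1, 2, 3))
  tt <- compare_centrality(a, a, method = "paired")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)
  expect_false(tt$degenerate)
})

test_that("pooled independent t matches the textbook formula", {
  # x=(1,2,3), y=(4,5,6): t = -3/sqrt(1*(2/3)) = -3.674, df = 4; the
  # comparison is UHSN - HSN, so pass x as the UHSN table
  tt <- compare_centrality(cent_table(c(4, 5, 6)), cent_table(c(1, 2, 3)),
                           method = "independent_pooled")
  expect_equal(tt$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(tt$statistic, 3), -3.674)
  expect_equal(tt$df, 4)
})

test_that("constant nonzero paired differences are flagged degenerate", {
  a <- cent_table(c(1, 2, 3))
  b <- cent_table(c(3, 4, 5))
  tt <- compare_centrality(b, a, method = "paired")
  expect_true(tt$degenerate)
  expect_true(is.na(tt$statistic))
})

test_that("paired comparison on shifted noise equals the one-sample t of differences", {
  set.seed(7)
  x <- rnorm(24, 10, 2)
  d <- rnorm(24, 1.5, 0.5)
  tt <- compare_centrality(cent_table(x), cent_table(x + d), method = "paired")
  oracle <- stats::t.test(d)
  expect_equal(tt$statistic, unname(oracle$statistic))
  expect_equal(tt$p, oracle$p.value)
})

test_that("insufficient observations raise a data error", {
  expect_error(compare_centrality(cent_table(1), cent_table(2),
                                  method = "independent_pooled"),
               class = "cornernet_data_error")
})

test_that("OLS slope matches the closed-form least-squares estimate", {
  stores <- toy_stores(6)
  stores$customers_per_day <- c(10, 20, 30, 40, 50, 60)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1, 12.2)
  ct <- cent_table(y, ids = stores$store_id)
  res <- bivariate_ols(stores, ct, "customers_per_day")
  x <- stores$customers_per_day
  expect_equal(res$b, sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
  expect_true(res$ci_95[1] <= res$b && res$b <= res$ci_95[2])
  expect_equal(res$n, 6)
})

test_that("a binary covariate's slope equals the difference of group means", {
  set.seed(19)
  stores <- toy_stores(10)
  y <- rnorm(10)
  ct <- cent_table(y, ids = stores$store_id)
  res <- bivariate_ols(stores, ct, "accepts_wic")
  expect_equal(res$b, mean(y[stores$accepts_wic]) - mean(y[!stores$accepts_wic]))

  # balanced null: equal group means -> b = 0 (WIC alternates TRUE/FALSE)
  y0 <- c(1, 5, 2, 4, 3, 3, 4, 2, 5, 1)
  ct0 <- cent_table(y0, ids = stores$store_id)
  expect_equal(bivariate_ols(stores, ct0, "accepts_wic")$b, 0)
})

test_that("perfect fits and zero-variance designs are handled explicitly", {
  stores <- toy_stores(5)
  stores$customers_per_day <- 1:5
  ct <- cent_table(2 * (1:5), ids = stores$store_id)
  res <- bivariate_ols(stores, ct, "customers_per_day")
  expect_equal(res$b, 2)
  expect_true(res$degenerate)
  expect_equal(res$ci_95, c(2, 2))

  expect_error(bivariate_ols(stores, ct, "accepts_snap"),
               class = "cornernet_data_error")  # all TRUE
  expect_error(bivariate_ols(stores, ct, "no_such_column"),
               class = "cornernet_usage_error")
})

test_that("robust slope variance agrees with the HC2 sandwich estimator", {
  skip_if_not_installed("sandwich")
  set.seed(8)
  stores <- toy_stores(12)
  stores$customers_per_day <- rnorm(12, 100, 30)
  y <- 0.05 * stores$customers_per_day + rnorm(12, 0, 2)
  ct <- cent_table(y, ids = stores$store_id)
  res <- bivariate_ols(stores, ct, "customers_per_day")
  fit <- lm(y ~ stores$customers_per_day)
  se_hc2 <- sqrt(sandwich::vcovHC(fit, type = "HC2")[2, 2])
  width <- diff(res$ci_95)
  # recover the implied df from the interval and check the SE matches
  expect_equal(width / 2 / qt(0.975, cornernet:::bm_slope_inference(
    stores$customers_per_day, y)$df), se_hc2, tolerance = 1e-8)
})

test_that("bootstrap density test is deterministic under a fixed seed", {
  set.seed(3)
  a <- make_er_one_mode(12, 0.6)
  b <- make_er_one_mode(12, 0.3)
  t1 <- bootstrap_density_compare(a, b, n_boot = 200, seed = 99)
  t2 <- bootstrap_density_compare(a, b, n_boot = 200, seed = 99)
  expect_identical(t1$statistic, t2$statistic)
  expect_error(bootstrap_density_compare(a, b, n_boot = 50, seed = 1),
               class = "cornernet_usage_error")
  expect_error(bootstrap_density_compare(a, b, n_boot = 200),
               class = "cornernet_usage_error")
})

test_that("comparing a network with itself is never significant", {
  set.seed(29)
  a <- make_er_one_mode(15, 0.5)
  ps <- vapply(1:20, function(s)
    bootstrap_density_compare(a, a, n_boot = 200, seed = s)$p, numeric(1))
  # identical graphs: zero observed difference, p = 1 every time
  expect_true(all(ps == 1))
})

test_that("full analysis recovers structure and honors degenerate cases", {
  ds <- generate_dataset(synthetic_config(), seed = 21)
  rep <- run_full_analysis(ds, list(seed = 21, n_boot = 200))
  expect_s3_class(rep, "cornernet_report")
  expect_equal(nrow(rep$regressions), 18)  # 9 covariates x 2 modes
  expect_equal(nrow(rep$sensitivity_regressions), 18)
  # effects act on the healthy network: UHSN density should dwarf HSN
  expect_gt(rep$density$UHSN, rep$density$HSN)

  # no delivering suppliers -> sensitivity tables identical to main tables
  ds2 <- ds
  ds2$suppliers$delivers <- FALSE
  ds2$purchases$via_delivery <- FALSE
  rep2 <- run_full_analysis(ds2, list(seed = 21, n_boot = 200))
  expect_equal(as.data.frame(rep2$sensitivity_regressions),
               as.data.frame(rep2$regressions))
})
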