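# Transfer model, verification statistics, and the reconstruction.

make_xy <- function(n = 54, slope = 400, intercept = -100, noise = 60,
                    seed = 1) {
  set.seed(seed)
  x <- setNames(rnorm(n, 1, 0.2), seq(2019 - n, 2018))
  y <- setNames(intercept + slope * x + rnorm(n, 0, noise), names(x))
  list(x = x, y = y)
}

test_that("an exact linear target is recovered perfectly", {
  x <- setNames(seq(0.5, 1.5, length.out = 40), 1979:2018)
  m <- fit_transfer(x, 2 * x + 1)
  expect_equal(m$slope, 2, tolerance = 1e-10)
  expect_equal(m$intercept, 1, tolerance = 1e-10)
  expect_equal(m$stats$R2, 1, tolerance = 1e-12)
  expect_lt(m$stats$RMSE, 1e-10)
})

test_that("calibration statistics are internally consistent", {
  d <- make_xy()
  m <- fit_transfer(d$x, d$y)
  expect_equal(m$stats$R2, m$stats$r^2, tolerance = 1e-12)
  expect_lte(m$stats$R2adj, m$stats$R2)
  # in-sample RE against the calibration mean equals R2 (OLS identity)
  expect_equal(re_ce(m$obs, m$fitted, m$cal_mean)$re, m$stats$R2,
               tolerance = 1e-10)
  expect_error(fit_transfer(setNames(rep(1, 40), 1979:2018), d$y[1:40]),
               "zero-variance")
})

test_that("the fitted model applies the printed coefficient arithmetic", {
  d <- make_xy()
  m <- fit_transfer(d$x, d$y)
  m$slope <- 430.6; m$intercept <- -107.51   # published-model arithmetic
  rc <- setNames(rep(0.5, 40), 1901:1940)
  out <- reconstruct(m, rc, 1901)
  expect_equal(out$values[1], 430.6 * 0.5 - 107.51, tolerance = 1e-12)
  expect_equal(out$values[1], 107.79, tolerance = 1e-12)
})

test_that("null targets give uniform F-test p-values", {
  set.seed(9)
  pvals <- vapply(1:300, function(i) {
    x <- setNames(rnorm(54, 1, 0.2), 1965:2018)
    y <- setNames(rnorm(54, 250, 70), 1965:2018)
    fit_transfer(x, y)$stats$p
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.001)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.04)
})

test_that("LOOCV equals direct refitting and behaves at the anchors", {
  d <- make_xy(seed = 2)
  m <- fit_transfer(d$x, d$y)
  cv <- loocv(m)
  # hat-matrix shortcut vs explicit leave-one-out refits
  direct <- vapply(seq_along(d$x), function(i) {
    f <- lm(y ~ x, data = data.frame(x = d$x[-i], y = d$y[-i]))
    unname(predict(f, data.frame(x = d$x[i])))
  }, numeric(1))
  expect_equal(unname(cv$predictions), direct, tolerance = 1e-10)
  expect_equal(cv$PRESS, sum((d$y - direct)^2), tolerance = 1e-8)

  # noise-free: predictions equal observations, RE = 1, RMSE = 0
  x <- setNames(seq(0.5, 1.5, length.out = 40), 1979:2018)
  cv0 <- loocv(fit_transfer(x, 2 * x + 1))
  expect_equal(unname(cv0$predictions), unname(2 * x + 1), tolerance = 1e-8)
  expect_equal(cv0$RE, 1, tolerance = 1e-10)
  expect_lt(cv0$RMSE, 1e-8)

  # mean-only predictions define RE = 0
  obs <- rnorm(30, 100, 10)
  expect_equal(re_ce(obs, rep(mean(obs), 30), mean(obs))$re, 0,
               tolerance = 1e-12)
})

test_that("LOOCV skill does not exceed in-sample skill on median", {
  set.seed(10)
  gaps <- vapply(1:50, function(i) {
    d <- make_xy(noise = 80, seed = 100 + i)
    m <- fit_transfer(d$x, d$y)
    m$stats$R2 - loocv(m)$R2
  }, numeric(1))
  expect_gte(median(gaps), 0)
})

test_that("split-sample statistics match a hand-computed integer oracle", {
  # cal 2001-05: x=1..5, y=(3,4,7,6,10): slope 16/10, intercept 1.2
  # ver 2006-10: pred=(10.8,12.4,14,15.6,17.2) vs obs=(11,14,12,15,18)
  # SSE=7.6; RE=1-7.6/350 (cal mean 6); CE=1-7.6/30 (ver mean 14)
  x <- setNames(1:10, 2001:2010)
  y <- setNames(c(3, 4, 7, 6, 10, 11, 14, 12, 15, 18), 2001:2010)
  ss <- split_sample(x, y, split_year = 2005, min_half = 5)
  expect_equal(ss$early_cal$verification$RE, 1 - 7.6 / 350,
               tolerance = 1e-12)
  expect_equal(ss$early_cal$verification$CE, 1 - 7.6 / 30,
               tolerance = 1e-12)
  expect_equal(ss$early_cal$verification$RMSE, sqrt(7.6 / 5),
               tolerance = 1e-12)
})

test_that("split-sample honours its analytic anchors", {
  # noise-free linear relation: RE = CE = 1 both ways
  x <- setNames(seq(0.4, 1.6, length.out = 40), 1979:2018)
  y <- 300 * x - 50
  ss <- split_sample(x, y)
  expect_equal(ss$early_cal$verification$RE, 1, tolerance = 1e-10)
  expect_equal(ss$late_cal$verification$CE, 1, tolerance = 1e-10)

  # equal half means make RE and CE identical
  set.seed(11)
  ya <- rnorm(20, 100, 15)
  yb <- rnorm(20, 100, 15)
  yb <- yb - mean(yb) + mean(ya)          # force identical half means
  y2 <- setNames(c(ya, yb), 1979:2018)
  x2 <- setNames(rnorm(40, 1, 0.2), 1979:2018)
  ss2 <- split_sample(x2, y2)
  expect_equal(ss2$early_cal$verification$RE,
               ss2$early_cal$verification$CE, tolerance = 1e-10)

  expect_error(split_sample(x[1:15], y[1:15], split_year = 1984), "12 years")
})

test_that("RE never falls below CE", {
  set.seed(12)
  for (i in 1:100) {
    obs <- rnorm(20, 50, 10)
    pred <- rnorm(20, 50, 10)
    rc <- re_ce(obs, pred, cal_mean = rnorm(1, 50, 5))
    expect_gte(rc$re, rc$ce)
    expect_lte(rc$ce, 1)
  }
})

test_that("sign test counts first-difference agreements", {
  obs <- c(1, 3, 2, 5, 4)
  pred <- c(2, 4, 1, 6, 5)
  st <- sign_test(obs, pred)
  expect_identical(st$agreements, 4L)
  expect_identical(st$disagreements, 0L)
  expect_equal(st$p, 2 * 0.5^4, tolerance = 1e-12)
  expect_identical(sign_test(obs, obs)$agreements, 4L)
  expect_identical(sign_test(obs, -obs)$agreements, 0L)
  # zero differences are dropped
  expect_identical(sign_test(c(1, 1, 2, 3), c(1, 2, 3, 4))$n, 2L)
  expect_error(sign_test(1:2, 1:2), "at least 3")
})

test_that("product-mean test matches hand arithmetic and flags degeneracy", {
  # products (4,2,2,-1,-1): m1=8/3, s1^2=4/3, m2=1, s2=0 -> t = 2.5
  obs <- c(4, 2, 2, -1, -1)
  pred <- rep(1, 5)
  pm <- product_mean_test(obs, pred, cal_mean = 0)
  expect_equal(pm$t, 2.5, tolerance = 1e-12)
  expect_false(pm$degenerate)

  same <- product_mean_test(obs, obs, cal_mean = 0)
  expect_true(same$degenerate)
  expect_identical(same$t, Inf)

  set.seed(13)
  ts <- vapply(1:200, function(i)
    product_mean_test(rnorm(30), rnorm(30), 0)$t, numeric(1))
  ts <- ts[is.finite(ts)]
  expect_lt(abs(mean(ts)), 0.5)
})

test_that("Durbin-Watson matches arithmetic and the independent oracle", {
  e <- rep(c(1, -1), 3)
  expect_equal(durbin_watson(e), 20 / 6, tolerance = 1e-12)
  set.seed(14)
  expect_lt(abs(durbin_watson(rnorm(2000)) - 2), 0.2)
  expect_error(durbin_watson(rep(2, 10)), "zero residual variance")

  d <- make_xy(seed = 3)
  m <- fit_transfer(d$x, d$y)
  oracle <- unname(lmtest::dwtest(lm(d$y ~ d$x))$statistic)
  expect_equal(m$stats$DW, oracle, tolerance = 1e-10)
})

test_that("reconstruction reduces to the calibration mean at the mean index", {
  d <- make_xy(seed = 4)
  m <- fit_transfer(d$x, d$y)
  flat <- setNames(rep(mean(m$index), 50), 1801:1850)
  out <- reconstruct(m, flat, 1801)
  expect_equal(out$values, rep(mean(m$obs), 50), tolerance = 1e-10)
  expect_equal(out$upper - out$values, rep(m$stats$RMSE, 50))
  expect_identical(out$years[1], 1801L)
  expect_error(reconstruct(m, flat, 1700), "outside")
})
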