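# Seasonal aggregation, bootstrapped correlation functions, seascorr
# partial correlations, moving correlations, climate-mode tables.

test_that("seasonalize sums and means the documented windows", {
  prec <- matrix(rep(seq(10, 120, by = 10), each = 3), 3, 12,
                 dimnames = list(2001:2003, month.abb))
  tmean <- matrix(17, 3, 12, dimnames = list(2001:2003, month.abb))
  mc <- toy_climate(2001:2003, prec, tmean)
  fj <- seasonalize(mc, "prec", c(2, 6))
  expect_equal(unname(fj$values["2002"]), 20 + 30 + 40 + 50 + 60)
  tm <- seasonalize(mc, "tmean", c(2, 6))
  expect_equal(unname(tm$values["2002"]), 17)
  # first year has no previous-year months for windows that need them
  w17 <- seasonalize(mc, "prec", c(-6, 10))
  expect_true(is.na(w17$values["2001"]))
  expect_false(is.na(w17$values["2002"]))
})

test_that("previous-year months are pulled from year - 1", {
  # cell value = year * 100 + month makes every month traceable
  years <- 1991:1993
  prec <- outer(years * 100, rep(1, 12)) + outer(rep(1, 3), 1:12)
  rownames(prec) <- years
  mc <- toy_climate(years, prec)
  v <- seasonalize(mc, "prec", c(-6, 10))$values["1992"]
  manual <- sum(199100 + 6:12) + sum(199200 + 1:10)
  expect_equal(unname(v), manual)
})

test_that("a data gap propagates NA to windows that cross it", {
  prec <- matrix(50, 3, 12, dimnames = list(1965:1967, month.abb))
  prec[2, ] <- NA  # 1966 missing
  mc <- toy_climate(1965:1967, prec)
  v <- seasonalize(mc, "prec", c(-6, 10))$values
  expect_true(is.na(v["1966"]))
  expect_true(is.na(v["1967"]))  # needs previous-year 1966 months
})

test_that("a chronology equal to May precipitation correlates 1 in May", {
  cl <- fx_climate()
  may <- seasonalize(cl$climate, "prec", c(5, 5))$values
  v <- (may - mean(may)) / sd(may) + 1
  cf <- bootstrap_corrfun(v, cl$climate, variables = "prec",
                          nboot = 200, seed = 1)
  row <- cf[cf$label == "May" & cf$kind == "month", ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  expect_true(row$sig)
})

test_that("the synthetic forest shows the moisture-stress sign structure", {
  cl <- fx_climate()
  ch <- fx_chron()
  cf <- bootstrap_corrfun(ch, cl$climate, nboot = 300, seed = 2)
  fj_p <- cf[cf$variable == "prec" & cf$label == "FMAMJ", ]
  expect_gt(fj_p$r, 0.3)
  expect_true(fj_p$sig)
  fj_t <- cf[cf$variable == "tmean" & cf$label == "FMAMJ", ]
  expect_lt(fj_t$r, 0)
  # bootstrap intervals are deterministic under the seed
  cf2 <- bootstrap_corrfun(ch, cl$climate, nboot = 300, seed = 2)
  expect_identical(cf, cf2)
})

test_that("an unrelated chronology is flagged at roughly the nominal rate", {
  cl <- fx_climate()
  set.seed(3)
  rate <- mean(vapply(1:10, function(i) {
    v <- setNames(rnorm(80), 1939:2018)
    cf <- bootstrap_corrfun(v, cl$climate, nboot = 300,
                            seed = 1000 + i)
    mean(cf$sig)
  }, numeric(1)))
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)
})

test_that("seascorr reduces to known partial-correlation identities", {
  cl <- fx_climate()
  tr <- cl$truth
  # chronology = z_P exactly: saturated primary at the Feb-Jun window
  v <- setNames(tr$z_P + 1, tr$years)
  sc <- seascorr(v, cl$climate, nsim = 200, seed = 4)
  fmamj_p <- sc[sc$variable == "primary" & sc$end_month == 6 &
                  sc$length == 5, ]
  expect_equal(fmamj_p$r, 1, tolerance = 1e-10)
  expect_true(fmamj_p$sig)
  fmamj_s <- sc[sc$variable == "secondary" & sc$end_month == 6 &
                  sc$length == 5, ]
  expect_lt(abs(fmamj_s$r), 1e-6)
})

test_that("with orthogonal drivers the partial equals the simple r", {
  set.seed(5)
  n <- 400
  years <- 1601:2000
  Q <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))  # exactly orthogonal columns
  P <- Q[, 1] * 30 + 100
  Tm <- Q[, 2] * 2 + 15
  prec <- matrix(rexp(n * 12, 1 / 40), n, 12, dimnames = list(years, NULL))
  tmean <- matrix(rnorm(n * 12, 15, 2), n, 12, dimnames = list(years, NULL))
  prec[, 5] <- P
  tmean[, 5] <- Tm
  mc <- toy_climate(years, prec, tmean)
  v <- setNames(scale(Q[, 1])[, 1] + scale(Q[, 2])[, 1] + 5, years)
  sc <- seascorr(v, mc, season_lengths = 1, nsim = 100, seed = 6)
  may_s <- sc[sc$variable == "secondary" & sc$end_month == 5, ]
  simple <- cor(unname(v), Tm)
  expect_equal(may_s$r, simple, tolerance = 0.02)
})

test_that("a constant secondary variable leaves the primary column simple", {
  cl <- fx_climate()
  mc <- cl$climate
  mc$data$tmean[] <- 17
  v <- chronology_values(fx_chron())
  sc <- seascorr(v, mc, season_lengths = c(1, 5), nsim = 50, seed = 7)
  may <- sc[sc$variable == "primary" & sc$end_month == 5 & sc$length == 1, ]
  p <- seasonalize(mc, "prec", c(5, 5))$values
  common <- intersect(names(v), names(p))
  expect_equal(may$r, cor(v[common], p[common]), tolerance = 1e-10)
  expect_true(all(sc$r[sc$variable == "secondary"] == 0))
})

test_that("moving correlations localize a constructed regime shift", {
  cl <- fx_climate()
  tr <- cl$truth
  n <- length(tr$years)
  half <- floor(n / 2)
  set.seed(8)
  v <- c(tr$z_P[1:half] + rnorm(half, 0, 0.4),
         rnorm(n - half, 0, 1.1))
  v <- setNames(v + 2, tr$years)
  mv <- moving_corr(v, cl$climate, "prec", window = 30, step = 2,
                    months = NULL, seasons = list(FMAMJ = c(2, 6)))
  mid <- tr$years[half]
  early <- mv$window_end <= mid
  expect_gt(mean(mv$sig[early]), 0.8)
  expect_lt(mean(mv$sig[!early & mv$window_start > mid]), 0.3)
  expect_error(moving_corr(setNames(rnorm(20), 1999:2018), cl$climate,
                           "prec", window = 30), "window")
})

test_that("index correlations recover identity and reject no overlap", {
  ch <- fx_chron()
  v <- chronology_values(ch)
  idx <- matrix(rep(unname(v), 12), ncol = 12,
                dimnames = list(names(v), NULL))
  tab <- index_corr(v, idx)
  expect_true(all(abs(tab$r - 1) < 1e-12))
  expect_error(index_corr(v, matrix(rnorm(120), 10, 12,
                                    dimnames = list(1001:1010, NULL))),
               "overlap")
})
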