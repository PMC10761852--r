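# Detrending, prewhitening, biweight mean, Rbar/EPS, chronology building.

test_that("model-true negexp input detrends to an index of exactly 1", {
  t <- 1:200
  s <- ring_series("EXACT", 1800, 2.0 * exp(-0.05 * t) + 0.5)
  d <- detrend_negexp(s)
  expect_identical(d$kind, "negexp")
  expect_false(d$fallback)
  expect_lt(max(abs(d$index - 1)), 1e-6)
})

test_that("constant and increasing series trigger the mean fallback", {
  s <- ring_series("CONST", 1900, rep(1.50, 60))
  d <- detrend_negexp(s)
  expect_identical(d$kind, "mean")
  expect_equal(d$index, rep(1, 60), tolerance = 1e-12)

  s2 <- ring_series("GROW", 1900, seq(0.5, 3.5, length.out = 80))
  d2 <- detrend_negexp(s2)
  expect_true(d2$fallback)
  expect_equal(mean(d2$index), 1, tolerance = 1e-12)
})

test_that("detrended indices average to one", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(60:300, 1)
    w <- (2.5 * exp(-0.03 * (1:n)) + 0.4) *
      pmax(0.05, 1 + rnorm(n, 0, 0.25))
    d <- detrend_negexp(ring_series("P", 1500, round(w, 2)))
    tol <- if (d$kind == "negexp") 0.05 else 1e-9
    expect_lt(abs(mean(d$index) - 1), tol)
  }
})

test_that("degenerate detrending inputs are rejected", {
  expect_error(detrend_negexp(ring_series("Z", 1900, rep(0, 30))),
               "all-zero")
  expect_error(detrend_negexp(ring_series("S", 1900, rep(1, 5))),
               "too short")
})

test_that("prewhitening removes known AR(1) persistence", {
  set.seed(42)
  x <- as.numeric(arima.sim(list(ar = 0.7), 500)) * 0.2 + 1
  d <- prewhiten(make_detrended(x))
  expect_gte(d$ar_order, 1L)
  res <- d$index
  ac1 <- cor(res[-1], res[-length(res)])
  expect_lt(abs(ac1), 0.1)
  expect_equal(mean(res), 1, tolerance = 1e-12)
})

test_that("white noise is mostly left alone and constants always are", {
  set.seed(43)
  orders <- vapply(1:100, function(i)
    prewhiten(make_detrended(rnorm(200, 1, 0.2)), max_order = 5)$ar_order,
    integer(1))
  expect_gt(mean(orders == 0L), 0.5)
  d <- prewhiten(make_detrended(rep(1, 100)))
  expect_identical(d$ar_order, 0L)
  expect_equal(d$index, rep(1, 100))
})

test_that("biweight mean matches its anchors and the independent oracle", {
  expect_equal(biweight_mean(c(0.8, 1.0, 1.2)), 1.0)
  expect_equal(biweight_mean(3.7), 3.7)
  x <- c(rep(1, 9), 10)
  bw <- biweight_mean(x)
  expect_gte(bw, 1.0)
  expect_lt(bw, 1.9)
  expect_lt(bw, mean(x))
  expect_equal(bw, biweight_oracle(x), tolerance = 1e-8)
  # symmetric outlier-free sample: equals the arithmetic mean
  expect_equal(biweight_mean(c(0.9, 0.95, 1, 1.05, 1.1)), 1,
               tolerance = 1e-9)
})

test_that("a single outlier has bounded influence", {
  x <- c(0.8, 0.9, 1.0, 1.1, 1.2, 1.0, 0.95)
  expect_equal(biweight_mean(c(x, 100)), biweight_mean(c(x, 1e9)),
               tolerance = 1e-6)
})

test_that("running Rbar/EPS matches the equicorrelation closed form", {
  set.seed(44)
  n <- 500
  sig <- rnorm(n)
  m <- sapply(1:10, function(j) sig + rnorm(n))  # signal:noise var 1:1
  rownames(m) <- 1401:1900
  run <- running_rbar_eps(m, window = n, overlap = 0)
  expect_equal(run$rbar[1], 0.5, tolerance = 0.05)
  expect_equal(run$eps[1], 10 * 0.5 / (10 * 0.5 + 0.5), tolerance = 0.05)
  expect_equal(run$n[1], 10)

  ident <- sapply(1:5, function(j) sig)
  rownames(ident) <- 1401:1900
  run2 <- running_rbar_eps(ident, window = n, overlap = 0)
  expect_equal(run2$rbar[1], 1)
  expect_equal(run2$eps[1], 1)

  indep <- sapply(1:10, function(j) rnorm(n))
  rownames(indep) <- 1401:1900
  run3 <- running_rbar_eps(indep, window = n, overlap = 0)
  expect_lt(abs(run3$rbar[1]), 0.05)
  expect_lt(run3$eps[1], 0.35)
})

test_that("EPS grows with replication at fixed common signal", {
  set.seed(45)
  n <- 400
  sig <- rnorm(n)
  eps_at <- vapply(c(2, 4, 8, 16), function(k) {
    m <- sapply(1:k, function(j) sig + rnorm(n))
    rownames(m) <- seq_len(n) + 1500
    running_rbar_eps(m, window = n, overlap = 0)$eps[1]
  }, numeric(1))
  expect_true(all(diff(eps_at) > 0))
})

test_that("windows with fewer than two overlapping series yield NA", {
  m <- matrix(NA_real_, 100, 2, dimnames = list(1801:1900, c("a", "b")))
  m[1:50, 1] <- rnorm(50)
  m[61:100, 2] <- rnorm(40)
  run <- running_rbar_eps(m, window = 50, overlap = 0, min_overlap = 10)
  expect_true(all(is.na(run$eps)))
})

test_that("chronology statistics match a hand-computed alternating series", {
  # alternating 1,2 detrends by the mean line to x = (2/3, 4/3, ...)
  s <- ring_series("ALT", 1900, rep(c(1, 2), 30))
  ch <- build_chronology(site_collection(s), prewhiten = FALSE)
  expect_equal(ch$stats$std$ms, 2 / 3, tolerance = 1e-9)
  expect_lt(ch$stats$std$ac1, -0.9)
  expect_true(all(ch$depth == 1))
})

test_that("pooling identical collections is idempotent", {
  coll <- fx_forest()$collections[[1]]
  one <- build_chronology(coll, prewhiten = FALSE)
  two <- build_chronology(list(coll, coll), prewhiten = FALSE)
  expect_equal(two$std, one$std, tolerance = 1e-12)
  expect_equal(two$depth, 2 * one$depth)
})

test_that("residual chronology has less persistence than the standard", {
  ch <- fx_chron()
  ok <- !is.na(ch$res)
  expect_lt(abs(ch$stats$res$ac1), abs(cor(ch$std[ok][-1],
                                           ch$std[ok][-sum(ok)])))
  expect_lte(ch$stats$res$sd, ch$stats$std$sd * 1.05)
})

test_that("EPS truncation follows the all-subsequent-windows rule", {
  fake <- structure(list(
    years = 1300:2000,
    running = data.frame(start = 0, end = 0,
                         mid = c(1310, 1399, 1400, 1990),
                         rbar = 0.5, n = 10,
                         eps = c(0.80, 0.80, 0.95, 0.95))),
    class = "chronology")
  expect_identical(truncate_by_eps(fake, 0.85), 1400L)

  fake$running$eps <- c(0.9, 0.92, 0.95, 0.96)
  expect_identical(truncate_by_eps(fake, 0.85), 1300L)

  fake$running$eps <- c(0.5, 0.6, 0.7, 0.8)
  expect_error(truncate_by_eps(fake, 0.85), "never reaches")
})

test_that("site PCA recovers exact equicorrelation eigenstructure", {
  set.seed(46)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3)
  X <- scale(X, scale = FALSE)
  # whiten, then impose an exact sample correlation of 0.6
  X <- X %*% solve(chol(cov(X)))
  R <- matrix(0.6, 3, 3); diag(R) <- 1
  Y <- X %*% chol(R)
  vs <- lapply(1:3, function(j) setNames(Y[, j], 1801:2000))
  p <- pca_sites(vs)
  expect_equal(p$variance_fraction[1], (1 + 2 * 0.6) / 3, tolerance = 1e-10)

  ident <- lapply(1:3, function(j) vs[[1]])
  expect_equal(pca_sites(ident)$variance_fraction[1], 1, tolerance = 1e-10)

  indep <- lapply(1:3, function(j) setNames(rnorm(500), 1501:2000))
  expect_true(all(abs(pca_sites(indep)$variance_fraction - 1 / 3) < 0.08))

  expect_error(pca_sites(lapply(1:2, function(j)
    setNames(rnorm(10), 1991:2000))), "common span")
})
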