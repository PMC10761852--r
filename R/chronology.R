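# Detrending, prewhitening and chronology building.

#' Detrend a ring-width series with a modified negative exponential curve
#'
#' Fits `a * exp(-b * t) + k` (a > 0, b > 0, k >= 0) by constrained least
#' squares over the cambial-age axis t = 1..n and returns the ratio index
#' width / fitted. When the constrained fit is unattainable (non-declining
#' growth, constant series, or a boundary solution) the fit falls back to
#' the horizontal mean (or, optionally, a declining regression line), which
#' preserves low-frequency variance conservatively.
#'
#' @param series A `ring_series`.
#' @param fallback `"mean"` (default) or `"line"`; `"line"` is only used
#'   when the fitted slope is negative, otherwise the mean is used.
#' @return A `detrended_series`: years, dimensionless `index` values with
#'   expectation 1, the curve kind (`"negexp"`, `"mean"` or `"line"`),
#'   curve parameters, and a `fallback` flag.
#' @export
detrend_negexp <- function(series, fallback = c("mean", "line")) {
  stopifnot(inherits(series, "ring_series"))
  fallback <- match.arg(fallback)
  w <- series$widths
  n <- length(w)
  if (n < 10L) stop("series too short to detrend (need >= 10 rings)")
  if (all(w == 0)) stop("all-zero series cannot be detrended")
  t <- seq_len(n)

  fit <- NULL
  kind <- NA_character_
  pars <- c(a = NA_real_, b = NA_real_, k = NA_real_)
  # starting values from a crude log-linear fit of the declining part
  wbar <- mean(w)
  starts <- list(
    c(a = max(w) - min(w) + 0.1 * wbar, b = 2 / n, k = max(min(w), 0.01 * wbar)),
    c(a = wbar, b = 0.01, k = 0.5 * wbar),
    c(a = 0.5 * wbar, b = 0.1, k = 0.25 * wbar))
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(w ~ a * exp(-b * t) + k,
                        start = as.list(st),
                        lower = c(a = 0, b = 0, k = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(f)) next
    cf <- stats::coef(f)
    if (cf["a"] > 1e-4 * wbar && cf["b"] > 1e-6) {
      fitted <- cf["a"] * exp(-cf["b"] * t) + cf["k"]
      if (all(fitted > 0)) {
        fit <- fitted; kind <- "negexp"; pars <- cf
        break
      }
    }
  }
  used_fallback <- is.null(fit)
  if (used_fallback) {
    if (fallback == "line") {
      lf <- stats::lm(w ~ t)
      if (stats::coef(lf)[2L] < 0 && all(stats::fitted(lf) > 0)) {
        fit <- as.numeric(stats::fitted(lf)); kind <- "line"
      }
    }
    if (is.null(fit)) {
      fit <- rep(wbar, n); kind <- "mean"
    }
  }
  structure(
    list(series_id = series$series_id,
         years = series_years(series),
         index = as.numeric(w / fit),
         fitted = as.numeric(fit),
         kind = kind, params = pars, fallback = used_fallback,
         ar_order = NA_integer_),
    class = "detrended_series")
}

#' Remove autoregressive persistence from a detrended series
#'
#' Fits an AR(p) model with p selected by AIC over 0..`max_order`
#' (Yule-Walker), takes the innovations, and re-centres them to mean 1 so
#' the residual index remains on the chronology scale. The first p years
#' are dropped. Zero-variance input is returned unchanged with p = 0.
#'
#' @param d A `detrended_series`.
#' @param max_order Maximum AR order considered.
#' @return A `detrended_series` of residual indices with `ar_order` set.
#' @export
prewhiten <- function(d, max_order = 10L) {
  stopifnot(inherits(d, "detrended_series"))
  x <- d$index
  if (length(x) < 3L * max_order)
    max_order <- max(1L, length(x) %/% 3L)
  if (stats::var(x) < .Machine$double.eps) {
    d$ar_order <- 0L
    return(d)
  }
  fit <- stats::ar(x, aic = TRUE, order.max = max_order, method = "yule-walker")
  p <- fit$order
  if (p == 0L) {
    d$ar_order <- 0L
    return(d)
  }
  res <- fit$resid[-seq_len(p)]
  d$index <- res - mean(res) + 1
  d$years <- d$years[-seq_len(p)]
  d$fitted <- d$fitted[-seq_len(p)]
  d$ar_order <- p
  d
}

#' Tukey biweight robust mean
#'
#' Biweight location with tuning constant `c` and scale fixed at the
#' median absolute deviation from the median; the weighted-mean fixed
#' point is iterated to `tol`. With one or two values (or zero MAD) the
#' arithmetic mean (median) is returned.
#'
#' @param x Numeric vector.
#' @param c Tuning constant (9 rejects beyond 9 MADs).
#' @param tol Convergence tolerance on the location update.
#' @return The robust mean, a scalar.
#' @export
biweight_mean <- function(x, c = 9, tol = 1e-8) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n <= 2L) return(mean(x))
  med <- stats::median(x)
  S <- stats::median(abs(x - med))
  if (S <= 0) return(med)
  T0 <- med
  for (i in 1:100) {
    u <- (x - T0) / (c * S)
    w <- (1 - u^2)^2
    w[abs(u) >= 1] <- 0
    if (sum(w) == 0) return(T0)
    T1 <- sum(w * x) / sum(w)
    if (abs(T1 - T0) < tol) return(T1)
    T0 <- T1
  }
  T0
}

#' Running mean inter-series correlation (Rbar) and EPS
#'
#' Over sliding windows of `window` years advancing by `window - overlap`,
#' computes Rbar as the mean of pairwise Pearson correlations among series
#' with at least `min_overlap` common years inside the window, the mean
#' sample depth N, and the expressed population signal
#' EPS = N * Rbar / (N * Rbar + 1 - Rbar), clipped to [0, 1].
#'
#' @param m Year x series index matrix (NA outside series spans).
#' @param window Window length in years.
#' @param overlap Years of overlap between consecutive windows.
#' @param min_overlap Minimum common years for a pair to contribute.
#' @return Data frame with columns start, end, mid, rbar, n, eps; windows
#'   with fewer than two overlapping series carry NA.
#' @export
running_rbar_eps <- function(m, window = 50L, overlap = 25L,
                             min_overlap = 30L) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  years <- as.integer(rownames(m))
  step <- max(1L, window - overlap)
  starts <- seq(years[1L], max(years[1L], years[length(years)] - window + 1L),
                by = step)
  out <- data.frame(start = starts, end = pmin(starts + window - 1L,
                                               years[length(years)]))
  out$mid <- (out$start + out$end) / 2
  out$rbar <- NA_real_
  out$n <- NA_real_
  for (i in seq_len(nrow(out))) {
    sub <- m[years >= out$start[i] & years <= out$end[i], , drop = FALSE]
    keep <- colSums(!is.na(sub)) > 0L
    sub <- sub[, keep, drop = FALSE]
    if (ncol(sub) < 2L) next
    rs <- numeric(0)
    for (a in 1:(ncol(sub) - 1L)) for (b in (a + 1L):ncol(sub)) {
      ok <- !is.na(sub[, a]) & !is.na(sub[, b])
      if (sum(ok) >= min(min_overlap, nrow(sub))) {
        if (stats::sd(sub[ok, a]) > 0 && stats::sd(sub[ok, b]) > 0)
          rs <- c(rs, stats::cor(sub[ok, a], sub[ok, b]))
      }
    }
    if (length(rs) == 0L) next
    out$rbar[i] <- mean(rs)
    out$n[i] <- mean(rowSums(!is.na(sub)))
  }
  out$eps <- with(out, pmin(1, pmax(0, n * rbar / (n * rbar + 1 - rbar))))
  out
}

#' Build a standard and residual chronology from one or more collections
#'
#' Pools all series across the supplied collections (a composite is built
#' from the pooled cores, not from per-site averages), detrends each with
#' [detrend_negexp()], prewhitens each with [prewhiten()], and averages
#' across series per year with the Tukey biweight mean. Running Rbar/EPS
#' and the usual descriptive statistics (mean sensitivity, SD, lag-1
#' autocorrelation) are attached.
#'
#' @param collections A `site_collection` or list of them.
#' @param prewhiten Logical; compute the residual chronology (default TRUE).
#' @param max_order Max AR order for prewhitening.
#' @param biweight Use the biweight mean (TRUE) or arithmetic mean.
#' @param rbar_window,rbar_overlap,min_overlap Running Rbar/EPS windowing.
#' @param fallback Detrending fallback, see [detrend_negexp()].
#' @return A `chronology`: years, `std` and `res` indices, `depth`,
#'   running stats data frame, summary `stats`, and the detrended series.
#' @export
build_chronology <- function(collections, prewhiten = TRUE, max_order = 10L,
                             biweight = TRUE, rbar_window = 50L,
                             rbar_overlap = 25L, min_overlap = 30L,
                             fallback = "mean") {
  if (inherits(collections, "site_collection")) collections <- list(collections)
  if (length(collections) == 0L) stop("no collections supplied")
  series <- unlist(lapply(collections, `[[`, "series"), recursive = FALSE)
  if (length(series) == 0L) stop("no series in input")

  det <- lapply(series, detrend_negexp, fallback = fallback)
  idx_std <- .index_matrix(det)
  res <- if (prewhiten) lapply(det, prewhiten, max_order = max_order) else det
  idx_res <- .index_matrix(res)

  avg <- function(m) apply(m, 1L, if (biweight) biweight_mean else
    function(v) mean(v, na.rm = TRUE))
  std <- avg(idx_std)
  depth <- rowSums(!is.na(idx_std))
  resid_c <- avg(idx_res)
  # align residual chronology onto the standard years
  res_full <- rep(NA_real_, length(std))
  names(res_full) <- rownames(idx_std)
  res_full[rownames(idx_res)] <- resid_c

  run <- running_rbar_eps(idx_std, window = rbar_window,
                          overlap = rbar_overlap, min_overlap = min_overlap)
  structure(
    list(years = as.integer(rownames(idx_std)),
         std = unname(std), res = unname(res_full), depth = unname(depth),
         running = run,
         stats = list(std = .chron_stats(std), res = .chron_stats(res_full)),
         detrended = det,
         params = list(prewhiten = prewhiten, biweight = biweight,
                       rbar_window = rbar_window, rbar_overlap = rbar_overlap,
                       min_overlap = min_overlap)),
    class = "chronology")
}

.index_matrix <- function(det_list) {
  yrs <- range(unlist(lapply(det_list, `[[`, "years")))
  years <- yrs[1]:yrs[2]
  ids <- vapply(det_list, `[[`, character(1), "series_id")
  m <- matrix(NA_real_, length(years), length(det_list),
              dimnames = list(years, ids))
  for (j in seq_along(det_list))
    m[as.character(det_list[[j]]$years), j] <- det_list[[j]]$index
  m
}

.chron_stats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) return(list(ms = NA_real_, sd = NA_real_, ac1 = NA_real_))
  d <- diff(x)
  s <- x[-length(x)] + x[-1L]
  ms <- mean(abs(2 * d / s)[s != 0])
  list(ms = ms, sd = stats::sd(x),
       ac1 = stats::cor(x[-length(x)], x[-1L]))
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf(
    "chronology: %d-%d CE, %d series, SD %.3f, MS %.3f, AC1 %.3f\n",
    min(x$years), max(x$years), length(x$detrended),
    x$stats$std$sd, x$stats$std$ms, x$stats$std$ac1))
  invisible(x)
}

#' Chronology values as a year-indexed vector
#' @param ch A `chronology`.
#' @param type `"res"` (residual, default) or `"std"`.
#' @return Named numeric vector (names are years), NA years dropped.
#' @export
chronology_values <- function(ch, type = c("res", "std")) {
  type <- match.arg(type)
  v <- stats::setNames(ch[[type]], ch$years)
  v[!is.na(v)]
}

#' First reliable year by the EPS criterion
#'
#' Interpolates the running EPS from window midpoints to years and returns
#' the earliest year from which every subsequent year has EPS at or above
#' `threshold` (first crossings that later dip below again are skipped).
#'
#' @param ch A `chronology`.
#' @param threshold EPS threshold (conventionally 0.85).
#' @return First reliable calendar year (integer).
#' @export
truncate_by_eps <- function(ch, threshold = 0.85) {
  stopifnot(inherits(ch, "chronology"))
  run <- ch$running[!is.na(ch$running$eps), ]
  if (nrow(run) == 0L) stop("no EPS windows available")
  if (max(run$eps) < threshold)
    stop(sprintf("EPS never reaches %.2f (max attained %.3f)",
                 threshold, max(run$eps)))
  eps_y <- if (nrow(run) == 1L) rep(run$eps, length(ch$years)) else
    stats::approx(run$mid, run$eps, xout = ch$years, rule = 2)$y
  below <- which(eps_y < threshold)
  if (length(below) == 0L) return(min(ch$years))
  last_bad <- max(below)
  if (last_bad == length(ch$years))
    stop(sprintf("EPS below %.2f at the modern end (max attained %.3f)",
                 threshold, max(run$eps)))
  ch$years[last_bad + 1L]
}

#' Principal component analysis of site chronologies
#'
#' PCA on the correlation matrix of the standard chronologies over their
#' common span; used to judge whether sites share enough signal to be
#' pooled into a regional composite.
#'
#' @param chronologies List of >= 2 `chronology` objects (or year-named
#'   numeric vectors).
#' @param type `"std"` or `"res"` indices.
#' @return List with `loadings` (variables x components), `variance_fraction`
#'   (sums to 1), `common_span`, and the pairwise correlation matrix.
#' @export
pca_sites <- function(chronologies, type = "std") {
  stopifnot(length(chronologies) >= 2L)
  vs <- lapply(chronologies, function(ch)
    if (inherits(ch, "chronology")) chronology_values(ch, type = type)
    else ch[!is.na(ch)])
  common <- Reduce(intersect, lapply(vs, names))
  if (length(common) < 30L) stop("common span too short (< 30 yr)")
  m <- sapply(vs, function(v) v[common])
  colnames(m) <- paste0("site", seq_along(vs))
  R <- stats::cor(m)
  e <- eigen(R, symmetric = TRUE)
  list(loadings = e$vectors, variance_fraction = e$values / sum(e$values),
       common_span = range(as.integer(common)), correlations = R)
}
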