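# Reconstruction characterization: low-pass spline, extreme years and
# persistent wet/dry periods, per-century extreme counts, multitaper
# spectrum with red-noise significance, and Morlet wavelet power.

.cache <- new.env(parent = emptyenv())

.recon_values <- function(x) {
  if (inherits(x, "reconstruction"))
    return(stats::setNames(x$values, x$years))
  if (inherits(x, "chronology")) return(chronology_values(x))
  if (is.null(names(x))) stats::setNames(x, seq_along(x)) else x
}

# Stiffness (physical lambda, yearly units) with 50% amplitude response at
# the cutoff period, found once per cutoff by bisection against a measured
# sinusoid response, then cached.
.spline_lambda <- function(cutoff) {
  key <- paste0("lam", cutoff)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  n <- max(40L * cutoff, 400L)
  t <- seq_len(n)
  y <- sin(2 * pi * t / cutoff)
  core <- t > n * 0.15 & t < n * 0.85
  response <- function(lam_phys) {
    sm <- stats::smooth.spline(t, y, lambda = lam_phys / (n - 1)^3,
                               all.knots = TRUE)$y
    X <- cbind(sin(2 * pi * t / cutoff), cos(2 * pi * t / cutoff))
    b <- stats::coef(stats::lm(sm[core] ~ X[core, ] - 1))
    sqrt(sum(b^2))
  }
  lo <- log(1 / (2 * pi / cutoff)^4) - 3
  hi <- lo + 6
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (response(exp(mid)) > 0.5) lo <- mid else hi <- mid
    if (hi - lo < 1e-4) break
  }
  .cache[[key]] <- exp((lo + hi) / 2)
  .cache[[key]]
}

#' Low-pass cubic smoothing spline
#'
#' Smoothing spline whose amplitude frequency response is 0.5 at a
#' wavelength of `cutoff` years (the conventional "n-yr spline" of
#' dendroclimatology). Constants and linear trends pass unchanged; short
#' periods are suppressed.
#'
#' @param x Numeric series (or year-named vector / `reconstruction`).
#' @param cutoff Half-amplitude wavelength in years.
#' @return Smoothed series of the same length (names preserved).
#' @export
lowpass_spline <- function(x, cutoff = 10) {
  v <- .recon_values(x)
  n <- length(v)
  if (n < 3 * cutoff) stop("series shorter than 3 x cutoff")
  lam <- .spline_lambda(cutoff)
  sm <- stats::smooth.spline(seq_len(n), unname(v),
                             lambda = lam / (n - 1)^3, all.knots = TRUE)$y
  stats::setNames(sm, names(v))
}

#' Extreme wet and dry years
#'
#' Years beyond `mean +/- k * SD` of the full series; thresholds are
#' computed on the whole span. Lists are sorted most extreme first.
#'
#' @param x A `reconstruction` or year-named numeric vector (>= 30 yr).
#' @param k Threshold in SD units (1.5 by convention).
#' @return List: `wet` and `dry` data frames (year, value), `mean`, `sd`,
#'   `threshold_wet`, `threshold_dry`.
#' @export
find_extremes <- function(x, k = 1.5) {
  v <- .recon_values(x)
  if (length(v) < 30L) stop("span shorter than 30 years")
  m <- mean(v); s <- stats::sd(v)
  wet <- v[v > m + k * s]
  dry <- v[v < m - k * s]
  wet <- wet[order(-wet)]
  dry <- dry[order(dry)]
  list(wet = data.frame(year = as.integer(names(wet)), value = unname(wet)),
       dry = data.frame(year = as.integer(names(dry)), value = unname(dry)),
       mean = m, sd = s, k = k,
       threshold_wet = m + k * s, threshold_dry = m - k * s)
}

#' Persistent wet and dry periods from the low-pass series
#'
#' Maximal runs of at least `min_len` consecutive years whose `cutoff`-yr
#' low-pass value lies beyond `mean +/- k * SD` of the low-pass series
#' itself.
#'
#' @param x A `reconstruction` or year-named numeric vector.
#' @param cutoff Low-pass half-amplitude wavelength, years.
#' @param k Threshold in low-pass SD units.
#' @param min_len Minimum run length in years.
#' @return Data frame: kind ("wet"/"dry"), start, end, length.
#' @export
find_periods <- function(x, cutoff = 10, k = 1.0, min_len = 2L) {
  v <- .recon_values(x)
  lp <- lowpass_spline(v, cutoff)
  m <- mean(lp); s <- stats::sd(lp)
  years <- as.integer(names(v))
  runs_of <- function(flag, kind) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    if (!any(keep)) return(NULL)
    data.frame(kind = kind, start = years[starts[keep]],
               end = years[ends[keep]], length = r$lengths[keep])
  }
  out <- rbind(runs_of(lp > m + k * s, "wet"),
               runs_of(lp < m - k * s, "dry"))
  if (is.null(out))
    out <- data.frame(kind = character(0), start = integer(0),
                      end = integer(0), length = integer(0))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extreme-year counts per century
#'
#' Bins the span into hundred-year blocks from the first year (the last
#' block may be partial and is flagged and excluded from the monotone
#' trend statement).
#'
#' @param x A `reconstruction` or year-named vector (span >= 200 yr).
#' @param k Extreme threshold in SD units.
#' @return Data frame: start, end, years, n_extreme, pct, partial; with
#'   attribute `increasing` (TRUE if counts over complete centuries are
#'   non-decreasing).
#' @export
extremes_per_century <- function(x, k = 1.5) {
  v <- .recon_values(x)
  years <- as.integer(names(v))
  if (diff(range(years)) + 1L < 200L) stop("span shorter than 200 years")
  ex <- find_extremes(v, k)
  exy <- c(ex$wet$year, ex$dry$year)
  starts <- seq(min(years), max(years), by = 100L)
  out <- data.frame(start = starts, end = pmin(starts + 99L, max(years)))
  out$years <- out$end - out$start + 1L
  out$n_extreme <- vapply(seq_len(nrow(out)), function(i)
    sum(exy >= out$start[i] & exy <= out$end[i]), integer(1))
  out$pct <- 100 * out$n_extreme / out$years
  out$partial <- out$years < 100L
  full <- out$n_extreme[!out$partial]
  attr(out, "increasing") <- length(full) > 1L && all(diff(full) >= 0)
  out
}

# ---- Multitaper spectrum --------------------------------------------------

# Discrete prolate spheroidal sequences via the symmetric tridiagonal
# eigenproblem (Percival & Walden 1993, ch. 8); cached by (n, nw, k).
.dpss <- function(n, nw, k) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  W <- nw / n
  t <- 0:(n - 1)
  d <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  e <- (1:(n - 1)) * ((n - 1):1) / 2
  A <- matrix(0, n, n)
  diag(A) <- d
  A[cbind(1:(n - 1), 2:n)] <- e
  A[cbind(2:n, 1:(n - 1))] <- e
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tapers[, j] <- tapers[, j] / sqrt(sum(tapers[, j]^2))
    if (sum(tapers[, j]) < 0) tapers[, j] <- -tapers[, j]
  }
  .cache[[key]] <- tapers
  tapers
}

#' Multitaper power spectrum with AR(1) red-noise significance
#'
#' Slepian-tapered spectrum estimate (time-bandwidth `nw`, `k_tapers`
#' eigentapers) of the linearly detrended series. The null continuum is
#' the theoretical AR(1) spectrum fitted from the lag-1 autocorrelation,
#' scaled to the series variance; 95% and 99% levels use a chi-square with
#' `2 * k_tapers` degrees of freedom. Significant peaks are local maxima
#' of the spectrum above the 95% curve.
#'
#' @param x Numeric series (length >= 50); year spacing is 1.
#' @param nw Time-bandwidth product.
#' @param k_tapers Number of tapers (typically `2 * nw - 1`).
#' @return An `mtm_spectrum`: freq (cyc/yr), power, background, sig95,
#'   sig99, peaks (periods, yr, sorted), rayleigh (1/n), nw, k.
#' @export
mtm_spectrum <- function(x, nw = 2, k_tapers = 3) {
  v <- unname(.recon_values(x))
  n <- length(v)
  if (n < 50L) stop("series shorter than 50")
  if (stats::var(v) < .Machine$double.eps) stop("constant series")
  t <- seq_len(n)
  v <- stats::residuals(stats::lm(v ~ t))  # remove mean and linear trend
  sigma2 <- mean(v^2)

  tapers <- .dpss(n, nw, k_tapers)
  nfft <- 2^ceiling(log2(n) + 1)
  freq_i <- 1:(nfft / 2)
  freq <- freq_i / nfft
  P <- matrix(0, length(freq), k_tapers)
  for (j in seq_len(k_tapers)) {
    ft <- stats::fft(c(v * tapers[, j], rep(0, nfft - n)))
    P[, j] <- Mod(ft[freq_i + 1L])^2
  }
  power <- 2 * rowMeans(P)          # one-sided, unit year spacing

  r1 <- stats::cor(v[-n], v[-1L])
  r1 <- max(min(r1, 0.99), 0)
  bg <- 2 * sigma2 * (1 - r1^2) / (1 + r1^2 - 2 * r1 * cos(2 * pi * freq))
  dof <- 2 * k_tapers
  sig95 <- bg * stats::qchisq(0.95, dof) / dof
  sig99 <- bg * stats::qchisq(0.99, dof) / dof

  # one peak per contiguous significant run, located at the power-weighted
  # centroid (a tapered line spreads over the 2W bandwidth; the centroid
  # restores sub-Rayleigh localization)
  runs <- rle(power > sig95)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peaks <- numeric(0)
  for (i in which(runs$values)) {
    idx <- starts[i]:ends[i]
    peaks <- c(peaks, sum(freq[idx] * power[idx]) / sum(power[idx]))
  }
  structure(
    list(freq = freq, power = power, background = bg,
         sig95 = sig95, sig99 = sig99,
         peaks = sort(1 / peaks), rayleigh = 1 / n,
         nw = nw, k = k_tapers, n = n, variance = sigma2),
    class = "mtm_spectrum")
}

#' @export
print.mtm_spectrum <- function(x, ...) {
  cat(sprintf("mtm_spectrum: n=%d, NW=%g, K=%d; significant peaks (yr): %s\n",
              x$n, x$nw, x$k,
              if (length(x$peaks)) paste(sprintf("%.1f", x$peaks),
                                         collapse = ", ") else "none"))
  invisible(x)
}

# ---- Morlet wavelet -------------------------------------------------------

#' Continuous Morlet wavelet transform (Torrence-Compo)
#'
#' Morlet (omega0 = 6) continuous wavelet transform of the demeaned
#' series, with cone of influence at the e-folding distance sqrt(2)*scale,
#' pointwise 95% significance against the AR(1) red-noise background, and
#' the global (time-mean) wavelet spectrum.
#'
#' @param x Numeric series, length >= 64; unit year spacing.
#' @param omega0 Nondimensional Morlet frequency.
#' @param dj Scale resolution in octaves (default 1/4).
#' @return A `wavelet_result`: period (yr), time, power (period x time),
#'   coi (period above which each time is edge-affected), signif (ratio
#'   power / 95% level; > 1 is significant), in_coi logical matrix,
#'   gws (global spectrum).
#' @export
morlet_wavelet <- function(x, omega0 = 6, dj = 0.25) {
  v0 <- .recon_values(x)
  n <- length(v0)
  if (n < 64L) stop("series shorter than 64")
  if (stats::var(v0) < .Machine$double.eps) stop("constant series")
  v <- unname(v0) - mean(v0)
  sigma2 <- mean(v^2)

  nfft <- 2^ceiling(log2(n))
  if (nfft < 2 * n) nfft <- 2 * nfft    # full zero padding
  omega <- 2 * pi * c(0:(nfft / 2), -((nfft / 2 - 1):1)) / nfft
  fx <- stats::fft(c(v, rep(0, nfft - n)))

  s0 <- 2
  J <- floor(log2(n / s0) / dj)
  scales <- s0 * 2^(dj * (0:J))
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  period <- fourier_factor * scales

  W <- matrix(0 + 0i, length(scales), n)
  norm_const <- pi^(-1 / 4)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- norm_const * sqrt(2 * pi * s) * exp(-(s * omega - omega0)^2 / 2)
    psi[omega <= 0] <- 0
    w <- stats::fft(fx * psi, inverse = TRUE) / nfft
    W[j, ] <- w[seq_len(n)]
  }
  power <- Mod(W)^2

  tgrid <- seq_len(n)
  coi_t <- pmin(tgrid - 1, n - tgrid) + 1e-8
  coi <- fourier_factor / sqrt(2) * coi_t        # max credible period per time
  in_coi <- outer(period, coi, `>`)

  r1 <- stats::cor(v[-n], v[-1L]); r1 <- max(min(r1, 0.99), 0)
  fper <- 1 / period
  bg <- sigma2 * (1 - r1^2) / (1 + r1^2 - 2 * r1 * cos(2 * pi * fper))
  lev95 <- bg * stats::qchisq(0.95, 2) / 2
  signif <- sweep(power, 1L, lev95, `/`)

  structure(
    list(period = period, time = as.integer(names(v0)) %||% tgrid,
         power = power, coi = coi, signif = signif, in_coi = in_coi,
         gws = rowMeans(power), background = bg, omega0 = omega0, n = n),
    class = "wavelet_result")
}

`%||%` <- function(a, b) if (is.null(a) || all(is.na(a))) b else a

#' @export
print.wavelet_result <- function(x, ...) {
  gp <- x$period[which.max(x$gws)]
  cat(sprintf(
    "wavelet_result: %d times x %d scales (%.1f-%.1f yr); global peak at %.1f yr\n",
    ncol(x$power), nrow(x$power), min(x$period), max(x$period), gp))
  invisible(x)
}
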