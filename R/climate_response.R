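# Growth-climate response: seasonal aggregation, bootstrapped correlation
# functions over a 17-month dendroclimatic window, seascorr-style partial
# correlations, moving-window correlations, and climate-mode index tables.

# Signed-month convention: positive m = month m of the growth year,
# negative m = month |m| of the previous year. A window is given as
# c(start, end) and expands chronologically, e.g. c(-6, 10) = previous
# June .. current October (17 months).
.expand_window <- function(window) {
  pos <- function(s) ifelse(s > 0, s + 12L, -s)
  p <- pos(window[1L]):pos(window[2L])
  if (any(p < 1L) || any(p > 24L)) stop("window outside pJan..Dec range")
  data.frame(pos = p,
             month = ifelse(p > 12L, p - 12L, p),
             prev = p <= 12L)
}

.signed_label <- function(month, prev)
  paste0(ifelse(prev, "p", ""), month.abb[month])

#' Aggregate monthly climate to a seasonal target series
#'
#' Builds a year-indexed seasonal series (e.g. the February-June
#' precipitation total) from monthly climate. Previous-year months are
#' pulled from year - 1. A year's value exists only if every member month
#' is present.
#'
#' @param mc A `monthly_climate`.
#' @param variable Variable name in `mc$data`.
#' @param window Signed-month window `c(start, end)`; negative months are
#'   previous-year months (e.g. `c(2, 6)` = Feb-Jun, `c(-6, 10)` =
#'   previous June through current October).
#' @param aggregation `"sum"` (default for precipitation) or `"mean"`
#'   (temperatures).
#' @return A `seasonal_series`: list with `values` (year-named numeric),
#'   `variable`, `window`, `aggregation`.
#' @export
seasonalize <- function(mc, variable = "prec", window = c(2, 6),
                        aggregation = if (variable == "prec") "sum" else "mean") {
  stopifnot(inherits(mc, "monthly_climate"))
  if (!variable %in% names(mc$data)) stop("variable '", variable, "' absent")
  w <- .expand_window(window)
  m <- mc$data[[variable]]
  yrs <- mc$years
  agg <- if (aggregation == "sum") rowSums else rowMeans
  vals <- vapply(seq_along(yrs), function(i) {
    v <- numeric(nrow(w))
    for (j in seq_len(nrow(w))) {
      yi <- if (w$prev[j]) i - 1L else i
      v[j] <- if (yi >= 1L) m[yi, w$month[j]] else NA_real_
    }
    if (anyNA(v)) NA_real_ else agg(matrix(v, 1L))
  }, numeric(1))
  structure(list(values = stats::setNames(vals, yrs), variable = variable,
                 window = window, aggregation = aggregation),
            class = "seasonal_series")
}

.season_defaults <- list(DJF = c(-12, 2), MAM = c(3, 5), MAMJ = c(3, 6),
                         FMAMJ = c(2, 6), JJAS = c(6, 9))

# complete-pair Pearson correlation of two year-named vectors
.paired <- function(a, b) {
  common <- intersect(names(a), names(b))
  x <- a[common]; y <- b[common]
  ok <- !is.na(x) & !is.na(y)
  list(x = unname(x[ok]), y = unname(y[ok]),
       years = as.integer(common[ok]))
}

#' Bootstrapped monthly and seasonal correlation function
#'
#' Pearson correlations between a chronology and each month of a signed
#' dendroclimatic window (default previous June .. current October, 17
#' months) plus standard seasonal windows, with classical pairs-bootstrap
#' 95% percentile intervals; a coefficient is flagged significant when its
#' interval excludes zero. Per-coefficient intervals are not adjusted for
#' multiplicity.
#'
#' @param ch A `chronology` (or year-named numeric vector).
#' @param mc A `monthly_climate`.
#' @param variables Climate variables to correlate.
#' @param window Signed-month window for the monthly coefficients.
#' @param seasons Named list of seasonal windows.
#' @param nboot Bootstrap replicates.
#' @param seed RNG seed (bootstrap is deterministic under it).
#' @param type Chronology type passed to [chronology_values()].
#' @return Data frame: variable, label, kind, r, lo, hi, sig, n.
#' @export
bootstrap_corrfun <- function(ch, mc, variables = c("prec", "tmean"),
                              window = c(-6, 10),
                              seasons = .season_defaults,
                              nboot = 1000L, seed = 1L, type = "res") {
  v <- if (inherits(ch, "chronology")) chronology_values(ch, type) else ch
  set.seed(seed)
  rows <- list()
  for (var in variables) {
    if (!var %in% names(mc$data)) {
      warning("variable '", var, "' absent; skipped")
      next
    }
    w <- .expand_window(window)
    targets <- lapply(seq_len(nrow(w)), function(j)
      seasonalize(mc, var, rep(ifelse(w$prev[j], -w$month[j], w$month[j]), 2)))
    labels <- .signed_label(w$month, w$prev)
    kinds <- rep("month", nrow(w))
    for (sn in names(seasons)) {
      targets <- c(targets, list(seasonalize(mc, var, seasons[[sn]])))
      labels <- c(labels, sn)
      kinds <- c(kinds, "season")
    }
    for (j in seq_along(targets)) {
      p <- .paired(v, targets[[j]]$values)
      n <- length(p$x)
      if (n < 30L) next
      r <- stats::cor(p$x, p$y)
      bs <- vapply(seq_len(nboot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        if (stats::sd(p$x[i]) == 0 || stats::sd(p$y[i]) == 0) return(NA_real_)
        stats::cor(p$x[i], p$y[i])
      }, numeric(1))
      ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = var, label = labels[j], kind = kinds[j],
        r = r, lo = ci[1L], hi = ci[2L],
        sig = ci[1L] > 0 | ci[2L] < 0, n = n)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "nboot") <- nboot
  attr(out, "seed") <- seed
  out
}

#' Seasonal partial-correlation (seascorr-style) analysis
#'
#' For every ending month and season length, correlates the chronology
#' with the primary variable (simple Pearson r) and with the part of the
#' secondary variable that is orthogonal to the primary (semipartial
#' correlation, so the secondary coefficient reflects information beyond
#' the primary signal).
#' Significance comes from a Monte-Carlo null of `nsim` AR(1) surrogate
#' chronologies that preserve the chronology's lag-1 autocorrelation:
#' empirical non-exceedance probabilities of |r|.
#'
#' @param ch A `chronology` or year-named vector.
#' @param mc A `monthly_climate`.
#' @param primary,secondary Variable names (precipitation and temperature
#'   by convention; primary aggregates by its default, see [seasonalize()]).
#' @param season_lengths Season lengths in months, each ending at the
#'   ending month.
#' @param nsim Surrogates for the null distribution.
#' @param seed RNG seed.
#' @param alpha Significance level.
#' @param type Chronology type.
#' @return Data frame: end_month, length, variable (primary/secondary),
#'   r, p, sig.
#' @export
seascorr <- function(ch, mc, primary = "prec", secondary = "tmean",
                     season_lengths = c(1, 3, 5, 12), nsim = 1000L,
                     seed = 1L, alpha = 0.05, type = "res") {
  v <- if (inherits(ch, "chronology")) chronology_values(ch, type) else ch
  for (nm in c(primary, secondary))
    if (!nm %in% names(mc$data)) stop("variable '", nm, "' absent")
  set.seed(seed)

  cases <- expand.grid(end_month = 1:12, len = season_lengths)
  prim <- sec <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    endpos <- cases$end_month[i] + 12L
    startpos <- endpos - cases$len[i] + 1L
    win <- c(if (startpos <= 12L) -startpos else startpos - 12L,
             cases$end_month[i])
    prim[[i]] <- seasonalize(mc, primary, win)$values
    sec[[i]] <- seasonalize(mc, secondary, win)$values
  }
  common <- names(v)
  for (i in seq_len(nrow(cases))) {
    common <- intersect(common, names(prim[[i]])[!is.na(prim[[i]])])
    common <- intersect(common, names(sec[[i]])[!is.na(sec[[i]])])
  }
  if (length(common) < 30L) stop("overlap shorter than 30 years")
  x <- unname(v[common])
  n <- length(x)

  safe_cor <- function(a, b)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
  stat_pair <- function(x) vapply(seq_len(nrow(cases)), function(i) {
    p <- unname(prim[[i]][common]); s <- unname(sec[[i]][common])
    r_xp <- safe_cor(x, p)
    r_xs <- safe_cor(x, s); r_ps <- safe_cor(p, s)
    # part (semipartial) correlation: the primary signal is removed from
    # the secondary variable, not from the chronology, so a secondary
    # orthogonal to the primary keeps its simple correlation
    part <- (r_xs - r_xp * r_ps) / sqrt(pmax(1 - r_ps^2, 1e-12))
    c(r_xp, part)
  }, numeric(2))

  obs <- stat_pair(x)
  phi <- stats::cor(x[-n], x[-1L])
  null <- array(NA_real_, c(2L, nrow(cases), nsim))
  for (b in seq_len(nsim))
    null[, , b] <- stat_pair(.ar1_path(n, max(min(phi, 0.99), 0), stats::sd(x)))
  pvals <- obs
  for (k in 1:2) for (i in seq_len(nrow(cases)))
    pvals[k, i] <- mean(abs(null[k, i, ]) >= abs(obs[k, i]))

  out <- rbind(
    data.frame(end_month = cases$end_month, length = cases$len,
               variable = "primary", r = obs[1L, ], p = pvals[1L, ]),
    data.frame(end_month = cases$end_month, length = cases$len,
               variable = "secondary", r = obs[2L, ], p = pvals[2L, ]))
  out$sig <- out$p < alpha
  attr(out, "primary") <- primary
  attr(out, "secondary") <- secondary
  attr(out, "n") <- n
  out
}

#' Moving-window growth-climate correlations
#'
#' Pearson correlations between the chronology and monthly/seasonal
#' climate in sliding calibration windows, to check the temporal stability
#' of the response.
#'
#' @param ch A `chronology` or year-named vector.
#' @param mc A `monthly_climate`.
#' @param variable Climate variable.
#' @param window Window length, years.
#' @param step Window advance, years.
#' @param months Current-year months to include.
#' @param seasons Named list of seasonal windows.
#' @param alpha Two-tailed significance level per window.
#' @param type Chronology type.
#' @return Long data frame: window_start, window_end, label, r, p, sig.
#' @export
moving_corr <- function(ch, mc, variable = "prec", window = 30L, step = 2L,
                        months = 1:12, seasons = .season_defaults,
                        alpha = 0.05, type = "res") {
  v <- if (inherits(ch, "chronology")) chronology_values(ch, type) else ch
  targets <- c(lapply(months, function(m) seasonalize(mc, variable, c(m, m))),
               lapply(seasons, function(w) seasonalize(mc, variable, w)))
  labels <- c(month.abb[months], names(seasons))
  p0 <- .paired(v, targets[[1L]]$values)
  if (length(p0$years) < window) stop("overlap shorter than the window")
  starts <- seq(min(p0$years), max(p0$years) - window + 1L, by = step)
  rows <- list()
  for (s0 in starts) for (j in seq_along(targets)) {
    p <- .paired(v, targets[[j]]$values)
    keep <- p$years >= s0 & p$years <= s0 + window - 1L
    if (sum(keep) < window * 0.8) next
    ct <- stats::cor.test(p$x[keep], p$y[keep])
    rows[[length(rows) + 1L]] <- data.frame(
      window_start = s0, window_end = s0 + window - 1L, label = labels[j],
      r = unname(ct$estimate), p = ct$p.value, sig = ct$p.value < alpha)
  }
  do.call(rbind, rows)
}

#' Correlation with a monthly climate-mode index
#'
#' Pearson correlation (and two-tailed p) between a year-indexed series
#' (reconstruction or chronology) and each calendar month of a monthly
#' climate-mode index (ENSO, AMO, NAO, ...).
#'
#' @param x Year-named numeric vector, `chronology`, or `reconstruction`.
#' @param index A `monthly_climate` with one variable, or a year x 12
#'   matrix with year rownames.
#' @param months Calendar months to test.
#' @return Data frame: month, r, p, n.
#' @export
index_corr <- function(x, index, months = 1:12) {
  if (inherits(x, "chronology")) x <- chronology_values(x)
  if (inherits(x, "reconstruction"))
    x <- stats::setNames(x$values, x$years)
  m <- if (inherits(index, "monthly_climate")) index$data[[1L]] else index
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  rows <- lapply(months, function(mo) {
    idx <- stats::setNames(m[, mo], rownames(m))
    p <- .paired(x, idx)
    if (length(p$x) < 30L) stop("overlap shorter than 30 years")
    ct <- stats::cor.test(p$x, p$y)
    data.frame(month = mo, r = unname(ct$estimate), p = ct$p.value,
               n = length(p$x))
  })
  do.call(rbind, rows)
}
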