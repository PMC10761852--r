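# Linear transfer function, calibration/verification statistics, and the
# truncated reconstruction with an uncertainty band.

#' Durbin-Watson statistic
#'
#' `DW = sum(diff(e)^2) / sum(e^2)`, in [0, 4]; values near 2 indicate
#' uncorrelated residuals.
#'
#' @param residuals Numeric vector, n >= 3.
#' @return The statistic.
#' @export
durbin_watson <- function(residuals) {
  e <- residuals[!is.na(residuals)]
  if (length(e) < 3L) stop("need at least 3 residuals")
  if (stats::var(e) < .Machine$double.eps) stop("zero residual variance")
  sum(diff(e)^2) / sum(e^2)
}

#' Sign test on first-difference agreement
#'
#' Counts year-to-year changes whose direction agrees between observed and
#' predicted series; pairs in which either difference is zero are dropped.
#' Two-tailed binomial p under P(agree) = 1/2.
#'
#' @param obs,pred Paired numeric vectors (same length, n >= 3).
#' @return List: agreements, disagreements, n, p.
#' @export
sign_test <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  if (length(obs) < 3L) stop("need at least 3 paired values")
  s <- sign(diff(obs)) * sign(diff(pred))
  s <- s[s != 0]
  agree <- sum(s > 0)
  n <- length(s)
  p <- if (n > 0) stats::binom.test(agree, n, 0.5)$p.value else NA_real_
  list(agreements = agree, disagreements = n - agree, n = n, p = p)
}

#' Product-mean test (Fritts)
#'
#' Products of observed and predicted departures from the calibration mean
#' are split into positives (count n1, mean m1, sd s1) and the absolute
#' values of negatives (n2, m2, s2);
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` (Welch-type denominator).
#' A positive t indicates that correct joint departures dominate.
#'
#' @param obs,pred Paired numeric vectors, n >= 5.
#' @param cal_mean Calibration-period mean used as the departure origin.
#' @return List: t, n_pos, n_neg, mean_pos, mean_neg, degenerate (TRUE when
#'   one of the groups is empty; t is then +Inf by convention).
#' @export
product_mean_test <- function(obs, pred, cal_mean) {
  stopifnot(length(obs) == length(pred))
  if (length(obs) < 5L) stop("need at least 5 paired values")
  z <- (obs - cal_mean) * (pred - cal_mean)
  pos <- z[z > 0]
  neg <- abs(z[z < 0])
  if (length(pos) == 0L || length(neg) == 0L)
    return(list(t = Inf, n_pos = length(pos), n_neg = length(neg),
                mean_pos = if (length(pos)) mean(pos) else NA_real_,
                mean_neg = if (length(neg)) mean(neg) else NA_real_,
                degenerate = TRUE))
  t <- (mean(pos) - mean(neg)) /
    sqrt(stats::var(pos) / length(pos) + stats::var(neg) / length(neg))
  list(t = t, n_pos = length(pos), n_neg = length(neg),
       mean_pos = mean(pos), mean_neg = mean(neg), degenerate = FALSE)
}

#' Reduction of error / coefficient of efficiency
#'
#' `RE = 1 - SSE / sum((obs - cal_mean)^2)`;
#' `CE = 1 - SSE / sum((obs - mean(obs))^2)` (verification-period mean).
#' Both are at most 1; positive values beat the respective mean-only null
#' predictor, and CE <= RE always.
#'
#' @param obs,pred Paired numeric vectors on the verification set.
#' @param cal_mean Calibration-period mean of the predictand.
#' @return List with `re` and `ce`.
#' @export
re_ce <- function(obs, pred, cal_mean) {
  sse <- sum((obs - pred)^2)
  list(re = 1 - sse / sum((obs - cal_mean)^2),
       ce = 1 - sse / sum((obs - mean(obs))^2))
}

.target_values <- function(target) {
  if (inherits(target, "seasonal_series")) target$values else target
}

#' Fit the linear transfer function
#'
#' Ordinary least squares of the seasonal climate target on the chronology
#' index over the calibration span, with the full calibration statistic
#' set (r, R2, adjusted R2, F, p, RMSE, Durbin-Watson).
#'
#' @param ch A `chronology` or year-named index vector.
#' @param target A `seasonal_series` or year-named vector (e.g. Feb-Jun
#'   precipitation, mm).
#' @param span Optional `c(first, last)` calibration years.
#' @param type Chronology type (`"res"` default, the reconstruction
#'   convention here).
#' @return A `transfer_model`: slope (mm per index unit), intercept (mm),
#'   calibration years, stats, fitted values and residuals.
#' @export
fit_transfer <- function(ch, target, span = NULL, type = "res") {
  v <- if (inherits(ch, "chronology")) chronology_values(ch, type) else ch
  y <- .target_values(target)
  p <- .paired(v, y)
  if (!is.null(span)) {
    keep <- p$years >= span[1L] & p$years <= span[2L]
    p <- list(x = p$x[keep], y = p$y[keep], years = p$years[keep])
  }
  n <- length(p$x)
  if (n < 25L) stop("calibration overlap shorter than 25 years")
  if (stats::sd(p$x) == 0) stop("zero-variance predictor")
  fit <- stats::lm(y ~ x, data = data.frame(x = p$x, y = p$y))
  e <- stats::residuals(fit)
  r <- stats::cor(p$x, p$y)
  R2 <- r^2
  sm <- suppressWarnings(summary(fit))  # noise-free targets are legitimate
  stats <- list(
    r = r, R2 = R2, R2adj = sm$adj.r.squared,
    RMSE = sqrt(mean(e^2)),
    F = unname(sm$fstatistic[1L]),
    p = stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                  lower.tail = FALSE),
    DW = tryCatch(durbin_watson(e), error = function(cond) NA_real_))
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         years = p$years, index = p$x, obs = p$y,
         fitted = unname(stats::fitted(fit)), residuals = unname(e),
         cal_mean = mean(p$y), stats = stats,
         slope_ci = unname(suppressWarnings(stats::confint(fit))[2L, ]),
         type = type),
    class = "transfer_model")
}

#' @export
print.transfer_model <- function(x, ...) {
  cat(sprintf(
    "transfer_model: target = %.2f * index %+.2f  (cal %d-%d, n=%d)\n",
    x$slope, x$intercept, min(x$years), max(x$years), length(x$years)))
  cat(sprintf("  r=%.3f R2=%.3f R2adj=%.3f RMSE=%.2f F=%.1f DW=%.2f\n",
              x$stats$r, x$stats$R2, x$stats$R2adj, x$stats$RMSE,
              x$stats$F, x$stats$DW))
  invisible(x)
}

#' Leave-one-out cross-validation of the transfer model
#'
#' Each calibration year is predicted from a model fitted without it
#' (computed via the hat matrix). RE is taken against the full-calibration
#' mean; PRESS is the sum of squared LOOCV residuals; sign and
#' product-mean tests are run on the LOOCV predictions.
#'
#' @param model A `transfer_model`.
#' @return List of validation statistics: r, R2, RMSE, RE, PRESS,
#'   sign (list), pmt (list), predictions.
#' @export
loocv <- function(model) {
  stopifnot(inherits(model, "transfer_model"))
  x <- model$index; y <- model$obs
  n <- length(x)
  h <- 1 / n + (x - mean(x))^2 / sum((x - mean(x))^2)
  e_cv <- model$residuals / (1 - h)
  pred <- y - e_cv
  rc <- re_ce(y, pred, model$cal_mean)
  list(r = stats::cor(y, pred), R2 = stats::cor(y, pred)^2,
       RMSE = sqrt(mean(e_cv^2)), RE = rc$re, PRESS = sum(e_cv^2),
       sign = sign_test(y, pred),
       pmt = product_mean_test(y, pred, model$cal_mean),
       predictions = stats::setNames(pred, model$years))
}

#' Split-sample calibration/verification
#'
#' Splits the calibration span at `split_year` (default: median year),
#' fits on each half and verifies on the other. Verification R2 is the
#' squared Pearson correlation of observed and predicted values; RE uses
#' the calibration-half mean and CE the verification-half mean.
#'
#' @param ch A `chronology` or year-named index vector.
#' @param target A `seasonal_series` or year-named vector.
#' @param span Optional calibration span `c(first, last)`.
#' @param split_year Last year of the early half.
#' @param type Chronology type.
#' @param min_half Minimum years per half (12 by default; lower it only
#'   for toy data).
#' @return List with elements `early_cal` and `late_cal`, each holding
#'   `calibration` (span, R2, R2adj) and `verification` (span, R2, RE, CE,
#'   RMSE, sign, pmt), plus the `split_year`.
#' @export
split_sample <- function(ch, target, span = NULL, split_year = NULL,
                         type = "res", min_half = 12L) {
  v <- if (inherits(ch, "chronology")) chronology_values(ch, type) else ch
  y <- .target_values(target)
  p <- .paired(v, y)
  if (!is.null(span)) {
    keep <- p$years >= span[1L] & p$years <= span[2L]
    p <- list(x = p$x[keep], y = p$y[keep], years = p$years[keep])
  }
  if (is.null(split_year))
    split_year <- stats::median(p$years)
  early <- p$years <= split_year
  if (sum(early) < min_half || sum(!early) < min_half)
    stop("each half needs at least ", min_half, " years")

  one_direction <- function(cal, ver) {
    xc <- p$x[cal]; yc <- p$y[cal]
    fit <- stats::lm(yc ~ xc)
    pred <- stats::coef(fit)[1L] + stats::coef(fit)[2L] * p$x[ver]
    rc <- re_ce(p$y[ver], pred, mean(yc))
    n <- sum(cal)
    R2c <- stats::cor(xc, yc)^2
    list(calibration = list(
      span = range(p$years[cal]), n = n, R2 = R2c,
      R2adj = 1 - (1 - R2c) * (n - 1) / (n - 2)),
      verification = list(
        span = range(p$years[ver]), n = sum(ver),
        R2 = stats::cor(p$y[ver], pred)^2,
        RE = rc$re, CE = rc$ce,
        RMSE = sqrt(mean((p$y[ver] - pred)^2)),
        sign = sign_test(p$y[ver], pred),
        pmt = product_mean_test(p$y[ver], pred, mean(yc))))
  }
  list(early_cal = one_direction(early, !early),
       late_cal = one_direction(!early, early),
       split_year = split_year)
}

#' Apply the transfer model back in time
#'
#' Predicts the seasonal climate target for every chronology year from
#' `truncation_year` onward, with a symmetric uncertainty band of plus or
#' minus one calibration RMSE (configurable multiplier). Negative
#' predicted precipitation is possible under a linear model and is
#' flagged, not clipped.
#'
#' @param model A `transfer_model`.
#' @param ch The `chronology` used for prediction.
#' @param truncation_year First reliable year (from [truncate_by_eps()]).
#' @param band RMSE multiplier for the uncertainty band.
#' @return A `reconstruction`: years, values (mm), lower/upper band,
#'   long-term mean and SD, `negative_years` flag list.
#' @export
reconstruct <- function(model, ch, truncation_year, band = 1) {
  stopifnot(inherits(model, "transfer_model"))
  v <- if (inherits(ch, "chronology")) chronology_values(ch, model$type) else ch
  yrs <- as.integer(names(v))
  if (truncation_year < min(yrs) || truncation_year > max(yrs))
    stop("truncation year ", truncation_year, " outside chronology span ",
         min(yrs), "-", max(yrs))
  keep <- yrs >= truncation_year
  pred <- model$slope * unname(v[keep]) + model$intercept
  rmse <- model$stats$RMSE
  structure(
    list(years = yrs[keep], values = pred,
         lower = pred - band * rmse, upper = pred + band * rmse,
         rmse = rmse, band = band,
         mean = mean(pred), sd = stats::sd(pred),
         negative_years = yrs[keep][pred < 0],
         truncation_year = truncation_year,
         model = model),
    class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf(
    "reconstruction: %d-%d (%d yr), mean %.1f mm, SD %.1f mm, band +/- %.1f mm\n",
    min(x$years), max(x$years), length(x$years), x$mean, x$sd,
    x$band * x$rmse))
  invisible(x)
}
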