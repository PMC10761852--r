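# Cross-dating quality checks: Gleichlaeufigkeit and COFECHA-style
# segment correlations against a leave-one-out master.

#' Gleichlaeufigkeit (sign agreement) between two dated series
#'
#' The proportion of overlapping year-to-year changes whose signs agree;
#' pairs in which either series has a zero first difference count one half
#' by convention. Symmetric in its arguments and invariant to adding a
#' constant to either series.
#'
#' @param a,b Year-named numeric vectors or `ring_series`.
#' @return Proportion in [0, 1].
#' @export
glk <- function(a, b) {
  a <- .as_year_vector(a); b <- .as_year_vector(b)
  common <- intersect(names(a), names(b))
  common <- as.character(sort(as.integer(common)))
  if (length(common) < 2L) stop("overlap shorter than 2 years")
  da <- sign(diff(a[common]))
  db <- sign(diff(b[common]))
  agree <- ifelse(da == 0 | db == 0, 0.5, as.numeric(da == db))
  mean(agree)
}

.as_year_vector <- function(x) {
  if (inherits(x, "ring_series"))
    return(stats::setNames(x$widths, series_years(x)))
  if (is.null(names(x))) stop("series must be year-named or a ring_series")
  x[!is.na(x)]
}

#' t-value associated with a correlation
#' @param r Pearson correlation.
#' @param n Number of pairs.
#' @return t statistic `r * sqrt((n - 2) / (1 - r^2))`.
#' @export
corr_tvalue <- function(r, n) r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))

# one-tailed critical correlation at level alpha for n pairs
.critical_r <- function(alpha, n) {
  t <- stats::qt(1 - alpha, df = n - 2)
  t / sqrt(n - 2 + t^2)
}

# detrended, prewhitened index of every series, as year-named vectors;
# the same AR machinery as the chronology module, for internal consistency
.prep_indices <- function(collection) {
  lapply(collection$series, function(s) {
    d <- prewhiten(detrend_negexp(s))
    stats::setNames(d$index, d$years)
  })
}

# leave-one-out master: biweight mean of the other series' standardized
# prewhitened indices
.loo_master <- function(prepped, exclude) {
  others <- prepped[names(prepped) != exclude]
  yrs <- range(unlist(lapply(others, function(v) as.integer(names(v)))))
  years <- yrs[1]:yrs[2]
  m <- matrix(NA_real_, length(years), length(others),
              dimnames = list(years, names(others)))
  for (j in seq_along(others))
    m[names(others[[j]]), j] <- scale(others[[j]])[, 1L]
  master <- stats::setNames(apply(m, 1L, biweight_mean), years)
  master[!is.na(master)]
}

.segment_check_impl <- function(series_id, prepped, seg_len, seg_lag,
                                max_lag, alpha) {
  test <- prepped[[series_id]]
  master <- .loo_master(prepped, series_id)
  common <- sort(as.integer(intersect(names(test), names(master))))
  if (length(common) < seg_len)
    stop("overlap with master (", length(common),
         " yr) shorter than segment length for '", series_id, "'")
  starts <- seq(common[1L], common[length(common)] - seg_len + 1L, by = seg_lag)
  rcrit <- .critical_r(alpha, seg_len)
  rows <- lapply(starts, function(s0) {
    seg_years <- s0:(s0 + seg_len - 1L)
    x <- test[as.character(seg_years)]
    lags <- -max_lag:max_lag
    rs <- vapply(lags, function(L) {
      ym <- master[as.character(seg_years + L)]
      ok <- !is.na(x) & !is.na(ym)
      if (sum(ok) < seg_len / 2) return(NA_real_)
      stats::cor(x[ok], ym[ok])
    }, numeric(1))
    r0 <- unname(rs[lags == 0L])
    best <- lags[which.max(rs)]
    data.frame(start = s0, end = s0 + seg_len - 1L, n = seg_len,
               r = r0, best_lag = best,
               r_best = max(rs, na.rm = TRUE),
               t = corr_tvalue(r0, seg_len),
               flag = is.na(r0) || r0 < rcrit || best != 0L)
  })
  out <- do.call(rbind, rows)
  attr(out, "critical_r") <- rcrit
  attr(out, "glk") <- glk(test, master)
  attr(out, "series_id") <- series_id
  out
}

#' COFECHA-style segment check of one series against the collection
#'
#' Builds a leave-one-out master (biweight mean of the other series'
#' detrended, prewhitened, standardized indices), cuts the test series
#' into segments of `seg_len` years lagged by `seg_lag`, and correlates
#' each segment with the master at lags `-max_lag..+max_lag`. A segment is
#' flagged when its lag-0 correlation falls below the one-tailed critical
#' r at `alpha`, or when a nonzero lag beats lag 0. Positive best lag
#' means the series appears dated too old (its values match the master
#' that many years later).
#'
#' @param series_id Id of the series to check (must be in the collection).
#' @param collection A `site_collection` with >= 3 series.
#' @param seg_len,seg_lag Segment length and spacing in years (COFECHA
#'   conventions: 50 and 25).
#' @param max_lag Maximum dating offset searched.
#' @param alpha One-tailed significance level for the critical r.
#' @return Data frame: segment start/end, n, r (lag 0), best_lag, r_best,
#'   t, flag; attributes `critical_r` and `glk` (vs the master).
#' @export
segment_check <- function(series_id, collection, seg_len = 50L, seg_lag = 25L,
                          max_lag = 10L, alpha = 0.01) {
  stopifnot(inherits(collection, "site_collection"))
  if (!series_id %in% names(collection$series))
    stop("series '", series_id, "' not found in collection")
  if (length(collection$series) < 3L)
    stop("need at least 3 series for a leave-one-out master")
  .segment_check_impl(series_id, .prep_indices(collection),
                      seg_len, seg_lag, max_lag, alpha)
}

#' Cross-date every series in a collection
#'
#' Runs the segment check for each series against its leave-one-out
#' master and summarises overall correlation, GLK, and flagged segments.
#'
#' @inheritParams segment_check
#' @return List with `segments` (one data frame per series), a `summary`
#'   data frame (series, r_master, glk, n_segments, n_flagged), and the
#'   critical r used.
#' @export
crossdate <- function(collection, seg_len = 50L, seg_lag = 25L,
                      max_lag = 10L, alpha = 0.01) {
  stopifnot(inherits(collection, "site_collection"))
  if (length(collection$series) < 3L)
    stop("need at least 3 series for a leave-one-out master")
  prepped <- .prep_indices(collection)
  ids <- names(collection$series)
  segs <- lapply(ids, function(id)
    .segment_check_impl(id, prepped, seg_len, seg_lag, max_lag, alpha))
  names(segs) <- ids
  summary <- do.call(rbind, lapply(ids, function(id) {
    s <- segs[[id]]
    data.frame(series = id,
               r_master = stats::weighted.mean(s$r, s$n, na.rm = TRUE),
               glk = attr(s, "glk"),
               n_segments = nrow(s), n_flagged = sum(s$flag))
  }))
  list(segments = segs, summary = summary,
       critical_r = attr(segs[[1L]], "critical_r"))
}
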