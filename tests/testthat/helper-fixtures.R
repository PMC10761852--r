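# Shared fixtures and independent oracles, built in code at test time.

.fx <- new.env(parent = emptyenv())

# moderate synthetic scenario shared across test files (computed once)
fx_climate <- function() {
  if (is.null(.fx$climate))
    .fx$climate <- simulate_climate(climate_sim_config(years = 1800:2018,
                                                       seed = 101L))
  .fx$climate
}

fx_forest <- function() {
  if (is.null(.fx$forest))
    .fx$forest <- simulate_forest(
      forest_sim_config(n_sites = 2L, trees_per_site = 4L, seed = 102L),
      fx_climate())
  .fx$forest
}

fx_chron <- function() {
  if (is.null(.fx$chron))
    .fx$chron <- build_chronology(fx_forest()$collections)
  .fx$chron
}

# wrap a plain vector as a detrended series for prewhiten()
make_detrended <- function(x, first_year = 1800L) {
  structure(
    list(series_id = "TEST", years = seq(first_year, length.out = length(x)),
         index = as.numeric(x), fitted = rep(1, length(x)),
         kind = "mean", params = c(a = NA, b = NA, k = NA),
         fallback = FALSE, ar_order = NA_integer_),
    class = "detrended_series")
}

# random valid collection for round-trip property tests
random_collection <- function(seed, n_series = 4L) {
  set.seed(seed)
  series <- lapply(seq_len(n_series), function(j) {
    n <- sample(12:180, 1L)
    w <- round(pmax(0, 1.2 + cumsum(rnorm(n, 0, 0.08))), 2L)
    w[sample(n, size = rbinom(1L, 2L, 0.3))] <- 0  # missing rings
    ring_series(sprintf("R%02d%03d", j, seed %% 1000L),
                sample(1300:1900, 1L), w)
  })
  site_collection(series, site_id = "RAND")
}

# independent biweight-location oracle: plain fixed-point iteration from
# the defining weighted mean, started at the plain mean, run to 1e-12
biweight_oracle <- function(x, c = 9) {
  med <- median(x)
  S <- median(abs(x - med))
  if (S <= 0) return(med)
  T0 <- mean(x)
  for (i in 1:500) {
    u <- (x - T0) / (c * S)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    T1 <- sum(w * x) / sum(w)
    if (abs(T1 - T0) < 1e-12) break
    T0 <- T1
  }
  T1
}

# tiny monthly climate with fully specified precipitation values
toy_climate <- function(years, prec, tmean = NULL) {
  data <- list(prec = prec)
  if (!is.null(tmean)) data$tmean <- tmean
  monthly_climate(data, years, station_id = "TOY")
}
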