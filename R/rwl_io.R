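# Tucson/RWL decadal ring-width I/O and monthly station climate tables.

#' Create a ring-width series
#'
#' A `ring_series` holds the dated ring widths of one increment core:
#' a series identifier (at most 8 characters, the Tucson field width),
#' the calendar year of the innermost measured ring, and the ordered ring
#' widths in millimetres. Missing (locally absent) rings are encoded as
#' width 0, the ITRDB convention, and are treated as valid zero growth.
#'
#' @param series_id Character scalar, <= 8 characters.
#' @param first_year Integer calendar year CE of the first ring.
#' @param widths Numeric vector of ring widths in mm, all >= 0.
#' @param precision Measurement resolution in mm (0.01 or 0.001).
#' @return An object of class `ring_series`.
#' @export
ring_series <- function(series_id, first_year, widths, precision = 0.01) {
  series_id <- as.character(series_id)
  if (nchar(series_id) < 1L || nchar(series_id) > 8L)
    stop("series_id must be 1-8 characters, got '", series_id, "'")
  first_year <- as.integer(first_year)
  widths <- as.numeric(widths)
  if (length(widths) == 0L) stop("widths must be non-empty")
  if (anyNA(widths) || any(widths < 0))
    stop("widths must be non-missing and >= 0")
  if (!precision %in% c(0.01, 0.001))
    stop("precision must be 0.01 or 0.001 mm")
  structure(
    list(series_id = series_id, first_year = first_year,
         widths = widths, precision = precision),
    class = "ring_series")
}

#' Years spanned by a ring series
#' @param x A `ring_series`.
#' @return Integer vector of calendar years, one per ring.
#' @export
series_years <- function(x) {
  stopifnot(inherits(x, "ring_series"))
  seq.int(x$first_year, length.out = length(x$widths))
}

#' @export
print.ring_series <- function(x, ...) {
  yr <- series_years(x)
  cat(sprintf("ring_series '%s': %d rings, %d-%d CE, precision %.3f mm\n",
              x$series_id, length(x$widths), yr[1L], yr[length(yr)],
              x$precision))
  invisible(x)
}

#' Create a site collection of ring-width series
#'
#' @param series List of `ring_series` objects with unique ids.
#' @param site_id Site identifier.
#' @param species_code Species code (e.g. "CDDE" for Cedrus deodara).
#' @return An object of class `site_collection`.
#' @export
site_collection <- function(series, site_id = "SITE", species_code = "UNKN") {
  if (inherits(series, "ring_series")) series <- list(series)
  if (length(series) == 0L) stop("a site_collection needs at least one series")
  ok <- vapply(series, inherits, logical(1), "ring_series")
  if (!all(ok)) stop("all elements of 'series' must be ring_series objects")
  ids <- vapply(series, `[[`, character(1), "series_id")
  if (anyDuplicated(ids)) stop("duplicate series ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(series) <- ids
  structure(list(site_id = site_id, species_code = species_code,
                 series = series),
            class = "site_collection")
}

#' @export
print.site_collection <- function(x, ...) {
  yrs <- range(unlist(lapply(x$series, series_years)))
  cat(sprintf("site_collection '%s' (%s): %d series, %d-%d CE\n",
              x$site_id, x$species_code, length(x$series), yrs[1], yrs[2]))
  invisible(x)
}

#' Ring-width matrix (year x series) of a collection
#'
#' Pools one or more collections into a single year-by-series matrix with
#' NA outside each series' span. Row names are calendar years.
#'
#' @param x A `site_collection` or list of them.
#' @return Numeric matrix, years x series.
#' @export
rwl_matrix <- function(x) {
  if (inherits(x, "site_collection")) x <- list(x)
  series <- unlist(lapply(x, `[[`, "series"), recursive = FALSE)
  ids <- vapply(series, `[[`, character(1), "series_id")
  if (anyDuplicated(ids))
    stop("duplicate series ids across pooled collections: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  yrs <- range(unlist(lapply(series, series_years)))
  years <- yrs[1]:yrs[2]
  m <- matrix(NA_real_, length(years), length(series),
              dimnames = list(years, ids))
  for (j in seq_along(series)) {
    s <- series[[j]]
    m[as.character(series_years(s)), j] <- s$widths
  }
  m
}

# ---- Tucson/RWL decadal format ------------------------------------------

#' Read a Tucson/RWL decadal ring-width file
#'
#' Parses the ITRDB decadal layout: each line carries a series id (columns
#' 1-8), the calendar year of the first value on the line, and up to ten
#' width values, one per year, running to the end of the decade. A series
#' is terminated by a stop marker: 999 for data stored in 0.01 mm units,
#' -9999 for 0.001 mm; the marker fixes the series' precision and is not a
#' data value. Widths are returned in millimetres.
#'
#' @param path Path to the RWL file.
#' @param site_id,species_code Metadata attached to the returned collection
#'   (the decadal format itself carries none).
#' @return A `site_collection`.
#' @export
read_rwl <- function(path, site_id = NULL, species_code = "UNKN") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty RWL file: ", path)
  if (is.null(site_id))
    site_id <- toupper(sub("\\.[^.]*$", "", basename(path)))

  open <- list()    # series_id -> list(first_year, vals, next_year)
  done <- list()    # finished ring_series
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    id <- trimws(substr(ln, 1L, 8L))
    rest <- substring(ln, 9L)
    toks <- strsplit(trimws(rest), "[ \t]+")[[1]]
    if (length(toks) < 2L)
      stop("line ", i, ": expected a year and at least one value")
    year <- suppressWarnings(as.integer(toks[1L]))
    if (is.na(year))
      stop("line ", i, ": unparseable year field '", toks[1L], "'")
    vals <- suppressWarnings(as.numeric(toks[-1L]))
    if (anyNA(vals))
      stop("line ", i, ": unparseable value token '",
           toks[-1L][which(is.na(vals))[1L]], "'")

    if (id %in% names(done) && !id %in% names(open))
      stop("line ", i, ": duplicate series id '", id, "'")
    if (!id %in% names(open)) {
      open[[id]] <- list(first_year = year, vals = numeric(0), next_year = year)
    } else if (year != open[[id]]$next_year) {
      stop("line ", i, ": non-monotone decade line for series '", id,
           "': expected year ", open[[id]]$next_year, ", got ", year)
    }

    st <- open[[id]]
    stopped <- FALSE
    for (v in vals) {
      if (v == 999 || v == -9999) {
        prec <- if (v == 999) 0.01 else 0.001
        if (length(st$vals) == 0L)
          stop("line ", i, ": series '", id, "' has a stop marker but no data")
        done[[id]] <- ring_series(id, st$first_year, st$vals * prec,
                                  precision = prec)
        open[[id]] <- NULL
        stopped <- TRUE
        break
      }
      if (v < 0) stop("line ", i, ": negative width ", v, " in series '", id, "'")
      st$vals <- c(st$vals, v)
    }
    if (!stopped) {
      st$next_year <- st$first_year + length(st$vals)
      open[[id]] <- st
    }
  }
  if (length(open) > 0L)
    stop("series without stop marker: ", paste(names(open), collapse = ", "))
  site_collection(unname(done), site_id = site_id, species_code = species_code)
}

#' Write a collection to a Tucson/RWL decadal file
#'
#' Emits the decadal fixed-width layout with right-aligned value columns;
#' the stop marker matches each series' precision (999 for 0.01 mm, -9999
#' for 0.001 mm), so `read_rwl(write_rwl(x))` reproduces series ids,
#' first years and widths exactly.
#'
#' @param collection A `site_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(collection, path) {
  stopifnot(inherits(collection, "site_collection"))
  if (length(collection$series) == 0L) stop("nothing to serialize")
  con <- file(path, "w")
  on.exit(close(con))
  for (s in collection$series) {
    if (nchar(s$series_id) > 8L)
      stop("series id '", s$series_id, "' longer than 8 characters")
    units <- round(s$widths / s$precision)
    marker <- if (s$precision == 0.01) 999 else -9999
    stream <- c(units, marker)
    yr <- s$first_year
    pos <- 1L
    while (pos <= length(stream)) {
      n_in_line <- 10L - (yr %% 10L)                # through decade end
      take <- min(n_in_line, length(stream) - pos + 1L)
      vals <- stream[pos:(pos + take - 1L)]
      writeLines(sprintf("%-8s%4d%s", s$series_id, yr,
                         paste0(sprintf("%6d", vals), collapse = "")), con)
      pos <- pos + take
      yr <- yr + take
    }
  }
  invisible(path)
}

# ---- Monthly climate tables ---------------------------------------------

#' Create a monthly climate object
#'
#' Holds station monthly climate over a contiguous year span as a named
#' list of year-by-12 matrices, one per variable. Recognised variable
#' names: `prec` (mm), `tmean`/`tmax`/`tmin` (deg C), `rh` (%),
#' `scpdsi` (index). Missing values are NA.
#'
#' @param data Named list of numeric year x 12 matrices.
#' @param years Integer vector of years (contiguous; gaps are filled with
#'   all-NA rows).
#' @param station_id Station identifier.
#' @return An object of class `monthly_climate`.
#' @export
monthly_climate <- function(data, years, station_id = "STATION") {
  years <- as.integer(years)
  if (length(years) == 0L) stop("no years")
  span <- min(years):max(years)
  out <- lapply(data, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 12L) stop("every variable matrix needs 12 monthly columns")
    full <- matrix(NA_real_, length(span), 12L,
                   dimnames = list(span, month.abb))
    full[as.character(years), ] <- m
    full
  })
  if (!is.null(out$prec) && any(out$prec < 0, na.rm = TRUE))
    stop("precipitation must be >= 0")
  if (all(c("tmax", "tmean", "tmin") %in% names(out))) {
    idx <- !is.na(out$tmax) & !is.na(out$tmean) & !is.na(out$tmin)
    if (any(out$tmax[idx] < out$tmean[idx]) ||
        any(out$tmean[idx] < out$tmin[idx]))
      stop("temperature ordering violated: need tmax >= tmean >= tmin")
  }
  structure(list(station_id = station_id, years = span, data = out),
            class = "monthly_climate")
}

#' @export
print.monthly_climate <- function(x, ...) {
  cat(sprintf("monthly_climate '%s': %d-%d, variables: %s\n", x$station_id,
              min(x$years), max(x$years), paste(names(x$data), collapse = ", ")))
  invisible(x)
}

#' Read a monthly climate table from CSV
#'
#' Two layouts are supported. `wide`: one variable per file with columns
#' `year, jan, feb, ..., dec` (case-insensitive); pass the variable name
#' via `variable`. `long`: columns `year, month, variable, value` with
#' month in 1-12. Year gaps are filled with NA rows so the span is
#' contiguous.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @param variable Variable name for wide layout (e.g. `"prec"`).
#' @param station_id Station identifier for the returned object.
#' @return A `monthly_climate`.
#' @export
read_climate_table <- function(path, layout = c("wide", "long"),
                               variable = "prec", station_id = "STATION") {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- tolower(names(df))
  if (layout == "wide") {
    mo <- tolower(month.abb)
    need <- c("year", mo)
    if (!all(need %in% names(df)))
      stop("wide layout needs columns: year, ", paste(month.abb, collapse = ", "))
    if (anyDuplicated(df$year)) stop("duplicate year rows")
    m <- as.matrix(df[, mo])
    rownames(m) <- df$year
    data <- stats::setNames(list(m), variable)
    return(monthly_climate(data, df$year, station_id))
  }
  need <- c("year", "month", "variable", "value")
  if (!all(need %in% names(df)))
    stop("long layout needs columns: year, month, variable, value")
  if (any(df$month < 1 | df$month > 12))
    stop("month outside 1-12")
  key <- paste(df$year, df$month, df$variable)
  if (anyDuplicated(key))
    stop("duplicate (year, month, variable) entries")
  years <- sort(unique(df$year))
  span <- min(years):max(years)
  data <- lapply(split(df, df$variable), function(d) {
    m <- matrix(NA_real_, length(span), 12L, dimnames = list(span, month.abb))
    m[cbind(match(d$year, span), d$month)] <- d$value
    m
  })
  monthly_climate(data, span, station_id)
}

#' Write monthly climate to wide CSV files (one per variable)
#'
#' @param mc A `monthly_climate`.
#' @param dir Output directory.
#' @return Named character vector of paths written.
#' @export
write_climate_table <- function(mc, dir) {
  stopifnot(inherits(mc, "monthly_climate"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (v in names(mc$data)) {
    df <- data.frame(year = mc$years, mc$data[[v]], check.names = FALSE)
    names(df) <- c("year", tolower(month.abb))
    p <- file.path(dir, paste0(mc$station_id, "_", v, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths[v] <- p
  }
  invisible(paths)
}
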