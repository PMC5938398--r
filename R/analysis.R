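# Onset analyses over the harmonized table: trait-pair selection, 0.1-degree
# gridding, earliest observation per grid cell and year, decade filtering,
# per-decade medians, and Gaussian KDE with the IQR rule-of-thumb bandwidth.

#' Select harmonized rows bearing one trait class but not another
#'
#' The canonical query shape is a required class with an optional exclusion —
#' e.g. leafing-out dates are observations with 'true leaves present' that do
#' not also carry 'senescing true leaves present'. Genus matching is
#' case-insensitive and exact.
#'
#' @param rows harmonized-row tibble (see [read_harmonized_csv()]).
#' @param require_class presence-class id each kept row must bear.
#' @param exclude_class optional presence-class id no kept row may bear.
#' @param genus optional genus filter.
#' @param years optional integer vector of years to keep.
#' @param catalog optional catalog to verify the class ids resolve.
#' @return the filtered rows.
#' @export
select_observations <- function(rows, require_class, exclude_class = NULL,
                                genus = NULL, years = NULL, catalog = NULL) {
  if (!is.null(catalog)) {
    for (cls in c(require_class, exclude_class)) {
      if (!cls %in% catalog$classes$class_id) abort_unknown_term(cls)
    }
  }
  if (!is.null(exclude_class) && identical(exclude_class, require_class)) {
    abort_parameter("exclude_class must differ from require_class")
  }
  class_sets <- strsplit(rows$inferred_classes, "|", fixed = TRUE)
  keep <- vapply(class_sets, function(s) require_class %in% s, logical(1))
  if (!is.null(exclude_class)) {
    keep <- keep & !vapply(class_sets, function(s) exclude_class %in% s, logical(1))
  }
  if (!is.null(genus)) {
    keep <- keep & !is.na(rows$genus) & tolower(rows$genus) == tolower(genus)
  }
  if (!is.null(years)) {
    keep <- keep & as.integer(format(rows$date, "%Y")) %in% years
  }
  rows[keep, , drop = FALSE]
}

#' Round coordinates to the 0.1-degree analysis grid
#'
#' Half-away-from-zero rounding to one decimal, applied symmetrically to
#' latitude and longitude (so 0.05 maps to 0.1 and -0.05 to -0.1).
#'
#' @param latitude,longitude decimal degrees (vectorized).
#' @return tibble with columns `cell_lat`, `cell_lon`.
#' @export
grid_cell <- function(latitude, longitude) {
  if (any(abs(latitude) > 90, na.rm = TRUE)) {
    abort_range("latitude outside [-90, 90]")
  }
  if (any(abs(longitude) > 180, na.rm = TRUE)) {
    abort_range("longitude outside [-180, 180]")
  }
  tibble(cell_lat = round_half_away(latitude, 1L),
         cell_lon = round_half_away(longitude, 1L))
}

# round() in R rounds half to even; the analysis grid uses half-away-from-zero
round_half_away <- function(x, digits) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Earliest observation per grid cell and year
#'
#' Collapses the selected rows to one onset estimate per occupied
#' (0.1-degree cell, year): the minimum day of year in that group. Ties on
#' day of year resolve to the lexicographically smallest observation id, so
#' output is deterministic. Rows without coordinates are skipped and counted.
#'
#' @param rows harmonized rows with `date`, `latitude`, `longitude`.
#' @return tibble of class `onset_estimates`: `cell_lat`, `cell_lon`, `year`,
#'   `day_of_year`, `observation_id`; attribute `n_skipped_no_coordinates`.
#' @export
earliest_per_cell_year <- function(rows) {
  has_coords <- !is.na(rows$latitude) & !is.na(rows$longitude)
  skipped <- sum(!has_coords)
  rows <- rows[has_coords, , drop = FALSE]

  cells <- grid_cell(rows$latitude, rows$longitude)
  est <- rows |>
    dplyr::mutate(cell_lat = cells$cell_lat,
                  cell_lon = cells$cell_lon,
                  year = as.integer(format(.data$date, "%Y")),
                  day_of_year = day_of_year(.data$date)) |>
    dplyr::group_by(.data$cell_lat, .data$cell_lon, .data$year) |>
    dplyr::arrange(.data$day_of_year, .data$observation_id, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("cell_lat", "cell_lon", "year", "day_of_year",
                  "observation_id") |>
    dplyr::arrange(.data$cell_lat, .data$cell_lon, .data$year)
  attr(est, "n_skipped_no_coordinates") <- skipped
  class(est) <- c("onset_estimates", class(est))
  est
}

#' Day of year from a calendar date
#'
#' 1-based (January 1 = 1), leap-aware (February 29 exists and December 31 of
#' a leap year is day 366).
#'
#' @param date a `Date` vector.
#' @return integer vector.
#' @export
day_of_year <- function(date) {
  as.POSIXlt(date)$yday + 1L
}

#' Drop onset estimates from under-sampled decades
#'
#' Decades are calendar decades (`floor(year / 10) * 10`). A decade whose
#' estimate count is below `min_records` is discarded entirely. The two
#' conventional thresholds are 1,000 records (most analyses) and 400 records
#' (sparser genera).
#'
#' @param estimates an `onset_estimates` tibble.
#' @param min_records minimum per-decade record count (>= 0).
#' @return the retained estimates.
#' @export
filter_decades <- function(estimates, min_records) {
  stopifnot(is.numeric(min_records), min_records >= 0)
  decade <- floor(estimates$year / 10) * 10
  counts <- table(decade)
  keep_decades <- as.numeric(names(counts)[counts >= min_records])
  estimates[decade %in% keep_decades, , drop = FALSE]
}

#' Rule-of-thumb KDE bandwidth based on the interquartile range
#'
#' \deqn{h = 0.9 \min(s, \mathrm{IQR}/1.34)\, n^{-1/5}}
#' where `s` is the sample standard deviation and the IQR uses
#' linear-interpolation quantiles. If the IQR is zero (heavily tied data) the
#' standard deviation alone is used.
#'
#' @param values numeric sample, `n >= 2`, not all identical.
#' @return the bandwidth, in the units of `values`.
#' @export
rule_of_thumb_bandwidth <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) abort_insufficient_data("bandwidth requires at least 2 values")
  s <- sd(values)
  if (s == 0) abort_degenerate_data("all values identical; zero spread")
  iqr <- unname(diff(quantile(values, c(0.25, 0.75), type = 7)))
  spread <- if (iqr > 0) min(s, iqr / 1.34) else s
  0.9 * spread * n^(-1 / 5)
}

#' Gaussian kernel density estimate on a day-of-year grid
#'
#' Bandwidth from [rule_of_thumb_bandwidth()]; the evaluation grid spans the
#' data range extended by four bandwidths on each side, so the trapezoidal
#' integral of the density over the grid is 1 to within 1e-3.
#'
#' @param values numeric sample (days of year, typically).
#' @param n_grid number of evaluation points (default 512).
#' @return tibble with columns `doy`, `density`; attribute `bandwidth`.
#' @export
kde_density <- function(values, n_grid = 512L) {
  values <- values[!is.na(values)]
  h <- rule_of_thumb_bandwidth(values)
  d <- stats::density(values, bw = h, kernel = "gaussian",
                      from = min(values) - 4 * h, to = max(values) + 4 * h,
                      n = n_grid)
  out <- tibble(doy = d$x, density = d$y)
  attr(out, "bandwidth") <- h
  out
}

# trapezoidal integral of a density curve (used by tests and summaries)
trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Per-decade onset summaries: counts, medians, and density curves
#'
#' For every decade retained by [filter_decades()], reports the record count,
#' the median onset day of year (mean of the two central order statistics for
#' even counts), and the Gaussian KDE of the onset distribution.
#'
#' @param estimates an `onset_estimates` tibble.
#' @param min_records per-decade threshold passed to [filter_decades()].
#' @param n_grid KDE grid size.
#' @return tibble with columns `decade`, `n`, `median_doy`, and a `density`
#'   list-column of `(doy, density)` tibbles (`NULL` when a density is not
#'   estimable, i.e. fewer than 2 distinct values).
#' @export
decade_summary <- function(estimates, min_records = 0, n_grid = 512L) {
  kept <- filter_decades(estimates, min_records)
  if (nrow(kept) == 0) {
    return(tibble(decade = integer(), n = integer(), median_doy = numeric(),
                  density = list()))
  }
  kept |>
    dplyr::mutate(decade = as.integer(floor(.data$year / 10) * 10)) |>
    dplyr::group_by(.data$decade) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_doy = median(.data$day_of_year),
      density = list(tryCatch(kde_density(.data$day_of_year, n_grid = n_grid),
                              phenokit_error = function(e) NULL)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$decade)
}

#' Flatten decade summaries for CSV export
#'
#' @param summaries output of [decade_summary()].
#' @return list with `summary` (decade, n, median_doy) and `densities`
#'   (decade, doy, density) tibbles.
#' @export
flatten_decade_summary <- function(summaries) {
  dens <- purrr::map2(summaries$decade, summaries$density, function(d, tab) {
    if (is.null(tab)) return(NULL)
    dplyr::mutate(tab, decade = d, .before = 1L)
  })
  list(
    summary = dplyr::select(summaries, "decade", "n", "median_doy"),
    densities = dplyr::bind_rows(dens)
  )
}
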