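# Seeded synthetic-data generator. Emits status-dialect and event-dialect
# observation files with a ground-truth ledger (true onset per plant-year and
# expected emitted-row counts), so the pipeline and the onset analyses can be
# validated end to end without any network downloads.

#' Simulation parameters
#'
#' Onset day of year for each plant-year is drawn from a Normal with mean
#' `onset_intercept + onset_slope * latitude` and standard deviation
#' `onset_sd`, truncated to `[1, 366 - season_length]`; the structure stays
#' visible for `season_length` days. The status network visits every plant
#' every `status_cadence` days starting on day 1 and records yes/no with an
#' intensity count window; the event network reports the true onset day
#' directly, except for a fraction of records that carry an agricultural code
#' instead (and are expected to be skipped at mapping time).
#'
#' @param seed integer RNG seed; the single source of randomness.
#' @param n_plants number of plants (>= 1).
#' @param genera character vector of genus names, recycled over plants.
#' @param lat_range,lon_range numeric length-2 ranges in decimal degrees.
#' @param years integer vector of observation years.
#' @param onset_intercept intercept a of the onset model (DOY at latitude 0).
#' @param onset_slope slope b (days per degree latitude).
#' @param onset_sd standard deviation of onset (days, >= 0).
#' @param season_length days a structure remains visible after onset.
#' @param status_cadence days between status-network visits (>= 1).
#' @param networks subset of `c("status", "event")`.
#' @param fraction_agricultural fraction of event records carrying an
#'   agricultural code, in `[0, 1]`.
#' @param status_code,event_code,agricultural_code source-vocabulary codes
#'   written into the emitted files (defaults match the shipped mapping).
#' @return a validated `simulation_params` list.
#' @export
simulation_params <- function(seed = 1L,
                              n_plants = 200L,
                              genera = c("Acer", "Quercus"),
                              lat_range = c(40, 60),
                              lon_range = c(-10, 30),
                              years = 2000:2009,
                              onset_intercept = 20,
                              onset_slope = 2.5,
                              onset_sd = 5,
                              season_length = 150L,
                              status_cadence = 7L,
                              networks = c("status", "event"),
                              fraction_agricultural = 0.05,
                              status_code = "leaves",
                              event_code = "BBCH11",
                              agricultural_code = "BBCH99") {
  p <- list(seed = as.integer(seed), n_plants = as.integer(n_plants),
            genera = genera, lat_range = lat_range, lon_range = lon_range,
            years = as.integer(years), onset_intercept = onset_intercept,
            onset_slope = onset_slope, onset_sd = onset_sd,
            season_length = as.integer(season_length),
            status_cadence = as.integer(status_cadence), networks = networks,
            fraction_agricultural = fraction_agricultural,
            status_code = status_code, event_code = event_code,
            agricultural_code = agricultural_code)
  if (p$n_plants < 1) abort_parameter("n_plants must be >= 1")
  if (p$onset_sd < 0) abort_parameter("onset_sd must be >= 0")
  if (p$status_cadence < 1) abort_parameter("status_cadence must be >= 1")
  if (p$season_length < 0) abort_parameter("season_length must be >= 0")
  if (p$fraction_agricultural < 0 || p$fraction_agricultural > 1) {
    abort_parameter("fraction_agricultural must be in [0, 1]")
  }
  if (!all(p$networks %in% c("status", "event")) || length(p$networks) == 0) {
    abort_parameter("networks must be a non-empty subset of {status, event}")
  }
  if (366 - p$season_length < 1) {
    abort_parameter("season_length leaves no feasible onset window in [1, 366]")
  }
  if (length(p$years) < 1) abort_parameter("years must be non-empty")
  class(p) <- "simulation_params"
  p
}

#' Simulate plants and their true onsets (the ground-truth ledger)
#'
#' Plant locations are uniform over the configured latitude/longitude box and
#' fixed across years; onset is drawn independently per plant-year from the
#' truncated Normal described in [simulation_params()] (inverse-CDF sampling,
#' so the draw is deterministic under a fixed seed). Onsets are rounded to
#' whole days.
#'
#' @param params a `simulation_params` object.
#' @return the truth ledger: one row per plant-year with `subject_id`,
#'   `genus`, `species`, `latitude`, `longitude`, `cell_lat`, `cell_lon`,
#'   `year`, `onset_doy`, `senescence_doy`.
#' @export
simulate_plants <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  n <- params$n_plants
  plants <- tibble(
    subject_id = sprintf("plant_%05d", seq_len(n)),
    genus = rep_len(params$genera, n),
    species = "",
    latitude = runif(n, params$lat_range[1], params$lat_range[2]),
    longitude = runif(n, params$lon_range[1], params$lon_range[2])
  )
  cells <- grid_cell(plants$latitude, plants$longitude)
  plants$cell_lat <- cells$cell_lat
  plants$cell_lon <- cells$cell_lon

  ledger <- tidyr::expand_grid(plants, year = params$years)
  lo <- 1
  hi <- 366 - params$season_length
  mu <- params$onset_intercept + params$onset_slope * ledger$latitude
  if (params$onset_sd == 0) {
    onset <- pmin(pmax(round(mu), lo), hi)
  } else {
    u <- runif(nrow(ledger))
    p_lo <- pnorm(lo, mu, params$onset_sd)
    p_hi <- pnorm(hi, mu, params$onset_sd)
    if (any(p_hi - p_lo < 1e-12)) {
      abort_parameter("onset model places essentially no mass in [1, 366 - season_length]")
    }
    onset <- pmin(pmax(round(qnorm(p_lo + u * (p_hi - p_lo), mu, params$onset_sd)),
                       lo), hi)
  }
  ledger$onset_doy <- as.integer(onset)
  ledger$senescence_doy <- as.integer(onset + params$season_length)
  ledger
}

#' Emit status-dialect records for a truth ledger
#'
#' Visits fall on days `1, 1 + cadence, 1 + 2*cadence, ...` of each year. A
#' visit reports `yes` when its day lies in `[onset, senescence)`, with an
#' intensity count window `(k, k + 10)` where `k` grows through the season
#' (`k = day - onset + 1`), and `no` otherwise. The emission itself is
#' deterministic given the ledger.
#'
#' @param ledger output of [simulate_plants()].
#' @param params the matching `simulation_params`.
#' @return list with `records` (status-dialect tibble) and `ledger` (input
#'   ledger with `n_status_rows`, `n_status_yes`, `first_status_yes_doy`).
#' @export
emit_status_records <- function(ledger, params) {
  stopifnot(inherits(params, "simulation_params"))
  year_days <- 365L + as.integer(leap_year(ledger$year))
  visits <- lapply(unique(year_days), function(nd) {
    seq.int(1L, nd, by = params$status_cadence)
  })
  names(visits) <- as.character(unique(year_days))

  per_py <- lapply(seq_len(nrow(ledger)), function(i) {
    doys <- visits[[as.character(year_days[i])]]
    yes <- doys >= ledger$onset_doy[i] & doys < ledger$senescence_doy[i]
    k <- ifelse(yes, doys - ledger$onset_doy[i] + 1L, NA_integer_)
    tibble(
      plant_id = ledger$subject_id[i],
      genus = ledger$genus[i],
      species = ledger$species[i],
      latitude = ledger$latitude[i],
      longitude = ledger$longitude[i],
      date = as.Date(paste0(ledger$year[i], "-01-01")) + doys - 1L,
      phenophase_code = params$status_code,
      status = ifelse(yes, "yes", "no"),
      intensity_lower = as.numeric(k),
      intensity_upper = as.numeric(k + 10L)
    )
  })
  records <- dplyr::bind_rows(per_py)
  records <- dplyr::mutate(records,
                           record_id = sprintf("S%08d", dplyr::row_number()),
                           .before = 1L)

  ledger$n_status_rows <- vapply(per_py, nrow, integer(1))
  ledger$n_status_yes <- vapply(per_py, function(x) sum(x$status == "yes"),
                                integer(1))
  ledger$first_status_yes_doy <- vapply(per_py, function(x) {
    yes_dates <- x$date[x$status == "yes"]
    if (length(yes_dates) == 0) NA_integer_ else day_of_year(min(yes_dates))
  }, integer(1))
  list(records = records, ledger = ledger)
}

#' Emit event-dialect records for a truth ledger
#'
#' One event per plant-year with `day_of_year` equal to the true onset. A
#' seeded fraction of records carry the agricultural code instead of the
#' onset code; the ledger marks exactly which.
#'
#' @inheritParams emit_status_records
#' @return list with `records` (event-dialect tibble) and `ledger` (with
#'   logical column `event_agricultural`).
#' @export
emit_event_records <- function(ledger, params) {
  stopifnot(inherits(params, "simulation_params"))
  n <- nrow(ledger)
  n_agri <- floor(params$fraction_agricultural * n)
  set.seed(params$seed + 1L, kind = "Mersenne-Twister")
  agri <- rep(FALSE, n)
  if (n_agri > 0) agri[sample.int(n, n_agri)] <- TRUE

  records <- tibble(
    record_id = sprintf("E%08d", seq_len(n)),
    plant_or_station_id = ledger$subject_id,
    genus = ledger$genus,
    species = ledger$species,
    latitude = ledger$latitude,
    longitude = ledger$longitude,
    year = ledger$year,
    event_code = ifelse(agri, params$agricultural_code, params$event_code),
    day_of_year = ledger$onset_doy
  )
  ledger$event_agricultural <- agri
  list(records = records, ledger = ledger)
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_plants()] and the configured emitters, annotates the ledger
#' with the expected harmonized-row count per plant-year, and (optionally)
#' writes `status.csv`, `events.csv`, and `ledger.csv` to a directory.
#' Identical parameters produce byte-identical files.
#'
#' @param params a `simulation_params` object.
#' @param out_dir optional output directory (created if missing).
#' @return list with `ledger`, `status`, `events` (tibbles; `NULL` for
#'   networks not simulated), and `paths` when `out_dir` is given.
#' @export
simulate_dataset <- function(params, out_dir = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  ledger <- simulate_plants(params)
  status <- NULL
  events <- NULL
  if ("status" %in% params$networks) {
    s <- emit_status_records(ledger, params)
    status <- s$records
    ledger <- s$ledger
  }
  if ("event" %in% params$networks) {
    e <- emit_event_records(ledger, params)
    events <- e$records
    ledger <- e$ledger
  }
  ledger$n_harmonized_expected <-
    (if (!is.null(status)) ledger$n_status_rows else 0L) +
    (if (!is.null(events)) as.integer(!ledger$event_agricultural) else 0L)

  paths <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- list()
    if (!is.null(status)) {
      paths$status <- file.path(out_dir, "status.csv")
      readr::write_csv(status, paths$status, na = "", progress = FALSE)
    }
    if (!is.null(events)) {
      paths$events <- file.path(out_dir, "events.csv")
      readr::write_csv(events, paths$events, na = "", progress = FALSE)
    }
    paths$ledger <- file.path(out_dir, "ledger.csv")
    readr::write_csv(ledger, paths$ledger, na = "", progress = FALSE)
  }
  list(ledger = ledger, status = status, events = events, paths = paths)
}

#' The mapping table shipped with phenokit
#'
#' Covers the simulator's source vocabularies: the status code `leaves` and
#' event code `BBCH11` map to 'true leaf presence', `flowers`/`BBCH60` to
#' 'flower presence', and `BBCH99` is flagged agricultural. Real network
#' vocabularies require a user-supplied table in the same layout.
#'
#' @param catalog catalog to validate against (default [default_catalog()]).
#' @return a validated mapping tibble.
#' @export
default_mapping <- function(catalog = default_catalog()) {
  path <- system.file("extdata", "phenokit_mapping.csv", package = "phenokit",
                      mustWork = TRUE)
  read_mapping_csv(path, catalog)
}
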