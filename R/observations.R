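# Observation model: plant subjects, observing events, and range-valued
# measurement data. Observations are stored flat, one measurement per row,
# grouped by observation_id; an unbounded upper count is Inf in memory and an
# empty field on disk.

observation_columns <- c("observation_id", "subject_id", "genus", "species",
                         "latitude", "longitude", "date", "trait_id",
                         "value_kind", "lower", "upper", "source",
                         "source_record_id")

#' Construct a validated measurement datum
#'
#' A measurement datum is a count or percentage range attached to a trait:
#' the observer asserts the true value lies in `[lower, upper]`. Counts must
#' be whole numbers (an unbounded upper count is expressed as `Inf`);
#' percentages must lie within `[0, 100]`.
#'
#' @param trait_id trait identifier (checked against `catalog` if supplied).
#' @param value_kind `"count"` or `"percent"`.
#' @param lower,upper non-negative bounds, `lower <= upper`.
#' @param catalog optional `trait_catalog` to resolve the trait against.
#' @return a one-row tibble with columns `trait_id`, `value_kind`, `lower`,
#'   `upper`.
#' @export
make_measurement <- function(trait_id, value_kind, lower, upper, catalog = NULL) {
  if (!value_kind %in% c("count", "percent")) {
    abort_schema(paste0("value_kind must be 'count' or 'percent', got: ", value_kind))
  }
  if (!is.numeric(lower) || !is.numeric(upper) || is.na(lower) || is.na(upper)) {
    abort_range("measurement bounds must be non-missing numbers")
  }
  if (lower < 0 || upper < 0) abort_range("measurement bounds must be non-negative")
  if (lower > upper) {
    abort_range(sprintf("lower bound (%s) exceeds upper bound (%s)", lower, upper))
  }
  if (value_kind == "count") {
    if (!is_whole(lower) || !(is.infinite(upper) || is_whole(upper))) {
      abort_range("count bounds must be whole numbers (upper may be Inf)")
    }
  } else {
    if (is.infinite(lower) || is.infinite(upper) || upper > 100) {
      abort_range("percent bounds must lie in [0, 100]")
    }
  }
  if (!is.null(catalog) && !trait_id %in% catalog$traits$id) {
    abort_unknown_term(trait_id)
  }
  tibble(trait_id = trait_id, value_kind = value_kind,
         lower = as.numeric(lower), upper = as.numeric(upper))
}

is_whole <- function(x) is.finite(x) && abs(x - round(x)) < 1e-9

#' Validate a table of observations against a catalog
#'
#' Checks the observation-model invariants and returns violations as data:
#' unique measurement per (observation, trait), valid dates and coordinate
#' bounds, resolvable trait ids, well-formed ranges. Missing coordinates are
#' reported as warnings (`severity = "warning"`): such records are legal but
#' will be excluded from spatial analyses.
#'
#' @param observations a tibble in the observation layout (one measurement per
#'   row; see [read_observations_csv()] for the column set).
#' @param catalog a `trait_catalog`.
#' @return tibble with columns `observation_id`, `severity`, `rule`, `detail`;
#'   zero rows iff every invariant holds.
#' @export
validate_observations <- function(observations, catalog) {
  obs <- as_tibble(observations)
  missing_cols <- setdiff(observation_columns, names(obs))
  if (length(missing_cols) > 0) {
    abort_schema(paste0("observation table missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  v <- list()
  add <- function(id, severity, rule, detail) {
    v[[length(v) + 1L]] <<- tibble(observation_id = id, severity = severity,
                                   rule = rule, detail = detail)
  }

  dup <- obs |>
    dplyr::count(.data$observation_id, .data$trait_id) |>
    dplyr::filter(.data$n > 1L)
  for (i in seq_len(nrow(dup))) {
    add(dup$observation_id[i], "error", "duplicate_trait",
        paste0("trait measured more than once: ", dup$trait_id[i]))
  }

  for (i in seq_len(nrow(obs))) {
    row <- obs[i, ]
    if (is.na(row$observation_id) || !nzchar(row$observation_id)) {
      add(row$observation_id, "error", "missing_id", "empty observation_id")
    }
    if (is.na(row$subject_id) || !nzchar(row$subject_id)) {
      add(row$observation_id, "error", "missing_subject", "empty subject_id")
    }
    if (is.na(row$date)) {
      add(row$observation_id, "error", "bad_date", "date missing or unparseable")
    }
    if (!row$trait_id %in% catalog$traits$id) {
      add(row$observation_id, "error", "unknown_trait",
          paste0("trait not in catalog: ", row$trait_id))
    }
    if (is.na(row$latitude) || is.na(row$longitude)) {
      add(row$observation_id, "warning", "missing_coordinates",
          "record will be excluded from spatial analyses")
    } else if (abs(row$latitude) > 90 || abs(row$longitude) > 180) {
      add(row$observation_id, "error", "coordinates_out_of_bounds",
          sprintf("(%s, %s)", row$latitude, row$longitude))
    }
    rng <- range_violation(row$value_kind, row$lower, row$upper)
    if (!is.null(rng)) add(row$observation_id, "error", "bad_range", rng)
  }

  if (length(v) == 0) {
    tibble(observation_id = character(), severity = character(),
           rule = character(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}

# NULL if the range is valid, else a human-readable reason.
range_violation <- function(value_kind, lower, upper) {
  if (!value_kind %in% c("count", "percent")) {
    return(paste0("bad value_kind: ", value_kind))
  }
  if (is.na(lower) || is.na(upper)) return("missing bound")
  if (lower < 0 || upper < 0) return("negative bound")
  if (lower > upper) return("lower > upper")
  if (value_kind == "count" &&
      (!is_whole(lower) || !(is.infinite(upper) || is_whole(upper)))) {
    return("non-integer count bound")
  }
  if (value_kind == "percent" && (upper > 100 || is.infinite(lower))) {
    return("percent outside [0, 100]")
  }
  NULL
}

#' Read / write the observation CSV dialect
#'
#' UTF-8 comma-separated, one measurement per row, grouped by
#' `observation_id`, ISO 8601 dates. An empty `upper` field denotes an
#' unbounded upper count (read as `Inf`). Writing then reading a valid table
#' reproduces it field for field.
#'
#' @param path file path.
#' @return for the reader, a tibble in the observation layout.
#' @export
read_observations_csv <- function(path) {
  if (!file.exists(path)) abort_schema(paste0("file not found: ", path))
  out <- readr::read_csv(path, col_types = readr::cols(
    observation_id = readr::col_character(),
    subject_id = readr::col_character(),
    genus = readr::col_character(),
    species = readr::col_character(),
    latitude = readr::col_double(),
    longitude = readr::col_double(),
    date = readr::col_date(),
    trait_id = readr::col_character(),
    value_kind = readr::col_character(),
    lower = readr::col_double(),
    upper = readr::col_double(),
    source = readr::col_character(),
    source_record_id = readr::col_character()
  ), progress = FALSE)
  missing_cols <- setdiff(observation_columns, names(out))
  if (length(missing_cols) > 0) {
    abort_schema(paste0("observation CSV missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  out$upper[is.na(out$upper) & !is.na(out$lower)] <- Inf
  out$species[is.na(out$species)] <- ""
  out
}

#' @rdname read_observations_csv
#' @param observations tibble in the observation layout.
#' @export
write_observations_csv <- function(observations, path) {
  out <- as_tibble(observations)[, observation_columns]
  out$upper <- ifelse(is.infinite(out$upper), NA_real_, out$upper)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
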