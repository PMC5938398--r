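# Four-stage integration pipeline:
#   1. normalize   — read the source dialect CSVs, rejecting malformed rows
#   2. map         — translate source phenophase/event codes to catalog
#                    traits via a user-supplied mapping table
#   3. infer       — materialize presence-class closures (see reasoner)
#   4. export      — one flat harmonized row per observation
# Every input row is accounted for: harmonized + rejected + skipped is exact.

status_columns <- c("record_id", "plant_id", "genus", "species", "latitude",
                    "longitude", "date", "phenophase_code", "status",
                    "intensity_lower", "intensity_upper")

event_columns <- c("record_id", "plant_or_station_id", "genus", "species",
                   "latitude", "longitude", "year", "event_code",
                   "day_of_year")

mapping_columns <- c("source_dialect", "source_code", "trait_id", "value_rule")

read_dialect_raw <- function(path, required) {
  if (!file.exists(path)) abort_schema(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort_schema(paste0("missing mandatory column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  raw
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

coord_reason <- function(lat, lon) {
  dplyr::case_when(
    is.na(lat) | is.na(lon) ~ NA_character_,  # permitted; excluded spatially
    abs(lat) > 90 ~ "latitude out of bounds",
    abs(lon) > 180 ~ "longitude out of bounds",
    .default = NA_character_
  )
}

#' Read a status-dialect observation file
#'
#' The status dialect is one row per visit and phenophase: a yes/no/unknown
#' status with optional intensity bounds, as produced by status-based
#' monitoring networks. Malformed rows are rejected with a line number and
#' reason, never aborting the parse; row order is preserved.
#'
#' @param path CSV path with columns `record_id, plant_id, genus, species,
#'   latitude, longitude, date, phenophase_code, status, intensity_lower,
#'   intensity_upper`.
#' @return list with `records` (parsed tibble) and `rejects`
#'   (`line`, `record_id`, `reason`).
#' @export
read_status_csv <- function(path) {
  raw <- read_dialect_raw(path, status_columns)
  parsed <- raw |>
    dplyr::mutate(
      line = dplyr::row_number() + 1L,
      latitude = num_or_na(.data$latitude),
      longitude = num_or_na(.data$longitude),
      date = as.Date(.data$date, format = "%Y-%m-%d"),
      intensity_lower = num_or_na(.data$intensity_lower),
      intensity_upper = num_or_na(.data$intensity_upper),
      species = dplyr::coalesce(.data$species, "")
    )
  reason <- with(parsed, dplyr::case_when(
    is.na(record_id) | !nzchar(record_id) ~ "missing record_id",
    duplicated(record_id) ~ "duplicate record_id",
    is.na(plant_id) | !nzchar(plant_id) ~ "missing plant_id",
    is.na(date) ~ "missing or unparseable date",
    !status %in% c("yes", "no", "unknown") ~ "invalid status",
    status == "unknown" &
      (!is.na(intensity_lower) | !is.na(intensity_upper)) ~
      "unknown status cannot carry intensity",
    !is.na(intensity_lower) & intensity_lower < 0 ~ "negative intensity",
    !is.na(intensity_lower) & !is.na(intensity_upper) &
      intensity_lower > intensity_upper ~ "intensity lower > upper",
    .default = coord_reason(latitude, longitude)
  ))
  list(
    records = parsed[is.na(reason), c("line", status_columns)],
    rejects = tibble(line = parsed$line[!is.na(reason)],
                     record_id = parsed$record_id[!is.na(reason)],
                     reason = reason[!is.na(reason)])
  )
}

#' Read an event-dialect observation file
#'
#' The event dialect is one row per phenological event: a BBCH-like code and
#' the day of year on which the event occurred, as produced by event-based
#' monitoring networks.
#'
#' @param path CSV path with columns `record_id, plant_or_station_id, genus,
#'   species, latitude, longitude, year, event_code, day_of_year`.
#' @return list with `records` and `rejects` as in [read_status_csv()].
#' @export
read_event_csv <- function(path) {
  raw <- read_dialect_raw(path, event_columns)
  parsed <- raw |>
    dplyr::mutate(
      line = dplyr::row_number() + 1L,
      latitude = num_or_na(.data$latitude),
      longitude = num_or_na(.data$longitude),
      year = suppressWarnings(as.integer(.data$year)),
      day_of_year = suppressWarnings(as.integer(.data$day_of_year)),
      species = dplyr::coalesce(.data$species, "")
    )
  year_days <- ifelse(is.na(parsed$year), NA_integer_,
                      365L + as.integer(leap_year(parsed$year)))
  reason <- with(parsed, dplyr::case_when(
    is.na(record_id) | !nzchar(record_id) ~ "missing record_id",
    duplicated(record_id) ~ "duplicate record_id",
    is.na(plant_or_station_id) | !nzchar(plant_or_station_id) ~
      "missing plant_or_station_id",
    is.na(year) ~ "missing or unparseable year",
    is.na(day_of_year) ~ "missing or unparseable day_of_year",
    day_of_year < 1 | day_of_year > year_days ~ "day_of_year outside year",
    .default = coord_reason(latitude, longitude)
  ))
  list(
    records = parsed[is.na(reason), c("line", event_columns)],
    rejects = tibble(line = parsed$line[!is.na(reason)],
                     record_id = parsed$record_id[!is.na(reason)],
                     reason = reason[!is.na(reason)])
  )
}

leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' Read and validate a source-code mapping table
#'
#' Maps `(source_dialect, source_code)` pairs to catalog traits. The
#' `value_rule` column is one of `status_to_range` (status records carry the
#' range), `event_onset` (event date asserts presence), or
#' `excluded_agricultural` (the code records agricultural information, such
#' as a harvest date, and is deliberately outside the model's scope).
#'
#' @param path CSV with columns `source_dialect, source_code, trait_id,
#'   value_rule`.
#' @param catalog catalog against which trait ids must resolve (except for
#'   `excluded_agricultural` rows).
#' @return validated mapping tibble.
#' @export
read_mapping_csv <- function(path, catalog) {
  if (!file.exists(path)) abort_schema(paste0("file not found: ", path))
  m <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  missing_cols <- setdiff(mapping_columns, names(m))
  if (length(missing_cols) > 0) {
    abort_schema(paste0("mapping table missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  key <- paste(m$source_dialect, m$source_code)
  if (anyDuplicated(key)) {
    abort_schema(paste0("duplicate mapping for: ",
                        paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  bad_rule <- setdiff(unique(m$value_rule),
                      c("status_to_range", "event_onset", "excluded_agricultural"))
  if (length(bad_rule) > 0) {
    abort_schema(paste0("unknown value_rule: ", paste(bad_rule, collapse = ", ")))
  }
  needs_trait <- m$value_rule != "excluded_agricultural"
  unresolved <- setdiff(m$trait_id[needs_trait], catalog$traits$id)
  if (length(unresolved) > 0) abort_unresolved_reference(unresolved)
  m
}

#' Map source records to catalog-based observations
#'
#' Stage 2 of the pipeline. Status semantics: `yes` with intensity bounds
#' becomes a count range; `yes` without intensities asserts presence of
#' unknown magnitude (lower 1, unbounded upper); `no` becomes the exact zero
#' range; `unknown` is skipped. Event records assert presence (lower 1,
#' unbounded upper) on the event date only — no persistence to later dates is
#' implied. Codes mapped as agricultural, and codes with no mapping at all,
#' produce skip notices, never exceptions.
#'
#' @param records parsed records from [read_status_csv()] or
#'   [read_event_csv()].
#' @param dialect `"status"` or `"event"`.
#' @param mapping validated mapping tibble.
#' @param catalog the trait catalog.
#' @return list with `observations` (observation-layout tibble) and `skips`
#'   (`record_id`, `reason`).
#' @export
map_records <- function(records, dialect, mapping, catalog) {
  stopifnot(dialect %in% c("status", "event"))
  map <- mapping[mapping$source_dialect == dialect, ]
  code_col <- if (dialect == "status") "phenophase_code" else "event_code"
  joined <- dplyr::left_join(records, map,
                             by = setNames("source_code", code_col))

  skip_reason <- if (dialect == "status") {
    dplyr::case_when(
      is.na(joined$value_rule) ~ "unmapped",
      joined$value_rule == "excluded_agricultural" ~ "agricultural",
      joined$status == "unknown" ~ "unknown_status",
      .default = NA_character_
    )
  } else {
    dplyr::case_when(
      is.na(joined$value_rule) ~ "unmapped",
      joined$value_rule == "excluded_agricultural" ~ "agricultural",
      .default = NA_character_
    )
  }

  kept <- joined[is.na(skip_reason), , drop = FALSE]
  observations <- if (dialect == "status") {
    tibble(
      observation_id = paste0("status:", kept$record_id),
      subject_id = kept$plant_id,
      genus = kept$genus,
      species = kept$species,
      latitude = kept$latitude,
      longitude = kept$longitude,
      date = kept$date,
      trait_id = kept$trait_id,
      value_kind = "count",
      lower = dplyr::case_when(
        kept$status == "no" ~ 0,
        !is.na(kept$intensity_lower) ~ kept$intensity_lower,
        .default = 1
      ),
      upper = dplyr::case_when(
        kept$status == "no" ~ 0,
        !is.na(kept$intensity_upper) ~ kept$intensity_upper,
        .default = Inf
      ),
      source = "status_network",
      source_record_id = kept$record_id
    )
  } else {
    tibble(
      observation_id = paste0("event:", kept$record_id),
      subject_id = kept$plant_or_station_id,
      genus = kept$genus,
      species = kept$species,
      latitude = kept$latitude,
      longitude = kept$longitude,
      date = as.Date(paste0(kept$year, "-01-01")) + kept$day_of_year - 1L,
      trait_id = kept$trait_id,
      value_kind = "count",
      lower = 1,
      upper = Inf,
      source = "event_network",
      source_record_id = kept$record_id
    )
  }

  list(
    observations = observations,
    skips = tibble(record_id = joined$record_id[!is.na(skip_reason)],
                   reason = skip_reason[!is.na(skip_reason)])
  )
}

harmonized_columns <- c("observation_id", "subject_id", "genus", "species",
                        "latitude", "longitude", "date", "source",
                        "inferred_classes")

#' Run the full four-stage integration pipeline
#'
#' Reads every source file, maps records to observations, materializes
#' inferred presence classes, and writes one flat row per observation with
#' its inferred classes as a pipe-delimited, sorted list. Observations whose
#' measurements contradict each other (a trait inferred both present and
#' absent) are excluded from the output and reported as skips with reason
#' `"conflict"`. The accounting identity
#' `rows read = harmonized + rejected + skipped` holds exactly on every run,
#' and identical inputs produce byte-identical output (rows ordered by source,
#' then record id).
#'
#' @param sources list of `list(dialect =, path =)` entries (dialect
#'   `"status"` or `"event"`).
#' @param mapping validated mapping tibble (see [read_mapping_csv()]).
#' @param catalog catalog with derived presence classes.
#' @param out_path path for the harmonized CSV.
#' @return a `pipeline_report` list: per-source counts (rows read, rejects,
#'   skips by reason, harmonized rows, share of the final table) and totals.
#' @export
run_pipeline <- function(sources, mapping, catalog, out_path) {
  stopifnot(isTRUE(catalog$derived))
  per_source <- list()
  all_obs <- list()

  for (i in seq_along(sources)) {
    src <- sources[[i]]
    stopifnot(is.list(src), !is.null(src$dialect), !is.null(src$path))
    parsed <- if (src$dialect == "status") read_status_csv(src$path)
              else read_event_csv(src$path)
    mapped <- map_records(parsed$records, src$dialect, mapping, catalog)
    all_obs[[i]] <- mapped$observations
    per_source[[i]] <- list(
      dialect = src$dialect,
      path = src$path,
      rows_read = nrow(parsed$records) + nrow(parsed$rejects),
      rejected = nrow(parsed$rejects),
      reject_reasons = count_by(parsed$rejects$reason),
      skipped = nrow(mapped$skips),
      skip_reasons = count_by(mapped$skips$reason),
      mapped = nrow(mapped$observations)
    )
  }

  observations <- dplyr::bind_rows(all_obs)
  mat <- materialize(observations, catalog)
  conflicts <- check_consistency(mat)

  class_strings <- mat$assertions |>
    dplyr::group_by(.data$observation_id) |>
    dplyr::summarise(inferred_classes = paste(sort(.data$class_id), collapse = "|"),
                     .groups = "drop")

  harmonized <- observations |>
    dplyr::distinct(.data$observation_id, .data$subject_id, .data$genus,
                    .data$species, .data$latitude, .data$longitude,
                    .data$date, .data$source) |>
    dplyr::left_join(class_strings, by = "observation_id") |>
    dplyr::mutate(inferred_classes = dplyr::coalesce(.data$inferred_classes, ""))

  conflicted <- harmonized$observation_id %in% conflicts$observation_id
  harmonized <- harmonized[!conflicted, harmonized_columns]

  # stable order: source file order, then record id within source
  order_key <- match(harmonized$observation_id, observations$observation_id)
  src_index <- rep(seq_along(all_obs), vapply(all_obs, nrow, integer(1)))
  harmonized <- harmonized[order(src_index[order_key],
                                 observations$source_record_id[order_key]), ]

  write_harmonized_csv(harmonized, out_path)

  n_conflict <- sum(conflicted)
  for (i in seq_along(per_source)) {
    src_ids <- all_obs[[i]]$observation_id
    per_source[[i]]$conflicts <- sum(conflicts$observation_id %in% src_ids)
    per_source[[i]]$harmonized <- sum(harmonized$observation_id %in% src_ids)
    per_source[[i]]$share_of_output <-
      if (nrow(harmonized) > 0) per_source[[i]]$harmonized / nrow(harmonized) else 0
  }

  report <- list(
    sources = per_source,
    totals = list(
      rows_read = sum(vapply(per_source, `[[`, numeric(1), "rows_read")),
      rejected = sum(vapply(per_source, `[[`, numeric(1), "rejected")),
      skipped = sum(vapply(per_source, `[[`, numeric(1), "skipped")) + n_conflict,
      conflicts = n_conflict,
      harmonized = nrow(harmonized)
    ),
    out_path = out_path
  )
  class(report) <- "pipeline_report"
  report
}

count_by <- function(x) {
  if (length(x) == 0) return(list())
  as.list(table(x))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  t <- x$totals
  cat(sprintf("  rows read: %d  harmonized: %d  rejected: %d  skipped: %d (conflicts: %d)\n",
              t$rows_read, t$harmonized, t$rejected, t$skipped, t$conflicts))
  for (s in x$sources) {
    cat(sprintf("  - %s %s: read %d, harmonized %d (%.1f%% of output)\n",
                s$dialect, basename(s$path), s$rows_read, s$harmonized,
                100 * s$share_of_output))
  }
  invisible(x)
}

#' Read / write the harmonized-row CSV
#'
#' One row per observation: subject, taxon, location, date, source, and the
#' inferred presence classes as a sorted pipe-delimited list.
#'
#' @param path file path.
#' @export
read_harmonized_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    observation_id = readr::col_character(),
    subject_id = readr::col_character(),
    genus = readr::col_character(),
    species = readr::col_character(),
    latitude = readr::col_double(),
    longitude = readr::col_double(),
    date = readr::col_date(),
    source = readr::col_character(),
    inferred_classes = readr::col_character()
  ), progress = FALSE) |>
    dplyr::mutate(inferred_classes = dplyr::coalesce(.data$inferred_classes, ""),
                  species = dplyr::coalesce(.data$species, ""))
}

#' @rdname read_harmonized_csv
#' @param rows harmonized-row tibble.
#' @export
write_harmonized_csv <- function(rows, path) {
  readr::write_csv(rows[, harmonized_columns], path, na = "", progress = FALSE)
  invisible(path)
}
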