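# Inference engine: classify count/percentage ranges into present / absent /
# indeterminate, and materialize the full presence-class closure for every
# observation. Materialization is eager — the flat export carries all
# entailed classes, so queries never need the catalog.

#' Classify a measurement range as present, absent, or indeterminate
#'
#' A plant with one or more of a structure bears the "present" class; a
#' measurement whose range is exactly zero licenses the "absent" class; a
#' range straddling zero (`lower = 0 < upper`) licenses neither — no
#' assertion is made rather than a disjunction. For percentages the present
#' threshold is any strictly positive lower bound, mirroring the count rule
#' "one or more".
#'
#' @param value_kind `"count"` or `"percent"` (vectorized).
#' @param lower,upper numeric bounds (vectorized).
#' @return character vector: `"present"`, `"absent"`, or `"indeterminate"`.
#' @export
classify_polarity <- function(value_kind, lower, upper) {
  present <- ifelse(value_kind == "count", lower >= 1, lower > 0)
  dplyr::case_when(
    present ~ "present",
    upper == 0 ~ "absent",
    .default = "indeterminate"
  )
}

#' Presence classes entailed by a single measurement
#'
#' Returns the polarity's convenience class for the measured trait plus its
#' full superclass closure; an indeterminate range entails nothing.
#'
#' @param trait_id trait id (must resolve in `catalog`).
#' @param value_kind,lower,upper the measurement range.
#' @param catalog a catalog with derived presence classes.
#' @return character vector of presence-class ids (possibly empty), in
#'   breadth-first closure order.
#' @export
infer_types <- function(trait_id, value_kind, lower, upper, catalog) {
  if (!trait_id %in% catalog$traits$id) abort_unknown_term(trait_id)
  pol <- classify_polarity(value_kind, lower, upper)
  if (pol == "indeterminate") return(character())
  presence_superclasses(presence_class_id(trait_id, pol), catalog)
}

#' Materialize inferred presence classes for a table of observations
#'
#' Stage-3 reasoning of the integration pipeline: every measurement is
#' classified and its entailed classes computed, then unioned per
#' observation. Every observation appears in the output, including those
#' whose measurements are all indeterminate (they entail the empty set).
#' Measurements on traits unknown to the catalog do not abort the run; they
#' are collected in the `problems` report.
#'
#' @param observations observation-layout tibble (one measurement per row).
#' @param catalog a catalog with derived presence classes.
#' @return a list of class `materialized_traits`:
#'   \describe{
#'     \item{assertions}{tibble `(observation_id, class_id)`, sorted}
#'     \item{polarities}{tibble `(observation_id, trait_id, polarity)` for
#'       every classified measurement}
#'     \item{problems}{tibble `(observation_id, rule, detail)`}
#'   }
#' @export
materialize <- function(observations, catalog) {
  stopifnot(inherits(catalog, "trait_catalog"))
  if (!isTRUE(catalog$derived)) {
    pk_abort("catalog has no derived presence classes", "phenokit_not_derived_error")
  }
  obs <- as_tibble(observations)

  known <- obs$trait_id %in% catalog$traits$id
  problems <- tibble(
    observation_id = obs$observation_id[!known],
    rule = rep("unknown_trait", sum(!known)),
    detail = paste0("trait not in catalog: ", obs$trait_id[!known])
  )
  obs <- obs[known, , drop = FALSE]

  polarities <- tibble(
    observation_id = obs$observation_id,
    trait_id = obs$trait_id,
    polarity = classify_polarity(obs$value_kind, obs$lower, obs$upper)
  )

  determinate <- polarities |>
    dplyr::filter(.data$polarity != "indeterminate") |>
    dplyr::mutate(class_id = presence_class_id(.data$trait_id, .data$polarity))

  # one closure computation per distinct start class, then a join
  starts <- unique(determinate$class_id)
  adj <- closure_adjacency(catalog)
  closures <- purrr::map(starts, bfs_closure, adj = adj)
  closure_tbl <- tibble(
    class_id = rep(starts, lengths(closures)),
    entailed = as.character(unlist(closures, use.names = FALSE))
  )

  assertions <- determinate |>
    dplyr::inner_join(closure_tbl, by = "class_id",
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$observation_id, class_id = .data$entailed) |>
    dplyr::arrange(.data$observation_id, .data$class_id)

  # observations whose measurements entail nothing still appear (empty set)
  all_ids <- unique(as_tibble(observations)$observation_id)
  structure(
    list(assertions = assertions,
         polarities = polarities,
         observation_ids = all_ids,
         problems = problems),
    class = "materialized_traits"
  )
}

#' @export
print.materialized_traits <- function(x, ...) {
  cat("<materialized_traits>\n")
  cat("  observations:", length(x$observation_ids), "\n")
  cat("  assertions:  ", nrow(x$assertions), "\n")
  cat("  problems:    ", nrow(x$problems), "\n")
  invisible(x)
}

#' Detect contradictory presence assertions
#'
#' A conflict is an (observation, trait) pair inferred both present and
#' absent — typically two source rows for the same trait merged into one
#' observation. Conflicts are data, not errors: the pipeline excludes the
#' affected observations from analysis exports and reports them.
#'
#' @param materialized a `materialized_traits` object.
#' @return tibble `(observation_id, trait_id)`, one row per conflict.
#' @export
check_consistency <- function(materialized) {
  stopifnot(inherits(materialized, "materialized_traits"))
  materialized$polarities |>
    dplyr::filter(.data$polarity != "indeterminate") |>
    dplyr::distinct(.data$observation_id, .data$trait_id, .data$polarity) |>
    dplyr::count(.data$observation_id, .data$trait_id) |>
    dplyr::filter(.data$n > 1L) |>
    dplyr::select("observation_id", "trait_id")
}

#' Write materialized assertions as a long CSV
#'
#' Columns `(observation_id, class_id)`, sorted; expected-assertion fixture
#' files use the same layout so a diff is a straight file comparison.
#'
#' @param materialized a `materialized_traits` object.
#' @param path output path.
#' @export
write_assertions_csv <- function(materialized, path) {
  readr::write_csv(materialized$assertions, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_assertions_csv
#' @export
read_assertions_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    observation_id = readr::col_character(),
    class_id = readr::col_character()
  ), progress = FALSE)
}
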