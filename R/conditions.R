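# Structured condition classes. Every phenokit error carries a subclass of
# "phenokit_error" so callers can branch on the failure kind rather than on
# message text.

pk_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "phenokit_error"), ...)
}

abort_duplicate_term <- function(ids) {
  pk_abort(
    paste0("duplicate term id(s): ", paste(unique(ids), collapse = ", ")),
    "phenokit_duplicate_term_error"
  )
}

abort_unresolved_reference <- function(ids) {
  pk_abort(
    paste0("unresolved reference(s): ", paste(unique(ids), collapse = ", ")),
    "phenokit_unresolved_reference_error"
  )
}

abort_cycle <- function(ids) {
  pk_abort(
    paste0("cycle in subclass links involving: ", paste(ids, collapse = ", ")),
    "phenokit_cycle_error"
  )
}

abort_already_derived <- function() {
  pk_abort("presence classes have already been derived for this catalog",
           "phenokit_already_derived_error")
}

abort_unknown_term <- function(id) {
  pk_abort(paste0("unknown term: ", id), "phenokit_unknown_term_error")
}

abort_range <- function(message) {
  pk_abort(message, "phenokit_range_error")
}

abort_schema <- function(message) {
  pk_abort(message, "phenokit_schema_error")
}

abort_insufficient_data <- function(message) {
  pk_abort(message, "phenokit_insufficient_data_error")
}

abort_degenerate_data <- function(message) {
  pk_abort(message, "phenokit_degenerate_data_error")
}

abort_parameter <- function(message) {
  pk_abort(message, "phenokit_parameter_error")
}
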