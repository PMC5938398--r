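#' Construct a trait catalog from its component tables
#'
#' A trait catalog holds the graph of plant-structure terms (subclass and
#' parthood links), the phenological-trait terms that measure them, and —
#' after [derive_presence_classes()] — the machine-derived present/absent
#' convenience-class hierarchies. Most users will call [load_catalog()] or
#' [default_catalog()] instead of this low-level constructor.
#'
#' @param structures tibble with columns `id`, `label`.
#' @param subclass tibble with columns `child`, `parent` (both structure ids);
#'   read as "child is a subclass of parent".
#' @param parthood tibble with columns `whole`, `part`; read as "whole has
#'   visible part some part".
#' @param traits tibble with columns `id`, `label`, `structure`, `modality`
#'   (`"attached"` or `"abscised"`).
#' @param validate if `TRUE` (default), invariant violations raise errors;
#'   set `FALSE` to build deliberately broken catalogs for inspection with
#'   [validate_catalog()].
#' @return an object of class `trait_catalog`.
#' @export
trait_catalog <- function(structures,
                          subclass = empty_edge_table("child", "parent"),
                          parthood = empty_edge_table("whole", "part"),
                          traits = tibble(id = character(), label = character(),
                                          structure = character(),
                                          modality = character()),
                          validate = TRUE) {
  cat <- structure(
    list(
      structures = dplyr::arrange(as_tibble(structures), .data$id),
      subclass = dplyr::distinct(dplyr::arrange(as_tibble(subclass),
                                                .data$child, .data$parent)),
      parthood = dplyr::distinct(dplyr::arrange(as_tibble(parthood),
                                                .data$whole, .data$part)),
      traits = dplyr::arrange(as_tibble(traits), .data$id),
      classes = NULL,
      class_edges = NULL,
      derived = FALSE
    ),
    class = "trait_catalog"
  )
  if (validate) {
    stop_on_violations(cat)
  }
  cat
}

empty_edge_table <- function(a, b) {
  out <- tibble(x = character(), y = character())
  names(out) <- c(a, b)
  out
}

catalog_schema_columns <- c("record_kind", "subject_id", "object_id",
                            "label", "modality")

#' Load a trait catalog from a TSV definition file
#'
#' The file is a UTF-8 TSV with columns `record_kind`, `subject_id`,
#' `object_id`, `label`, `modality`. `record_kind` is one of:
#' \describe{
#'   \item{structure}{declares a plant-structure term (`subject_id`, `label`)}
#'   \item{subclass}{`subject_id` is a subclass of `object_id`}
#'   \item{part}{`subject_id` has visible part some `object_id`}
#'   \item{trait}{declares a phenological trait (`subject_id`) measured by the
#'     count/percentage of structure `object_id`, with `modality` either
#'     `attached` (structures on the plant) or `abscised` (structures the
#'     plant has shed)}
#' }
#' Row order never affects the result. Presence classes are not derived yet;
#' call [derive_presence_classes()] on the result.
#'
#' @param path path to the catalog TSV.
#' @return a validated `trait_catalog` (presence classes not yet derived).
#' @seealso [default_catalog()] for the catalog shipped with the package.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) {
    abort_schema(paste0("catalog file not found: ", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(catalog_schema_columns, names(raw))
  if (length(missing_cols) > 0) {
    abort_schema(paste0("catalog file missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  bad_kind <- setdiff(unique(raw$record_kind),
                      c("structure", "subclass", "part", "trait"))
  if (length(bad_kind) > 0) {
    abort_schema(paste0("unknown record_kind: ", paste(bad_kind, collapse = ", ")))
  }

  structures <- raw |>
    dplyr::filter(.data$record_kind == "structure") |>
    dplyr::transmute(id = .data$subject_id,
                     label = dplyr::coalesce(.data$label, .data$subject_id))
  subclass <- raw |>
    dplyr::filter(.data$record_kind == "subclass") |>
    dplyr::transmute(child = .data$subject_id, parent = .data$object_id)
  parthood <- raw |>
    dplyr::filter(.data$record_kind == "part") |>
    dplyr::transmute(whole = .data$subject_id, part = .data$object_id)
  traits <- raw |>
    dplyr::filter(.data$record_kind == "trait") |>
    dplyr::transmute(id = .data$subject_id,
                     label = dplyr::coalesce(.data$label, .data$subject_id),
                     structure = .data$object_id,
                     modality = dplyr::coalesce(.data$modality, "attached"))
  bad_modality <- setdiff(unique(traits$modality), c("attached", "abscised"))
  if (length(bad_modality) > 0) {
    abort_schema(paste0("unknown trait modality: ",
                        paste(bad_modality, collapse = ", ")))
  }

  trait_catalog(structures, subclass, parthood, traits, validate = TRUE)
}

# Raise the first invariant violation as a typed error (load-time contract).
stop_on_violations <- function(cat) {
  dup <- c(cat$structures$id[duplicated(cat$structures$id)],
           cat$traits$id[duplicated(cat$traits$id)],
           intersect(cat$structures$id, cat$traits$id))
  if (length(dup) > 0) abort_duplicate_term(dup)

  known <- cat$structures$id
  dangling <- c(setdiff(c(cat$subclass$child, cat$subclass$parent), known),
                setdiff(c(cat$parthood$whole, cat$parthood$part), known),
                setdiff(cat$traits$structure, known))
  if (length(dangling) > 0) abort_unresolved_reference(dangling)

  cyc <- find_cycle(cat$subclass$child, cat$subclass$parent)
  if (!is.null(cyc)) abort_cycle(cyc)
  invisible(cat)
}

# Depth-first cycle detection on a directed edge list; returns the node ids on
# one cycle, or NULL if the graph is acyclic. Self-loops count as cycles.
find_cycle <- function(from, to) {
  nodes <- unique(c(from, to))
  if (length(nodes) == 0) return(NULL)
  adj <- split(to, factor(from, levels = nodes))
  color <- setNames(rep(0L, length(nodes)), nodes)  # 0 white, 1 grey, 2 black
  for (root in nodes) {
    if (color[[root]] != 0L) next
    # iterative DFS with an explicit stack of (node, next-child-index)
    stack <- list(list(node = root, i = 1L))
    color[[root]] <- 1L
    path <- root
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      kids <- adj[[top$node]]
      if (is.null(kids) || top$i > length(kids)) {
        color[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
        path <- path[-length(path)]
        next
      }
      stack[[length(stack)]]$i <- top$i + 1L
      child <- kids[[top$i]]
      if (color[[child]] == 1L) {
        start <- match(child, path)
        return(c(path[start:length(path)], child))
      }
      if (color[[child]] == 0L) {
        color[[child]] <- 1L
        stack[[length(stack) + 1L]] <- list(node = child, i = 1L)
        path <- c(path, child)
      }
    }
  }
  NULL
}

# Mechanical id for a presence class: the trait id with a trailing "_presence"
# stripped, plus the polarity suffix.
presence_class_id <- function(trait_id, polarity) {
  if (length(trait_id) == 0) return(character(0))
  paste0(sub("_presence$", "", trait_id), "_", polarity)
}

presence_class_label <- function(trait_label, polarity) {
  paste(sub(" presence$", "", trait_label), polarity)
}

#' Derive present/absent convenience classes and their hierarchies
#'
#' For every trait two qualitative classes are created, one per polarity
#' (`present` / `absent`). Superclass edges between them are derived from the
#' structure graph, never authored:
#' \itemize{
#'   \item For a structure subclass edge child \eqn{\sqsubseteq} parent, where
#'     both structures are measured by traits of the same modality:
#'     present(child) \eqn{\sqsubseteq} present(parent), and — the hierarchy is
#'     inverted for the absent classes — absent(parent) \eqn{\sqsubseteq}
#'     absent(child). A plant with dormant leaf buds has leaf buds; a plant
#'     with no leaf buds at all has no dormant leaf buds.
#'   \item For a parthood edge whole –has visible part→ part (an existential
#'     requirement), with both structures trait-measured at the same modality:
#'     present(whole) \eqn{\sqsubseteq} present(part), and contrapositively
#'     absent(part) \eqn{\sqsubseteq} absent(whole).
#' }
#'
#' @param catalog a validated `trait_catalog` without derived classes.
#' @param use_parthood whether parthood edges propagate presence (default
#'   `TRUE`); toggleable because only the subclass rule is forced by the
#'   structure hierarchy itself.
#' @return the catalog with `classes` and `class_edges` populated.
#' @export
derive_presence_classes <- function(catalog, use_parthood = TRUE) {
  stopifnot(inherits(catalog, "trait_catalog"))
  if (isTRUE(catalog$derived)) abort_already_derived()

  traits <- catalog$traits
  classes <- dplyr::bind_rows(
    tibble(class_id = presence_class_id(traits$id, "present"),
           trait_id = traits$id, polarity = "present",
           label = presence_class_label(traits$label, "present")),
    tibble(class_id = presence_class_id(traits$id, "absent"),
           trait_id = traits$id, polarity = "absent",
           label = presence_class_label(traits$label, "absent"))
  ) |> dplyr::arrange(.data$class_id)

  by_structure <- traits |> dplyr::select(trait = "id", "structure", "modality")

  pair_edges <- function(edges, lower_col, upper_col) {
    # pair traits across a structure edge; lower/upper in the presence sense
    edges |>
      dplyr::inner_join(by_structure, by = setNames("structure", lower_col),
                        relationship = "many-to-many") |>
      dplyr::rename(trait_lo = "trait", modality_lo = "modality") |>
      dplyr::inner_join(by_structure, by = setNames("structure", upper_col),
                        relationship = "many-to-many") |>
      dplyr::rename(trait_hi = "trait", modality_hi = "modality") |>
      dplyr::filter(.data$modality_lo == .data$modality_hi)
  }

  pairs <- pair_edges(catalog$subclass, "child", "parent")
  if (use_parthood) {
    # whole plays the specific role (its presence implies the part's)
    pairs <- dplyr::bind_rows(
      pairs,
      pair_edges(catalog$parthood, "whole", "part")
    )
  }

  class_edges <- dplyr::bind_rows(
    tibble(class_id = presence_class_id(pairs$trait_lo, "present"),
           superclass_id = presence_class_id(pairs$trait_hi, "present"),
           polarity = "present"),
    tibble(class_id = presence_class_id(pairs$trait_hi, "absent"),
           superclass_id = presence_class_id(pairs$trait_lo, "absent"),
           polarity = "absent")
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$polarity, .data$class_id, .data$superclass_id)

  catalog$classes <- classes
  catalog$class_edges <- class_edges
  catalog$derived <- TRUE
  catalog
}

#' Reflexive-transitive superclass closure of a presence class
#'
#' Returns the class itself plus every more general class reachable along
#' derived superclass edges, in deterministic order: breadth-first from the
#' query class, lexicographic within each level, first discovery wins.
#'
#' @param class_id a presence-class id.
#' @param catalog a catalog with derived presence classes.
#' @return character vector of class ids (the closure, query class first).
#' @export
presence_superclasses <- function(class_id, catalog) {
  stopifnot(inherits(catalog, "trait_catalog"))
  if (!isTRUE(catalog$derived)) {
    pk_abort("presence classes have not been derived; call derive_presence_classes()",
             "phenokit_not_derived_error")
  }
  if (!class_id %in% catalog$classes$class_id) abort_unknown_term(class_id)
  adj <- closure_adjacency(catalog)
  bfs_closure(class_id, adj)
}

# superclass adjacency list keyed by class_id, values sorted for determinism;
# memoised on the catalog object via attribute when called through materialize
closure_adjacency <- function(catalog) {
  e <- catalog$class_edges
  lapply(split(e$superclass_id, factor(e$class_id, levels = unique(e$class_id))),
         sort)
}

bfs_closure <- function(start, adj) {
  seen <- start
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- sort(unique(unlist(adj[frontier], use.names = FALSE)))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Validate a trait catalog and report violations
#'
#' Unlike the load-time checks, this never throws: violations are returned as
#' data, one row each, so corrupted catalogs can be triaged. An empty report
#' means the catalog satisfies every structural invariant (and, when presence
#' classes are derived, the duality and pairing invariants too).
#'
#' @param catalog a `trait_catalog` (possibly built with `validate = FALSE`).
#' @return tibble with columns `rule`, `subject`, `detail`.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "trait_catalog"))
  v <- list()
  add <- function(rule, subject, detail) {
    v[[length(v) + 1L]] <<- tibble(rule = rule, subject = subject, detail = detail)
  }

  for (id in unique(catalog$structures$id[duplicated(catalog$structures$id)])) {
    add("duplicate_term", id, "structure id declared more than once")
  }
  for (id in unique(catalog$traits$id[duplicated(catalog$traits$id)])) {
    add("duplicate_term", id, "trait id declared more than once")
  }
  for (id in intersect(catalog$structures$id, catalog$traits$id)) {
    add("duplicate_term", id, "id used for both a structure and a trait")
  }

  known <- unique(catalog$structures$id)
  for (id in setdiff(c(catalog$subclass$child, catalog$subclass$parent), known)) {
    add("unresolved_reference", id, "subclass link references undeclared structure")
  }
  for (id in setdiff(c(catalog$parthood$whole, catalog$parthood$part), known)) {
    add("unresolved_reference", id, "parthood link references undeclared structure")
  }
  for (id in setdiff(unique(catalog$traits$structure), known)) {
    add("unresolved_reference", id, "trait measures undeclared structure")
  }

  cyc <- find_cycle(catalog$subclass$child, catalog$subclass$parent)
  if (!is.null(cyc)) {
    add("cycle", paste(cyc, collapse = " -> "), "cycle in structure subclass links")
  }

  for (m in setdiff(unique(catalog$traits$modality), c("attached", "abscised"))) {
    add("bad_modality", m, "trait modality must be 'attached' or 'abscised'")
  }

  if (isTRUE(catalog$derived)) {
    counts <- catalog$classes |>
      dplyr::count(.data$trait_id, .data$polarity)
    per_trait <- tidyr::pivot_wider(counts, names_from = "polarity",
                                    values_from = "n", values_fill = 0L)
    for (i in seq_len(nrow(per_trait))) {
      row <- per_trait[i, ]
      if (!identical(row$present, 1L) || !identical(row$absent, 1L)) {
        add("polarity_pairing", row$trait_id,
            "trait must have exactly one class per polarity")
      }
    }
    mism <- duality_mismatches(catalog)
    for (i in seq_len(nrow(mism))) {
      add("duality", paste(mism$class_id[i], "->", mism$superclass_id[i]),
          "absent edge set is not the polarity-flipped reverse of the present edges")
    }
    cyc2 <- find_cycle(catalog$class_edges$class_id,
                       catalog$class_edges$superclass_id)
    if (!is.null(cyc2)) {
      add("cycle", paste(cyc2, collapse = " -> "), "cycle in derived presence hierarchy")
    }
  }

  if (length(v) == 0) {
    tibble(rule = character(), subject = character(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}

# Edges violating the duality mirror, in either direction. The expected
# relationship: (a_absent -> b_absent) is an edge iff (b_present -> a_present)
# is one, where a/b are the class stems.
duality_mismatches <- function(catalog) {
  e <- catalog$class_edges
  stem <- function(x, pol) sub(paste0("_", pol, "$"), "", x)
  present <- e[e$polarity == "present", ]
  absent <- e[e$polarity == "absent", ]
  mirrored_present <- tibble(
    class_id = paste0(stem(absent$superclass_id, "absent"), "_present"),
    superclass_id = paste0(stem(absent$class_id, "absent"), "_present"),
    polarity = "present"
  )
  dplyr::bind_rows(
    dplyr::anti_join(present, mirrored_present,
                     by = c("class_id", "superclass_id")),
    dplyr::anti_join(mirrored_present, present,
                     by = c("class_id", "superclass_id"))
  )
}

#' Write the derived presence-class hierarchy as a TSV edge list
#'
#' @param catalog a derived catalog.
#' @param path output path; columns `class_id`, `superclass_id`, `polarity`.
#' @return `path`, invisibly.
#' @export
write_presence_edges <- function(catalog, path) {
  stopifnot(inherits(catalog, "trait_catalog"), isTRUE(catalog$derived))
  readr::write_tsv(catalog$class_edges, path, progress = FALSE)
  invisible(path)
}

#' The trait catalog shipped with phenokit
#'
#' A compact catalog covering leaf buds (dormant, non-dormant, swelling,
#' breaking), true leaves (unfolding, unfolded, expanding, senescing), flowers
#' (buds, open, pollen-releasing, senesced), fruits, and cones, with one
#' attached presence trait per structure plus abscised-leaf and abscised-fruit
#' traits. This is a working subset for analysis and testing, not a full
#' ontology release.
#'
#' @param derive derive the presence classes before returning (default `TRUE`).
#' @param use_parthood passed to [derive_presence_classes()].
#' @return a `trait_catalog`.
#' @export
default_catalog <- function(derive = TRUE, use_parthood = TRUE) {
  path <- system.file("extdata", "phenokit_catalog.tsv", package = "phenokit",
                      mustWork = TRUE)
  cat <- load_catalog(path)
  if (derive) cat <- derive_presence_classes(cat, use_parthood = use_parthood)
  cat
}

#' @export
print.trait_catalog <- function(x, ...) {
  cat("<trait_catalog>\n")
  cat("  structures:      ", nrow(x$structures), "\n")
  cat("  subclass links:  ", nrow(x$subclass), "\n")
  cat("  parthood links:  ", nrow(x$parthood), "\n")
  cat("  traits:          ", nrow(x$traits), "\n")
  if (isTRUE(x$derived)) {
    cat("  presence classes:", nrow(x$classes),
        "(", nrow(x$class_edges), "derived edges )\n")
  } else {
    cat("  presence classes: not derived\n")
  }
  invisible(x)
}
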