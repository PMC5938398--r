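# Shared test utilities: random catalog/measurement generators and
# independent oracles. The oracles deliberately re-derive presence edges with
# plain nested loops and use igraph reachability, so they share no code with
# the package's dplyr-join + BFS implementation.

# Random acyclic catalog: structure edges always point from a higher to a
# lower index, so the structure graph (subclass plus parthood) is acyclic by
# construction.
random_catalog <- function(n_structures = 12, p_subclass = 0.25,
                           p_parthood = 0.08, p_attached = 0.8,
                           p_abscised = 0.25) {
  ids <- sprintf("s%02d", seq_len(n_structures))
  sub <- list(); part <- list()
  for (i in seq_len(n_structures)) {
    for (j in seq_len(i - 1)) {
      r <- runif(1)
      if (r < p_subclass) {
        sub[[length(sub) + 1]] <- c(ids[i], ids[j])
      } else if (r < p_subclass + p_parthood) {
        part[[length(part) + 1]] <- c(ids[i], ids[j])
      }
    }
  }
  traits <- list()
  for (i in seq_len(n_structures)) {
    if (runif(1) < p_attached) {
      traits[[length(traits) + 1]] <- c(paste0("t_", ids[i], "_att"), ids[i], "attached")
    }
    if (runif(1) < p_abscised) {
      traits[[length(traits) + 1]] <- c(paste0("t_", ids[i], "_abs"), ids[i], "abscised")
    }
  }
  if (length(traits) == 0) {
    traits[[1]] <- c(paste0("t_", ids[1], "_att"), ids[1], "attached")
  }
  to_tbl <- function(lst, nms) {
    m <- do.call(rbind, lst)
    out <- tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
    names(out) <- nms
    out
  }
  trait_catalog(
    structures = tibble::tibble(id = ids, label = ids),
    subclass = if (length(sub)) to_tbl(sub, c("child", "parent"))
               else tibble::tibble(child = character(), parent = character()),
    parthood = if (length(part)) to_tbl(part, c("whole", "part"))
               else tibble::tibble(whole = character(), part = character()),
    traits = {
      tt <- to_tbl(traits, c("id", "structure", "modality"))
      tibble::tibble(id = tt$id, label = tt$id, structure = tt$structure,
                     modality = tt$modality)
    }
  )
}

# Independent re-derivation of the presence edge set: nested loops over every
# structure edge and every trait pair.
oracle_presence_edges <- function(catalog) {
  traits <- catalog$traits
  edges <- list()
  add <- function(a, b, pol) {
    edges[[length(edges) + 1]] <<- c(a, b, pol)
  }
  stem <- function(tid) sub("_presence$", "", tid)
  struct_edges <- rbind(
    cbind(lo = catalog$subclass$child, hi = catalog$subclass$parent),
    cbind(lo = catalog$parthood$whole, hi = catalog$parthood$part)
  )
  if (nrow(struct_edges) > 0) {
    for (k in seq_len(nrow(struct_edges))) {
      for (i in which(traits$structure == struct_edges[k, "lo"])) {
        for (j in which(traits$structure == struct_edges[k, "hi"])) {
          if (traits$modality[i] == traits$modality[j]) {
            add(paste0(stem(traits$id[i]), "_present"),
                paste0(stem(traits$id[j]), "_present"), "present")
            add(paste0(stem(traits$id[j]), "_absent"),
                paste0(stem(traits$id[i]), "_absent"), "absent")
          }
        }
      }
    }
  }
  if (length(edges) == 0) {
    return(tibble::tibble(class_id = character(), superclass_id = character(),
                          polarity = character()))
  }
  m <- do.call(rbind, edges)
  unique(tibble::tibble(class_id = m[, 1], superclass_id = m[, 2],
                        polarity = m[, 3]))
}

# Reachability closure via igraph on an independently derived edge set.
oracle_closure <- function(class_id, catalog) {
  edges <- oracle_presence_edges(catalog)
  all_classes <- unique(c(
    paste0(sub("_presence$", "", catalog$traits$id), "_present"),
    paste0(sub("_presence$", "", catalog$traits$id), "_absent")
  ))
  g <- igraph::graph_from_data_frame(
    edges[, c("class_id", "superclass_id")],
    directed = TRUE, vertices = all_classes
  )
  sort(names(igraph::subcomponent(g, class_id, mode = "out")))
}

# Independent polarity rule for the oracle route.
oracle_polarity <- function(value_kind, lower, upper) {
  if ((value_kind == "count" && lower >= 1) ||
      (value_kind == "percent" && lower > 0)) return("present")
  if (upper == 0) return("absent")
  "indeterminate"
}

random_measurement <- function(catalog) {
  trait <- sample(catalog$traits$id, 1)
  kind <- sample(c("count", "percent"), 1)
  shape <- sample(c("zero", "straddle", "positive", "unbounded"), 1)
  if (kind == "count") {
    b <- switch(shape,
                zero = c(0, 0),
                straddle = c(0, sample(1:20, 1)),
                positive = sort(sample(1:30, 2, replace = TRUE)),
                unbounded = c(sample(1:5, 1), Inf))
  } else {
    b <- switch(shape,
                zero = c(0, 0),
                straddle = c(0, runif(1, 1, 100)),
                positive = sort(runif(2, 0.5, 100)),
                unbounded = sort(runif(2, 0.5, 100)))
  }
  list(trait_id = trait, value_kind = kind, lower = b[1], upper = b[2])
}

# Minimal observation-layout row.
obs_row <- function(observation_id, trait_id, value_kind, lower, upper,
                    subject_id = "plant_1", genus = "Acer", species = "",
                    latitude = 48.2, longitude = 16.4,
                    date = as.Date("2015-06-01"), source = "other",
                    source_record_id = observation_id) {
  tibble::tibble(
    observation_id = observation_id, subject_id = subject_id, genus = genus,
    species = species, latitude = latitude, longitude = longitude,
    date = date, trait_id = trait_id, value_kind = value_kind,
    lower = lower, upper = upper, source = source,
    source_record_id = source_record_id
  )
}

# Small catalog used across reasoner tests: a three-level subclass chain plus
# one parthood edge.
chain_catalog <- function() {
  derive_presence_classes(trait_catalog(
    structures = tibble::tibble(
      id = c("a", "b", "c", "w"),
      label = c("a", "b", "c", "w")
    ),
    subclass = tibble::tibble(child = c("a", "b"), parent = c("b", "c")),
    parthood = tibble::tibble(whole = "w", part = "a"),
    traits = tibble::tibble(
      id = c("ta", "tb", "tc", "tw"),
      label = c("ta", "tb", "tc", "tw"),
      structure = c("a", "b", "c", "w"),
      modality = "attached"
    )
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

write_lines_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
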