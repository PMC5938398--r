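leafbud_file <- function() {
  write_lines_tmp(c(
    "record_kind\tsubject_id\tobject_id\tlabel\tmodality",
    "structure\tleaf_bud\t\tleaf bud\t",
    "structure\tdormant_leaf_bud\t\tdormant leaf bud\t",
    "subclass\tdormant_leaf_bud\tleaf_bud\t\t",
    "trait\tleaf_bud_presence\tleaf_bud\tleaf bud presence\tattached",
    "trait\tdormant_leaf_bud_presence\tdormant_leaf_bud\tdormant leaf bud presence\tattached"
  ), ext = ".tsv")
}

test_that("load_catalog parses structures, links, and traits", {
  cat_ <- load_catalog(leafbud_file())
  expect_equal(nrow(cat_$structures), 2)
  expect_equal(nrow(cat_$traits), 2)
  expect_equal(nrow(cat_$subclass), 1)
  expect_false(cat_$derived)

  empty <- load_catalog(write_lines_tmp(
    "record_kind\tsubject_id\tobject_id\tlabel\tmodality", ext = ".tsv"))
  expect_equal(nrow(empty$structures), 0)
  expect_equal(nrow(empty$traits), 0)
})

test_that("load_catalog rejects malformed catalogs with typed errors", {
  expect_error(
    load_catalog(write_lines_tmp(c(
      "record_kind\tsubject_id\tobject_id\tlabel\tmodality",
      "structure\tleaf_bud\t\tleaf bud\t",
      "structure\tleaf_bud\t\tleaf bud again\t"
    ), ext = ".tsv")),
    class = "phenokit_duplicate_term_error"
  )
  expect_error(
    load_catalog(write_lines_tmp(c(
      "record_kind\tsubject_id\tobject_id\tlabel\tmodality",
      "structure\tleaf_bud\t\tleaf bud\t",
      "subclass\tleaf_bud\tghost\t\t"
    ), ext = ".tsv")),
    class = "phenokit_unresolved_reference_error"
  )
  expect_error(
    load_catalog(write_lines_tmp(c(
      "record_kind\tsubject_id\tobject_id\tlabel\tmodality",
      "structure\tdormant_leaf_bud\t\tdormant leaf bud\t",
      "subclass\tdormant_leaf_bud\tdormant_leaf_bud\t\t"
    ), ext = ".tsv")),
    class = "phenokit_cycle_error"
  )
  expect_error(load_catalog(write_lines_tmp("record_kind\tsubject_id",
                                            ext = ".tsv")),
               class = "phenokit_schema_error")
})

test_that("subclass edges invert for absent classes", {
  cat_ <- derive_presence_classes(load_catalog(leafbud_file()))
  expect_true(
    "leaf_bud_present" %in%
      presence_superclasses("dormant_leaf_bud_present", cat_)
  )
  # the absent hierarchy is reversed: lacking leaf buds entails lacking
  # dormant leaf buds, never the other way around
  expect_true(
    "dormant_leaf_bud_absent" %in% presence_superclasses("leaf_bud_absent", cat_)
  )
  expect_identical(presence_superclasses("dormant_leaf_bud_absent", cat_),
                   "dormant_leaf_bud_absent")
})

test_that("a lone trait yields two classes and no edges", {
  cat_ <- derive_presence_classes(trait_catalog(
    structures = tibble::tibble(id = "leaf", label = "leaf"),
    traits = tibble::tibble(id = "leaf_presence", label = "leaf presence",
                            structure = "leaf", modality = "attached")
  ))
  expect_equal(nrow(cat_$classes), 2)
  expect_equal(nrow(cat_$class_edges), 0)
  expect_identical(presence_superclasses("leaf_present", cat_), "leaf_present")
})

test_that("parthood edges propagate presence from whole to part", {
  cat_ <- derive_presence_classes(trait_catalog(
    structures = tibble::tibble(id = c("breaking_leaf_bud", "unfolding_true_leaf"),
                                label = c("breaking leaf bud", "unfolding true leaf")),
    parthood = tibble::tibble(whole = "breaking_leaf_bud",
                              part = "unfolding_true_leaf"),
    traits = tibble::tibble(
      id = c("breaking_leaf_bud_presence", "unfolding_true_leaf_presence"),
      label = c("breaking leaf bud presence", "unfolding true leaf presence"),
      structure = c("breaking_leaf_bud", "unfolding_true_leaf"),
      modality = "attached"
    )
  ))
  expect_setequal(
    presence_superclasses("breaking_leaf_bud_present", cat_),
    c("breaking_leaf_bud_present", "unfolding_true_leaf_present")
  )
  # contrapositive: no visible part implies the whole cannot be present
  expect_setequal(
    presence_superclasses("unfolding_true_leaf_absent", cat_),
    c("unfolding_true_leaf_absent", "breaking_leaf_bud_absent")
  )
  # toggled off, the parthood rule contributes nothing
  plain <- derive_presence_classes(trait_catalog(
    structures = tibble::tibble(id = c("breaking_leaf_bud", "unfolding_true_leaf"),
                                label = c("a", "b")),
    parthood = tibble::tibble(whole = "breaking_leaf_bud",
                              part = "unfolding_true_leaf"),
    traits = tibble::tibble(
      id = c("breaking_leaf_bud_presence", "unfolding_true_leaf_presence"),
      label = c("a", "b"),
      structure = c("breaking_leaf_bud", "unfolding_true_leaf"),
      modality = "attached"
    )
  ), use_parthood = FALSE)
  expect_equal(nrow(plain$class_edges), 0)
})

test_that("presence propagation never crosses modalities", {
  cat_ <- derive_presence_classes(trait_catalog(
    structures = tibble::tibble(id = c("true_leaf", "unfolded_true_leaf"),
                                label = c("true leaf", "unfolded true leaf")),
    subclass = tibble::tibble(child = "unfolded_true_leaf", parent = "true_leaf"),
    traits = tibble::tibble(
      id = c("unfolded_true_leaf_presence", "abscised_true_leaf_presence"),
      label = c("x", "y"),
      structure = c("unfolded_true_leaf", "true_leaf"),
      modality = c("attached", "abscised")
    )
  ))
  expect_equal(nrow(cat_$class_edges), 0)
})

test_that("deriving twice is an error", {
  cat_ <- derive_presence_classes(load_catalog(leafbud_file()))
  expect_error(derive_presence_classes(cat_),
               class = "phenokit_already_derived_error")
})

test_that("catalog construction is invariant to input row order", {
  path <- leafbud_file()
  lines <- readLines(path)
  shuffled <- write_lines_tmp(c(lines[1], lines[c(6, 4, 2, 5, 3)]), ext = ".tsv")
  a <- derive_presence_classes(load_catalog(path))
  b <- derive_presence_classes(load_catalog(shuffled))
  expect_identical(a$structures, b$structures)
  expect_identical(a$subclass, b$subclass)
  expect_identical(a$traits, b$traits)
  expect_identical(a$classes, b$classes)
  expect_identical(a$class_edges, b$class_edges)
})

test_that("closure follows a chain and is returned breadth-first", {
  cat_ <- chain_catalog()
  expect_identical(presence_superclasses("ta_present", cat_),
                   c("ta_present", "tb_present", "tc_present"))
  expect_identical(presence_superclasses("tc_absent", cat_),
                   c("tc_absent", "tb_absent", "ta_absent", "tw_absent"))
  expect_error(presence_superclasses("nope_present", cat_),
               class = "phenokit_unknown_term_error")
})

test_that("closure equals igraph reachability on random catalogs", {
  set.seed(101)
  for (rep in 1:200) {
    cat_ <- derive_presence_classes(
      random_catalog(n_structures = sample(2:50, 1))
    )
    cls <- sample(cat_$classes$class_id, 1)
    expect_setequal(presence_superclasses(cls, cat_), oracle_closure(cls, cat_))
  }
})

test_that("derived edge sets match the nested-loop oracle", {
  set.seed(202)
  for (rep in 1:50) {
    cat_ <- derive_presence_classes(random_catalog(n_structures = sample(2:30, 1)))
    got <- dplyr::arrange(cat_$class_edges, class_id, superclass_id, polarity)
    want <- dplyr::arrange(oracle_presence_edges(cat_),
                           class_id, superclass_id, polarity)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("duality mirror and acyclicity hold on random catalogs", {
  set.seed(303)
  for (rep in 1:50) {
    cat_ <- derive_presence_classes(random_catalog(n_structures = sample(2:40, 1)))
    e <- cat_$class_edges
    present <- e[e$polarity == "present", c("class_id", "superclass_id")]
    absent <- e[e$polarity == "absent", c("class_id", "superclass_id")]
    flipped <- data.frame(
      class_id = sub("_absent$", "_present", absent$superclass_id),
      superclass_id = sub("_absent$", "_present", absent$class_id)
    )
    expect_setequal(paste(present$class_id, present$superclass_id),
                    paste(flipped$class_id, flipped$superclass_id))
    g <- igraph::graph_from_data_frame(e[, c("class_id", "superclass_id")])
    expect_true(igraph::is_dag(g))
  }
})

test_that("validate_catalog reports exactly the planted violations", {
  # hand-planted corruption
  broken <- trait_catalog(
    structures = tibble::tibble(id = c("a", "a", "b"), label = c("a", "a", "b")),
    subclass = tibble::tibble(child = c("b", "ghost"), parent = c("a", "a")),
    traits = tibble::tibble(id = "t1", label = "t1", structure = "missing",
                            modality = "floating"),
    validate = FALSE
  )
  report <- validate_catalog(broken)
  expect_setequal(report$rule, c("duplicate_term", "unresolved_reference",
                                 "bad_modality"))
  expect_equal(nrow(report), 4)

  expect_equal(nrow(validate_catalog(default_catalog())), 0)

  # randomly corrupted catalogs: report count equals an independent re-count
  set.seed(404)
  for (rep in 1:20) {
    cat_ <- random_catalog(n_structures = 10)
    n_dangle <- sample(0:3, 1)
    extra <- tibble::tibble(child = sprintf("ghost%d", seq_len(n_dangle)),
                            parent = sample(cat_$structures$id, n_dangle,
                                            replace = TRUE))
    cat_$subclass <- dplyr::bind_rows(cat_$subclass, extra)
    report <- validate_catalog(cat_)
    expect_equal(sum(report$rule == "unresolved_reference"), n_dangle)
  }
})

test_that("the derived hierarchy exports as a TSV edge list", {
  cat_ <- default_catalog()
  path <- tempfile(fileext = ".tsv")
  write_presence_edges(cat_, path)
  back <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  expect_equal(nrow(back), nrow(cat_$class_edges))
  expect_named(back, c("class_id", "superclass_id", "polarity"))
})
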