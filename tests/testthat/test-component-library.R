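test_that("complex labels are canonical, flat and idempotent", {
  expect_identical(make_complex_label(c("E", "A")), "A|E")
  expect_identical(make_complex_label(c("M", "G")), "G|M")
  expect_identical(make_complex_label("A"), "A")
  expect_identical(make_complex_label(c("A", "E")),
                   make_complex_label(constituents("E|A")))
  expect_error(make_complex_label(character(0L)))
  expect_error(make_complex_label(c("A|E", "B")))
  expect_identical(constituents("Raf1|ERKPP|RKIP"),
                   c("ERKPP", "RKIP", "Raf1"))
})

test_that("library generation yields 3 components per species-enzyme pair", {
  lib <- generate_library("A", "E")
  sigs <- vapply(lib$components, component_signature, character(1L))
  expect_setequal(sigs, c("A + E => A|E", "A|E => A + E", "A|E => AP + E"))
  expect_identical(length(generate_library(c("A", "B"), "E")$components), 6L)
  expect_error(generate_library("A", character(0L)))
  expect_error(generate_library(character(0L), "E"))
  # exhaustive size/duplicate check over all small set sizes
  for (ns in 1:3) {
    for (ne in 1:3) {
      lib <- generate_library(LETTERS[seq_len(ns)],
                              paste0("E", seq_len(ne)))
      sigs <- vapply(lib$components, component_signature, character(1L))
      expect_identical(length(sigs), 3L * ns * ne)
      expect_false(anyDuplicated(sigs) > 0L)
      for (cc in lib$components) {
        expect_true(validate_component(cc, strict = TRUE))
      }
    }
  }
})

test_that("compose merges places and rejects duplicates", {
  lib <- generate_library("A", "E")
  m <- petri_model(lib$components[[1L]])
  m2 <- compose(m, lib$components[[2L]])
  m3 <- compose(m2, lib$components[[3L]])
  expect_setequal(m3$places, c("A", "E", "A|E", "AP"))
  expect_length(m3$components, 3L)
  # merging adds no place when all labels already present
  expect_setequal(compose(m, lib$components[[2L]])$places, m2$places)
  # duplicate composition rejected, original untouched
  expect_error(compose(m2, lib$components[[1L]]),
               class = "qml_duplicate_component")
  expect_length(m2$components, 2L)
})

test_that("subtract inverts a fresh compose and drops orphaned places", {
  lib <- toy_library()
  m <- petri_model(lib$components[1:3])
  c4 <- lib$components[[4L]]
  expect_true(models_equal(subtract(compose(m, c4), c4), m))
  expect_error(subtract(petri_model(lib$components[[1L]]),
                        lib$components[[1L]]))
  expect_error(subtract(m, lib$components[[10L]]))
  # orphaned place dropped: verified against an igraph connectivity oracle
  skip_if_not_installed("igraph")
  big <- petri_model(list(component(c("A", "E"), "A|E"),
                          component(c("B", "F"), "B|F")))
  rem <- subtract(big, big$components[[2L]])
  g <- igraph::graph_from_edgelist(arcs(big))
  comp <- igraph::components(g)
  kept <- names(comp$membership)[
    comp$membership == comp$membership[["A"]]]
  expect_setequal(rem$places, intersect(big$places, kept))
})

test_that("place merging is order independent and canonical", {
  lib <- toy_library()
  idx <- c(1L, 4L, 7L, 10L)
  for (rep in 1:5) {
    perm <- sample(idx)
    m <- petri_model(lib$components[perm])
    expect_identical(m$places, petri_model(lib$components[idx])$places)
  }
  # A|E and E|A are the same place
  m <- petri_model(list(component(c("E", "A"), "E|A"),
                        component("A|E", c("A", "E"))))
  expect_identical(sum(m$places == "A|E"), 1L)
  expect_length(m$places, 3L)
})

test_that("crossover conserves the component multiset and repairs offspring", {
  lib <- toy_library()
  set.seed(11)
  for (i in 1:100) {
    n1 <- sample(2:6, 1L); n2 <- sample(2:6, 1L)
    m1 <- petri_model(lib$components[sample(12L, n1)])
    m2 <- petri_model(lib$components[sample(12L, n2)])
    off <- crossover(m1, m2)
    parent_sigs <- sort(c(model_signatures(m1), model_signatures(m2)))
    child_sigs <- sort(c(model_signatures(off[[1L]]),
                         model_signatures(off[[2L]])))
    expect_identical(child_sigs, parent_sigs)
    expect_true(validate_model(off[[1L]]))
    expect_true(validate_model(off[[2L]]))
  }
  # identical parents reproduce themselves up to component order
  m <- petri_model(lib$components[1:4])
  off <- crossover(m, m)
  expect_true(models_equal(off[[1L]], m))
  expect_true(models_equal(off[[2L]], m))
  # single-component parents degenerate to swap-or-identity
  s1 <- petri_model(lib$components[[1L]])
  s2 <- petri_model(lib$components[[4L]])
  off <- crossover(s1, s2)
  expect_true(isTRUE(attr(off, "degenerate")))
  expect_setequal(c(model_signatures(off[[1L]]), model_signatures(off[[2L]])),
                  c(model_signatures(s1), model_signatures(s2)))
})

test_that("arcs use name-free transition signatures", {
  a <- arcs(petri_model(component(c("A", "E"), "A|E")))
  expect_identical(nrow(a), 3L)
  expect_setequal(paste(a[, "from"], a[, "to"], sep = " -> "),
                  c("A -> A + E => A|E", "E -> A + E => A|E",
                    "A + E => A|E -> A|E"))
  # identical reactions built independently give identical arc keys
  m1 <- petri_model(component(c("E", "A"), "E|A"))
  m2 <- petri_model(component(c("A", "E"), "A|E"))
  expect_identical(arcs(m1), arcs(m2))
  # deterministic across calls on a larger fixture
  rk <- fixture_rkip()$model
  expect_identical(arcs(rk), arcs(rk))
})

test_that("models round-trip through JSON and export to PNML", {
  for (fx in list(fixture_enzymatic(), fixture_mgd(), fixture_rkip(),
                  fixture_stress_standin())) {
    back <- model_from_json(model_to_json(fx$model))
    expect_true(models_equal(back, fx$model))
    expect_identical(back$places, fx$model$places)
  }
  skip_if_not_installed("xml2")
  path <- withr::local_tempfile(fileext = ".pnml")
  write_pnml(fixture_enzymatic()$model, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, "//d1:place", ns), 4L)
  expect_length(xml2::xml_find_all(doc, "//d1:transition", ns), 3L)
})
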