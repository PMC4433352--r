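test_that("the enzymatic toy fixture encodes the reversible reaction", {
  fx <- fixture_enzymatic()
  expect_length(fx$model$places, 4L)
  expect_length(fx$model$components, 3L)
  sigs <- model_signatures(fx$model)
  expect_true("A + E => A|E" %in% sigs)
  expect_true("A|E => A + E" %in% sigs)
  expect_true(validate_model(fx$model))
  expect_setequal(fx$compared_variables, c("A", "AP"))
})

test_that("the MG-D fixture matches the pathway description", {
  fx <- fixture_mgd()
  prim <- fx$model$places[!is_complex(fx$model$places)]
  expect_setequal(prim, c("M", "G", "H", "S", "G1", "G2"))
  # d-lactate is not encoded
  expect_false(any(grepl("lact", fx$model$places, ignore.case = TRUE)))
  # one non-enzymatic reaction plus two reversible enzymatic conversions
  expect_length(fx$model$components, 7L)
  kinds <- table(vapply(fx$model$components, `[[`, character(1L), "kind"))
  expect_identical(unname(kinds[["binding"]]), 3L)
  expect_identical(unname(kinds[["unbinding"]]), 4L)
  expect_setequal(fx$compared_variables, c("M", "G", "H", "S"))
  expect_identical(fx$renaming, mgd_renaming())
})

test_that("the RKIP fixture has 11 reactants and 11 reactions", {
  fx <- fixture_rkip()
  expect_length(fx$model$places, 11L)
  expect_length(fx$model$components, 11L)
  expect_true(validate_model(fx$model))
  # the ternary complex flattens its constituents canonically
  tern <- fx$model$places[vapply(fx$model$places,
                                 function(p) length(constituents(p)) == 3L,
                                 logical(1L))]
  expect_identical(tern, "ERKPP|RKIP|Raf1")
  expect_identical(constituents(tern), c("ERKPP", "RKIP", "Raf1"))
  expect_length(fx$compared_variables, 7L)
  expect_true(all(!is_complex(fx$compared_variables)))
  # the library regenerates the pathway's own phosphorylated RKIP label
  lib <- generate_library(fx$species, fx$enzymes)
  labels <- unique(unlist(lapply(lib$components,
                                 function(cc) c(cc$inputs, cc$outputs))))
  expect_true("RKIPP" %in% labels)
  expect_true("MEKPP|RKIPP" %in% labels)
})

test_that("the synthetic stress stand-in supports exploration", {
  fx <- fixture_stress_standin()
  expect_length(fx$model$places, 10L)
  expect_length(fx$model$components, 8L)
  expect_true(validate_model(fx$model))
  expect_true("Cap1Ox + PBS2 => Cap1Ox|PBS2" %in%
                model_signatures(fx$model))
  # exercises the frequency-report layout end to end
  lib <- generate_library(fx$species, fx$enzymes)
  tgt <- make_target_states(fx)
  set.seed(17)
  m <- petri_model(lib$components[[1L]])
  res <- run_bottomup(m, m$components[[1L]], lib, tgt,
                      config = sa_config(t_init = 1, t_min = 0.3,
                                         alpha = 0.6, iter_num = 8L,
                                         seed = 17L))
  rep <- frequency_report(list(res), top_fraction = 0.1)
  expect_identical(colnames(rep), c("frequency", "component"))
})

test_that("targets generated from a fixture are a fixed point", {
  for (fx in list(fixture_enzymatic(), fixture_mgd(),
                  fixture_stress_standin())) {
    tgt <- make_target_states(fx)
    expect_gt(state_count(tgt), 0)
    # deterministic across calls
    expect_same_states(tgt, make_target_states(fx))
    # contains the all-zero equilibrium
    allz <- apply(as.data.frame(tgt), 1L,
                  function(r) all(r == "zer,zer"))
    expect_identical(sum(allz), 1L)
    # the true model scores perfectly against its own targets
    ev <- evaluate_model(fx$model, tgt)
    expect_equal(ev$f1, 1)
    expect_equal(ev$f2, 0)
    expect_equal(ev$F, 2 / 3)
  }
})

test_that("integrative runs produce scored reports and replay exactly", {
  cfg <- integrative_config(
    "enzymatic", trials = 2L,
    es = es_config(generations = 8L, population = 4L),
    sa = sa_config(t_init = 1, t_min = 0.5, alpha = 0.5, iter_num = 3L),
    seed = 6L)
  rep1 <- run_integrative(cfg)
  rep2 <- run_integrative(cfg)
  expect_identical(rep1$models, rep2$models)
  expect_identical(rep1$traces, rep2$traces)
  expect_identical(rep1$frequencies, rep2$frequencies)
  expect_identical(sort(unique(rep1$models$trial)), c(1L, 2L))
  expect_true(all(c("f1", "f2", "F", "compression", "coverage", "bayes")
                  %in% colnames(rep1$models)))
  expect_true(all(rep1$models$coverage >= 0 & rep1$models$coverage <= 1))
  # report directory round-trip
  dir <- withr::local_tempdir()
  write_report(rep1, dir)
  expect_true(file.exists(file.path(dir, "models.tsv")))
  expect_true(file.exists(file.path(dir, "frequencies.tsv")))
  expect_true(file.exists(file.path(dir, "trace_trial1.tsv")))
  best <- read_model(file.path(dir, "best_model_trial1.json"))
  expect_true(models_equal(best, rep1$best_models[[1L]]))
})
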