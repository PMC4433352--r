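test_that("Metropolis acceptance matches exp(delta/t)", {
  expect_true(metropolis_accept(2, 1))
  expect_true(metropolis_accept(0, 1))
  set.seed(123)
  expect_false(metropolis_accept(-1, 1e-9))
  expect_error(metropolis_accept(1, 0))
  # empirical rate for delta = -1, t = 1 over 1e5 draws
  set.seed(99)
  acc <- mean(vapply(1:1e5, function(i) metropolis_accept(-1, 1),
                     logical(1L)))
  expect_lt(abs(acc - exp(-1)), 0.01)
})

test_that("proposals attach to the focal component", {
  fx <- fixture_mgd()
  lib <- generate_library(fx$species, fx$enzymes)
  sigs <- vapply(lib$components, component_signature, character(1L))
  focal <- lib$components[[match("G + M => G|M", sigs)]]
  m <- petri_model(focal)
  shared_ok <- function(cc) {
    length(intersect(c(cc$inputs, cc$outputs),
                     c(focal$inputs, focal$outputs))) > 0L
  }
  set.seed(4)
  for (i in 1:1000) {
    p <- propose_component(m, focal, lib)
    expect_true(shared_ok(p))
    expect_false(component_in_model(m, p))
  }
  # a component sharing the complex place only is proposable
  unb <- lib$components[[match("G|M => G + M", sigs)]]
  expect_true(shared_ok(unb))
  # exhaustion: all connectable components already present
  conn <- Filter(shared_ok, lib$components)
  full <- petri_model(conn)
  expect_error(propose_component(full, focal, lib), class = "qml_exhausted")
  expect_error(propose_component(m, lib$components[[2L]], lib))
})

test_that("the cooling schedule is geometric, finite and complete", {
  fx <- fixture_enzymatic()
  lib <- generate_library(fx$species, fx$enzymes)
  tgt <- make_target_states(fx)
  m <- petri_model(lib$components[[1L]])
  cfg <- sa_config(t_init = 1, t_min = 0.25, alpha = 0.5, iter_num = 2L,
                   seed = 8L)
  res <- run_bottomup(m, lib$components[[1L]], lib, tgt, config = cfg)
  temps <- unique(res$trajectory$temperature)
  expect_equal(temps, c(1, 0.5, 0.25))
  expect_true(all(diff(temps) < 0))
})

test_that("rejection-only annealing returns the input model", {
  fx <- fixture_enzymatic()
  lib <- generate_library(fx$species, fx$enzymes)
  tgt <- make_target_states(fx)
  m <- petri_model(lib$components[[1L]])
  # freezing temperatures: worsening moves have acceptance ~ 0; improving
  # moves would still be taken, so force rejection via a greedy-only check
  cfg <- sa_config(t_init = 1e-9, t_min = 1e-9 / 2, alpha = 0.5,
                   iter_num = 20L, seed = 13L)
  res <- run_bottomup(m, lib$components[[1L]], lib, tgt, config = cfg)
  for (row in seq_len(nrow(res$trajectory))) {
    if (res$trajectory$accepted[row]) {
      expect_gte(res$trajectory$delta[row], 0)
    }
  }
  if (res$accepted == 0L) {
    expect_true(models_equal(res$final_model, m))
  }
})

test_that("high temperatures accept some score-decreasing additions", {
  fx <- fixture_mgd()
  lib <- generate_library(fx$species, fx$enzymes)
  tgt <- make_target_states(fx)
  m <- petri_model(lib$components[[1L]])
  cfg <- sa_config(t_init = 2, t_min = 1, alpha = 0.7, iter_num = 25L,
                   seed = 31L)
  res <- run_bottomup(m, m$components[[1L]], lib, tgt, config = cfg)
  tr <- res$trajectory
  expect_gt(sum(tr$accepted & tr$delta < 0), 0L)
  # frequencies sum to total acceptances
  expect_identical(sum(res$frequencies), sum(tr$accepted))
  expect_identical(res$accepted, sum(tr$accepted))
})

test_that("bottom-up runs replay exactly under a fixed seed", {
  fx <- fixture_enzymatic()
  lib <- generate_library(fx$species, fx$enzymes)
  tgt <- make_target_states(fx)
  m <- petri_model(lib$components[[1L]])
  cfg <- sa_config(t_init = 1, t_min = 0.2, alpha = 0.6, iter_num = 5L,
                   seed = 77L)
  r1 <- run_bottomup(m, lib$components[[1L]], lib, tgt, config = cfg)
  r2 <- run_bottomup(m, lib$components[[1L]], lib, tgt, config = cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$frequencies, r2$frequencies)
  expect_true(models_equal(r1$final_model, r2$final_model))
})

test_that("frequency reports aggregate, rank and truncate", {
  mk <- function(freq) {
    structure(list(final_model = NULL, frequencies = freq,
                   trajectory = data.frame(), accepted = sum(freq),
                   exhausted = FALSE),
              class = "qml_exploration")
  }
  r1 <- mk(c("a => b" = 3L, "c => d" = 1L))
  r2 <- mk(c("c => d" = 2L, "e => f" = 2L))
  full <- frequency_report(list(r1, r2), top_fraction = 1)
  expect_identical(full$component, c("a => b", "c => d", "e => f"))
  expect_identical(full$frequency, c(3L, 3L, 2L))
  # permutation invariance
  expect_identical(frequency_report(list(r2, r1), top_fraction = 1), full)
  # top-10% of k components is ceiling(0.1 k)
  many <- mk(stats::setNames(rep(1L, 20L), sprintf("c%02d => x", 1:20)))
  expect_identical(nrow(frequency_report(list(many), top_fraction = 0.1)),
                   2L)
  # disjoint runs aggregate to the union of counts
  expect_identical(sum(full$frequency),
                   sum(r1$frequencies) + sum(r2$frequencies))
})
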