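test_that("fitness algebra reproduces the closed-form extremes", {
  expect_equal(combine_fitness(1, 0), 2 / 3)
  expect_equal(combine_fitness(0, 1), 1 / 3)
  expect_equal(combine_fitness(0, 0), 0.5)
  tgt <- demo_target_states()
  # a model reproducing exactly the target states: f1 = 1, f2 = 0
  f <- fitness(tgt, tgt, universe_size = 6^4)
  expect_equal(f$f1, 1)
  expect_equal(f$f2, 0)
  expect_equal(f$F, 2 / 3)
  expect_identical(f$target, 14L)
  expect_error(fitness(tgt, tgt, universe_size = 10))
})

test_that("F is monotone increasing in f1 and decreasing in f2", {
  g <- seq(0, 1, length.out = 101L)
  for (f2 in c(0, 0.25, 0.5, 1)) {
    expect_true(all(diff(combine_fitness(g, f2)) > 0))
  }
  for (f1 in c(0, 0.25, 0.5, 1)) {
    expect_true(all(diff(combine_fitness(f1, g)) < 0))
  }
  grid <- combine_fitness(rep(g, each = 101L), rep(g, times = 101L))
  expect_gte(min(grid), 1 / 3)
  expect_lte(max(grid), 2 / 3 + 1e-12)
  expect_equal(range(grid), c(1 / 3, 2 / 3))
})

test_that("fitness counts intersections over a shifted generated set", {
  tgt <- demo_target_states()
  # generated set = 10 of the 14 target states plus 6 novel states
  df <- as.data.frame(tgt)[1:10, ]
  novel <- data.frame(A = rep("pos,pos", 6L), AP = rep("pos,pos", 6L),
                      B = c("zer,zer", "zer,pos", "pos,neg", "pos,pos",
                            "zer,neg", "pos,zer"),
                      BP = rep("zer,neg", 6L))
  gen <- states_from_table(rbind(df, novel))
  f <- fitness(gen, tgt, universe_size = 6^4)
  expect_equal(f$intersection, 10L)
  expect_equal(f$f1, 10 / 14)
  expect_equal(f$f2, 6 / (6^4 - 14))
})

test_that("models outside the compared variables are discarded", {
  lib <- generate_library(c("X", "Y"), "Z")
  m <- petri_model(lib$components[[1L]])
  expect_false(discard_check(m, c("A", "AP", "B", "BP")))
  keep <- petri_model(component(c("A", "Z"), "A|Z"))
  chk <- discard_check(keep, c("A", "AP", "B", "BP"))
  expect_true(chk)
  expect_identical(attr(chk, "shared"), "A")
  full <- fixture_mgd()
  expect_true(discard_check(full$model, full$compared_variables))
  # the driver-level evaluator flags the same condition
  tgt <- demo_target_states()
  ev <- evaluate_model(m, tgt)
  expect_true(ev$discarded)
  expect_identical(ev$F, 0)
})

test_that("structural scores follow the compression/coverage definitions", {
  fx <- fixture_enzymatic()
  s <- structure_score(fx$model, fx$model)
  expect_equal(s$compression, 1)
  expect_equal(s$coverage, 1)
  # hand-built arc counts: intersection 8, target 11, generated 20
  tgt <- petri_model(lapply(1:11, function(i) {
    component(paste0("t", i), c(paste0("u", i), paste0("w", i)))
  }))
  gen <- petri_model(c(tgt$components[1:8], lapply(1:12, function(i) {
    component(paste0("g", i), c(paste0("h", i), paste0("k", i)))
  })))
  # arcs per disjoint 1->2 component: 3; intersection 24, target 33, gen 60
  s <- structure_score(tgt, gen)
  expect_equal(s$intersection, 24L)
  expect_equal(s$compression, 24 / 60)
  expect_equal(s$coverage, 24 / 33)
  expect_equal(s$compression, 0.4)
  expect_equal(round(s$coverage, 3), 0.727)
  # disjoint arc sets
  d <- structure_score(tgt, petri_model(gen$components[9:20]))
  expect_equal(d$compression, 0)
  expect_equal(d$coverage, 0)
})

test_that("the MG-D renaming identifies derived species with complexes", {
  rn <- mgd_renaming()
  expect_identical(unname(rn["H"]), "G|M")
  expect_identical(unname(rn["S"]), "G1|H")
  expect_identical(unname(rn["G"]), "G2|S")
  # unmapped labels pass through
  m <- petri_model(component(c("A", "E"), "A|E"))
  expect_true(models_equal(rename_places(m, rn), m))
  # the true MG-D model, renamed, matches itself perfectly
  fx <- fixture_mgd()
  s <- structure_score(fx$model, fx$model, rn)
  expect_equal(s$compression, 1)
  expect_equal(s$coverage, 1)
  # the renamed target is the arc set of a library-composable model
  lib <- generate_library(fx$species, fx$enzymes)
  sigs <- vapply(lib$components, component_signature, character(1L))
  key <- c("G + M => G|M", "G1 + H => G1|H", "G1|H => G1 + H",
           "G2 + S => G2|S", "G2|S => G2 + S")
  ideal <- petri_model(lib$components[match(key, sigs)])
  s2 <- structure_score(fx$model, ideal, rn)
  expect_equal(s2$coverage, 1)
})

test_that("the Bayesian score trades generality against size", {
  m <- fixture_enzymatic()$model
  szM <- model_size(m)
  # four variables, each constrained by its adjacent transitions:
  # A (t1 -, t2 +), E (-, +, +), A|E (+, -, -), AP (+): 4*1 + 9 terms
  expect_identical(szM, 13L)
  # gM = 1 leaves only the size penalty
  b <- bayes_score(m, qs_g_count = 6^4, universe_size = 6^4, p = 5L)
  expect_equal(b$score, -log(szM))
  # independent arithmetic: p = 14, 14 of 1296 states, size 30
  direct <- 14 * log(1296 / 14) - log(30)
  # five disjoint 1 -> 2 reactions: 15 variables, one term each: 5 * 6 = 30
  m30 <- petri_model(lapply(1:5, function(i) {
    component(paste0("x", i), c(paste0("y", i), paste0("z", i)))
  }))
  expect_identical(model_size(m30), 30L)
  b2 <- bayes_score(m30, qs_g_count = 14, universe_size = 1296, p = 14L)
  expect_equal(b2$score, direct)
  # monotone: more states (higher generality) lowers the score
  s_lo <- bayes_score(m, qs_g_count = 20, universe_size = 6^4, p = 14L)$score
  s_hi <- bayes_score(m, qs_g_count = 200, universe_size = 6^4, p = 14L)$score
  expect_gt(s_lo, s_hi)
  # strictly increasing in p when gM < 1
  s_p5 <- bayes_score(m, qs_g_count = 20, universe_size = 6^4, p = 5L)$score
  expect_gt(s_lo, s_p5)
  expect_error(bayes_score(m, qs_g_count = 0, universe_size = 6^4, p = 1L))
})

test_that("the internal state count agrees with enumeration", {
  set.seed(21)
  lib <- toy_library()
  for (i in 1:6) {
    m <- petri_model(lib$components[sample(12L, sample(2:5, 1L))])
    expect_equal(qmlearn:::own_state_count(m),
                 state_count(enumerate_states(m)))
  }
})
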