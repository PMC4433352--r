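# Model scoring: qualitative-state fitness, structural compression/coverage,
# and the Bayesian score for learning from positive-only data.

#' Combine coverage and spuriousness into the fitness value
#'
#' `F = 1 - 1/(1 + f1 + 1/(1 + f2))`. F increases with the target-state
#' coverage `f1` and decreases with the spurious-state rate `f2`; over
#' `f1, f2` in `[0,1]^2` its range is exactly `[1/3, 2/3]`.
#'
#' @param f1 target-state coverage ratio in `[0, 1]`.
#' @param f2 spurious-state ratio in `[0, 1]`.
#' @return the fitness value (vectorized).
#' @export
combine_fitness <- function(f1, f2) {
  1 - 1 / (1 + f1 + 1 / (1 + f2))
}

#' Qualitative-state fitness of a generated state set
#'
#' Compares the states generated by a model (`qs_g`) with the given target
#' states (`qs_t`) over the same variable list. `f1` is the fraction of
#' target states reproduced; `f2` is the fraction of the complementary state
#' set (the universe of all possible assignments minus the target states)
#' that the model also generates — its spurious-state rate; the two combine
#' into `F` via [combine_fitness()].
#'
#' @param qs_g generated states, a `qml_states` over the compared variables.
#' @param qs_t target states, a non-empty `qml_states` over the same
#'   variables.
#' @param universe_size number of possible assignments over the compared
#'   variables; `6^N` for N variables with nonnegative magnitudes (use
#'   `9^N` for the full-signs universe).
#' @return an object of class `qml_fitness`: list with `f1`, `f2`, `F`,
#'   and the underlying counts.
#' @export
fitness <- function(qs_g, qs_t, universe_size) {
  stopifnot(inherits(qs_g, "qml_states"), inherits(qs_t, "qml_states"))
  if (!identical(sort_labels(qs_g$vars), sort_labels(qs_t$vars))) {
    stop("generated and target state sets must share the same variables")
  }
  qs_t <- materialize_states(qs_t)
  nt <- length(qs_t$key)
  if (nt == 0L) stop("target state set is empty")
  if (universe_size <= nt) {
    stop("universe_size must exceed the number of target states")
  }
  qs_g <- materialize_states(project_states(qs_g, qs_t$vars))
  inter <- sum(qs_g$key %in% qs_t$key)
  f1 <- inter / nt
  f2 <- (length(qs_g$key) - inter) / (universe_size - nt)
  structure(list(f1 = f1, f2 = f2, F = combine_fitness(f1, f2),
                 intersection = inter, generated = length(qs_g$key),
                 target = nt, universe = universe_size),
            class = "qml_fitness")
}

#' @export
print.qml_fitness <- function(x, ...) {
  cat(sprintf("<fitness> f1 = %.4f, f2 = %.4f, F = %.4f\n",
              x$f1, x$f2, x$F))
  invisible(x)
}

#' Evaluate a model against target states
#'
#' Convenience wrapper used throughout the learning loops: derives the QDE,
#' enumerates the model's states projected onto the variables shared with
#' the target, and scores them with [fitness()] semantics. Models containing
#' none of the compared variables are discarded (`discarded = TRUE`,
#' `F = 0`). When the target covers the entire universe over the shared
#' subset the spurious rate is defined as 0 (no spurious state is
#' expressible).
#'
#' @param model a `qml_model`.
#' @param target a materialized `qml_states` over the compared variables.
#' @param base universe base per variable: 6 (default, nonnegative
#'   magnitudes) or 9 (full signs).
#' @return a list with `discarded`, `f1`, `f2`, `F`, `shared` (variables
#'   compared), `qsg` and `qst` counts.
#' @export
evaluate_model <- function(model, target, base = 6) {
  eval_model_fitness(model, target, base = base)
}

#' Accept or discard a model for evaluation
#'
#' A composed model none of whose reactants appear among the compared
#' variables cannot be scored against the target and is discarded; accepted
#' models are compared on the shared subset.
#'
#' @param model a `qml_model`.
#' @param compared_variables character vector of target variable labels.
#' @return `TRUE` (accept) or `FALSE` (discard); the shared variables are
#'   attached as attribute `"shared"`.
#' @export
discard_check <- function(model, compared_variables) {
  shared <- intersect(model$places, compared_variables)
  structure(length(shared) > 0L, shared = shared)
}

#' Reactant renaming for the methylglyoxal pathway
#'
#' Identifies each derived species of the MG detoxification pathway with the
#' complex a composed model builds it from: hemithioacetal `H` with `G|M`,
#' S-lactoyl-glutathione `S` with `G1|H`, and the regenerated glutathione
#' `G` with `G2|S`.
#'
#' @return a named character vector usable as the `renaming` argument of
#'   [structure_score()] and [rename_places()].
#' @export
mgd_renaming <- function() {
  c(H = make_complex_label(c("G", "M")),
    S = make_complex_label(c("G1", "H")),
    G = make_complex_label(c("G2", "S")))
}

#' Structural comparison of two models
#'
#' Counts exactly matching arcs (see [arcs()]; transitions are matched by
#' canonical signature) between a target and a generated model and reports
#' `compression = |intersection| / max(|target|, |generated|)` and
#' `coverage = |intersection| / |target|`. When a renaming is supplied both
#' models are mapped onto the common quotient namespace with
#' [rename_places()] before arcs are taken, so that a derived species and
#' the complex a composed model builds in its place compare as the same
#' reactant.
#'
#' @param target the target `qml_model`.
#' @param generated the generated `qml_model`.
#' @param renaming optional named character vector of label identifications.
#' @return an object of class `qml_structure`: `intersection`,
#'   `target_count`, `generated_count`, `compression`, `coverage`.
#' @export
structure_score <- function(target, generated, renaming = NULL) {
  if (!is.null(renaming) && length(renaming) > 0L) {
    target <- rename_places(target, renaming)
    generated <- rename_places(generated, renaming)
  }
  ta <- arc_keys(target)
  ga <- arc_keys(generated)
  inter <- length(intersect(ta, ga))
  structure(list(intersection = inter,
                 target_count = length(ta),
                 generated_count = length(ga),
                 compression = inter / max(length(ta), length(ga)),
                 coverage = inter / length(ta)),
            class = "qml_structure")
}

#' @export
print.qml_structure <- function(x, ...) {
  cat(sprintf(
    "<structure> matched %d of %d target arcs (generated %d): compression = %.3f, coverage = %.3f\n",
    x$intersection, x$target_count, x$generated_count,
    x$compression, x$coverage))
  invisible(x)
}

#' Size of a qualitative model
#'
#' The sum over QDE constraints of `1 + arity` (number of signed flux
#' terms), used by the Bayesian score.
#'
#' @param model a `qml_model`.
#' @return integer model size (at least 2).
#' @export
model_size <- function(model) {
  qde <- derive_qde(model)
  sum(vapply(qde$constraints, function(cn) 1L + length(cn$coef),
             integer(1L)))
}

#' Bayesian score of a model
#'
#' `Bayes(M) = p * ln(1 / g(M)) - ln(sz(M))`: the tradeoff between the
#' generality `g(M)` (proportion of the state universe the model generates
#' over its own variables) and its size `sz(M)`, for learning from `p`
#' positive examples. Bigger is better.
#'
#' @param model a `qml_model`.
#' @param qs_g_count number of states the model generates over its own
#'   variables (computed when omitted).
#' @param universe_size size of the state universe over the model's own
#'   variables (default `6^|V|`).
#' @param p number of positive examples (given target states).
#' @return an object of class `qml_bayes`: `p`, `gM`, `szM`, `score`.
#' @export
bayes_score <- function(model, qs_g_count = NULL, universe_size = NULL,
                        p = 1L) {
  if (p < 1L) stop("p must be at least 1")
  if (is.null(qs_g_count)) qs_g_count <- own_state_count(model)
  if (qs_g_count < 1) {
    stop("model generates no states; Bayesian score undefined")
  }
  nv <- length(model$places)
  if (is.null(universe_size)) universe_size <- 6 ^ nv
  szM <- model_size(model)
  score <- p * (log(universe_size) - log(qs_g_count)) - log(szM)
  structure(list(p = p, gM = qs_g_count / universe_size, szM = szM,
                 score = score),
            class = "qml_bayes")
}

#' @export
print.qml_bayes <- function(x, ...) {
  cat(sprintf("<bayes> p = %d, g(M) = %.4g, sz(M) = %d, score = %.4f\n",
              x$p, x$gM, x$szM, x$score))
  invisible(x)
}
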