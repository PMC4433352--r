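# Bottom-up component exploration by simulated annealing.
#
# Starting from a model handed over by the top-down route and a focal
# component, the explorer proposes library components that attach to the
# focal component (share at least one reactant label with it), scores the
# mutant by the Bayesian score, accepts or rejects through the classical
# Metropolis rule, and cools geometrically until the minimum temperature.
# Acceptance frequencies aggregated across runs point at the components the
# search keeps finding useful.

#' Simulated-annealing configuration
#'
#' Defaults are the package's standalone schedule; the integrative
#' experiments use a shorter one (see [integrative_config()]).
#'
#' @param t_init initial system temperature (> 0).
#' @param t_min final temperature, in `(0, t_init]`.
#' @param alpha geometric cooling rate in `(0, 1)`.
#' @param iter_num iterations per temperature level (>= 1).
#' @param seed integer RNG seed, or `NULL` to continue the caller's stream.
#' @return a list of class `qml_sa_config`.
#' @export
sa_config <- function(t_init = 1.0, t_min = 0.01, alpha = 0.9,
                      iter_num = 50L, seed = NULL) {
  stopifnot(t_init > 0, t_min > 0, t_min <= t_init,
            alpha > 0, alpha < 1, iter_num >= 1L)
  structure(list(t_init = t_init, t_min = t_min, alpha = alpha,
                 iter_num = as.integer(iter_num), seed = seed),
            class = "qml_sa_config")
}

#' Metropolis acceptance
#'
#' Accepts any non-worsening move; a worsening move (`delta < 0`) is
#' accepted with probability `exp(delta / t)`.
#'
#' @param delta score difference (proposed minus current; bigger is better).
#' @param t current temperature (> 0).
#' @return logical.
#' @export
metropolis_accept <- function(delta, t) {
  if (t <= 0) stop("temperature must be positive")
  if (delta >= 0) return(TRUE)
  stats::runif(1L) < exp(delta / t)
}

connectable_components <- function(model, focal, library) {
  labels <- c(focal$inputs, focal$outputs)
  sigs <- model_signatures(model)
  keep <- vapply(library$components, function(cc) {
    !(component_signature(cc) %in% sigs) &&
      length(intersect(c(cc$inputs, cc$outputs), labels)) > 0L
  }, logical(1L))
  library$components[keep]
}

#' Propose a component attached to the focal component
#'
#' Uniform draw among library components that share at least one reactant
#' label with the focal component and are not already in the model. When no
#' connectable component remains a condition of class `qml_exhausted` is
#' signalled.
#'
#' @param model the current `qml_model` (must contain `focal`).
#' @param focal the focal `qml_component`.
#' @param library a `qml_library`.
#' @return a `qml_component`.
#' @export
propose_component <- function(model, focal, library) {
  if (!component_in_model(model, focal)) {
    stop("focal component is not part of the model")
  }
  cand <- connectable_components(model, focal, library)
  if (length(cand) == 0L) {
    stop(structure(
      class = c("qml_exhausted", "error", "condition"),
      list(message = "no connectable component left to propose",
           call = sys.call())))
  }
  cand[[sample.int(length(cand), 1L)]]
}

#' Run the bottom-up simulated-annealing exploration
#'
#' For every temperature level `t = T, alpha*T, alpha^2*T, ... >= T_min`,
#' runs `iter_num` iterations of propose / score / Metropolis-accept.
#' Accepted mutants replace the current model and seed the next
#' exploration; the per-component acceptance counts are recorded. The score
#' is the Bayesian score ([bayes_score()]) with `p` positive examples; the
#' state fitness of the explored models is reported by the integrative
#' driver ([run_integrative()]), which scores every exploration's final
#' model.
#'
#' @param model the starting `qml_model`.
#' @param focal the focal `qml_component` (must be in `model`).
#' @param library a `qml_library`.
#' @param target materialized target `qml_states` (supplies the default
#'   `p`).
#' @param config a [sa_config()].
#' @param p number of positive examples for the Bayesian score
#'   (default: number of target states).
#' @param base universe base (6 or 9).
#' @param follow_chain when `TRUE` (default) each accepted component becomes
#'   the next focal component, so the exploration walks a trail of
#'   attachments across the network; `FALSE` keeps the handed-over focal
#'   fixed and explores only its immediate neighbourhood.
#' @param delta_scale divisor applied to the raw Bayesian-score difference
#'   before the Metropolis test. The Bayesian score is linear in `p`, so the
#'   default `p` expresses temperature in units of per-positive-example
#'   score change, making one cooling schedule meaningful across targets of
#'   any size; set to 1 for raw-score temperatures.
#' @return an object of class `qml_exploration`: `final_model`,
#'   `frequencies` (named acceptance counts by component signature),
#'   `trajectory` (one data.frame row per proposal: temperature, iteration,
#'   component, delta, accepted, score), `accepted` (total acceptances) and
#'   `exhausted` (whether the connectable pool ran out).
#' @export
run_bottomup <- function(model, focal, library, target,
                         config = sa_config(), p = NULL, base = 6,
                         follow_chain = TRUE, delta_scale = NULL) {
  stopifnot(inherits(model, "qml_model"), inherits(focal, "qml_component"))
  if (!component_in_model(model, focal)) {
    stop("focal component is not part of the model")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(p)) p <- state_count(target)
  if (is.null(delta_scale)) delta_scale <- p
  stopifnot(delta_scale > 0)
  target <- materialize_states(target)

  cur <- model
  cur_score <- bayes_score(cur, p = p,
                           universe_size = base ^ length(cur$places))$score
  freq <- integer(0L)
  rows <- list()
  exhausted <- FALSE
  # mutant scores are deterministic given the current model; memoize per
  # proposal signature and flush on acceptance
  score_cache <- new.env(parent = emptyenv())
  t <- config$t_init
  while (t >= config$t_min * (1 - 1e-12)) {
    for (it in seq_len(config$iter_num)) {
      cand <- connectable_components(cur, focal, library)
      if (length(cand) == 0L) { exhausted <- TRUE; break }
      prop <- cand[[sample.int(length(cand), 1L)]]
      sig <- component_signature(prop)
      new_score <- score_cache[[sig]]
      if (is.null(new_score)) {
        mutant <- compose(cur, prop)
        new_score <- bayes_score(
          mutant, p = p,
          universe_size = base ^ length(mutant$places))$score
        score_cache[[sig]] <- new_score
      }
      delta <- new_score - cur_score
      acc <- metropolis_accept(delta / delta_scale, t)
      if (acc) {
        cur <- compose(cur, prop)
        cur_score <- new_score
        if (follow_chain) focal <- prop
        freq[sig] <- if (sig %in% names(freq)) freq[[sig]] + 1L else 1L
        score_cache <- new.env(parent = emptyenv())
      }
      rows[[length(rows) + 1L]] <- data.frame(
        temperature = t, iteration = it, component = sig,
        delta = delta, accepted = acc, score = cur_score)
    }
    if (exhausted) break
    t <- t * config$alpha
  }
  structure(list(final_model = cur, frequencies = freq,
                 trajectory = if (length(rows)) do.call(rbind, rows)
                              else data.frame(),
                 accepted = sum(freq), exhausted = exhausted,
                 config = config),
            class = "qml_exploration")
}

#' @export
print.qml_exploration <- function(x, ...) {
  cat("<SA exploration> ", x$accepted, " accepted additions, final model ",
      length(x$final_model$components), " components",
      if (x$exhausted) " (pool exhausted)" else "", "\n", sep = "")
  invisible(x)
}

#' Most frequently explored components
#'
#' Aggregates acceptance counts across exploration results, sorts them in
#' decreasing order (ties broken by canonical component signature) and
#' returns the top fraction.
#'
#' @param results a non-empty list of `qml_exploration` objects (a single
#'   object is accepted).
#' @param top_fraction fraction of distinct explored components to report
#'   (default 0.10, the top 10 percent, rounded up).
#' @return a data.frame with columns `frequency` and `component`.
#' @export
frequency_report <- function(results, top_fraction = 0.10) {
  if (inherits(results, "qml_exploration")) results <- list(results)
  if (length(results) == 0L) stop("no exploration results")
  stopifnot(top_fraction > 0, top_fraction <= 1)
  total <- integer(0L)
  for (r in results) {
    for (sig in names(r$frequencies)) {
      total[sig] <- if (sig %in% names(total)) {
        total[[sig]] + r$frequencies[[sig]]
      } else {
        r$frequencies[[sig]]
      }
    }
  }
  if (length(total) == 0L) {
    return(data.frame(frequency = integer(0L), component = character(0L)))
  }
  ord <- order(-total, names(total), method = "radix")
  total <- total[ord]
  k <- ceiling(top_fraction * length(total))
  data.frame(frequency = unname(total[seq_len(k)]),
             component = names(total)[seq_len(k)])
}
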