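# Top-down model composition by a population of (1+1) evolution strategies.
#
# Each lineage evolves one Petri-net model: a component addition every
# generation (a subtraction instead at every subtraction_period-th
# generation), pairwise crossover between randomly paired lineages after the
# add/sub step, and elitist selection (the mutant replaces its parent only
# on a strict fitness improvement). A lineage that attains full coverage of
# the target states (f1 = 1) hands its model, with the component whose
# addition achieved it, to the bottom-up simulated-annealing explorer:
# beyond that point models cannot be distinguished by the state fitness
# alone.

#' Evolution-strategy configuration
#'
#' @param generations number of generations (default 100).
#' @param population number of (1+1) lineages evolved in parallel
#'   (default 20).
#' @param subtraction_period a subtraction replaces the addition every this
#'   many generations (default 10).
#' @param seed integer RNG seed, or `NULL` to continue the caller's stream.
#' @param mu,lambda parents/offspring per lineage; only (1+1) is supported.
#' @return a list of class `qml_es_config`.
#' @export
es_config <- function(generations = 100L, population = 20L,
                      subtraction_period = 10L, seed = NULL,
                      mu = 1L, lambda = 1L) {
  stopifnot(generations >= 0L, population >= 1L, subtraction_period >= 1L,
            mu == 1L, lambda == 1L)
  structure(list(generations = as.integer(generations),
                 population = as.integer(population),
                 subtraction_period = as.integer(subtraction_period),
                 seed = seed, mu = 1L, lambda = 1L),
            class = "qml_es_config")
}

new_individual <- function(model, fit, age = 0L) {
  list(model = model, fit = fit, age = age,
       last_added = NULL, triggered = FALSE, best_F = fit$F)
}

#' Initialize an ES population
#'
#' Each model seed is a single atomic component drawn uniformly (with
#' replacement) from the component library.
#'
#' @param library a `qml_library`.
#' @param config a [es_config()].
#' @param target materialized target `qml_states` used to evaluate the
#'   seeds; when `NULL` the individuals carry `F = NA` until evaluated.
#' @param base universe base (6 or 9).
#' @return a list of individuals (`model`, `fit`, `age`).
#' @export
init_population <- function(library, config, target = NULL, base = 6) {
  if (length(library$components) == 0L) stop("component library is empty")
  cache <- new.env(parent = emptyenv())
  lapply(seq_len(config$population), function(i) {
    m <- petri_model(library$components[[
      sample.int(length(library$components), 1L)]])
    fit <- if (is.null(target)) {
      list(discarded = NA, f1 = NA_real_, f2 = NA_real_, F = NA_real_)
    } else {
      eval_model_fitness(m, target, base = base, cache = cache)
    }
    new_individual(m, fit)
  })
}

#' Mutate an individual
#'
#' Applies an addition (a uniformly drawn library component not already in
#' the model) every generation; at generations divisible by the subtraction
#' period a subtraction of a uniformly drawn component is applied instead.
#' Subtraction on a single-component model falls back to addition; when no
#' addable component remains the individual stalls (returned unchanged with
#' `op = "stall"`).
#'
#' @param individual an individual (list with `model`).
#' @param library a `qml_library`.
#' @param generation current generation number (drives the schedule).
#' @param config a [es_config()].
#' @return a list `model` (mutated `qml_model`), `op`
#'   (`"add"`/`"subtract"`/`"stall"`), and `added` (the added component or
#'   `NULL`).
#' @export
mutate_individual <- function(individual, library, generation, config) {
  model <- individual$model
  want_sub <- generation %% config$subtraction_period == 0L &&
    length(model$components) >= 2L
  if (want_sub) {
    idx <- sample.int(length(model$components), 1L)
    return(list(model = subtract(model, model$components[[idx]]),
                op = "subtract", added = NULL))
  }
  sigs <- model_signatures(model)
  lib_sigs <- vapply(library$components, component_signature, character(1L))
  cand <- which(!(lib_sigs %in% sigs))
  if (length(cand) == 0L) {
    return(list(model = model, op = "stall", added = NULL))
  }
  comp <- library$components[[cand[[sample.int(length(cand), 1L)]]]]
  list(model = compose(model, comp), op = "add", added = comp)
}

#' (1+1) elitist selection
#'
#' The offspring replaces the parent only on a strict fitness improvement;
#' ties keep the parent.
#'
#' @param parent,offspring evaluated individuals (with `fit$F`).
#' @return the selected individual.
#' @export
select_individual <- function(parent, offspring) {
  if (is.na(parent$fit$F) || is.na(offspring$fit$F)) {
    stop("both individuals must be evaluated before selection")
  }
  if (offspring$fit$F > parent$fit$F) offspring else parent
}

#' Run the top-down evolution strategy
#'
#' Evolves `config$population` independent (1+1) lineages for
#' `config$generations` generations with the operator schedule described in
#' [mutate_individual()], pairwise crossover between randomly paired mutants
#' each generation, and elitist selection per lineage. When a lineage first
#' attains full target-state coverage (`f1 = 1`) and `sa_config` is given,
#' the model is handed to [run_bottomup()] with the last-added component as
#' the focal component (each lineage triggers at most once).
#'
#' @param library a `qml_library`.
#' @param target materialized target `qml_states` over the compared
#'   variables.
#' @param config a [es_config()].
#' @param sa_config optional [sa_config()] enabling the bottom-up trigger.
#' @param bayes_p number of positive examples for the bottom-up Bayesian
#'   score (default: the number of target states).
#' @param base universe base (6 or 9).
#' @return a list of class `qml_es_run`: `population` (final individuals
#'   sorted by decreasing F), `trace` (one data.frame row per lineage per
#'   generation), `explorations` (list of `qml_exploration` from triggered
#'   bottom-up runs), and `config`.
#' @export
run_topdown <- function(library, target, config = es_config(),
                        sa_config = NULL, bayes_p = NULL, base = 6) {
  stopifnot(inherits(library, "qml_library"),
            inherits(target, "qml_states"))
  if (state_count(target) == 0) stop("target state set is empty")
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(bayes_p)) bayes_p <- state_count(target)
  target <- materialize_states(target)
  cache <- new.env(parent = emptyenv())
  validate <- isTRUE(getOption("qmlearn.validate", FALSE))

  pop <- init_population(library, config, target = target, base = base)
  explorations <- list()
  trigger <- function(i, ind, added) {
    if (ind$triggered || is.null(sa_config)) return(ind)
    focal <- if (!is.null(added) && component_in_model(ind$model, added)) {
      added
    } else {
      ind$model$components[[sample.int(length(ind$model$components), 1L)]]
    }
    ex <- run_bottomup(ind$model, focal, library, target,
                       config = sa_config, p = bayes_p, base = base)
    ex$lineage <- i
    explorations[[length(explorations) + 1L]] <<- ex
    ind$triggered <- TRUE
    ind
  }
  for (i in seq_along(pop)) {
    if (!pop[[i]]$fit$discarded && pop[[i]]$fit$f1 == 1) {
      pop[[i]] <- trigger(i, pop[[i]], NULL)
    }
  }

  trace <- vector("list", config$generations)
  for (gen in seq_len(config$generations)) {
    muts <- lapply(pop, mutate_individual, library = library,
                   generation = gen, config = config)
    models <- lapply(muts, `[[`, "model")
    # pairwise crossover between randomly paired lineages
    if (config$population >= 2L) {
      perm <- sample.int(config$population)
      for (k in seq_len(config$population %/% 2L)) {
        a <- perm[[2L * k - 1L]]; b <- perm[[2L * k]]
        off <- crossover(models[[a]], models[[b]])
        models[[a]] <- off[[1L]]; models[[b]] <- off[[2L]]
      }
    }
    rows <- vector("list", config$population)
    for (i in seq_along(pop)) {
      if (validate) validate_model(models[[i]])
      fit <- eval_model_fitness(models[[i]], target, base = base,
                                cache = cache)
      off <- new_individual(models[[i]], fit, age = 0L)
      off$triggered <- pop[[i]]$triggered
      parent_F <- pop[[i]]$fit$F
      sel <- select_individual(pop[[i]], off)
      accepted <- sel$fit$F > parent_F
      if (accepted) {
        sel$best_F <- max(pop[[i]]$best_F, sel$fit$F)
        if (!sel$fit$discarded && sel$fit$f1 == 1) {
          sel <- trigger(i, sel, muts[[i]]$added)
        }
      } else {
        sel$age <- pop[[i]]$age + 1L
        sel$best_F <- pop[[i]]$best_F
      }
      pop[[i]] <- sel
      rows[[i]] <- data.frame(
        generation = gen, lineage = i, op = muts[[i]]$op,
        accepted = accepted, parent_F = parent_F,
        offspring_F = fit$F, f1 = sel$fit$f1, f2 = sel$fit$f2,
        best_F = sel$best_F, n_components = length(sel$model$components))
    }
    trace[[gen]] <- do.call(rbind, rows)
  }
  trace <- if (config$generations > 0L) do.call(rbind, trace) else
    data.frame()
  ord <- order(vapply(pop, function(x) x$fit$F, numeric(1L)),
               decreasing = TRUE)
  structure(list(population = pop[ord], lineage_order = ord,
                 trace = trace, explorations = explorations,
                 config = config),
            class = "qml_es_run")
}

#' @export
print.qml_es_run <- function(x, ...) {
  best <- if (length(x$population)) x$population[[1L]]$fit$F else NA
  cat("<ES run> ", length(x$population), " lineages, ",
      x$config$generations, " generations; best F = ",
      formatC(best, digits = 4, format = "f"), "; ",
      length(x$explorations), " bottom-up explorations\n", sep = "")
  invisible(x)
}

#' Write an ES trace as TSV
#'
#' @param run a `qml_es_run` (or any object with a `trace` data.frame).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(run, path) {
  utils::write.table(run$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
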