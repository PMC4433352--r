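# Integrative driver: top-down ES composition with bottom-up SA exploration
# triggered on full target-state coverage, repeated over trials, with
# per-model qualitative and structural scoring.

#' Integrative run configuration
#'
#' Bundles the ES and SA configurations with a fixture name and a trial
#' count. The SA defaults here are the shorter desk-scale schedule used for
#' the integrative experiments (7 temperature levels, 10 iterations each);
#' standalone bottom-up runs default to the longer [sa_config()] schedule.
#'
#' @param fixture fixture name (see [get_fixture()]).
#' @param trials number of independent trials (>= 1).
#' @param es a [es_config()].
#' @param sa a [sa_config()].
#' @param seed base RNG seed; trial `k` runs with seed `seed + 7919 * k`.
#' @param base universe base (6 or 9).
#' @return a list of class `qml_integrative_config`.
#' @export
integrative_config <- function(fixture = "mgd", trials = 1L,
                               es = es_config(),
                               sa = sa_config(t_min = 0.1, alpha = 0.7,
                                              iter_num = 10L),
                               seed = 1L, base = 6) {
  stopifnot(trials >= 1L)
  structure(list(fixture = fixture, trials = as.integer(trials),
                 es = es, sa = sa, seed = as.integer(seed), base = base),
            class = "qml_integrative_config")
}

#' Run the integrative top-down / bottom-up learner
#'
#' For each trial: generates the component library from the fixture's
#' species/enzyme partition, generates the target states by qualitative
#' simulation of the true fixture model, runs the top-down ES (which hands
#' full-coverage models to the bottom-up SA), and scores every resulting
#' model — the final ES population and the SA-explored models — by state
#' fitness, structural compression/coverage against the (renamed) target,
#' and the Bayesian score.
#'
#' @param config a [integrative_config()].
#' @return an object of class `qml_report`: `fixture`, `target_count`,
#'   `models` (one data.frame row per model: trial, lineage, source,
#'   f1/f2/F, compression/coverage, bayes, sizes), `frequencies`
#'   (aggregated SA acceptance counts), `traces` (per-trial ES traces),
#'   `explorations` (count per trial), `best_models` (per-trial best ES
#'   model), `config`.
#' @export
run_integrative <- function(config = integrative_config()) {
  fixture <- get_fixture(config$fixture)
  library <- generate_library(fixture$species, fixture$enzymes)
  target <- make_target_states(fixture)
  p <- state_count(target)

  rows <- list()
  traces <- vector("list", config$trials)
  all_explorations <- list()
  best_models <- vector("list", config$trials)

  score_model <- function(model, fit, trial, lineage, source) {
    st <- structure_score(fixture$model, model, fixture$renaming)
    bs <- bayes_score(model, p = p,
                      universe_size = config$base ^ length(model$places))
    data.frame(trial = trial, lineage = lineage, source = source,
               f1 = fit$f1, f2 = fit$f2, F = fit$F,
               discarded = isTRUE(fit$discarded),
               compression = st$compression, coverage = st$coverage,
               arcs_matched = st$intersection,
               bayes = bs$score,
               n_components = length(model$components),
               n_places = length(model$places))
  }

  for (trial in seq_len(config$trials)) {
    es <- config$es
    es$seed <- config$seed + 7919L * trial
    run <- run_topdown(library, target, config = es,
                       sa_config = config$sa, bayes_p = p,
                       base = config$base)
    traces[[trial]] <- run$trace
    for (j in seq_along(run$population)) {
      ind <- run$population[[j]]
      rows[[length(rows) + 1L]] <- score_model(
        ind$model, ind$fit, trial, run$lineage_order[[j]], "es")
    }
    for (ex in run$explorations) {
      fit <- eval_model_fitness(ex$final_model, target, base = config$base)
      rows[[length(rows) + 1L]] <- score_model(
        ex$final_model, fit, trial, ex$lineage, "sa")
      all_explorations[[length(all_explorations) + 1L]] <- ex
    }
    best_models[[trial]] <- run$population[[1L]]$model
  }

  freq <- if (length(all_explorations) > 0L) {
    frequency_report(all_explorations, top_fraction = 1)
  } else {
    data.frame(frequency = integer(0L), component = character(0L))
  }
  structure(list(fixture = config$fixture, target_count = p,
                 models = do.call(rbind, rows),
                 frequencies = freq,
                 traces = traces,
                 n_explorations = length(all_explorations),
                 best_models = best_models,
                 config = config),
            class = "qml_report")
}

#' @export
print.qml_report <- function(x, ...) {
  es <- x$models[x$models$source == "es", ]
  cat("<integrative report: ", x$fixture, "> ",
      length(x$traces), " trial(s), ", nrow(x$models), " scored models\n",
      "  best F = ", formatC(max(es$F), digits = 4, format = "f"),
      "; max coverage = ",
      formatC(max(x$models$coverage), digits = 3, format = "f"),
      "; explorations = ", x$n_explorations, "\n", sep = "")
  invisible(x)
}

#' Write an integrative report to a directory
#'
#' Writes `models.tsv` (per-model scores), `frequencies.tsv` (explored
#' component counts, most frequent first), `trace_trial<k>.tsv` (ES traces),
#' `best_model_trial<k>.json` and `config.json`.
#'
#' @param report a `qml_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$models, file.path(dir, "models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$frequencies, file.path(dir, "frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (k in seq_along(report$traces)) {
    utils::write.table(report$traces[[k]],
                       file.path(dir, sprintf("trace_trial%d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (k in seq_along(report$best_models)) {
    write_model(report$best_models[[k]],
                file.path(dir, sprintf("best_model_trial%d.json", k)))
  }
  cfg <- report$config
  writeLines(jsonlite::toJSON(
    list(fixture = cfg$fixture, trials = cfg$trials, seed = cfg$seed,
         base = cfg$base,
         es = unclass(cfg$es)[c("generations", "population",
                                "subtraction_period")],
         sa = unclass(cfg$sa)[c("t_init", "t_min", "alpha", "iter_num")]),
    auto_unbox = TRUE, pretty = TRUE), file.path(dir, "config.json"))
  invisible(dir)
}
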