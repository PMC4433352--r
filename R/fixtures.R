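# Encoded pathway fixtures. Each fixture bundles the target Petri-net
# model, the variables compared during evaluation, the species/enzyme
# partition its component library is generated from, and (for MG-D) the
# reactant renaming used for structural scoring.

new_fixture <- function(name, model, compared_variables, species, enzymes,
                        renaming = NULL, notes = NULL) {
  stopifnot(all(compared_variables %in% model$places))
  validate_model(model)
  structure(list(name = name, model = model,
                 compared_variables = compared_variables,
                 species = species, enzymes = enzymes,
                 renaming = renaming, notes = notes),
            class = "qml_fixture")
}

#' @export
print.qml_fixture <- function(x, ...) {
  cat("<fixture ", x$name, "> ", length(x$model$components),
      " reactions over ", length(x$model$places), " reactants; compared: ",
      paste(x$compared_variables, collapse = ", "), "\n", sep = "")
  if (!is.null(x$notes)) cat("  ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Enzymatic toy fixture
#'
#' The canonical single enzymatic reaction `A + E <=> A|E -> AP + E`: three
#' atomic components over the four places `A`, `E`, `A|E`, `AP`. Compared
#' variables are the substrate `A` and product `AP`.
#'
#' @return a `qml_fixture`.
#' @export
fixture_enzymatic <- function() {
  cx <- make_complex_label(c("A", "E"))
  m <- petri_model(list(
    component(c("A", "E"), cx, kind = "binding"),
    component(cx, c("A", "E"), kind = "unbinding"),
    component(cx, c("AP", "E"), kind = "unbinding")))
  new_fixture("enzymatic", m, compared_variables = c("A", "AP"),
              species = "A", enzymes = "E")
}

#' Methylglyoxal detoxification (MG-D) fixture
#'
#' Glutathione (`G`) reacts spontaneously with methylglyoxal (`M`) to form
#' hemithioacetal (`H`); `H` is converted by glyoxalase I (`G1`) into
#' S-lactoyl-glutathione (`S`), which glyoxalase II (`G2`) converts back to
#' `G` (releasing the non-toxic d-lactate, which does not contribute to the
#' kinetics and is not encoded). One non-enzymatic and two enzymatic
#' reaction groups over the six primitive reactants `M, G, H, S, G1, G2`;
#' qualitative states over `M, G, H, S` drive the evaluation. The renaming
#' [mgd_renaming()] identifies each derived species with its constructive
#' complex for structural scoring.
#'
#' @return a `qml_fixture`.
#' @export
fixture_mgd <- function() {
  hg1 <- make_complex_label(c("H", "G1"))
  sg2 <- make_complex_label(c("S", "G2"))
  m <- petri_model(list(
    component(c("M", "G"), "H", kind = "binding"),
    component(c("H", "G1"), hg1, kind = "binding"),
    component(hg1, c("H", "G1"), kind = "unbinding"),
    component(hg1, c("S", "G1"), kind = "unbinding"),
    component(c("S", "G2"), sg2, kind = "binding"),
    component(sg2, c("S", "G2"), kind = "unbinding"),
    component(sg2, c("G", "G2"), kind = "unbinding")))
  new_fixture("mgd", m, compared_variables = c("M", "G", "H", "S"),
              species = c("M", "H", "S"), enzymes = c("G", "G1", "G2"),
              renaming = mgd_renaming())
}

#' RKIP-inhibited ERK pathway fixture
#'
#' The ERK signalling cascade regulated by RKIP: Raf-1 binds RKIP; the
#' Raf1|RKIP complex binds doubly phosphorylated ERK (ERKPP) and the ternary
#' complex dissociates into Raf-1, ERK and phosphorylated RKIP (RKIPP);
#' active MEK (MEKPP) binds and phosphorylates ERK; the phosphatase RP
#' recycles RKIPP back to RKIP. Eleven reactants, eleven reactions. The
#' seven primitive reactants are the compared variables. (The one textual
#' ambiguity in the source material — the explored complex printed once as
#' `MEKPP|RP` and once as `MEKPP|RKIPP` — is resolved to `MEKPP|RKIPP`,
#' which the cascade's reachability argument supports.)
#'
#' @return a `qml_fixture`.
#' @export
fixture_rkip <- function() {
  rr <- make_complex_label(c("Raf1", "RKIP"))
  rre <- make_complex_label(c("Raf1", "RKIP", "ERKPP"))
  me <- make_complex_label(c("MEKPP", "ERK"))
  rp <- make_complex_label(c("RKIPP", "RP"))
  m <- petri_model(list(
    component(c("Raf1", "RKIP"), rr, kind = "binding"),
    component(rr, c("Raf1", "RKIP"), kind = "unbinding"),
    component(c(rr, "ERKPP"), rre, kind = "binding"),
    component(rre, c(rr, "ERKPP"), kind = "unbinding"),
    component(rre, c("Raf1", "ERK", "RKIPP"), kind = "unbinding"),
    component(c("MEKPP", "ERK"), me, kind = "binding"),
    component(me, c("MEKPP", "ERK"), kind = "unbinding"),
    component(me, c("MEKPP", "ERKPP"), kind = "unbinding"),
    component(c("RKIPP", "RP"), rp, kind = "binding"),
    component(rp, c("RKIPP", "RP"), kind = "unbinding"),
    component(rp, c("RKIP", "RP"), kind = "unbinding")))
  new_fixture(
    "rkip", m,
    compared_variables = c("Raf1", "RKIP", "ERK", "RKIPP", "MEKPP",
                           "ERKPP", "RP"),
    species = c("RKIP", "RKIPP", "ERK", "ERKPP"),
    enzymes = c("Raf1", "MEKPP", "RP"))
}

#' Synthetic combinatorial-stress stand-in fixture
#'
#' A small synthetic network in the vocabulary of the *Candida albicans*
#' oxidative/nitrosative stress response (Cap1, Pbs2, Hog1, thioredoxin,
#' glutathione, catalase), built to exercise the bottom-up exploration and
#' frequency reporting at desk scale. It is a stand-in: the network is NOT
#' the published stress-response map, only a plausible 8-reaction,
#' 10-reactant excerpt using its labels.
#'
#' @return a `qml_fixture`.
#' @export
fixture_stress_standin <- function() {
  cp <- make_complex_label(c("Cap1Ox", "PBS2"))
  tp <- make_complex_label(c("Trx1Red", "PBS2"))
  hc <- make_complex_label(c("Hog1Red", "CTA1"))
  gp <- make_complex_label(c("GSH", "PBS2"))
  m <- petri_model(list(
    component(c("Cap1Ox", "PBS2"), cp, kind = "binding"),
    component(cp, c("Cap1Ox", "PBS2"), kind = "unbinding"),
    component(c("Trx1Red", "PBS2"), tp, kind = "binding"),
    component(tp, c("Trx1Red", "PBS2"), kind = "unbinding"),
    component(c("Hog1Red", "CTA1"), hc, kind = "binding"),
    component(hc, c("Hog1Red", "CTA1"), kind = "unbinding"),
    component(c("GSH", "Hog1Red"), "PBS2", kind = "binding"),
    component(c("GSH", "PBS2"), gp, kind = "binding")))
  new_fixture(
    "stress_standin", m,
    compared_variables = c("Cap1Ox", "PBS2", "GSH", "Hog1Red"),
    species = c("Cap1Ox", "Trx1Red", "Hog1Red", "GSH"),
    enzymes = c("PBS2", "CTA1"),
    notes = "synthetic stand-in network, not the published stress map")
}

#' Look up a fixture by name
#'
#' @param name one of `"enzymatic"`, `"mgd"`, `"rkip"`, `"stress_standin"`.
#' @return a `qml_fixture`.
#' @export
get_fixture <- function(name) {
  switch(match.arg(name, c("enzymatic", "mgd", "rkip", "stress_standin")),
         enzymatic = fixture_enzymatic(),
         mgd = fixture_mgd(),
         rkip = fixture_rkip(),
         stress_standin = fixture_stress_standin())
}

#' Generate target qualitative states from a fixture
#'
#' Qualitatively simulates the fixture's true model and projects the
#' resulting state set onto the fixture's compared variables. By
#' construction the true model evaluated against these targets attains
#' `f1 = 1`, `f2 = 0`.
#'
#' @param fixture a `qml_fixture`.
#' @return a materialized `qml_states` over the compared variables.
#' @export
make_target_states <- function(fixture) {
  stopifnot(inherits(fixture, "qml_fixture"))
  project_states(enumerate_states(fixture$model),
                 fixture$compared_variables)
}
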