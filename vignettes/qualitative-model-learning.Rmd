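---
title: "Qualitative model learning of biochemical pathway structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative model learning of biochemical pathway structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmlearn)
```

## The problem

When kinetic rate constants and quantitative time courses are unavailable,
the structure of a biochemical pathway can still be learned from
*qualitative* observations: which reactant concentrations are zero or
positive, and whether they are rising, steady or falling. qmlearn infers
Petri-net pathway models from such data by composing atomic reaction
components and comparing the qualitative behaviour of candidate models
against target behaviour.

A **component** is an atomic reaction fragment instantiated from one of two
patterns: *binding* (`P1 + P2 -> P3`, with `P3 = P1|P2` a complex named by
joining the reactant labels) and *unbinding* (`P3 -> P1 + P2`). An
enzymatic conversion `A + E <=> A|E -> AP + E` therefore decomposes into
exactly three atomic components. `generate_library()` builds every such
component over a user-supplied species set and enzyme set — `3 * |species|
* |enzymes|` components in total. Models are sets of components merged over
shared places; `compose()`/`subtract()` grow and shrink them stepwise, and
`crossover()` recombines two models. Rate constants are deliberately not
modelled: only structure is learned.

## Qualitative semantics

Each reactant is a variable with a qualitative value `<magnitude,
derivative>` over the signs quantity space. Magnitudes range over
`{zer, pos}` — concentrations cannot be negative, and no observed state
table contains a negative magnitude — while derivatives keep all three
signs. Each variable's universe therefore has 6 values; the full-signs
alternative (9 per variable) is kept available through the `universe_size`
and `base` arguments of the scoring functions because "all possible states"
admits either reading, but 6 is the default everywhere.

`derive_qde()` maps a model to a qualitative differential equation: one
constraint per variable stating that its derivative sign lies in the signed
sum of its reactions' flux signs (`+` for producing, `-` for consuming
reactions). Under single-step mass-action kinetics a reaction rate is a
monomial in its input concentrations, so its sign abstraction
(`flux_sign()`) is zero exactly when some input is zero. Opposing nonzero
influences are qualitatively unresolvable and allow all three derivative
signs (`sum_signs()`).

A **qualitative state** is a complete assignment of sign pairs to all
variables. `enumerate_states()` returns the exact set of consistent states.
Because flux signs depend only on magnitudes, the set factorizes: for each
of the `2^|V|` magnitude assignments, the per-variable derivative sets are
independent. The implementation keeps this factored form (one block per
magnitude assignment) and materializes states only under projection onto a
small variable subset (`project_states()`), so models of a dozen or more
variables stay cheap. QSIM-style transition rules between states are
deliberately out of scope: all evaluation in this package operates on state
*sets*, never on trajectories, so the QDE transition component stays empty.

## Scoring

Candidate models are compared with the target over the variables present in
both (models sharing none are discarded). With `QS_G` the generated and
`QS_T` the target state set over `N` shared variables, and `U = 6^N` the
universe:

* `f1 = |QS_G ∩ QS_T| / |QS_T|` — target coverage, 1 is best;
* `f2 = |QS_G ∩ QS_C| / |QS_C|` — spurious-state rate against the
  complement `QS_C` (the universe minus the targets, held as a size rather
  than materialized), 0 is best;
* `F = 1 - 1 / (1 + f1 + 1 / (1 + f2))`.

`F` is monotone in the right directions, but its range over
`[0,1]^2` is exactly `[1/3, 2/3]` — the commonly quoted `[0, 1]` is not
attainable under this formula; best values near 0.66 sit at the cap. We
implement the formula verbatim. The complement reading of
`QS_C` is chosen over "all possible states" because the latter would make
`f2` insensitive to the model. In the degenerate case where the targets
fill the whole universe over the shared subset, the internal evaluator
defines `f2 = 0` (no spurious state is expressible); the exported
`fitness()` treats it as an error, since a universe no larger than the
target set indicates a misconfigured comparison.

Structure is scored by exact arc matching on the bipartite
place/transition graph, with transitions identified by their canonical
input/output signature so that independently built models can be compared:
`compression = |matched| / max(|target|, |generated|)` and `coverage =
|matched| / |target|`.

**Reactant renaming.** A composed model cannot invent the opaque name of a
derived species — it builds the complex instead. In the methylglyoxal
pathway, hemithioacetal `H` is what a model composes as `G|M`,
S-lactoyl-glutathione `S` as `G1|H`, and regenerated glutathione `G` as
`G2|S` (`mgd_renaming()`). We read this renaming as an *identification* of
labels and apply it to **both** models before arc comparison, merging
places that become equal. Two consequences are intended: first, the true
pathway renamed against itself scores compression = coverage = 1; second,
an identification can make an unbinding formally regenerate its own
substrate (`G1|H -> S + G1` becomes `G1|H -> G1|H + G1`), and such
transitions carry no interaction information on the quotient, so they are
excluded from the arc comparison (`rename_places(drop_degenerate =)`).
Under this semantics the renamed MG-D target is exactly the arc set of a
five-component library-composable model, so perfect coverage is attainable
by learning — which is also why the one-sided alternative (renaming the
target only) was rejected: it produces a target no composable model can
match.

The **Bayesian score** for learning from `p` positive examples (the given
target states) is `Bayes(M) = p * ln(1/g(M)) - ln(sz(M))`, with generality
`g(M)` the fraction of the state universe over the model's own variables
that the model generates, and size `sz(M)` the summed constraint sizes
(1 + arity per variable). It rewards specific, small models and is the
objective of the bottom-up explorer.

## The two search routes

**Top-down (`run_topdown()`).** A population (default 20) of independent
(1+1) evolution strategies. Each lineage starts from a single random
library component; every generation applies an addition of a random absent
library component (a subtraction of a random component instead at every
10th generation), then randomly paired lineages exchange a random proper
subset of components (crossover with repair, conserving the component
multiset), and elitist selection keeps the mutant only on a strict fitness
improvement. Ties keep the parent: accepting equal-fitness mutants lets
models drift and bloat without evidence. The population-of-(1+1)-lineages
reading reconciles a population of 20 evolved models with the (1+1)
selection rule.

**Hand-over.** `F` cannot distinguish models once all target states are
covered, and its nominal trigger "fitness = 1" is unattainable under the
capped formula; the trigger is therefore `f1 = 1`. When a lineage first
attains it, its model and the component whose addition achieved it are
handed to the bottom-up explorer. Each lineage triggers at most once per
run, which bounds the exploration budget without changing what is explored.

**Bottom-up (`run_bottomup()`).** Simulated annealing over component
additions: propose a library component that shares a reactant with the
focal component and is absent from the model, score the mutant by the
Bayesian score, accept by the Metropolis rule (always on improvement, with
probability `exp(delta/t)` on worsening), cool geometrically from `t_init`
to `t_min` by factor `alpha` with `iter_num` proposals per level. Each
accepted component becomes the next focal component, so exploration walks a
trail of attachments across the network (`follow_chain = FALSE` restores a
fixed focal neighbourhood). Only additions are explored; subtraction
belongs to the top-down route. Because the Bayesian score is linear in `p`,
raw score differences scale with the number of positive examples (hundreds
here), which would freeze the Metropolis rule into pure hill climbing at
any fixed temperature scale; the acceptance test therefore uses the score
difference *per positive example* (`delta_scale`, default `p`), so one
cooling schedule behaves comparably across targets. Acceptance counts per
component, aggregated over runs (`frequency_report()`), rank the
interactions the search keeps finding useful.

**Integrative driver (`run_integrative()`).** Per trial: generate the
library from the fixture's species/enzyme partition, generate target
states, run the ES with SA hand-overs, then score every final model (the
ES population and each exploration's final model) by fitness, structural
compression/coverage under the fixture's renaming, and the Bayesian score.
Everything is replayable: a run is a pure function of its configuration and
seed, and traces serialize to TSV byte-identically.

## Fixtures and the synthetic target generator

Four encoded fixtures serve as ground truth: the enzymatic toy (3
components), the methylglyoxal detoxification pathway MG-D (6 primitive
reactants, 7 reactions, compared over `M, G, H, S`), the RKIP-inhibited ERK
cascade (11 reactants, 11 reactions, compared over its 7 primitive
reactants), and a deliberately synthetic 10-reactant stand-in for a
combinatorial stress-response network (label vocabulary only; not the
published map). The RKIP reaction list is a reconstruction from the
cascade's description and its reactant table; where that table disagrees
with the running text on one explored complex (`MEKPP|RP` vs
`MEKPP|RKIPP`), the fixture follows the text, whose reachability argument
involves `MEKPP` and `RKIPP`. Species/enzyme partitions are declared per
fixture: MG-D uses species `{M, H, S}` and enzymes `{G, G1, G2}`; RKIP uses
the kinases and phosphatase `{Raf1, MEKPP, RP}` as enzymes and
`{RKIP, RKIPP, ERK, ERKPP}` as species, which makes every reactant the
search is expected to recover — including the explored `MEKPP|RKIPP`
complex — reachable, and lets the product rule regenerate the pathway's own
`RKIPP` label.

Target states are produced by `make_target_states()`: qualitative
simulation of the encoded true model projected onto the compared variables.
This replaces abstraction from numerical simulator output, which would
require rate constants and thresholds that are unavailable; it preserves
the property that a perfect reconstruction attains `f1 = 1, f2 = 0` —
the anchor of the self-consistency tests. What passing tests show is
therefore recovery of a *known generating model* from its own qualitative
behaviour; they do not show robustness to abstraction noise, to missing
observations, or to states pooled from several experimental conditions,
all of which real data would add.

## Numerical choices and scales

* Canonical complex labels: constituents sorted lexicographically
  (C collation) and joined with `|`; nested complexes flatten. This makes
  `A|E` and `E|A` one place and keeps arc matching name-free.
* Duplicate components in one model are disallowed; qualitative semantics
  is unchanged by duplication.
* State sets: factored representation throughout; projection materializes
  at most `6^N` states for `N` compared variables (`N <= 7` here).
  Enumeration refuses models beyond 20 variables (`qmlearn.var_cap`), and
  the evaluation engine enumerates only the variables relevant to the
  compared subset (cap 22, `qmlearn.enum_cap`).
* Default experiment scale, chosen to complete on a single desktop core
  while leaving the search room to converge: 100 generations, population 20,
  subtraction every 10 generations, crossover each generation; 1 trial for
  RKIP timing runs, 10 trials for MG-D coverage studies. The integrative SA
  schedule is `t_init = 1, t_min = 0.1, alpha = 0.7, iter_num = 10` (7
  levels); standalone SA defaults are longer (`t_min = 0.01, alpha = 0.9,
  iter_num = 50`). The SA temperature schedule is a package choice with no
  external reference value.
* Selection ties keep the parent; crossover on a single-component parent
  degenerates to swap-or-identity and is flagged in the result.

## Known limitations

* The library composes primitive species with primitive enzymes only, so
  complexes of complexes (the RKIP ternary complex) are not constructible
  by search — learned RKIP models approximate the cascade's behaviour
  without its ternary intermediate, as reflected in their structural
  scores.
* Evaluation is set-based; temporal ordering of states (qualitative
  behaviours, QSIM transitions) is not represented.
* The Bayesian score's size term uses `1 + arity` per constraint, a proxy
  for constraint size; other conventions would shift scores by a
  model-independent direction but may reorder close models.
* Magnitudes are binary (`zer`/`pos`); saturating or multi-landmark
  quantity spaces are out of scope.

## A worked example

```{r example, eval = FALSE}
fx <- fixture_mgd()
targets <- make_target_states(fx)          # 175 states over M, G, H, S
evaluate_model(fx$model, targets)          # f1 = 1, f2 = 0, F = 2/3

cfg <- integrative_config("mgd", trials = 1,
                          es = es_config(generations = 100,
                                         population = 20),
                          seed = 1)
report <- run_integrative(cfg)
report
max(report$models$F[report$models$source == "es"])
max(report$models$coverage)
head(report$frequencies)
```

The vignette does not execute the full run; the same computation is scripted
in `scripts/acceptance.R` and exercised by the test suite.
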