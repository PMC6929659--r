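---
title: "Synthesising heterogeneous pharmacovigilance evidence in a Bayesian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesising heterogeneous pharmacovigilance evidence in a Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrbayes)
```

## The problem

Deciding whether a drug causes an adverse effect is rarely settled by a
single study. The evidence is heterogeneous — randomised trials,
cohort and case-control studies, case reports, and basic-science work on
candidate biological pathways — and each piece speaks to causation only
indirectly and with a reliability that depends on how the study was run.
`adrbayes` encodes this assessment problem as a small discrete Bayesian
network and computes, by exact inference, the posterior probability of
the causal hypothesis as evidence accumulates.

The design follows the classic epidemiological viewpoints on causation
(difference-making, strength and shape of association, temporality,
biological plausibility): each viewpoint becomes a binary *indicator*
node between the hypothesis and the data, and each study becomes a
binary *report* node whose conditional distribution encodes how well
that study tracks the indicator it targets.

## The network

The hypothesis node `C` ("the drug causes the effect in the population
of interest") is the single root. Six indicators hang off it:

* `Delta` — difference-making: intervening on exposure changes the
  outcome. Difference-making entails causation, so
  `P(Delta | not C) = 0`; the converse default `P(Delta | C) = 1` is
  configurable, since causation embedded in a holistic structure need
  not admit link-wise intervention.
* `PD`, `DR`, `RoG` — the statistical block: probabilistic dependence,
  dose-response, and rate of growth, ordered by entailment
  (`RoG => DR => PD`, encoded as hard CPT rows
  `P(DR | RoG) = P(PD | DR) = 1`).
* `M` — existence of a biological mechanism. Causation requires some
  mechanism (`P(M | C) = 1`); a pathway may exist without causation, and
  that probability defaults to `P(M | not C) = 0.5`.
* `T` — correct temporal structure, entailed by either mechanism or
  causation (`P(T | M or C) = 1`), indifferent otherwise
  (`P(T | not M, not C) = 0.5`).

The free rows of the statistical block are derived from a family of
candidate dose-response curve shapes. Each curve flags which indicators
it exhibits and carries a prior weight under each hypothesis state; the
block conditionals are then probability quotients over the family, e.g.
`P(PD | C, not DR)` is the weight of curves showing dependence without a
dose-response pattern divided by the weight of all curves without one.
The bundled `default_curve_set()` has eight shapes (flat, inverted-U,
threshold, shallow linear, saturating, steep linear, sigmoid,
supralinear) with uniform weights. The shapes' flag assignments are a
design choice: monotone shapes exhibit `DR`; the three steep ones also
`RoG`; the inverted-U exhibits dependence only; the flat curve nothing.
Uniform weights make the block deliberately neutral (`P(Ind|C) =
P(Ind|not C)` for the statistical indicators), so the bundled family
never smuggles in dose-response diagnosticity the analyst did not
declare — for a real assessment the weights should be elicited, and
`check_indicator_positivity()` verifies the resulting ordering
`P(Ind | C) >= P(Ind) >= P(Ind | not C)`. The entailment orientation of
the block (`C -> RoG -> DR -> PD` with `C` a parent of each) is fixed by
the form of the elicited conditionals themselves, which condition on
`RoG` failing or `DR` failing.

## Study reports

A study enters the network as one binary report node `ES_<id>` whose
parents are the indicators the study targets. What a design may target
is constrained (`allowed_targets()`): trials speak to difference-making
and time course; cohorts to one statistical indicator plus time course;
case-control studies to one statistical indicator only; case
reports/series to time course. A study may target at most one of
`PD`/`DR`/`RoG` — the strongest its data support — since those speak
through the same statistical signal.

The report CPT has two regimes. When every targeted indicator holds,

```
P(ES = 1 | targets true) = (1 - SB/10) * (0.5 + avg(tracking)/2)
```

and for every other parent combination,

```
P(ES = 1 | otherwise) = (1 - SB/10) * 0.5 * (1 - avg(tracking'))
```

where the tracking set is `(A, SS, D)` for observational designs and
`(A, SS, D, B, R, Pl)` for trials; the second regime drops duration
`D`, because running a study longer cannot conjure an absent signal —
passing `D` there is rejected. `SB` is sponsorship bias: it attenuates
positive reports multiplicatively in both regimes (a conflicted sponsor
tends to hide harms), with the divisor 10 kept configurable.

```{r formulas}
cohort <- modulator_vector(A = 1, SS = 1, D = 1, SB = 0)
positive_report_probability(cohort, c("A", "SS", "D"))
negative_report_probability(cohort, c("A", "SS"))
```

Uncertainty about a modulator score is handled hierarchically:
`marginalize_uncertain_modulator()` mixes the deterministic CPT rows
under a discrete belief over the score, collapsing exactly to the point
CPT for point-mass beliefs. When several studies share a funder, a
single discrete bias node can be made an explicit parent of all their
reports (`shared_bias_variable()`), so the reports also update the
posterior over the group's bias. With a single-valued (point-mass)
belief no node is added; the value is folded into the CPTs, which is
equivalent.

## Mechanism evidence

A mechanism hypothesis `M_i` is a specific pathway, decomposed into an
ordered chain of sub-mechanism links. The chain CPTs implement three
rules: the mechanism entails each link; completing the whole chain
while the mechanism fails is logically inconsistent, so the final link
of a multi-link chain gets a zero row under `not M_i` when all earlier
links hold; every other row under `not M_i` takes the link's
*background* — 1 for steps established independently of the pathway,
0.5 for indifference, or any elicited value. For a single-link chain
the background row takes precedence (there are no earlier links to
complete), which also keeps a link shared between two chains consistent:
a shared link holds with certainty as soon as any parent mechanism
does, and otherwise falls back to its background.

Basic-science findings attach to links as report nodes graded by Bayes
factor: confident claims get likelihoods `0.91/0.09` (factor about 10),
cautious claims `0.75/0.25` (factor 3). Evidential modulators are
deliberately not modelled for mechanism reports; the grade is the whole
reliability judgement.

Mechanism evidence has a structural ceiling: however many positive
reports arrive, they bear on `C` only through `M`, so the posterior
odds of `C` can rise by at most a factor `1/P(M | not C)` (2 under the
0.5 default). The test-suite checks this bound on randomised mechanism
layers, end to end through the inference engine.

## Inference

`posterior()` runs variable elimination with a min-fill ordering;
`brute_force_posterior()` recomputes the same quantity by exhaustive
summation of the chain-rule joint and acts as the independent oracle
(the suite compares the two on hundreds of randomised networks, at
tolerance 1e-9). The networks this package builds are small — the
bundled case study has 22 binary nodes — so no log-space or approximate
machinery is needed; probabilities are 64-bit floats, CPT rows must sum
to 1 within 1e-12, and inference agreement is asserted at 1e-9.
`trajectory()` conditions on evidence one item at a time and records
each item's likelihood-ratio contribution (posterior odds after / odds
before); because inference is exact, the final row equals batch
conditioning and is invariant under evidence reordering, and both facts
are asserted at 1e-12. `sensitivity()` recomputes the posterior over a
grid of priors.

## The bundled case study

```{r case}
spec <- load_case_spec(system.file("extdata", "paracetamol_asthma.yaml",
                                   package = "adrbayes"))
res <- run_case(spec)
subset(as.data.frame(res$trajectory), prior == 0.01,
       select = c(step, item_id, posterior, lr_contribution))
```

The fixture encodes the debated paracetamol–asthma association: two
candidate mechanisms (NAPQI stimulating TRPA1 receptors leading to
neurogenic airway inflammation; glutathione depletion causing
oxidative-stress hyperresponsiveness) carrying six positive
basic-science reports, then a large null-result paediatric trial
feeding `Delta`, then a pregnancy cohort feeding `DR` and `T`. The
trial's report CPT is pinned by `cpt_override` to its published
assessment (`P(ES=0|Delta) = 13/40`, `P(ES=0|no Delta) = 91/100`)
rather than derived from the formula path, and the fixture's
reproduction targets are the mechanism-complete row and the trial row
of the reference posterior table; further published studies on this
hypothesis would need per-study report CPTs that are not bundled, so
they are omitted rather than guessed.

## Forward sampling and self-calibration

`forward_sample()` draws full assignments ancestrally, and
`generate_synthetic_case()` uses it to build cases with known ground
truth: it drafts a random specification consistent with the design
rules, samples the latent hypothesis, indicators and report outcomes in
one draw, and writes the sampled outcomes back as the observed data.
Because the observations come from the model's own generative
distribution, the posterior must discriminate (higher on average when
the sampled hypothesis is true) and be calibrated (among cases with
posterior near p, a fraction near p has the hypothesis true). The suite
checks both on 1000 seeded cases of one study plus one mechanism at
prior 0.5 — sizes chosen to keep the default run around two minutes.
These checks validate the updater against its own sampling
distribution; they say nothing about whether real studies follow the
report model, whether elicited curve weights, backgrounds or modulator
scores are right, or whether the binary effect-size abstraction fits a
given literature.

## Limitations

Effect sizes are binary; odds ratios, confidence intervals and
continuous dose-response fitting are out of scope, as are learning CPTs
from data, external-validity ("relevance") modulators, and
three-valued hypothesis spaces (causes / prevents / neither). Modulator
scores are taken as given rather than derived from quality-assessment
instruments. Exact inference limits networks to a few dozen nodes,
which is ample for assessments of this shape but not for thousands of
reports.
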