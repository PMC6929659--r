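Package: adrbayes
Title: Bayesian Network Synthesis of Heterogeneous Evidence for Drug-Harm
    Causal Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and queries discrete Bayesian networks that aggregate
    heterogeneous pharmacovigilance evidence (randomised trials,
    observational studies and basic-science mechanism reports) into a
    posterior probability that a drug causes an adverse effect. Evidence
    bears on the causal hypothesis through intermediate causal indicators
    (difference-making, probabilistic dependence, dose-response, rate of
    growth, mechanism and time course); study-quality modulators
    (adjustment, sample size, duration, blinding, randomisation, placebo
    control and sponsorship bias) set the likelihood that a study's report
    tracks the indicator it targets. Includes exact inference by variable
    elimination with a brute-force enumeration oracle, sequential posterior
    trajectories with per-item likelihood-ratio contributions, prior
    sensitivity analysis, a declarative YAML/JSON evidence-specification
    format with a bundled paracetamol-asthma case study, forward sampling
    and a synthetic-case generator for calibration checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
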