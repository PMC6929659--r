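# Bundled case study: does paracetamol cause asthma?
# Two candidate mechanisms with six positive basic-science reports, a
# null-result paediatric trial feeding difference-making (report CPT
# pinned to its published 13/40 and 91/100 values), and a pregnancy
# cohort feeding dose-response and time course. Further published
# studies in this debate are omitted: their report CPTs require
# per-study report parameters that are not bundled here.
priors:
- 0.01
- 0.005
- 0.001
mechanisms:
- id: M1
  p_given_m: 0.7
  links:
  - id: mu_1_1
    background: 1.0
  - id: mu_1_2
    background: 0.5
  - id: mu_1_3
    background: 0.5
  reports:
  - link: mu_1_2
    grade: confident
    outcome: 1
    id: Rep_mu_1_2
  - link: mu_1_3
    grade: confident
    outcome: 1
    id: Rep_mu_1_3
- id: M2
  p_given_m: 0.8
  links:
  - id: mu_2_1
    background: 0.01
  - id: mu_2_2
    background: 0.5
  reports:
  - link: mu_2_1
    grade: confident
    outcome: 1
    id: Rep_mu_2_1a
  - link: mu_2_1
    grade: confident
    outcome: 1
    id: Rep_mu_2_1b
  - link: mu_2_2
    grade: cautious
    outcome: 1
    id: Rep_mu_2_2a
  - link: mu_2_2
    grade: confident
    outcome: 1
    id: Rep_mu_2_2b
studies:
- id: ludwig_rct
  design: rct
  targets:
  - Delta
  modulators:
    A: 0.5
    SS: 1.0
    D: 0.0
    B: 1.0
    R: 1.0
    Pl: 0.5
    SB: 1.0
  outcome: 0
  cpt_override:
    p_es0_given_true: 0.325
    p_es0_given_false: 0.91
- id: shaheen_cohort
  design: cohort
  targets:
  - DR
  - T
  modulators:
    A: 1.0
    SS: 1.0
    D: 1.0
    B: 0.0
    R: 0.0
    Pl: 0.0
    SB: 0.0
  outcome: 1

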