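# Study reports: design -> indicator targeting rules, modulator-driven
# report likelihoods, sponsorship-bias attenuation and hierarchical
# uncertainty over modulator values.

MODULATOR_NAMES <- c("A", "SS", "D", "B", "R", "Pl", "SB")
STUDY_DESIGNS <- c("rct", "cohort", "case_control", "case_series",
                   "case_report", "basic_science")
SIGMA_INDICATORS <- c("PD", "DR", "RoG")

#' Study-quality modulator vector
#'
#' Quality scores in `[0, 1]` for adjustment (`A`), sample size (`SS`),
#' duration (`D`), blinding (`B`), randomisation (`R`) and placebo
#' control (`Pl`), plus sponsorship bias `SB` (0 = none, 1 = fully
#' conflicted; intermediate values allowed). Scores are taken as given —
#' mapping raw study characteristics (sample sizes, follow-up length)
#' onto `[0, 1]` is the analyst's job.
#'
#' @param A,SS,D,B,R,Pl,SB Scores in `[0, 1]`.
#' @return A `modulator_vector` object.
#' @export
modulator_vector <- function(A = 0, SS = 0, D = 0, B = 0, R = 0, Pl = 0,
                             SB = 0) {
  v <- c(A = A, SS = SS, D = D, B = B, R = R, Pl = Pl, SB = SB)
  bad <- names(v)[v < 0 | v > 1 | is.na(v)]
  if (length(bad))
    stop(sprintf("modulator %s out of [0,1]", bad[1L]), call. = FALSE)
  structure(as.list(v), class = "modulator_vector")
}

#' Indicators a study design can speak to
#'
#' Randomised trials inform difference-making and time course (and the
#' dose-related statistical indicators when multiple dose arms are
#' declared); cohort studies inform one statistical indicator plus time
#' course; case-control studies a statistical indicator only; case
#' reports and series time course only (difference-making under an
#' explicit causality-assessment override); basic-science studies speak
#' to mechanism links, handled by the mechanism layer.
#'
#' @param design One of `"rct"`, `"cohort"`, `"case_control"`,
#'   `"case_series"`, `"case_report"`, `"basic_science"`.
#' @param multi_dose RCT declared with several dose arms.
#' @param delta_override Allow a case report/series to target
#'   difference-making (e.g. a positive rechallenge scored by a
#'   causality-assessment instrument).
#' @return Character vector of permitted indicator nodes.
#' @export
allowed_targets <- function(design, multi_dose = FALSE,
                            delta_override = FALSE) {
  design <- match.arg(design, STUDY_DESIGNS)
  switch(design,
    rct = c("Delta", "T", if (isTRUE(multi_dose)) SIGMA_INDICATORS),
    cohort = c(SIGMA_INDICATORS, "T"),
    case_control = SIGMA_INDICATORS,
    case_series = ,
    case_report = c("T", if (isTRUE(delta_override)) "Delta"),
    basic_science = character(0))
}

#' One piece of study evidence
#'
#' @param id Unique study identifier.
#' @param design Study design, see [allowed_targets()].
#' @param targets Character vector of indicator nodes the study informs;
#'   must be permitted by the design and contain at most one of the
#'   statistical indicators `PD`, `DR`, `RoG` (declare the strongest one
#'   the study supports).
#' @param modulators A [modulator_vector()].
#' @param outcome Observed binary effect-size report: 1 (effect
#'   observed) or 0 (null result).
#' @param sponsor_group Optional key linking studies that share a
#'   sponsorship-bias variable, see [shared_bias_variable()].
#' @param cpt_override Optional list with `p_es0_given_true` and
#'   `p_es0_given_false`, pinning the report CPT instead of deriving it
#'   from the modulator formulas.
#' @param multi_dose,delta_override Design flags, see
#'   [allowed_targets()].
#' @return A `study_record` object.
#' @export
study_record <- function(id, design, targets, modulators, outcome,
                         sponsor_group = NULL, cpt_override = NULL,
                         multi_dose = FALSE, delta_override = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            inherits(modulators, "modulator_vector"))
  design <- match.arg(design, STUDY_DESIGNS)
  targets <- as.character(targets)
  if (!length(targets))
    stop("study must target at least one indicator", call. = FALSE)
  allowed <- allowed_targets(design, multi_dose, delta_override)
  bad <- setdiff(targets, allowed)
  if (length(bad))
    stop(sprintf("design '%s' cannot speak to indicator '%s'", design,
                 bad[1L]), call. = FALSE)
  if (sum(targets %in% SIGMA_INDICATORS) > 1L)
    stop("declare exactly one statistical indicator (the strongest the study supports)",
         call. = FALSE)
  if (!outcome %in% c(0, 1))
    stop("outcome must be 0 or 1", call. = FALSE)
  if (!is.null(cpt_override)) {
    stopifnot(is.list(cpt_override),
              all(c("p_es0_given_true", "p_es0_given_false") %in%
                    names(cpt_override)))
    ov <- unlist(cpt_override[c("p_es0_given_true", "p_es0_given_false")])
    if (any(ov < 0 | ov > 1))
      stop("cpt_override probabilities must lie in [0,1]", call. = FALSE)
  }
  structure(list(id = id, design = design, targets = targets,
                 modulators = modulators, outcome = as.integer(outcome),
                 sponsor_group = sponsor_group, cpt_override = cpt_override,
                 multi_dose = isTRUE(multi_dose),
                 delta_override = isTRUE(delta_override)),
            class = "study_record")
}

report_node_name <- function(study) paste0("ES_", study$id)

# signal-tracking component sets per design: trials are additionally
# scored on blinding, randomisation and placebo; duration never tracks
# the signal when the indicator is false.
tracking_components <- function(design) {
  if (design == "rct")
    list(positive = c("A", "SS", "D", "B", "R", "Pl"),
         negative = c("A", "SS", "B", "R", "Pl"))
  else
    list(positive = c("A", "SS", "D"),
         negative = c("A", "SS"))
}

#' Probability of a positive report when the targeted indicators hold
#'
#' `(1 - SB/10) * (0.5 + avg(tracking)/2)`: a study with no tracking
#' ability reports positives at chance (0.5); perfect tracking drives
#' the probability to 1; sponsorship bias attenuates it multiplicatively
#' (harms get hidden).
#'
#' @param m A [modulator_vector()].
#' @param tracking Non-empty character vector of modulator components
#'   averaged as the study's signal-tracking score.
#' @param sb_divisor Attenuation divisor in `(1 - SB/divisor)`,
#'   default 10.
#' @return `P(ES = 1 | indicators true, modulators)` in `[0, 1]`.
#' @export
positive_report_probability <- function(m, tracking, sb_divisor = 10) {
  stopifnot(inherits(m, "modulator_vector"))
  tracking <- as.character(tracking)
  if (!length(tracking))
    stop("tracking component set must be non-empty", call. = FALSE)
  bad <- setdiff(tracking, setdiff(MODULATOR_NAMES, "SB"))
  if (length(bad))
    stop(sprintf("unknown tracking component '%s'", bad[1L]), call. = FALSE)
  avg <- mean(unlist(m[tracking]))
  p <- (1 - m$SB / sb_divisor) * (0.5 + avg / 2)
  min(max(p, 0), 1)
}

#' Probability of a positive report when the targeted indicators fail
#'
#' The false-positive rate `(1 - SB/10) * 0.5 * (1 - avg(tracking))`: a
#' perfectly tracking study never reports a spurious positive; a
#' worthless one does so at chance. Duration is excluded — running a
#' study longer cannot make an absent signal appear — so passing `D`
#' here is an error.
#'
#' @inheritParams positive_report_probability
#' @return `P(ES = 1 | indicators false, modulators)` in `[0, 1]`.
#' @export
negative_report_probability <- function(m, tracking, sb_divisor = 10) {
  stopifnot(inherits(m, "modulator_vector"))
  tracking <- as.character(tracking)
  if ("D" %in% tracking)
    stop("duration is not a signal-tracking component when the indicator does not hold",
         call. = FALSE)
  if (!length(tracking))
    stop("tracking component set must be non-empty", call. = FALSE)
  bad <- setdiff(tracking, setdiff(MODULATOR_NAMES, "SB"))
  if (length(bad))
    stop(sprintf("unknown tracking component '%s'", bad[1L]), call. = FALSE)
  avg <- mean(unlist(m[tracking]))
  p <- (1 - m$SB / sb_divisor) * 0.5 * (1 - avg)
  min(max(p, 0), 1)
}

# P(ES = 1 | parent row) vector in canonical row order: the all-true
# parent combination gets the positive formula, every other row the
# negative (false-positive) formula.
study_p_true_rows <- function(study, modulators = study$modulators) {
  n_comb <- 2L^length(study$targets)
  if (!is.null(study$cpt_override)) {
    p <- rep(1 - study$cpt_override$p_es0_given_false, n_comb)
    p[n_comb] <- 1 - study$cpt_override$p_es0_given_true
    return(p)
  }
  tr <- tracking_components(study$design)
  p <- rep(negative_report_probability(modulators, tr$negative), n_comb)
  p[n_comb] <- positive_report_probability(modulators, tr$positive)
  p
}

#' Report CPT for a study
#'
#' @param study A [study_record()].
#' @return A [cpt()] for the study's report node with the targeted
#'   indicators as parents.
#' @export
study_report_cpt <- function(study) {
  stopifnot(inherits(study, "study_record"))
  binary_cpt(report_node_name(study), study$targets,
             p_true = study_p_true_rows(study))
}

#' Attach a study's report node to the network
#'
#' Adds one binary report node whose parents are the study's targeted
#' indicators. The CPT row where all targets hold uses
#' [positive_report_probability()]; every other row uses
#' [negative_report_probability()] (or the study's `cpt_override`, when
#' given).
#'
#' @param net A `causal_network` containing the causal scaffold.
#' @param study A [study_record()].
#' @param beliefs Optional list of [modulator_belief()] objects; when
#'   given, the report CPT is the belief-weighted mixture from
#'   [marginalize_uncertain_modulator()].
#' @return The updated network.
#' @export
attach_study <- function(net, study, beliefs = NULL) {
  stopifnot(inherits(net, "causal_network"), inherits(study, "study_record"))
  miss <- setdiff(study$targets, node_names(net))
  if (length(miss))
    stop(sprintf("missing node '%s'", miss[1L]), call. = FALSE)
  net <- add_variable(net, discrete_variable(report_node_name(study)),
                      "report")
  x <- if (is.null(beliefs)) study_report_cpt(study)
       else marginalize_uncertain_modulator(beliefs, study)
  attach_cpt(net, x)
}

#' Discrete belief over a modulator's value
#'
#' @param component Modulator name (one of `A`, `SS`, `D`, `B`, `R`,
#'   `Pl`, `SB`).
#' @param values Candidate values in `[0, 1]`.
#' @param probs Probabilities over `values`, summing to 1.
#' @return A `modulator_belief` object.
#' @export
modulator_belief <- function(component, values, probs) {
  component <- match.arg(component, MODULATOR_NAMES)
  values <- as.numeric(values); probs <- as.numeric(probs)
  stopifnot(length(values) == length(probs), length(values) >= 1L)
  if (any(values < 0 | values > 1))
    stop(sprintf("modulator %s out of [0,1]", component), call. = FALSE)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop("belief probabilities must be non-negative and sum to 1",
         call. = FALSE)
  structure(list(component = component, values = values, probs = probs),
            class = "modulator_belief")
}

#' Report CPT under modulator uncertainty
#'
#' When the analyst is unsure of a study's modulator scores, the report
#' CPT becomes a hierarchical mixture: each row is the belief-weighted
#' average of the deterministic rows obtained at every combination of
#' candidate modulator values. Point-mass beliefs collapse to the
#' deterministic CPT exactly.
#'
#' @param beliefs List of [modulator_belief()] objects (distinct
#'   components).
#' @param study A [study_record()].
#' @return A [cpt()] for the study's report node.
#' @export
marginalize_uncertain_modulator <- function(beliefs, study) {
  stopifnot(inherits(study, "study_record"))
  if (inherits(beliefs, "modulator_belief")) beliefs <- list(beliefs)
  stopifnot(all(vapply(beliefs, inherits, TRUE, "modulator_belief")))
  comps <- vapply(beliefs, `[[`, "", "component")
  if (anyDuplicated(comps))
    stop("one belief per modulator component", call. = FALSE)
  if (!is.null(study$cpt_override))
    stop("cannot mix modulator beliefs with a CPT override", call. = FALSE)
  n_comb <- 2L^length(study$targets)
  p <- rep(0, n_comb)
  grid <- expand.grid(lapply(beliefs, function(b) seq_along(b$values)),
                      KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(grid))) {
    w <- 1
    mods <- study$modulators
    for (k in seq_along(beliefs)) {
      i <- grid[r, k]
      w <- w * beliefs[[k]]$probs[i]
      mods[[comps[k]]] <- beliefs[[k]]$values[i]
    }
    p <- p + w * study_p_true_rows(study, modulators = mods)
  }
  binary_cpt(report_node_name(study), study$targets, p_true = p)
}

#' Shared sponsorship-bias variable for a group of studies
#'
#' Studies from the same author group or funder share one systematic
#' bias: rather than folding a separate `SB` score into each report CPT,
#' a single discrete bias node is added as an extra parent of each of
#' the group's report nodes, with the belief distribution as its prior.
#' Observing the reports then also updates the posterior over the
#' group's bias.
#'
#' @param net A `causal_network`.
#' @param group Sponsor-group key; every study must carry it in
#'   `sponsor_group`.
#' @param belief A [modulator_belief()] for component `SB`.
#' @param studies List of [study_record()] objects in the group.
#' @return The updated network (unchanged when `studies` is empty).
#' @export
shared_bias_variable <- function(net, group, belief, studies) {
  stopifnot(inherits(net, "causal_network"),
            inherits(belief, "modulator_belief"))
  if (belief$component != "SB")
    stop("shared bias variable requires a belief over SB", call. = FALSE)
  if (!length(studies)) return(net)
  if (inherits(studies, "study_record")) studies <- list(studies)
  stopifnot(all(vapply(studies, inherits, TRUE, "study_record")))
  for (s in studies)
    if (is.null(s$sponsor_group) || s$sponsor_group != group)
      stop(sprintf("study '%s' does not belong to sponsor group '%s'",
                   s$id, group), call. = FALSE)
  if (length(belief$values) == 1L) {
    # a point-mass belief needs no explicit node: fold the value into
    # each report CPT
    for (s in studies) {
      s$modulators$SB <- belief$values
      net <- attach_study(net, s)
    }
    return(net)
  }
  sb_node <- paste0("SB_", group)
  sb_states <- as.character(belief$values)
  net <- add_variable(net, discrete_variable(sb_node, states = sb_states),
                      "modulator")
  net <- attach_cpt(net, cpt(sb_node, probs = matrix(belief$probs, 1),
                             states = sb_states))
  for (s in studies) {
    miss <- setdiff(s$targets, node_names(net))
    if (length(miss))
      stop(sprintf("missing node '%s'", miss[1L]), call. = FALSE)
    rep_node <- report_node_name(s)
    if (!rep_node %in% node_names(net))
      net <- add_variable(net, discrete_variable(rep_node), "report")
    n_t <- 2L^length(s$targets)
    p <- numeric(0)
    for (v in belief$values) {
      mods <- s$modulators
      mods$SB <- v
      p <- c(p, study_p_true_rows(s, modulators = mods))
    }
    net <- attach_cpt(net, cpt(rep_node, c(s$targets, sb_node),
                               probs = cbind(1 - p, p),
                               parent_states = stats::setNames(
                                 list(sb_states), sb_node)))
  }
  net
}
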