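# The fixed causal scaffold: hypothesis node C, difference-making Delta,
# the statistical block (PD, DR, RoG), mechanism M and time course T,
# with entailment-constrained CPTs. The statistical-block CPTs are
# derived from a weighted family of candidate dose-response curve shapes.

INDICATOR_NODES <- c("Delta", "PD", "DR", "RoG", "M", "T")

#' Candidate dose-response curve shape
#'
#' Each curve flags which statistical indicators it exhibits:
#' probabilistic dependence (`pd`), a monotone dose-response pattern
#' (`dr`, implying `pd`) and a high rate of growth (`rog`, implying
#' `dr`). Weights are unnormalised prior plausibilities of the curve
#' conditional on causation holding (`weight_given_c`) or not
#' (`weight_given_not_c`).
#'
#' @param label Curve label.
#' @param pd,dr,rog Logical indicator flags; must respect
#'   `rog => dr => pd`.
#' @param weight_given_c,weight_given_not_c Non-negative weights.
#' @return A `curve_spec` object.
#' @export
curve_spec <- function(label, pd, dr, rog,
                       weight_given_c = 1, weight_given_not_c = 1) {
  pd <- isTRUE(as.logical(pd)); dr <- isTRUE(as.logical(dr))
  rog <- isTRUE(as.logical(rog))
  if ((rog && !dr) || (dr && !pd))
    stop(sprintf("inconsistent curve flags for '%s': rog => dr => pd", label),
         call. = FALSE)
  if (weight_given_c < 0 || weight_given_not_c < 0)
    stop("curve weights must be non-negative", call. = FALSE)
  structure(list(label = as.character(label), pd = pd, dr = dr, rog = rog,
                 weight_given_c = as.numeric(weight_given_c),
                 weight_given_not_c = as.numeric(weight_given_not_c)),
            class = "curve_spec")
}

#' Collect candidate curves into a set
#'
#' The set must be rich enough to define the statistical-block
#' conditionals: under each hypothesis state there must be positive
#' weight on at least one curve without a dose-response pattern and at
#' least one without a high rate of growth.
#'
#' @param curves List of [curve_spec()] objects.
#' @return A `curve_set` object.
#' @export
curve_set <- function(curves) {
  if (inherits(curves, "curve_spec")) curves <- list(curves)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, TRUE, "curve_spec")))
  labs <- vapply(curves, `[[`, "", "label")
  if (anyDuplicated(labs))
    stop("duplicate curve labels", call. = FALSE)
  cs <- structure(list(curves = curves), class = "curve_set")
  for (side in c("weight_given_c", "weight_given_not_c")) {
    w <- vapply(curves, `[[`, 1, side)
    if (sum(w) <= 0)
      stop(sprintf("curve weights %s sum to zero", side), call. = FALSE)
    dr <- vapply(curves, `[[`, TRUE, "dr")
    rog <- vapply(curves, `[[`, TRUE, "rog")
    if (sum(w[!dr]) <= 0)
      stop(sprintf("degenerate curve set: no weight on curves without dose-response (%s)",
                   side), call. = FALSE)
    if (sum(w[!rog]) <= 0)
      stop(sprintf("degenerate curve set: no weight on curves without rate-of-growth (%s)",
                   side), call. = FALSE)
  }
  cs
}

#' Default illustrative curve family
#'
#' Eight parametric dose-response shapes spanning no effect through
#' supralinear growth, with indicator flags assigned per shape and
#' uniform weights under both hypothesis states. The family is
#' illustrative: for a real assessment the analyst should supply curve
#' weights elicited for the drug-effect pair at hand.
#'
#' @return A `curve_set` of eight curves.
#' @export
default_curve_set <- function() {
  curve_set(list(
    curve_spec("flat",           pd = FALSE, dr = FALSE, rog = FALSE),
    curve_spec("inverted_u",     pd = TRUE,  dr = FALSE, rog = FALSE),
    curve_spec("shallow_linear", pd = TRUE,  dr = TRUE,  rog = FALSE),
    curve_spec("saturating",     pd = TRUE,  dr = TRUE,  rog = FALSE),
    curve_spec("threshold",      pd = TRUE,  dr = TRUE,  rog = FALSE),
    curve_spec("steep_linear",   pd = TRUE,  dr = TRUE,  rog = TRUE),
    curve_spec("sigmoid",        pd = TRUE,  dr = TRUE,  rog = TRUE),
    curve_spec("supralinear",    pd = TRUE,  dr = TRUE,  rog = TRUE)))
}

#' Bundle of statistical-block conditional probabilities
#'
#' Holds the six free conditionals of the PD/DR/RoG block; the
#' entailment rows `P(PD|DR) = P(DR|RoG) = 1` are hard-coded when the
#' block is assembled, not stored here.
#'
#' @param p_rog_given_c,p_rog_given_not_c `P(RoG | C)` and
#'   `P(RoG | not C)`.
#' @param p_dr_given_c_not_rog,p_dr_given_not_c_not_rog `P(DR | C, not
#'   RoG)` and `P(DR | not C, not RoG)`.
#' @param p_pd_given_c_not_dr,p_pd_given_not_c_not_dr `P(PD | C, not
#'   DR)` and `P(PD | not C, not DR)`.
#' @return A `sigma_cpt_bundle` object.
#' @export
sigma_cpt_bundle <- function(p_rog_given_c, p_rog_given_not_c,
                             p_dr_given_c_not_rog, p_dr_given_not_c_not_rog,
                             p_pd_given_c_not_dr, p_pd_given_not_c_not_dr) {
  vals <- c(p_rog_given_c = p_rog_given_c,
            p_rog_given_not_c = p_rog_given_not_c,
            p_dr_given_c_not_rog = p_dr_given_c_not_rog,
            p_dr_given_not_c_not_rog = p_dr_given_not_c_not_rog,
            p_pd_given_c_not_dr = p_pd_given_c_not_dr,
            p_pd_given_not_c_not_dr = p_pd_given_not_c_not_dr)
  if (any(vals < 0 | vals > 1))
    stop("sigma bundle probabilities must lie in [0,1]", call. = FALSE)
  structure(as.list(vals), class = "sigma_cpt_bundle")
}

#' Derive the statistical-block conditionals from a curve family
#'
#' With curve weights normalised per hypothesis state, the free
#' conditionals are probability quotients over the curve family, e.g.
#' `P(PD | C, not DR)` is the total weight of curves exhibiting
#' dependence but no dose-response pattern divided by the total weight
#' of curves without a dose-response pattern, all conditional on C.
#' The result is invariant under rescaling all weights by a positive
#' constant.
#'
#' @param curves A [curve_set()].
#' @return A [sigma_cpt_bundle()].
#' @export
derive_sigma_cpts <- function(curves) {
  stopifnot(inherits(curves, "curve_set"))
  pd <- vapply(curves$curves, `[[`, TRUE, "pd")
  dr <- vapply(curves$curves, `[[`, TRUE, "dr")
  rog <- vapply(curves$curves, `[[`, TRUE, "rog")
  one_side <- function(w) {
    w <- w / sum(w)
    if (sum(w[!rog]) <= 0)
      stop("degenerate curve set: conditioning event {no rate-of-growth} has probability 0",
           call. = FALSE)
    if (sum(w[!dr]) <= 0)
      stop("degenerate curve set: conditioning event {no dose-response} has probability 0",
           call. = FALSE)
    c(rog = sum(w[rog]),
      dr = sum(w[dr & !rog]) / sum(w[!rog]),
      pd = sum(w[pd & !dr]) / sum(w[!dr]))
  }
  a <- one_side(vapply(curves$curves, `[[`, 1, "weight_given_c"))
  b <- one_side(vapply(curves$curves, `[[`, 1, "weight_given_not_c"))
  sigma_cpt_bundle(p_rog_given_c = a[["rog"]], p_rog_given_not_c = b[["rog"]],
                   p_dr_given_c_not_rog = a[["dr"]],
                   p_dr_given_not_c_not_rog = b[["dr"]],
                   p_pd_given_c_not_dr = a[["pd"]],
                   p_pd_given_not_c_not_dr = b[["pd"]])
}

#' Configuration of the causal layer
#'
#' @param prior_c Prior probability of the causal hypothesis.
#' @param delta_given_c `P(Delta | C)`: 1 unless holistic causation
#'   (causation not admitting intervention on single links) is given
#'   credence, in which case `1 - P(holistic)`. `P(Delta | not C)` is
#'   fixed at 0 — difference-making entails causation.
#' @param m_given_not_c `P(M | not C)`: the probability that some
#'   physiological pathway from drug to effect exists even though the
#'   drug does not cause the effect; default 0.5.
#' @param t_given_neither `P(T | not M, not C)`: indifference default
#'   0.5 for correct temporal ordering absent both mechanism and
#'   causation.
#' @param sigma_cpts A [sigma_cpt_bundle()]; defaults to the bundle
#'   derived from [default_curve_set()].
#' @return A `causal_layer_config` object.
#' @export
causal_layer_config <- function(prior_c = 0.01, delta_given_c = 1,
                                m_given_not_c = 0.5, t_given_neither = 0.5,
                                sigma_cpts = derive_sigma_cpts(default_curve_set())) {
  vals <- c(prior_c, delta_given_c, m_given_not_c, t_given_neither)
  if (any(vals < 0 | vals > 1) || prior_c <= 0 || prior_c >= 1)
    stop("causal layer probabilities must lie in [0,1], prior in (0,1)",
         call. = FALSE)
  stopifnot(inherits(sigma_cpts, "sigma_cpt_bundle"))
  structure(list(prior_c = prior_c, delta_given_c = delta_given_c,
                 m_given_not_c = m_given_not_c,
                 t_given_neither = t_given_neither,
                 sigma_cpts = sigma_cpts),
            class = "causal_layer_config")
}

#' Build the causal scaffold network
#'
#' Creates the hypothesis root `C` and the six causal indicators with
#' their entailment-constrained CPTs: `P(Delta | not C) = 0` (difference
#' -making entails causation), `P(M | C) = 1` (causation requires a
#' mechanism), `P(T | M or C) = 1` (mechanism or causation fixes the
#' temporal order), `P(DR | RoG) = P(PD | DR) = 1` (statistical
#' entailments), with the free statistical-block rows taken from the
#' configured [sigma_cpt_bundle()].
#'
#' @param cfg A [causal_layer_config()].
#' @return A valid `causal_network` with nodes
#'   `C, Delta, RoG, DR, PD, M, T`.
#' @export
build_causal_layer <- function(cfg = causal_layer_config()) {
  stopifnot(inherits(cfg, "causal_layer_config"))
  s <- cfg$sigma_cpts
  net <- causal_network()
  net <- add_variable(net, discrete_variable("C"), "hypothesis")
  for (n in INDICATOR_NODES)
    net <- add_variable(net, discrete_variable(n), "indicator")
  net <- attach_cpt(net, binary_cpt("C", p_true = cfg$prior_c))
  # rows in canonical order, first parent varying fastest
  net <- attach_cpt(net, binary_cpt("Delta", "C",
                                    p_true = c(0, cfg$delta_given_c)))
  net <- attach_cpt(net, binary_cpt("RoG", "C",
                                    p_true = c(s$p_rog_given_not_c,
                                               s$p_rog_given_c)))
  net <- attach_cpt(net, binary_cpt("DR", c("C", "RoG"),
                                    p_true = c(s$p_dr_given_not_c_not_rog,
                                               s$p_dr_given_c_not_rog, 1, 1)))
  net <- attach_cpt(net, binary_cpt("PD", c("C", "DR"),
                                    p_true = c(s$p_pd_given_not_c_not_dr,
                                               s$p_pd_given_c_not_dr, 1, 1)))
  net <- attach_cpt(net, binary_cpt("M", "C",
                                    p_true = c(cfg$m_given_not_c, 1)))
  net <- attach_cpt(net, binary_cpt("T", c("M", "C"),
                                    p_true = c(cfg$t_given_neither, 1, 1, 1)))
  assert_valid(net)
  net
}

#' Check the indicator positivity ordering
#'
#' For a variable to function as a causal indicator its probability
#' should rise under causation: `P(Ind | C) >= P(Ind) >= P(Ind | not
#' C)`. This computes all three quantities by exact inference for every
#' indicator present and reports violations of the non-strict ordering
#' (tolerance `1e-12`).
#'
#' @param net A network containing the causal scaffold.
#' @return Character vector of diagnostics; empty if no indicator
#'   violates the ordering.
#' @export
check_indicator_positivity <- function(net) {
  assert_valid(net)
  h <- hypothesis_node(net)
  out <- character(0)
  for (ind in intersect(INDICATOR_NODES, node_names(net))) {
    p_c <- posterior(net, stats::setNames("true", h), target = ind)
    p_nc <- posterior(net, stats::setNames("false", h), target = ind)
    p <- posterior(net, character(), target = ind)
    if (p_c < p - 1e-12 || p < p_nc - 1e-12)
      out <- c(out, sprintf(
        "indicator %s violates positivity: P(%s|C)=%.6g, P(%s)=%.6g, P(%s|not C)=%.6g",
        ind, ind, p_c, ind, p, ind, p_nc))
  }
  out
}
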