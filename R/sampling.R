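# Forward (ancestral) sampling and the synthetic-case generator used
# for calibration and discrimination checks.

#' Forward-sample full assignments from a network
#'
#' Ancestral sampling in topological order: each node's state is drawn
#' from its CPT row given the already-sampled parent states. The
#' empirical joint converges to [joint_probability()].
#'
#' @param net A valid `causal_network`.
#' @param n Number of samples.
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame of `n` rows, one character column per node.
#' @export
forward_sample <- function(net, n, seed = NULL) {
  assert_valid(net)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  ord <- topological_order(net_parent_lists(net))
  out <- vector("list", length(ord))
  names(out) <- ord
  idx <- list()  # 0-based state indices per sampled node
  for (nd in ord) {
    x <- net$cpts[[nd]]
    row <- rep(1, n)
    stride <- 1
    for (p in x$parents) {
      row <- row + idx[[p]] * stride
      stride <- stride * length(x$parent_states[[p]])
    }
    cum <- t(apply(x$probs, 1L, cumsum))
    u <- stats::runif(n)
    st <- rowSums(u > cum[row, , drop = FALSE])  # 0-based state index
    st <- pmin(st, length(x$states) - 1L)
    idx[[nd]] <- st
    out[[nd]] <- x$states[st + 1L]
  }
  as.data.frame(out[node_names(net)], stringsAsFactors = FALSE)
}

sample_one <- function(values) values[sample.int(length(values), 1L)]

# a random study consistent with the design targeting rules
random_study <- function(id) {
  design <- sample_one(c("rct", "cohort", "case_control"))
  targets <- switch(design,
    rct = if (stats::runif(1) < 0.5) "Delta" else c("Delta", "T"),
    cohort = c(sample_one(SIGMA_INDICATORS), "T"),
    case_control = sample_one(SIGMA_INDICATORS))
  mods <- modulator_vector(
    A = sample_one(c(0, 0.5, 1)), SS = sample_one(c(0, 0.5, 1)),
    D = sample_one(c(0, 0.5, 1)), B = sample_one(c(0, 0.5, 1)),
    R = sample_one(c(0, 0.5, 1)), Pl = sample_one(c(0, 0.5, 1)),
    SB = sample_one(c(0, 1)))
  study_record(id, design = design, targets = targets, modulators = mods,
               outcome = 1)
}

random_mechanism <- function(id, max_links = 3L) {
  n_links <- sample.int(max_links, 1L)
  links <- lapply(seq_len(n_links), function(k)
    link_spec(sprintf("%s_link%d", id, k),
              background = sample_one(c(0.5, 0.5, 0.25, 0.75))))
  reports <- list()
  for (k in seq_len(n_links))
    if (stats::runif(1) < 0.7)
      reports[[length(reports) + 1L]] <-
        mech_report(sprintf("%s_link%d", id, k),
                    grade = sample_one(c("confident", "cautious")),
                    outcome = 1,
                    id = sprintf("Rep_%s_link%d", id, k))
  mechanism_spec(id, p_given_m = stats::runif(1, 0.3, 0.9), links = links,
                 reports = reports)
}

#' Generate a synthetic case with known ground truth
#'
#' Draws a random case specification (studies and mechanisms consistent
#' with the design targeting rules), samples one full assignment from
#' its generative network — the latent hypothesis and indicator states
#' and all report outcomes — and returns the specification with the
#' sampled outcomes filled in. Because the observed outcomes are drawn
#' from the model itself, posteriors computed on these cases must be
#' calibrated against the sampled ground truth; the test-suite checks
#' exactly that.
#'
#' @param seed Integer seed; the same seed reproduces the same case.
#' @param n_studies,n_mechanisms Counts of evidence items to draw
#'   (either may be 0).
#' @param prior Hypothesis prior used for generation and, by default,
#'   assessment.
#' @return A `synthetic_case`: list with `seed`, `spec` (outcomes filled
#'   with the sampled reports), `truth` (named character vector, the
#'   sampled full assignment) and `items` (the evidence data frame).
#' @export
generate_synthetic_case <- function(seed, n_studies = 2L,
                                    n_mechanisms = 1L, prior = 0.5) {
  stopifnot(n_studies >= 0L, n_mechanisms >= 0L)
  set.seed(seed)
  studies <- lapply(seq_len(n_studies), function(i)
    random_study(sprintf("study%d", i)))
  mechanisms <- lapply(seq_len(n_mechanisms), function(i)
    random_mechanism(sprintf("M%d", i)))
  spec <- case_spec(priors = prior, mechanisms = mechanisms,
                    studies = studies)
  items <- evidence_items(spec)
  if (!nrow(items))
    return(structure(list(seed = seed, spec = spec,
                          truth = character(0), items = items),
                     class = "synthetic_case"))
  net <- build_case_network(spec)
  draw <- forward_sample(net, 1L)
  truth <- vapply(names(draw), function(n) draw[[n]][1L], "")
  # write the sampled report outcomes back into the spec
  spec$studies <- lapply(spec$studies, function(s) {
    s$outcome <- as.integer(truth[[report_node_name(s)]] == "true")
    s
  })
  spec$mechanisms <- lapply(spec$mechanisms, function(m) {
    m$reports <- lapply(m$reports, function(r) {
      r$outcome <- as.integer(truth[[r$id]] == "true")
      r
    })
    m
  })
  items <- evidence_items(spec)
  structure(list(seed = seed, spec = spec, truth = truth, items = items),
            class = "synthetic_case")
}
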