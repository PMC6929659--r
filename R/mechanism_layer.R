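# Mechanism sub-networks: alternative mechanism hypotheses under the
# existential mechanism node M, ordered sub-mechanism chains with
# logical-consistency CPT rules, and Bayes-factor graded basic-science
# reports.

#' One link of a sub-mechanism chain
#'
#' `background` is the probability that the link holds when the parent
#' mechanism fails and the chain's earlier links are not all
#' established: 1 for links taken as established regardless of the
#' mechanism (e.g. a known metabolic step), 0.5 for indifference (the
#' default), or any elicited value in `[0, 1]`.
#'
#' @param id Unique link identifier.
#' @param background Probability in `[0, 1]`, default 0.5.
#' @param shared Optional id of a link of a previously declared
#'   mechanism that this chain re-uses instead of introducing a new
#'   node.
#' @return A `link_spec` object.
#' @export
link_spec <- function(id, background = 0.5, shared = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (background < 0 || background > 1)
    stop("link background must lie in [0,1]", call. = FALSE)
  structure(list(id = id, background = as.numeric(background),
                 shared = shared),
            class = "link_spec")
}

#' A basic-science report on a sub-mechanism link
#'
#' The likelihood pair `P(report positive | link)` /
#' `P(report positive | no link)` encodes the strength of the finding as
#' a Bayes factor: `"confident"` claims get `0.91/0.09` (factor about
#' 10), `"cautious"` claims `0.75/0.25` (factor 3); `"custom"` takes an
#' explicit pair with the first element exceeding the second.
#'
#' @param link Id of the reported link.
#' @param grade `"confident"`, `"cautious"` or `"custom"`.
#' @param outcome 1 for a positive finding, 0 for a negative one.
#' @param id Optional report node name; defaults to `Rep_<link>` with a
#'   numeric suffix when several reports share a link.
#' @param likelihoods Length-2 numeric, required for `grade = "custom"`.
#' @return A `mech_report` object.
#' @export
mech_report <- function(link, grade = c("confident", "cautious", "custom"),
                        outcome = 1, id = NULL, likelihoods = NULL) {
  grade <- match.arg(grade)
  lk <- switch(grade,
               confident = c(0.91, 0.09),
               cautious = c(0.75, 0.25),
               custom = as.numeric(likelihoods))
  if (length(lk) != 2L || any(is.na(lk)) || any(lk <= 0) || any(lk >= 1))
    stop("report likelihoods must be a pair in (0,1)", call. = FALSE)
  if (lk[1L] <= lk[2L])
    stop("uninformative report: P(rep|link) must exceed P(rep|no link)",
         call. = FALSE)
  if (!outcome %in% c(0, 1))
    stop("outcome must be 0 or 1", call. = FALSE)
  structure(list(link = link, grade = grade, likelihoods = lk,
                 outcome = as.integer(outcome), id = id),
            class = "mech_report")
}

#' A candidate mechanism hypothesis
#'
#' A mechanism `M_i` is a specific pathway from drug to adverse effect,
#' decomposed into an ordered chain of sub-mechanism links. `p_given_m`
#' is the probability of this pathway conditional on some mechanism
#' existing; `P(M_i | no mechanism)` is fixed at 0 (if no mechanism
#' exists, every specific one fails).
#'
#' @param id Unique mechanism identifier.
#' @param p_given_m `P(M_i | M)` in `[0, 1]`.
#' @param links List of [link_spec()] objects, in chain order.
#' @param reports Optional list of [mech_report()] objects on this
#'   chain's links.
#' @return A `mechanism_spec` object.
#' @export
mechanism_spec <- function(id, p_given_m, links, reports = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (p_given_m < 0 || p_given_m > 1)
    stop("p_given_m must lie in [0,1]", call. = FALSE)
  if (inherits(links, "link_spec")) links <- list(links)
  stopifnot(length(links) >= 1L,
            all(vapply(links, inherits, TRUE, "link_spec")))
  if (inherits(reports, "mech_report")) reports <- list(reports)
  stopifnot(all(vapply(reports, inherits, TRUE, "mech_report")))
  structure(list(id = id, p_given_m = as.numeric(p_given_m),
                 links = links, reports = reports),
            class = "mechanism_spec")
}

# P(link true | row) for a link with mechanism parents `n_mech`, earlier
# links `n_earlier`, in canonical order (mechanism parents first and
# varying fastest). Rules: any parent mechanism true -> 1; all
# mechanisms false, a final link of a multi-link chain, and all earlier
# links true -> 0 (the full chain being true entails the mechanism);
# otherwise the link's background. A single-link chain keeps its
# background row (the first-link rule), so only chains with earlier
# links carry the inconsistency zero.
link_p_true_rows <- function(n_mech, n_earlier, final, background) {
  g <- expand.grid(rep(list(c(FALSE, TRUE)), n_mech + n_earlier),
                   KEEP.OUT.ATTRS = FALSE)
  apply(g, 1L, function(row) {
    mech <- row[seq_len(n_mech)]
    earlier <- row[n_mech + seq_len(n_earlier)]
    if (any(mech)) 1
    else if (final && n_earlier > 0L && all(earlier)) 0
    else background
  })
}

#' Chain CPTs for one mechanism
#'
#' Implements the three chain rules: the mechanism entails each of its
#' links (`P(link | M_i, ...) = 1`); the final link is logically
#' inconsistent with the mechanism failing while all earlier links hold
#' (`P(last link | not M_i, earlier links true) = 0`); all remaining
#' rows under `not M_i` take the link's background probability.
#'
#' @param spec A [mechanism_spec()].
#' @return List of [cpt()] objects, one per (non-shared) link, with
#'   parents `M_i` plus all earlier links of the chain.
#' @export
chain_cpts <- function(spec) {
  stopifnot(inherits(spec, "mechanism_spec"))
  K <- length(spec$links)
  out <- list()
  ids <- vapply(spec$links, `[[`, "", "id")
  for (k in seq_len(K)) {
    lk <- spec$links[[k]]
    if (!is.null(lk$shared)) next
    parents <- c(spec$id, ids[seq_len(k - 1L)])
    out[[lk$id]] <- binary_cpt(
      lk$id, parents,
      p_true = link_p_true_rows(1L, k - 1L, final = (k == K),
                                background = lk$background))
  }
  out
}

#' Build the mechanism sub-network
#'
#' Adds, under the existential mechanism node `M`, one node per
#' mechanism hypothesis (`P(M_i | M) = p_given_m`, `P(M_i | not M) =
#' 0`), the sub-mechanism chain nodes with [chain_cpts()] semantics,
#' and re-uses shared links across chains (a shared link holds with
#' probability 1 as soon as any of its parent mechanisms holds;
#' otherwise its home chain's rules apply). Reports carried by the
#' specs are attached via [attach_mech_report()].
#'
#' @param net A `causal_network` containing node `M`.
#' @param specs List of [mechanism_spec()] objects.
#' @param attach_reports Attach the specs' reports too (default TRUE).
#' @return The updated network.
#' @export
build_mechanism_subnet <- function(net, specs, attach_reports = TRUE) {
  stopifnot(inherits(net, "causal_network"))
  if (inherits(specs, "mechanism_spec")) specs <- list(specs)
  if (!length(specs)) return(net)
  stopifnot(all(vapply(specs, inherits, TRUE, "mechanism_spec")))
  if (!"M" %in% node_names(net))
    stop("missing node 'M': build the causal layer first", call. = FALSE)
  # registry: for each concrete link node, its home chain data and the
  # set of mechanisms that share it
  registry <- list()
  for (spec in specs) {
    net <- add_variable(net, discrete_variable(spec$id), "mechanism")
    net <- attach_cpt(net, binary_cpt(spec$id, "M",
                                      p_true = c(0, spec$p_given_m)))
    ids <- character(0)
    K <- length(spec$links)
    for (k in seq_len(K)) {
      lk <- spec$links[[k]]
      if (!is.null(lk$shared)) {
        if (is.null(registry[[lk$shared]]))
          stop(sprintf("missing link '%s'", lk$shared), call. = FALSE)
        registry[[lk$shared]]$mechs <-
          c(registry[[lk$shared]]$mechs, spec$id)
        ids <- c(ids, lk$shared)
      } else {
        if (!is.null(registry[[lk$id]]) || lk$id %in% node_names(net))
          stop(sprintf("duplicate link '%s'", lk$id), call. = FALSE)
        registry[[lk$id]] <- list(mechs = spec$id, earlier = ids,
                                  final = (k == K),
                                  background = lk$background)
        ids <- c(ids, lk$id)
        net <- add_variable(net, discrete_variable(lk$id), "sub-mechanism")
      }
    }
  }
  for (id in names(registry)) {
    r <- registry[[id]]
    net <- attach_cpt(net, binary_cpt(
      id, c(r$mechs, r$earlier),
      p_true = link_p_true_rows(length(r$mechs), length(r$earlier),
                                final = r$final,
                                background = r$background)))
  }
  if (attach_reports)
    for (spec in specs)
      for (rep in spec$reports)
        net <- attach_mech_report(net, rep)
  net
}

#' Attach a basic-science report to a sub-mechanism link
#'
#' Adds a binary report node with the link as its single parent and the
#' report's Bayes-factor likelihood pair as its CPT. A link may carry
#' any number of reports (replications in other species or cell
#' cultures).
#'
#' @param net A `causal_network` containing the link node.
#' @param report A [mech_report()].
#' @return The updated network.
#' @export
attach_mech_report <- function(net, report) {
  stopifnot(inherits(net, "causal_network"), inherits(report, "mech_report"))
  if (!report$link %in% node_names(net))
    stop(sprintf("missing link '%s'", report$link), call. = FALSE)
  name <- report$id
  if (is.null(name)) {
    name <- paste0("Rep_", report$link)
    k <- 1L
    while (name %in% node_names(net)) {
      k <- k + 1L
      name <- paste0("Rep_", report$link, "_", k)
    }
  }
  net <- add_variable(net, discrete_variable(name), "report")
  attach_cpt(net, binary_cpt(name, report$link,
                             p_true = c(report$likelihoods[2L],
                                        report$likelihoods[1L])))
}
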