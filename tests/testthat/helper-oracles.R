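# Independent oracles and generators shared across the test files.

# Depth-first topological sort (three-colour DFS), independent of the
# package's Kahn implementation; returns NULL when a cycle exists.
helper_toposort <- function(parents_of) {
  nodes <- names(parents_of)
  colour <- stats::setNames(rep(0L, length(nodes)), nodes)
  order_out <- character(0)
  ok <- TRUE
  visit <- function(v) {
    if (!ok || colour[[v]] == 2L) return(invisible(NULL))
    if (colour[[v]] == 1L) {
      ok <<- FALSE
      return(invisible(NULL))
    }
    colour[[v]] <<- 1L
    for (p in intersect(parents_of[[v]], nodes)) visit(p)
    colour[[v]] <<- 2L
    order_out <<- c(order_out, v)
    invisible(NULL)
  }
  for (v in nodes) visit(v)
  if (ok) order_out else NULL
}

# Hand-rolled chain-rule product: finds each CPT row by filtering an
# expand.grid of parent states, independent of the package's stride
# arithmetic.
helper_joint <- function(net, assignment) {
  p <- 1
  for (nm in names(net$variables)) {
    x <- net$cpts[[nm]]
    row <- 1L
    if (length(x$parents)) {
      g <- expand.grid(x$parent_states, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
      names(g) <- x$parents
      hit <- rep(TRUE, nrow(g))
      for (pp in x$parents) hit <- hit & g[[pp]] == assignment[[pp]]
      row <- which(hit)
    }
    p <- p * unname(x$probs[row, match(assignment[[nm]], x$states)])
  }
  p
}

# Exhaustive-loop posterior built on helper_joint; only for tiny nets.
helper_enum_posterior <- function(net, evidence, target, state = "true") {
  nodes <- names(net$variables)
  grid <- expand.grid(lapply(nodes, function(n) net$variables[[n]]$states),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- nodes
  num <- den <- 0
  for (i in seq_len(nrow(grid))) {
    a <- stats::setNames(as.character(grid[i, ]), nodes)
    if (length(evidence) &&
        !all(a[names(evidence)] == unlist(evidence))) next
    p <- helper_joint(net, a)
    den <- den + p
    if (a[[target]] == state) num <- num + p
  }
  unname(num / den)
}

# Random all-binary network with node 1 the hypothesis root and edges
# only from earlier to later nodes (acyclic by construction).
random_binary_network <- function(n_nodes, p_edge = 0.4, max_parents = 3L) {
  nms <- c("C", if (n_nodes > 1L) paste0("X", seq_len(n_nodes - 1L)))
  net <- causal_network()
  net <- add_variable(net, discrete_variable("C"), "hypothesis")
  for (nm in nms[-1L])
    net <- add_variable(net, discrete_variable(nm), "report")
  for (i in seq_along(nms)) {
    pars <- character(0)
    if (i > 1L) {
      pars <- nms[seq_len(i - 1L)][stats::runif(i - 1L) < p_edge]
      if (length(pars) > max_parents) pars <- sample(pars, max_parents)
    }
    net <- attach_cpt(net, binary_cpt(nms[i], pars,
                                      p_true = stats::runif(2^length(pars))))
  }
  net
}

# Causal layer plus random mechanism chains carrying all-positive
# reports; returns the network and the report node names.
random_mechanism_network <- function(prior = 0.3, n_mech = 2L,
                                     max_links = 3L, m_given_not_c = 0.5) {
  specs <- lapply(seq_len(n_mech), function(i) {
    n_links <- sample.int(max_links, 1L)
    links <- lapply(seq_len(n_links), function(k)
      link_spec(sprintf("m%d_l%d", i, k),
                background = sample(c(0.01, 0.25, 0.5, 0.75, 1), 1L)))
    reports <- lapply(seq_len(n_links), function(k)
      mech_report(sprintf("m%d_l%d", i, k),
                  grade = sample(c("confident", "cautious"), 1L),
                  outcome = 1,
                  id = sprintf("rep_m%d_l%d", i, k)))
    mechanism_spec(sprintf("M%d", i),
                   p_given_m = stats::runif(1, 0.2, 0.95),
                   links = links, reports = reports)
  })
  net <- build_causal_layer(causal_layer_config(
    prior_c = prior, m_given_not_c = m_given_not_c))
  net <- build_mechanism_subnet(net, specs)
  reports <- names(net$tags)[net$tags == "report"]
  list(net = net, reports = reports)
}

# P(child = true) for one named parent combination, located through an
# expand.grid filter rather than the package's row indexing.
helper_p_true <- function(x, ...) {
  combo <- list(...)
  g <- expand.grid(x$parent_states, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  names(g) <- x$parents
  hit <- rep(TRUE, nrow(g))
  for (p in names(combo)) hit <- hit & g[[p]] == combo[[p]]
  stopifnot(sum(hit) == 1L)
  unname(x$probs[which(hit), "true"])
}

fixture_path <- function() {
  system.file("extdata", "paracetamol_asthma.yaml", package = "adrbayes")
}
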