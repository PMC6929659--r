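#' @keywords internal
"_PACKAGE"

NODE_TAGS <- c("hypothesis", "indicator", "mechanism", "sub-mechanism",
               "report", "modulator")

#' Define a discrete network variable
#'
#' All causal, indicator, mechanism and report variables in an evidence
#' network are binary with states ordered `c("false", "true")`; explicit
#' modulator nodes (e.g. a shared sponsorship-bias variable) may take any
#' finite ordered state set.
#'
#' @param name Unique, non-empty node name.
#' @param states Character vector of at least two unique state labels,
#'   defaulting to `c("false", "true")`.
#' @return An object of class `discrete_variable`.
#' @examples
#' discrete_variable("C")
#' discrete_variable("SB_group1", states = c("0", "1"))
#' @export
discrete_variable <- function(name, states = c("false", "true")) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("variable name must be a non-empty string", call. = FALSE)
  states <- as.character(states)
  if (length(states) < 2L || anyDuplicated(states) || any(!nzchar(states)))
    stop("states must be >= 2 unique non-empty labels", call. = FALSE)
  structure(list(name = name, states = states), class = "discrete_variable")
}

#' Construct a conditional probability table
#'
#' Rows are indexed by the full parent-state combinations in canonical
#' order (first parent varying fastest, as in [expand.grid()]); columns by
#' the child states. Each row must sum to 1 within `1e-12`.
#'
#' @param child Name of the child node.
#' @param parents Character vector of parent node names (may be empty for
#'   a root prior).
#' @param states Child state labels, default binary.
#' @param parent_states Named list giving the state labels of each parent;
#'   binary `c("false", "true")` is assumed for parents not listed.
#' @param probs Numeric matrix, `n_combos x n_states`, or for a root node
#'   a single probability row.
#' @return An object of class `cpt`.
#' @seealso [binary_cpt()] for the common all-binary case.
#' @examples
#' cpt("C", probs = matrix(c(0.99, 0.01), 1))
#' @export
cpt <- function(child, parents = character(), probs,
                states = c("false", "true"), parent_states = list()) {
  stopifnot(is.character(child), length(child) == 1L)
  parents <- as.character(parents)
  if (anyDuplicated(parents))
    stop("duplicate parent names", call. = FALSE)
  states <- as.character(states)
  pstates <- lapply(parents, function(p) {
    s <- parent_states[[p]]
    if (is.null(s)) c("false", "true") else as.character(s)
  })
  names(pstates) <- parents
  n_comb <- prod(vapply(pstates, length, 1L))
  probs <- as.matrix(probs)
  if (nrow(probs) != n_comb || ncol(probs) != length(states))
    stop(sprintf("probs must be %d x %d for child '%s'", n_comb,
                 length(states), child), call. = FALSE)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0,1]", call. = FALSE)
  bad <- which(abs(rowSums(probs) - 1) > 1e-12)
  if (length(bad))
    stop(sprintf("unnormalized row for parent combination '%s' of '%s' (sum %.15g)",
                 cpt_row_label(parents, pstates, bad[1L]), child,
                 rowSums(probs)[bad[1L]]), call. = FALSE)
  dimnames(probs) <- list(NULL, states)
  structure(list(child = child, parents = parents, parent_states = pstates,
                 states = states, probs = probs),
            class = "cpt")
}

#' Binary conditional probability table from P(child = true) values
#'
#' @param child Child node name.
#' @param parents Parent node names (all binary).
#' @param p_true Numeric vector of `P(child = true)` per parent-state
#'   combination, canonical order (first parent varying fastest); length
#'   `2^length(parents)`.
#' @return A `cpt` object.
#' @examples
#' # P(Delta | C): rows C=false, C=true
#' binary_cpt("Delta", "C", p_true = c(0, 1))
#' @export
binary_cpt <- function(child, parents = character(), p_true) {
  p_true <- as.numeric(p_true)
  cpt(child, parents, probs = cbind(1 - p_true, p_true))
}

# canonical row index for a parent-state combination; states given as a
# named character vector. First parent varies fastest.
cpt_row_index <- function(x, states) {
  if (!length(x$parents)) return(1L)
  idx <- 1L
  stride <- 1L
  for (p in x$parents) {
    s <- match(states[[p]], x$parent_states[[p]])
    if (is.na(s))
      stop(sprintf("unknown state '%s' for parent '%s'", states[[p]], p),
           call. = FALSE)
    idx <- idx + (s - 1L) * stride
    stride <- stride * length(x$parent_states[[p]])
  }
  idx
}

cpt_row_label <- function(parents, pstates, row) {
  if (!length(parents)) return("(root)")
  row <- row - 1L
  lab <- character(length(parents))
  for (k in seq_along(parents)) {
    n <- length(pstates[[k]])
    lab[k] <- paste0(parents[k], "=", pstates[[k]][row %% n + 1L])
    row <- row %/% n
  }
  paste(lab, collapse = ",")
}

# data.frame of parent-state combinations in canonical row order
cpt_parent_grid <- function(x) {
  if (!length(x$parents)) return(data.frame(row.names = 1L))
  g <- expand.grid(x$parent_states, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  names(g) <- x$parents
  g
}

#' Create an empty evidence network
#'
#' A `causal_network` holds discrete variables, one conditional
#' probability table per variable, and a role tag per node (one of
#' `"hypothesis"`, `"indicator"`, `"mechanism"`, `"sub-mechanism"`,
#' `"report"`, `"modulator"`). Networks are immutable by contract: every
#' modifying operation returns a new network and leaves its input intact.
#'
#' @return An empty `causal_network`.
#' @export
causal_network <- function() {
  structure(list(variables = list(), tags = character(0), cpts = list()),
            class = "causal_network")
}

#' Add a variable to a network
#'
#' @param net A `causal_network`.
#' @param var A [discrete_variable()].
#' @param tag Node role, one of `"hypothesis"`, `"indicator"`,
#'   `"mechanism"`, `"sub-mechanism"`, `"report"`, `"modulator"`.
#' @return The updated network (the input is not modified).
#' @export
add_variable <- function(net, var, tag) {
  stopifnot(inherits(net, "causal_network"), inherits(var, "discrete_variable"))
  tag <- match.arg(tag, NODE_TAGS)
  if (var$name %in% names(net$variables))
    stop(sprintf("duplicate variable '%s'", var$name), call. = FALSE)
  if (tag == "hypothesis" && "hypothesis" %in% net$tags)
    stop("network already has a hypothesis node", call. = FALSE)
  net$variables[[var$name]] <- var
  net$tags[[var$name]] <- tag
  net
}

node_names <- function(net) names(net$variables)

node_states <- function(net, name) net$variables[[name]]$states

node_parents <- function(net, name) {
  x <- net$cpts[[name]]
  if (is.null(x)) character(0) else x$parents
}

nodes_with_tag <- function(net, tag) names(net$tags)[net$tags == tag]

hypothesis_node <- function(net) {
  h <- nodes_with_tag(net, "hypothesis")
  if (length(h) != 1L)
    stop("network must have exactly one hypothesis node", call. = FALSE)
  h
}

# Kahn's algorithm on the parent lists; NULL if a directed cycle exists.
topological_order <- function(parents_of) {
  nodes <- names(parents_of)
  indeg <- vapply(parents_of, function(p) sum(p %in% nodes), 1L)
  children <- lapply(nodes, function(n)
    nodes[vapply(parents_of, function(p) n %in% p, TRUE)])
  names(children) <- nodes
  queue <- nodes[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

net_parent_lists <- function(net) {
  out <- lapply(node_names(net), function(n) node_parents(net, n))
  names(out) <- node_names(net)
  out
}

#' Attach a conditional probability table to a network
#'
#' Replaces any previous table for the same child. The child and all
#' parents must already be in the network, rows must be normalised, and
#' the new parent list must not introduce a directed cycle.
#'
#' @param net A `causal_network`.
#' @param x A [cpt()].
#' @return The updated network.
#' @export
attach_cpt <- function(net, x) {
  stopifnot(inherits(net, "causal_network"), inherits(x, "cpt"))
  for (n in c(x$child, x$parents))
    if (!n %in% node_names(net))
      stop(sprintf("missing node '%s'", n), call. = FALSE)
  if (!identical(x$states, node_states(net, x$child)))
    stop(sprintf("CPT states do not match states of '%s'", x$child),
         call. = FALSE)
  for (p in x$parents)
    if (!identical(x$parent_states[[p]], node_states(net, p)))
      stop(sprintf("CPT parent states do not match states of '%s'", p),
           call. = FALSE)
  net$cpts[[x$child]] <- x
  if (is.null(topological_order(net_parent_lists(net))))
    stop(sprintf("cycle introduced by CPT for '%s'", x$child), call. = FALSE)
  net
}

#' Validate a network
#'
#' Returns diagnostics rather than throwing: an empty character vector
#' means every variable has a CPT, the graph is acyclic, all rows are
#' normalised and the hypothesis node is a root.
#'
#' @param net A `causal_network`.
#' @return Character vector of diagnostic messages (empty if valid).
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "causal_network"))
  out <- character(0)
  h <- nodes_with_tag(net, "hypothesis")
  if (length(h) != 1L)
    out <- c(out, sprintf("expected exactly one hypothesis node, found %d",
                          length(h)))
  for (n in node_names(net)) {
    x <- net$cpts[[n]]
    if (is.null(x)) {
      out <- c(out, sprintf("no CPT: %s", n))
      next
    }
    bad <- which(abs(rowSums(x$probs) - 1) > 1e-12)
    if (length(bad))
      out <- c(out, sprintf("unnormalized row in CPT of %s", n))
  }
  if (is.null(topological_order(net_parent_lists(net))))
    out <- c(out, "cycle in network graph")
  if (length(h) == 1L && length(node_parents(net, h)) > 0L)
    out <- c(out, "hypothesis not a root")
  out
}

assert_valid <- function(net) {
  d <- validate_network(net)
  if (length(d))
    stop(paste0("invalid network: ", paste(d, collapse = "; ")), call. = FALSE)
  invisible(net)
}

#' Joint probability of a full assignment
#'
#' Chain-rule product over all nodes of the CPT entry for the node's
#' state given its parents' states.
#'
#' @param net A valid `causal_network`.
#' @param assignment Named character vector mapping every node to a state.
#' @return A probability in `[0, 1]`.
#' @export
joint_probability <- function(net, assignment) {
  assert_valid(net)
  miss <- setdiff(node_names(net), names(assignment))
  if (length(miss))
    stop(sprintf("incomplete assignment: missing %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  p <- 1
  for (n in node_names(net)) {
    x <- net$cpts[[n]]
    s <- match(assignment[[n]], x$states)
    if (is.na(s))
      stop(sprintf("unknown state '%s' for node '%s'", assignment[[n]], n),
           call. = FALSE)
    p <- p * unname(x$probs[cpt_row_index(x, assignment), s])
    if (p == 0) return(0)
  }
  p
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf("<causal_network> %d nodes\n", length(x$variables)))
  if (length(x$variables)) {
    tg <- table(factor(x$tags, levels = NODE_TAGS))
    tg <- tg[tg > 0]
    cat("  roles:", paste(sprintf("%s=%d", names(tg), tg), collapse = ", "),
        "\n")
    miss <- setdiff(node_names(x), names(x$cpts))
    if (length(miss))
      cat("  nodes without CPT:", paste(miss, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.cpt <- function(x, ...) {
  cat(sprintf("<cpt> %s | %s\n", x$child,
              if (length(x$parents)) paste(x$parents, collapse = ", ")
              else "(root)"))
  g <- cpt_parent_grid(x)
  tab <- cbind(g, as.data.frame(x$probs))
  print(tab, row.names = FALSE)
  invisible(x)
}
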