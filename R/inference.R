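# Exact inference: variable elimination over discrete factors, plus an
# independent brute-force enumeration oracle used throughout the tests.

# ---- factors ---------------------------------------------------------------

# A factor is list(vars, states (named list), values (array, dims in var
# order; scalar when vars is empty)).
new_factor <- function(vars, states, values) {
  if (length(vars)) {
    dim(values) <- vapply(states[vars], length, 1L)
  }
  list(vars = vars, states = states, values = values)
}

factor_from_cpt <- function(x) {
  lens <- c(vapply(x$parent_states, length, 1L), length(x$states))
  states <- c(x$parent_states, stats::setNames(list(x$states), x$child))
  # canonical CPT row order (first parent fastest) is column-major over
  # (parents..., child)
  new_factor(c(x$parents, x$child), states,
             array(as.vector(x$probs), dim = lens))
}

factor_reduce <- function(f, var, state) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  s <- match(state, f$states[[var]])
  if (is.na(s))
    stop(sprintf("unknown state '%s' for node '%s'", state, var), call. = FALSE)
  idx <- rep(list(quote(expr = )), length(f$vars))
  idx[[i]] <- s
  v <- do.call(`[`, c(list(f$values), idx, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), i)
  vars <- f$vars[keep]
  if (length(vars)) dim(v) <- dim(f$values)[keep] else v <- as.vector(v)
  new_factor(vars, f$states[vars], v)
}

expand_factor_to <- function(f, vars, states) {
  v <- f$values
  missing <- setdiff(vars, f$vars)
  cur <- f$vars
  for (m in missing) {
    v <- outer(as.array(v), rep(1, length(states[[m]])))
    cur <- c(cur, m)
  }
  if (!length(vars)) return(as.vector(v))
  dim(v) <- vapply(states[cur], length, 1L)
  aperm(v, match(vars, cur))
}

factor_product <- function(f, g) {
  vars <- union(f$vars, g$vars)
  states <- c(f$states, g$states)[vars]
  new_factor(vars, states,
             expand_factor_to(f, vars, states) * expand_factor_to(g, vars, states))
}

factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  keep <- setdiff(seq_along(f$vars), i)
  v <- aperm(as.array(f$values), c(i, keep))
  dim(v) <- c(dim(f$values)[i], prod(dim(f$values)[keep]))
  v <- colSums(v)
  vars <- f$vars[keep]
  if (length(vars)) dim(v) <- dim(f$values)[keep]
  new_factor(vars, f$states[vars], v)
}

# min-fill elimination order over the factor interaction graph
min_fill_order <- function(factor_vars, to_eliminate) {
  adj <- list()
  all_vars <- unique(unlist(factor_vars))
  for (v in all_vars) adj[[v]] <- character(0)
  for (fv in factor_vars)
    for (v in fv)
      adj[[v]] <- union(adj[[v]], setdiff(fv, v))
  order_out <- character(0)
  remaining <- to_eliminate
  while (length(remaining)) {
    fill <- vapply(remaining, function(v) {
      nb <- intersect(adj[[v]], names(adj))
      if (length(nb) < 2L) return(0L)
      cnt <- 0L
      for (a in seq_len(length(nb) - 1L))
        for (b in (a + 1L):length(nb))
          if (!nb[b] %in% adj[[nb[a]]]) cnt <- cnt + 1L
      cnt
    }, integer(1))
    v <- remaining[which.min(fill)]
    nb <- adj[[v]]
    for (a in nb) adj[[a]] <- union(setdiff(adj[[a]], v), setdiff(nb, a))
    adj[[v]] <- NULL
    remaining <- setdiff(remaining, v)
    order_out <- c(order_out, v)
  }
  order_out
}

check_evidence_nodes <- function(net, evidence) {
  if (!length(evidence)) return(invisible(NULL))
  if (is.null(names(evidence)) || any(!nzchar(names(evidence))))
    stop("evidence must be a named character vector (node = state)",
         call. = FALSE)
  bad <- setdiff(names(evidence), node_names(net))
  if (length(bad))
    stop(sprintf("unknown evidence node '%s'", bad[1L]), call. = FALSE)
  invisible(NULL)
}

# unnormalised joint over the target after conditioning, as a named vector
ve_target_weights <- function(net, target, evidence) {
  factors <- lapply(net$cpts, factor_from_cpt)
  for (n in names(evidence))
    factors <- lapply(factors, factor_reduce, var = n, state = evidence[[n]])
  elim <- setdiff(node_names(net), c(target, names(evidence)))
  ord <- min_fill_order(lapply(factors, function(f) f$vars), elim)
  for (v in ord) {
    uses <- vapply(factors, function(f) v %in% f$vars, TRUE)
    prod_f <- Reduce(factor_product, factors[uses])
    factors <- c(factors[!uses], list(factor_marginalize(prod_f, v)))
  }
  res <- Reduce(factor_product, factors)
  w <- as.vector(res$values)
  if (length(res$vars)) {
    w <- as.vector(aperm(as.array(res$values),
                         match(target, res$vars)))
    names(w) <- res$states[[target]]
  }
  w
}

#' Exact posterior probability by variable elimination
#'
#' Computes `P(target = state | evidence)` exactly. The elimination order
#' is chosen by the min-fill heuristic; correctness does not depend on the
#' order and is cross-checked against [brute_force_posterior()] in the
#' test-suite.
#'
#' @param net A valid `causal_network`.
#' @param evidence Named character vector of observed states, e.g.
#'   `c(ES_ludwig = "false")`. May be empty.
#' @param target Query node; defaults to the hypothesis node.
#' @param state Queried state of the target, default `"true"`.
#' @return `P(target = state | evidence)`.
#' @export
posterior <- function(net, evidence = character(), target = NULL,
                      state = "true") {
  assert_valid(net)
  if (is.null(target)) target <- hypothesis_node(net)
  evidence <- unlist(evidence)
  check_evidence_nodes(net, evidence)
  if (target %in% names(evidence))
    stop("target node is observed", call. = FALSE)
  w <- ve_target_weights(net, target, evidence)
  tot <- sum(w)
  if (tot <= 0)
    stop(sprintf("impossible evidence: {%s} has probability 0",
                 paste(names(evidence), evidence, sep = "=", collapse = ", ")),
         call. = FALSE)
  s <- match(state, node_states(net, target))
  if (is.na(s))
    stop(sprintf("unknown state '%s' for node '%s'", state, target),
         call. = FALSE)
  w[[s]] / tot
}

#' Posterior by exhaustive enumeration
#'
#' Sums the chain-rule joint over every full assignment consistent with
#' the evidence. Serves as the independent oracle for [posterior()];
#' refuses joint state spaces larger than `2^22`.
#'
#' @inheritParams posterior
#' @return `P(target = state | evidence)`.
#' @export
brute_force_posterior <- function(net, evidence = character(), target = NULL,
                                  state = "true") {
  assert_valid(net)
  if (is.null(target)) target <- hypothesis_node(net)
  evidence <- unlist(evidence)
  check_evidence_nodes(net, evidence)
  nodes <- node_names(net)
  lens <- vapply(nodes, function(n) length(node_states(net, n)), 1L)
  N <- prod(lens)
  if (N > 2^22)
    stop("network too large for brute-force enumeration", call. = FALSE)
  strides <- c(1, cumprod(lens))[seq_along(nodes)]
  names(strides) <- nodes
  seq0 <- seq_len(N) - 1
  state_idx <- function(n) (seq0 %/% strides[[n]]) %% lens[[n]]
  joint <- rep(1, N)
  for (n in nodes) {
    x <- net$cpts[[n]]
    row <- rep(1, N)
    pstride <- 1
    for (p in x$parents) {
      row <- row + state_idx(p) * pstride
      pstride <- pstride * lens[[p]]
    }
    joint <- joint * x$probs[cbind(row, state_idx(n) + 1)]
  }
  for (n in names(evidence)) {
    s <- match(evidence[[n]], node_states(net, n))
    if (is.na(s))
      stop(sprintf("unknown state '%s' for node '%s'", evidence[[n]], n),
           call. = FALSE)
    joint <- joint * (state_idx(n) == s - 1)
  }
  tot <- sum(joint)
  if (tot <= 0)
    stop(sprintf("impossible evidence: {%s} has probability 0",
                 paste(names(evidence), evidence, sep = "=", collapse = ", ")),
         call. = FALSE)
  s <- match(state, node_states(net, target))
  sum(joint * (state_idx(target) == s - 1)) / tot
}

#' Replace the hypothesis prior
#'
#' @param net A `causal_network` with a hypothesis root node.
#' @param prior New `P(hypothesis = true)`, in `(0, 1)`.
#' @return The updated network.
#' @export
set_hypothesis_prior <- function(net, prior) {
  stopifnot(is.numeric(prior), length(prior) == 1L, prior > 0, prior < 1)
  h <- hypothesis_node(net)
  if (length(node_parents(net, h)))
    stop("hypothesis node is not a root", call. = FALSE)
  attach_cpt(net, binary_cpt(h, p_true = prior))
}

#' Sequential posterior trajectory
#'
#' Conditions on evidence items one at a time, in the order given, and
#' records the running posterior of the hypothesis for each configured
#' prior along with each item's likelihood-ratio contribution
#' (posterior odds after the item divided by odds before it).
#'
#' @param net A valid `causal_network`.
#' @param items Ordered evidence: a named character vector
#'   (`c(node = state, ...)`) or a data frame with columns `id`, `node`,
#'   `state`.
#' @param priors Numeric vector of hypothesis priors, each in `(0, 1)`.
#' @return A data frame of class `posterior_trajectory` with columns
#'   `step`, `item_id`, `node`, `state`, `prior`, `posterior`,
#'   `lr_contribution`. Step 0 carries the prior itself.
#' @export
trajectory <- function(net, items, priors) {
  assert_valid(net)
  stopifnot(is.numeric(priors), length(priors) >= 1L,
            all(priors > 0), all(priors < 1))
  if (is.data.frame(items)) {
    stopifnot(all(c("node", "state") %in% names(items)))
    ids <- if ("id" %in% names(items)) as.character(items$id)
           else as.character(items$node)
    nodes <- as.character(items$node)
    states <- as.character(items$state)
  } else {
    items <- unlist(items)
    ids <- names(items)
    nodes <- names(items)
    states <- as.character(items)
  }
  if (anyDuplicated(nodes))
    stop("evidence nodes must be distinct", call. = FALSE)
  h <- hypothesis_node(net)
  rows <- list()
  for (pr in priors) {
    np <- set_hypothesis_prior(net, pr)
    odds_prev <- pr / (1 - pr)
    rows[[length(rows) + 1L]] <- data.frame(
      step = 0L, item_id = "(prior)", node = h, state = NA_character_,
      prior = pr, posterior = pr, lr_contribution = NA_real_)
    for (t in seq_along(nodes)) {
      ev <- stats::setNames(states[seq_len(t)], nodes[seq_len(t)])
      post <- posterior(np, ev)
      odds <- if (post < 1) post / (1 - post) else Inf
      rows[[length(rows) + 1L]] <- data.frame(
        step = t, item_id = ids[t], node = nodes[t], state = states[t],
        prior = pr, posterior = post, lr_contribution = odds / odds_prev)
      odds_prev <- odds
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("posterior_trajectory", "data.frame")
  out
}

#' @export
print.posterior_trajectory <- function(x, digits = 4, ...) {
  cat("<posterior_trajectory>\n")
  df <- as.data.frame(x)
  df$posterior <- round(df$posterior, digits)
  df$lr_contribution <- round(df$lr_contribution, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Prior sensitivity analysis
#'
#' Recomputes the posterior of the hypothesis under a fixed evidence set
#' for each prior in `priors`.
#'
#' @inheritParams posterior
#' @param priors Numeric vector of priors, each strictly inside `(0, 1)`.
#' @return Data frame with columns `prior` and `posterior`.
#' @export
sensitivity <- function(net, evidence, priors) {
  stopifnot(is.numeric(priors), length(priors) >= 1L)
  if (any(priors <= 0 | priors >= 1))
    stop("priors must lie strictly inside (0, 1)", call. = FALSE)
  data.frame(
    prior = priors,
    posterior = vapply(priors, function(pr)
      posterior(set_hypothesis_prior(net, pr), evidence), numeric(1)))
}

#' Export a trajectory or sensitivity table
#'
#' Writes CSV (full precision plus a 4-decimal column for comparison
#' against published tables) or JSON.
#'
#' @param x A `posterior_trajectory` or sensitivity data frame.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  if ("posterior" %in% names(df))
    df$posterior_4dp <- round(df$posterior, 4)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}
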