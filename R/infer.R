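# ---- factor-table primitives for variable elimination --------------------
#
# A factor table is list(vars, vals): `vars` an ordered character scope and
# `vals` a flat numeric vector of length 2^|vars|, var i having stride
# 2^(i-1) with state code 0 = TRUE, 1 = FALSE (so index 1 is all-TRUE).

ft_new <- function(vars, vals) list(vars = vars, vals = vals)

# map every cell of a table over `vars` to its index in a sub-scope
ft_subindex <- function(vars, sub) {
  m <- length(vars)
  cells <- seq_len(2^m) - 1L
  idx <- rep(1, 2^m)
  pos <- match(sub, vars)
  for (j in seq_along(sub))
    idx <- idx + ((cells %/% 2^(pos[j] - 1)) %% 2) * 2^(j - 1)
  idx
}

ft_product <- function(f, g) {
  vars <- union(f$vars, g$vars)
  ft_new(vars, f$vals[ft_subindex(vars, f$vars)] *
           g$vals[ft_subindex(vars, g$vars)])
}

ft_sumout <- function(f, var) {
  stopifnot(var %in% f$vars)
  rest <- setdiff(f$vars, var)
  if (!length(rest))
    return(ft_new(character(), sum(f$vals)))
  idx <- ft_subindex(f$vars, rest)
  ft_new(rest, as.vector(tapply(f$vals, idx, sum)))
}

# fix var to a state (TRUE/FALSE) and drop it from the scope
ft_restrict <- function(f, var, state) {
  if (!(var %in% f$vars)) return(f)
  pos <- match(var, f$vars)
  cells <- seq_len(2^length(f$vars)) - 1L
  keep <- ((cells %/% 2^(pos - 1)) %% 2) == (if (state) 0L else 1L)
  ft_new(f$vars[-pos], f$vals[keep])
}

# CPT of `node` as a factor table over c(node, parents)
cpt_factor <- function(model, node) {
  cp <- model$cpts[[node]]
  vars <- c(node, cp$parents)
  m <- length(vars)
  cells <- seq_len(2^m) - 1L
  node_true <- (cells %% 2L) == 0L
  if (length(cp$parents)) {
    # canonical combo index from the parent state codes
    k <- length(cp$parents)
    combo <- rep(1L, 2^m)
    for (j in seq_len(k))
      combo <- combo + ((cells %/% 2^j) %% 2) * 2L^(k - j)
    p_true <- cp$p[combo]
  } else {
    p_true <- rep(cp$p, 2^m)
  }
  ft_new(vars, ifelse(node_true, p_true, 1 - p_true))
}

# greedy min-fill elimination order over the given scopes,
# deterministic tie-break by node id
min_fill_order <- function(scopes, to_eliminate) {
  adj <- list()
  for (v in unique(unlist(scopes))) adj[[v]] <- character()
  for (sc in scopes)
    for (v in sc) adj[[v]] <- union(adj[[v]], setdiff(sc, v))
  order <- character()
  remaining <- sort(to_eliminate)
  while (length(remaining)) {
    fill <- vapply(remaining, function(v) {
      nb <- intersect(adj[[v]], names(adj))
      if (length(nb) < 2) return(0L)
      prs <- utils::combn(nb, 2)
      sum(!vapply(seq_len(ncol(prs)), function(i)
        prs[2, i] %in% adj[[prs[1, i]]], logical(1)))
    }, integer(1))
    v <- remaining[which.min(fill)]  # ties: first in sorted id order
    nb <- adj[[v]]
    for (a in nb) adj[[a]] <- union(setdiff(adj[[a]], v), setdiff(nb, a))
    adj[[v]] <- NULL
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
  }
  order
}

run_elimination <- function(factors, eliminate, order = NULL) {
  if (is.null(order))
    order <- min_fill_order(lapply(factors, `[[`, "vars"), eliminate)
  for (v in order) {
    involved <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(involved)) next
    prod <- Reduce(ft_product, factors[involved])
    factors <- c(factors[!involved], list(ft_sumout(prod, v)))
  }
  Reduce(ft_product, factors)
}

# ---- public inference API ------------------------------------------------

as_evidence <- function(evidence) {
  if (is.null(evidence) || !length(evidence)) return(logical())
  ev <- unlist(evidence)
  nm <- names(ev)
  if (is.character(ev)) ev <- toupper(ev) == "TRUE"
  stopifnot(is.logical(ev) || all(ev %in% c(0, 1)))
  ev <- stats::setNames(as.logical(ev), nm)
  if (is.null(names(ev)) || anyDuplicated(names(ev)))
    stop("evidence must have unique node names", call. = FALSE)
  ev
}

#' Joint probability of a complete assignment
#'
#' Evaluates the Bayesian-network factorization: the product over nodes of
#' the CPT entry for the node's state given its parents' states.
#'
#' @param model An `ffh_bn`.
#' @param assignment Named logical (or 0/1) vector covering every node.
#' @return A probability.
#' @export
joint_probability <- function(model, assignment) {
  a <- as_evidence(assignment)
  if (!setequal(names(a), model$graph$nodes))
    stop("assignment must cover exactly the model's nodes", call. = FALSE)
  p <- 1
  for (v in model$graph$nodes) {
    cp <- model$cpts[[v]]
    r <- if (length(cp$parents))
      combo_index(matrix(as.integer(a[cp$parents]), nrow = 1)) else 1L
    pv <- cp$p[r]
    p <- p * if (a[[v]]) pv else 1 - pv
  }
  unname(p)
}

#' Exact posterior probability by variable elimination
#'
#' Computes `P(query = TRUE | evidence)` exactly: evidence is absorbed
#' into the CPT factor tables, all other variables are summed out in
#' greedy min-fill order, and the result is normalized. Supports both
#' predictive queries (evidence on causes, query on the outcome) and
#' diagnostic queries (evidence on the outcome, query on causes).
#'
#' @param model An `ffh_bn`.
#' @param query A node id not among the evidence.
#' @param evidence Named logical (or 0/1, or "TRUE"/"FALSE") vector of
#'   observed nodes; may be empty.
#' @param order Optional explicit elimination order (node ids); defaults
#'   to min-fill.
#' @return A list of class `posterior_result` with `query`, `p_true` and
#'   the echoed `evidence`.
#' @export
posterior <- function(model, query, evidence = NULL, order = NULL) {
  ev <- as_evidence(evidence)
  unknown <- setdiff(c(query, names(ev)), model$graph$nodes)
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (query %in% names(ev))
    stop("query node must not be part of the evidence", call. = FALSE)
  factors <- lapply(model$graph$nodes, function(v) cpt_factor(model, v))
  for (v in names(ev))
    factors <- lapply(factors, ft_restrict, var = v, state = ev[[v]])
  eliminate <- setdiff(model$graph$nodes, c(query, names(ev)))
  if (!is.null(order)) order <- intersect(order, eliminate)
  res <- run_elimination(factors, eliminate, order)
  stopifnot(identical(res$vars, query) || !length(res$vars))
  z <- sum(res$vals)
  if (!is.finite(z) || z <= 0)
    stop("evidence has zero probability under the model", call. = FALSE)
  structure(list(query = query, p_true = res$vals[1] / z,
                 evidence = ev),
            class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, ...) {
  ev <- if (length(x$evidence))
    paste(names(x$evidence), "=", x$evidence, collapse = ", ") else "(none)"
  cat(sprintf("P(%s = TRUE | %s) = %.6f\n", x$query, ev, x$p_true))
  invisible(x)
}

#' Marginal probability of every node
#'
#' @param model An `ffh_bn`.
#' @return Named numeric vector of `P(node = TRUE)` with empty evidence.
#' @export
marginal_all <- function(model) {
  vapply(model$graph$nodes, function(v)
    posterior(model, v)$p_true, numeric(1))
}

#' Diagnostic probabilities given the accident outcome
#'
#' Backward reasoning: for every non-outcome node, the posterior
#' probability that the risk factor was present given that the outcome
#' occurred, `P(node = TRUE | outcome = TRUE)`.
#'
#' @param model An `ffh_bn`.
#' @param outcome Outcome node id (default: the model's outcome).
#' @return Named numeric vector over the non-outcome nodes.
#' @export
diagnostic_probabilities <- function(model, outcome = model$outcome) {
  stopifnot(outcome %in% model$graph$nodes)
  ev <- stats::setNames(TRUE, outcome)
  nodes <- setdiff(model$graph$nodes, outcome)
  vapply(nodes, function(v) posterior(model, v, ev)$p_true, numeric(1))
}
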