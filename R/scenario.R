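#' Enumerate all risk scenarios for the outcome node
#'
#' A risk scenario is one complete TRUE/FALSE assignment of the outcome's
#' parents; the table lists all `2^k` of them with the exact
#' `P(outcome = TRUE | scenario)`. Because the outcome is d-separated from
#' everything else given its parents, each probability equals the matching
#' CPT row.
#'
#' @param model An `ffh_bn` whose outcome has at least one parent.
#' @param outcome Outcome node id (default: the model's outcome).
#' @param parent_order Optional explicit column order for the parents
#'   (default: the CPT's canonical parent order). With the reference FFH
#'   topology, pass `ffh_scenario_parents()` to mirror the published
#'   column layout A2, D1, C3, E1, E2, E3, C1.
#' @return A `scenario_table`: a data frame with one logical column per
#'   parent (leftmost most significant, TRUE enumerated first) and a
#'   `p_outcome` column.
#' @export
enumerate_scenarios <- function(model, outcome = model$outcome,
                                parent_order = NULL) {
  stopifnot(outcome %in% model$graph$nodes)
  pa <- model$cpts[[outcome]]$parents
  if (!length(pa))
    stop("outcome node has no parents; no scenarios to enumerate",
         call. = FALSE)
  if (is.null(parent_order)) parent_order <- pa
  if (!setequal(parent_order, pa))
    stop("parent_order must be a permutation of the outcome's parents",
         call. = FALSE)
  combos <- parent_combos(parent_order)
  # conditioning on all parents d-separates the outcome from the rest of
  # the network, so P(outcome | scenario) is exactly the CPT entry
  cp <- model$cpts[[outcome]]
  p <- vapply(seq_len(nrow(combos)), function(r) {
    states <- matrix(as.integer(combos[r, match(cp$parents, parent_order)]),
                     nrow = 1)
    cp$p[combo_index(states)]
  }, numeric(1))
  out <- data.frame(combos, p_outcome = p, check.names = FALSE)
  structure(out, outcome = outcome, parent_order = parent_order,
            class = c("scenario_table", "data.frame"))
}

#' Published scenario column order for the FFH network
#'
#' @return The outcome-parent ids in the published table layout.
#' @export
ffh_scenario_parents <- function() {
  c("A2", "D1", "C3", "E1", "E2", "E3", "C1")
}

#' Highest-probability risk scenarios
#'
#' @param table A `scenario_table`.
#' @param n Number of scenarios to return, in `[1, nrow(table)]`.
#' @return The `n` rows with the highest `p_outcome`; ties broken by
#'   canonical enumeration order (so the result is deterministic).
#' @export
top_scenarios <- function(table, n) {
  if (length(n) != 1 || n < 1 || n > nrow(table))
    stop("n must lie in [1, ", nrow(table), "]", call. = FALSE)
  ord <- order(-table$p_outcome, seq_len(nrow(table)))
  table[ord[seq_len(n)], , drop = FALSE]
}

#' @export
print.scenario_table <- function(x, digits = 2, ...) {
  cat("Risk scenarios for", attr(x, "outcome"), "-", nrow(x), "rows\n")
  df <- as.data.frame(x)
  df$p_outcome <- sprintf(paste0("%.", digits, "f%%"), 100 * df$p_outcome)
  print(df, ...)
  invisible(x)
}

#' Rank risk factors by marginal and diagnostic probability
#'
#' Forward and backward influence summary: every non-outcome node with its
#' unconditional marginal `P(node = TRUE)` and its diagnostic posterior
#' `P(node = TRUE | outcome = TRUE)`, sorted by marginal descending (ties
#' by node id).
#'
#' @param model An `ffh_bn`.
#' @param outcome Outcome node id (default: the model's outcome).
#' @return A data frame with columns `node`, `marginal`, `diagnostic`.
#' @export
rank_risk_factors <- function(model, outcome = model$outcome) {
  marg <- marginal_all(model)
  marg <- marg[setdiff(names(marg), outcome)]
  diag <- if (outcome %in% model$graph$nodes)
    diagnostic_probabilities(model, outcome) else marg
  out <- data.frame(node = names(marg), marginal = unname(marg),
                    diagnostic = unname(diag[names(marg)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$marginal, out$node), ]
  rownames(out) <- NULL
  out
}

#' Write a scenario table as CSV
#'
#' Mirrors the published layout: a row number, one TRUE/FALSE column per
#' parent, and the outcome probability as a percentage with 2 decimals.
#'
#' @param table A `scenario_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(table, path) {
  pa <- attr(table, "parent_order")
  df <- data.frame(number = seq_len(nrow(table)))
  for (p in pa) df[[p]] <- ifelse(table[[p]], "TRUE", "FALSE")
  df$probability <- sprintf("%.2f%%", 100 * table$p_outcome)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
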