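#' Build a ground-truth Bayesian network for simulation
#'
#' Constructs a fully parameterized binary network to sample from. The
#' `"paper21"` preset uses the reference FFH topology (21 nodes, 24
#' edges, outcome parents A2, D1, C3, E1, E2, E3, C1); alternatively an
#' explicit edge list defines the topology. CPT entries are either drawn
#' from the seed (priors uniform on (0.15, 0.85), conditional rows
#' uniform on (0.05, 0.95), all strictly inside (0.02, 0.98)) or supplied
#' explicitly.
#'
#' @param topology `"paper21"`, a `risk_dag`, or a data frame of edges
#'   (`from`, `to`).
#' @param cpt_source `"random"` or a named list of CPT specs
#'   (`list(parents=, p=)` per node, canonical combo order).
#' @param seed Integer seed controlling the random CPTs.
#' @param outcome Outcome node id (default `"FFHA"`).
#' @return An `ffh_bn` usable with [sample_reports()] and all inference
#'   functions.
#' @export
make_ground_truth <- function(topology = "paper21", cpt_source = "random",
                              seed = 1, outcome = "FFHA") {
  graph <- if (identical(topology, "paper21")) ffh_topology("final")
           else if (inherits(topology, "risk_dag")) topology
           else assemble_graph(topology)
  cpts <- list()
  if (identical(cpt_source, "random")) {
    set.seed(seed)
    for (v in graph$nodes) {
      pa <- sort(parents(graph, v))
      cpts[[v]] <- list(
        parents = pa,
        p = if (length(pa)) stats::runif(2^length(pa), 0.05, 0.95)
            else stats::runif(1, 0.15, 0.85),
        provenance = rep("truth", 2^length(pa)))
    }
  } else {
    stopifnot(is.list(cpt_source))
    for (v in graph$nodes) {
      spec <- cpt_source[[v]]
      if (is.null(spec)) stop("no CPT supplied for node ", v, call. = FALSE)
      pa <- if (is.null(spec$parents)) sort(parents(graph, v)) else spec$parents
      stopifnot(setequal(pa, parents(graph, v)),
                length(spec$p) == 2^length(pa),
                all(spec$p > 0), all(spec$p < 1))
      cpts[[v]] <- list(parents = pa, p = as.numeric(spec$p),
                        provenance = rep("truth", length(spec$p)))
    }
  }
  structure(list(graph = graph, cpts = cpts,
                 outcome = if (outcome %in% graph$nodes) outcome else NA,
                 alpha = NA),
            class = "ffh_bn")
}

#' Ancestral sampling of accident reports from a known network
#'
#' Draws reports by forward sampling in topological order. With
#' `condition_outcome_true = TRUE` (emulating an accident-only corpus,
#' where every collected report has the outcome) rejection sampling keeps
#' drawing until `n` rows with the outcome TRUE are retained; the outcome
#' column is then dropped unless `keep_outcome` is set. Report ids are
#' zero-padded "001", "002", ...
#'
#' @param model An `ffh_bn` (typically from [make_ground_truth()]).
#' @param n Number of reports.
#' @param seed Integer seed.
#' @param condition_outcome_true Keep only rows with the outcome TRUE.
#' @param keep_outcome Retain the outcome column in the returned matrix.
#' @return An `incidence_matrix` (plus attribute `acceptance_rate` when
#'   rejection sampling was used).
#' @export
sample_reports <- function(model, n, seed = 1,
                           condition_outcome_true = FALSE,
                           keep_outcome = FALSE) {
  stopifnot(n >= 0)
  set.seed(seed)
  nodes <- topological_order(model$graph)
  draw <- function(m) {
    out <- matrix(0L, nrow = m, ncol = length(nodes),
                  dimnames = list(NULL, nodes))
    for (v in nodes) {
      cp <- model$cpts[[v]]
      p <- if (length(cp$parents)) {
        idx <- combo_index(out[, cp$parents, drop = FALSE])
        cp$p[idx]
      } else rep(cp$p, m)
      out[, v] <- as.integer(stats::runif(m) < p)
    }
    out
  }
  if (!condition_outcome_true) {
    rows <- draw(n)
    rate <- NA_real_
  } else {
    oc <- model$outcome
    stopifnot(!is.na(oc), oc %in% nodes)
    rows <- matrix(0L, 0, length(nodes), dimnames = list(NULL, nodes))
    tried <- 0L
    kept <- 0L
    while (kept < n) {
      batch <- draw(max(n, 256L))
      tried <- tried + nrow(batch)
      batch <- batch[batch[, oc] == 1L, , drop = FALSE]
      kept <- kept + nrow(batch)
      rows <- rbind(rows, batch)
      if (tried > 1e7 && kept == 0L)
        stop("sampling budget exhausted: P(outcome = TRUE) appears ",
             "to be below 1e-6", call. = FALSE)
    }
    rows <- rows[seq_len(n), , drop = FALSE]
    rate <- kept / tried
  }
  if (!keep_outcome && !is.na(model$outcome))
    rows <- rows[, setdiff(colnames(rows), model$outcome), drop = FALSE]
  # restore canonical catalog-like column order (stable across seeds)
  rows <- rows[, order(match(colnames(rows), model$graph$nodes)),
               drop = FALSE]
  width <- max(3L, nchar(as.character(n)))
  out <- incidence_matrix(rows,
                          report_ids = formatC(seq_len(n), width = width,
                                               flag = "0"))
  attr(out, "acceptance_rate") <- rate
  out
}

#' Simulate questionnaire panels for candidate causal links
#'
#' Emulates a 0-10 elicitation: for links present in the true graph,
#' respondent scores are drawn from a normal distribution centered at 8.5;
#' for absent links, centered at 2.0; in both cases with standard
#' deviation `noise_sd`, clipped to [0, 10] and rounded to integers
#' (round-half-even).
#'
#' @param true_graph A `risk_dag` defining which candidate links are real.
#' @param candidate_edges Data frame of candidate links (`from`, `to`).
#' @param n_expert,n_frontline Respondents per panel (>= 1).
#' @param noise_sd Score noise standard deviation.
#' @param seed Integer seed.
#' @return A response data frame (`from`, `to`, `panel`, `respondent`,
#'   `score`) suitable for [aggregate_responses()].
#' @export
simulate_questionnaires <- function(true_graph, candidate_edges,
                                    n_expert = 11, n_frontline = 41,
                                    noise_sd = 1.5, seed = 1) {
  stopifnot(n_expert >= 1, n_frontline >= 1, noise_sd >= 0)
  set.seed(seed)
  ce <- data.frame(from = as.character(candidate_edges$from),
                   to = as.character(candidate_edges$to),
                   stringsAsFactors = FALSE)
  truth <- paste(true_graph$edges$from, true_graph$edges$to)
  center <- ifelse(paste(ce$from, ce$to) %in% truth, 8.5, 2.0)
  out <- list()
  for (i in seq_len(nrow(ce))) {
    for (panel in c("expert", "frontline")) {
      m <- if (panel == "expert") n_expert else n_frontline
      raw <- stats::rnorm(m, mean = center[i], sd = noise_sd)
      score <- round(pmin(10, pmax(0, raw)))
      out[[length(out) + 1L]] <- data.frame(
        from = ce$from[i], to = ce$to[i], panel = panel,
        respondent = paste0(substr(panel, 1, 1), seq_len(m)),
        score = as.integer(score), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
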