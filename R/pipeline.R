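#' Run the full risk-scenario mapping pipeline
#'
#' Orchestrates every stage end-to-end: aggregate (or accept pre-fused)
#' panel supports, combine them with Dempster's rule, screen on
#' belief/conflict, assemble the expert graph, prune conditionally
#' independent links with empirical CMI, fit Laplace-smoothed parameters
#' from the incidence matrix, and derive marginal/diagnostic rankings plus
#' the exhaustive risk-scenario table.
#'
#' @param config A named list (or path to a YAML file with the same
#'   fields):
#'   \describe{
#'     \item{incidence}{`incidence_matrix` or CSV path (required).}
#'     \item{responses}{raw response data frame / CSV path, \emph{or}}
#'     \item{support}{pre-aggregated per-edge supports (`from`, `to`,
#'       `m1`, `m2`), e.g. [ffh_edge_support()].}
#'     \item{extra_edges}{optional extra candidate edges appended after
#'       screening (`from`, `to`), for links elicited outside the panels.}
#'     \item{alpha}{Laplace smoothing constant (default 1).}
#'     \item{cmi_threshold}{independence threshold (default 0.02).}
#'     \item{cmi_log_base}{logarithm base for CMI (default 2).}
#'     \item{bel_min, k_max}{screening thresholds (defaults 0.8, 0.5).}
#'     \item{extra_cmi}{optional extra CMI triples (`from`, `to`, `z`).}
#'     \item{outcome}{outcome node id (default "FFHA").}
#'     \item{outcome_column}{optional 0/1 outcome vector (see
#'       [fit_parameters()]).}
#'     \item{scenario_parent_order}{optional scenario column order.}
#'     \item{seed}{echoed into the manifest (default 1).}
#'     \item{out_dir}{optional directory; when set, all artifacts are
#'       written there as CSV/JSON/DOT.}
#'   }
#' @return A list with `fused`, `screened`, `graph_expert`, `pruning`
#'   (tests + threshold), `graph`, `model`, `ranking`, `scenarios`,
#'   `top5`, and a `manifest` echoing the configuration.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(alpha = 1, cmi_threshold = 0.02, cmi_log_base = 2,
         bel_min = 0.8, k_max = 0.5, outcome = "FFHA", seed = 1L,
         out_dir = NULL, extra_cmi = NULL, extra_edges = NULL,
         outcome_column = NULL, scenario_parent_order = NULL),
    config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  incidence <- stage("read", {
    if (is.character(cfg$incidence)) read_incidence(cfg$incidence)
    else cfg$incidence
  })

  support <- stage("fuse", {
    if (!is.null(cfg$support)) {
      if (is.character(cfg$support))
        utils::read.csv(cfg$support, stringsAsFactors = FALSE)
      else cfg$support
    } else if (!is.null(cfg$responses)) {
      resp <- if (is.character(cfg$responses)) read_responses(cfg$responses)
              else cfg$responses
      aggregate_responses(resp)
    } else stop("config needs either 'support' or 'responses'")
  })
  fused <- stage("fuse", fuse_edges(support))
  screened <- stage("screen",
                    screen_edges(fused, bel_min = cfg$bel_min,
                                 k_max = cfg$k_max))
  kept <- screened[screened$kept, c("from", "to")]
  if (!is.null(cfg$extra_edges))
    kept <- unique(rbind(kept, cfg$extra_edges[, c("from", "to")]))
  graph_expert <- stage("assemble", assemble_graph(kept))
  pruning <- stage("prune",
                   prune_edges(graph_expert, incidence,
                               threshold = cfg$cmi_threshold,
                               log_base = cfg$cmi_log_base,
                               extra = cfg$extra_cmi))
  model <- stage("fit",
                 fit_parameters(incidence, pruning$graph,
                                alpha = cfg$alpha, outcome = cfg$outcome,
                                outcome_column = cfg$outcome_column))
  ranking <- stage("infer", rank_risk_factors(model))
  scenarios <- stage("scenarios",
                     enumerate_scenarios(model,
                                         parent_order =
                                           cfg$scenario_parent_order))
  top5 <- top_scenarios(scenarios, min(5L, nrow(scenarios)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("ffhbn")),
    seed = cfg$seed, alpha = cfg$alpha,
    cmi_threshold = cfg$cmi_threshold, cmi_log_base = cfg$cmi_log_base,
    bel_min = cfg$bel_min, k_max = cfg$k_max, outcome = cfg$outcome,
    n_reports = nrow(incidence),
    n_candidate_edges = nrow(fused),
    n_screened_edges = nrow(kept),
    n_removed_edges = sum(unique(paste(pruning$tests$from,
                                       pruning$tests$to)[
                                         pruning$tests$removed]) != ""))

  result <- list(fused = fused, screened = screened,
                 graph_expert = graph_expert, pruning = pruning,
                 graph = pruning$graph, model = model, ranking = ranking,
                 scenarios = scenarios, top5 = top5, manifest = manifest)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(cfg$out_dir, f)
    utils::write.csv(screened, p("fused_edges.csv"), row.names = FALSE)
    write_edges(pruning$graph, p("pruned_graph.csv"))
    write_dot(pruning$graph, p("pruned_graph.dot"))
    utils::write.csv(pruning$tests, p("cmi_tests.csv"), row.names = FALSE)
    write_model(model, p("model.json"))
    utils::write.csv(ranking, p("risk_ranking.csv"), row.names = FALSE)
    write_scenarios(scenarios, p("scenarios.csv"))
    writeLines(utils::capture.output(print(top5)), p("top_scenarios.txt"))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  result
}

#' Validate a fitted model against held-out accident cases
#'
#' For each case, the listed risk factors are set TRUE as evidence and the
#' posterior probability of the outcome is computed (forward prediction).
#' An empty case returns the outcome marginal.
#'
#' @param model An `ffh_bn`.
#' @param cases A named list mapping case ids to character vectors of
#'   factors observed present (e.g.
#'   `list(T01 = c("D1", "B2", "B7", "B1"))`), or a data frame with
#'   columns `case` and `factor`.
#' @return A data frame with columns `case`, `evidence`, `p_outcome`, and
#'   `percent` formatted to 1 decimal.
#' @export
validate_cases <- function(model, cases) {
  if (is.data.frame(cases))
    cases <- split(as.character(cases$factor), cases$case)
  stopifnot(is.list(cases), length(names(cases)) == length(cases))
  rows <- lapply(names(cases), function(id) {
    present <- unique(as.character(cases[[id]]))
    unknown <- setdiff(present, model$graph$nodes)
    if (length(unknown))
      stop(sprintf("case %s names unknown node(s): %s", id,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    ev <- stats::setNames(rep(TRUE, length(present)), present)
    p <- posterior(model, model$outcome, ev)$p_true
    data.frame(case = id,
               evidence = paste(present, collapse = ","),
               p_outcome = p,
               percent = sprintf("%.1f%%", 100 * p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
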