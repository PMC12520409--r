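#' Laplace-smoothed probability estimates
#'
#' `estimate_prior()` implements the smoothed prior
#' `P(A = TRUE) = (X_A + alpha) / (N + 2 alpha)` for a binary factor
#' observed TRUE in `X_A` of `N` reports; `estimate_cpt_row()` the
#' analogous conditional `P(A = TRUE | C) = (X_A|C + alpha) / (N_C + 2
#' alpha)` for one parent-state combination `C` with `N_C` matching
#' reports. With `alpha > 0` every estimate is strictly inside (0, 1).
#'
#' @param x_a Count of TRUE observations (within the combination, for the
#'   conditional version).
#' @param n Total report count `N` (or combination count `N_C`).
#' @param alpha Laplace smoothing constant, > 0 (default 1).
#' @return A probability.
#' @examples
#' estimate_prior(184, 368)      # 0.5
#' estimate_cpt_row(3, 10)       # 4/12
#' @export
estimate_prior <- function(x_a, n, alpha = 1) {
  stopifnot(alpha > 0 || n > 0, x_a >= 0, x_a <= n)
  (x_a + alpha) / (n + 2 * alpha)
}

#' @rdname estimate_prior
#' @export
estimate_cpt_row <- function(x_a, n, alpha = 1) {
  stopifnot(alpha > 0, x_a >= 0, x_a <= n)
  (x_a + alpha) / (n + 2 * alpha)
}

#' Geometric-mean fallback for unseen parent combinations
#'
#' When a parent-state combination never occurs in the data, its CPT row
#' is estimated from the single-parent conditionals
#' `p_i = P(node = TRUE | parent_i = c_i)` (each computed from pairwise
#' counts with Laplace smoothing): the TRUE side is the geometric mean
#' `g_T` of the `p_i`, the FALSE side the geometric mean `g_F` of the
#' `1 - p_i`, and the returned probability is the normalized
#' `g_T / (g_T + g_F)` so that the two states remain complementary.
#'
#' @param p Numeric vector of single-parent conditionals, each strictly in
#'   (0, 1).
#' @return A probability.
#' @examples
#' fallback_row(c(0.8, 0.2))  # 0.5
#' @export
fallback_row <- function(p) {
  stopifnot(length(p) >= 1, all(p > 0), all(p < 1))
  g_t <- exp(mean(log(p)))
  g_f <- exp(mean(log(1 - p)))
  g_t / (g_t + g_f)
}

#' Canonical parent-state combinations
#'
#' Enumerates all `2^k` TRUE/FALSE assignments of `k` parents in canonical
#' order: the leftmost parent is most significant and TRUE precedes FALSE,
#' so row 1 is all-TRUE and the last row all-FALSE.
#'
#' @param parents Character vector of parent ids (may be length 0).
#' @return A logical matrix with `2^k` rows and one named column per
#'   parent.
#' @export
parent_combos <- function(parents) {
  k <- length(parents)
  if (k == 0)
    return(matrix(logical(0), nrow = 1, ncol = 0))
  i <- seq_len(2^k) - 1L
  combos <- vapply(seq_len(k), function(j)
    (i %/% 2^(k - j)) %% 2 == 0, logical(2^k))
  combos <- matrix(combos, ncol = k, dimnames = list(NULL, parents))
  combos
}

# 1-based canonical row index for each observation given parent states
# (columns of `states` follow the CPT's parent order; values 0/1 or logical)
combo_index <- function(states) {
  k <- ncol(states)
  if (k == 0) return(rep(1L, nrow(states)))
  idx <- rep(1L, nrow(states))
  for (j in seq_len(k))
    idx <- idx + as.integer(states[, j] == 0) * 2L^(k - j)
  idx
}

#' Fit Bayesian-network parameters from an incidence matrix
#'
#' Estimates one CPT per graph node from the binary report data: root
#' nodes get Laplace-smoothed priors, child rows with observed parent
#' combinations get smoothed conditionals, and unseen combinations fall
#' back to the normalized geometric mean of single-parent conditionals
#' (or to 0.5 with `fallback = "uniform"`). Each CPT row carries a
#' provenance flag (`"observed"` or `"fallback"`).
#'
#' The accident outcome node is typically absent from the matrix because
#' every collected report is an accident; by default it is fitted as if an
#' all-TRUE outcome column were present, which yields
#' `(N_C + alpha) / (N_C + 2 alpha)` for observed parent combinations.
#' Supplying `outcome_column` (e.g. synthetic controls) replaces that
#' convention with real 0/1 outcome data.
#'
#' @param matrix An `incidence_matrix` whose columns cover every
#'   non-outcome graph node.
#' @param graph A `risk_dag`.
#' @param alpha Laplace smoothing constant (default 1).
#' @param outcome Id of the outcome node (default `"FFHA"`); ignored if it
#'   is not a graph node.
#' @param outcome_column Optional 0/1 vector of length `nrow(matrix)` with
#'   the outcome state of each report.
#' @param fallback `"geometric_mean"` (default) or `"uniform"`.
#' @return An object of class `ffh_bn`: a list with `graph`, `cpts` (one
#'   per node: `parents`, `p` = P(node = TRUE | combo) over canonical
#'   combos, `provenance`), `outcome`, and `alpha`.
#' @export
fit_parameters <- function(matrix, graph, alpha = 1, outcome = "FFHA",
                           outcome_column = NULL,
                           fallback = c("geometric_mean", "uniform")) {
  fallback <- match.arg(fallback)
  stopifnot(alpha > 0)
  n <- nrow(matrix)
  missing <- setdiff(setdiff(graph$nodes, outcome), colnames(matrix))
  if (length(missing))
    stop("graph node(s) missing from the incidence matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.null(outcome_column)) {
    stopifnot(length(outcome_column) == n,
              all(outcome_column %in% c(0L, 1L)))
  }
  node_data <- function(v) {
    if (v %in% colnames(matrix)) return(as.integer(matrix[, v]))
    if (identical(v, outcome)) {
      if (!is.null(outcome_column)) return(as.integer(outcome_column))
      return(rep(1L, n))
    }
    stop("no data for node ", v, call. = FALSE)
  }
  # canonical parent order: matrix column order, outcome last
  canon <- c(colnames(matrix), setdiff(graph$nodes, colnames(matrix)))
  cpts <- list()
  for (v in graph$nodes) {
    pa <- intersect(canon, parents(graph, v))
    xv <- node_data(v)
    if (!length(pa)) {
      cpts[[v]] <- list(parents = character(),
                        p = estimate_prior(sum(xv == 1L), n, alpha),
                        provenance = "observed")
      next
    }
    k <- length(pa)
    pstates <- vapply(pa, node_data, integer(n))
    dim(pstates) <- c(n, k)
    idx <- combo_index(pstates)
    n_c <- tabulate(idx, nbins = 2^k)
    x_c <- as.vector(tapply(xv, factor(idx, levels = seq_len(2^k)), sum,
                            default = 0L))
    combos <- parent_combos(pa)
    p <- numeric(2^k)
    prov <- character(2^k)
    # single-parent conditionals for fallback rows, per parent and state
    pair_p <- NULL
    for (r in seq_len(2^k)) {
      if (n_c[r] > 0) {
        p[r] <- estimate_cpt_row(x_c[r], n_c[r], alpha)
        prov[r] <- "observed"
      } else if (fallback == "uniform") {
        p[r] <- 0.5
        prov[r] <- "fallback"
      } else {
        if (is.null(pair_p)) {
          pair_p <- vapply(seq_len(k), function(j) {
            vapply(c(TRUE, FALSE), function(s) {
              sel <- (pstates[, j] == 1L) == s
              estimate_cpt_row(sum(xv[sel] == 1L), sum(sel), alpha)
            }, numeric(1))
          }, numeric(2))  # rows: TRUE, FALSE state of parent j
        }
        pi <- vapply(seq_len(k), function(j)
          pair_p[if (combos[r, j]) 1 else 2, j], numeric(1))
        p[r] <- fallback_row(pi)
        prov[r] <- "fallback"
      }
    }
    cpts[[v]] <- list(parents = pa, p = p, provenance = prov)
  }
  structure(list(graph = graph, cpts = cpts, outcome = outcome,
                 alpha = alpha),
            class = "ffh_bn")
}

#' @export
print.ffh_bn <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$graph$nodes), "binary nodes,",
      nrow(x$graph$edges), "edges; outcome:", x$outcome, "\n")
  nfall <- sum(vapply(x$cpts, function(cp)
    sum(cp$provenance == "fallback"), numeric(1)))
  cat("CPT rows:", sum(vapply(x$cpts, function(cp) length(cp$p),
                              numeric(1))),
      sprintf("(%d fallback-estimated)\n", nfall))
  invisible(x)
}

#' Serialize / restore a fitted network as JSON
#'
#' The JSON object stores the node list, edge list, and per-node CPTs
#' (parent order, P(TRUE | combo) over canonical combinations, and row
#' provenance); `read_model(write_model(m, path))` restores an equivalent
#' model.
#'
#' @param model An `ffh_bn`.
#' @param path Output file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` an
#'   `ffh_bn`.
#' @export
write_model <- function(model, path) {
  obj <- list(
    nodes = model$graph$nodes,
    edges = model$graph$edges,
    outcome = model$outcome,
    alpha = model$alpha,
    cpts = lapply(model$cpts, function(cp)
      list(parents = cp$parents, p = cp$p, provenance = cp$provenance)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  graph <- assemble_graph(as.data.frame(obj$edges), nodes = obj$nodes)
  cpts <- lapply(obj$cpts, function(cp)
    list(parents = as.character(unlist(cp$parents)),
         p = as.numeric(unlist(cp$p)),
         provenance = as.character(unlist(cp$provenance))))
  structure(list(graph = graph, cpts = cpts, outcome = obj$outcome,
                 alpha = obj$alpha),
            class = "ffh_bn")
}
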