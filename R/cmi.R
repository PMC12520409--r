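#' Plug-in conditional mutual information between two binary factors
#'
#' Estimates `I(X; Y | Z)` from empirical frequencies of the incidence
#' matrix: `sum_{x,y,z} p(x,y,z) log[ p(x,y,z) p(z) / (p(x,z) p(y,z)) ]`,
#' with `p` the plug-in relative frequency `N(.)/N` and the convention
#' that cells with zero joint frequency contribute 0. Values below the
#' chosen independence threshold (0.02 by default in [prune_edges()])
#' indicate that the conditioning variable screens off the pair.
#'
#' @param matrix An `incidence_matrix` with `N > 0` rows.
#' @param x,y,z Distinct factor ids (columns of `matrix`).
#' @param log_base 2 (bits, default) or `exp(1)` (nats).
#' @return A non-negative number (up to a -1e-12 float tolerance). When a
#'   variable is constant in the data a degenerate-margin warning is
#'   emitted and 0 is returned.
#' @export
conditional_mutual_information <- function(matrix, x, y, z, log_base = 2) {
  check_factors(matrix, c(x, y, z))
  if (length(unique(c(x, y, z))) != 3)
    stop("x, y, z must be distinct factors", call. = FALSE)
  n <- nrow(matrix)
  if (n == 0) stop("incidence matrix has no rows", call. = FALSE)
  xs <- matrix[, x]; ys <- matrix[, y]; zs <- matrix[, z]
  degen <- c(x, y, z)[c(length(unique(xs)), length(unique(ys)),
                        length(unique(zs))) == 1]
  if (length(degen)) {
    warning("degenerate margin: factor(s) constant in the data: ",
            paste(degen, collapse = ", "), call. = FALSE)
    return(0)
  }
  # 8-cell joint counts, indexed by (x, y, z) states
  idx <- 1L + xs + 2L * ys + 4L * zs
  nxyz <- tabulate(idx, nbins = 8L)
  dim(nxyz) <- c(2L, 2L, 2L)
  nz  <- apply(nxyz, 3, sum)
  nxz <- apply(nxyz, c(1, 3), sum)
  nyz <- apply(nxyz, c(2, 3), sum)
  total <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    c_xyz <- nxyz[i, j, k]
    if (c_xyz == 0) next
    total <- total +
      (c_xyz / n) * log((c_xyz * nz[k]) / (nxz[i, k] * nyz[j, k]),
                        base = log_base)
  }
  max(total, 0)
}

#' Candidate conditional-independence tests for a graph
#'
#' For every edge `X -> Y` whose removal leaves a directed two-step path
#' `X -> Z -> Y` through a single mediator `Z`, emits the triple
#' `(X -> Y, Z)`: such shortcut edges are the ones d-separation predicts
#' may be spurious once the mediator is conditioned on. User-supplied
#' triples are appended verbatim and deduplicated; a triple naming an
#' absent edge triggers a warning, not an error.
#'
#' @param graph A `risk_dag`.
#' @param extra Optional data frame with columns `from`, `to`, `z`.
#' @return A data frame with columns `from`, `to`, `z` (possibly 0 rows).
#' @export
candidate_cmi_tests <- function(graph, extra = NULL) {
  ed <- graph$edges
  out <- data.frame(from = character(), to = character(), z = character(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ed))) {
    x <- ed$from[i]; y <- ed$to[i]
    mediators <- intersect(children(graph, x), parents(graph, y))
    if (length(mediators))
      out <- rbind(out, data.frame(from = x, to = y, z = sort(mediators)))
  }
  if (!is.null(extra) && NROW(extra)) {
    extra <- data.frame(from = as.character(extra$from),
                        to = as.character(extra$to),
                        z = as.character(extra$z), stringsAsFactors = FALSE)
    known <- paste(ed$from, ed$to)
    missing <- !(paste(extra$from, extra$to) %in% known)
    if (any(missing))
      warning("extra CMI triple(s) reference edges absent from the graph: ",
              paste(paste(extra$from, "->", extra$to)[missing],
                    collapse = ", "), call. = FALSE)
    out <- rbind(out, extra)
  }
  out[!duplicated(paste(out$from, out$to, out$z)), , drop = FALSE]
}

#' Prune conditionally independent edges using empirical CMI
#'
#' Runs every candidate test (auto-generated mediator triples plus any
#' user-supplied ones) against the incidence data and removes an edge
#' when at least one tested conditioner yields conditional mutual
#' information below `threshold`. Removing edges from a DAG cannot create
#' cycles, so the result is again acyclic.
#'
#' @param graph A `risk_dag`.
#' @param matrix An `incidence_matrix` covering the tested factors.
#' @param threshold Independence threshold on CMI (default 0.02).
#' @param log_base Base for the CMI logarithm (default 2).
#' @param extra Optional extra test triples (see [candidate_cmi_tests()]).
#' @return A list with the pruned `graph`, a `tests` data frame
#'   (columns `from`, `to`, `z`, `cmi`, `verdict`, `removed`), and the
#'   `threshold` used.
#' @export
prune_edges <- function(graph, matrix, threshold = 0.02, log_base = 2,
                        extra = NULL) {
  cand <- candidate_cmi_tests(graph, extra)
  cand <- cand[paste(cand$from, cand$to) %in%
                 paste(graph$edges$from, graph$edges$to), , drop = FALSE]
  if (!nrow(cand))
    return(list(graph = graph,
                tests = data.frame(from = character(), to = character(),
                                   z = character(), cmi = numeric(),
                                   verdict = character(),
                                   removed = logical()),
                threshold = threshold))
  cand$cmi <- vapply(seq_len(nrow(cand)), function(i)
    conditional_mutual_information(matrix, cand$from[i], cand$to[i],
                                   cand$z[i], log_base = log_base),
    numeric(1))
  cand$verdict <- ifelse(cand$cmi < threshold, "independent", "dependent")
  edge_key <- paste(cand$from, cand$to)
  drop_keys <- unique(edge_key[cand$verdict == "independent"])
  cand$removed <- edge_key %in% drop_keys
  keep <- !(paste(graph$edges$from, graph$edges$to) %in% drop_keys)
  pruned <- assemble_graph(graph$edges[keep, , drop = FALSE],
                           nodes = graph$nodes)
  list(graph = pruned, tests = cand, threshold = threshold)
}
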