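# Independent oracles used to cross-check the package's algorithms.
# These deliberately avoid the implementation paths they verify: the
# posterior oracle enumerates the full joint table, the d-separation
# oracle enumerates undirected paths, and the CMI oracle loops over the
# eight joint cells with scalar arithmetic.

# Kahn topological sort straight from the edge list
oracle_topo <- function(graph) {
  nodes <- graph$nodes
  edges <- graph$edges
  indeg <- stats::setNames(rep(0L, length(nodes)), nodes)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  order <- character()
  ready <- nodes[indeg == 0L]
  while (length(ready)) {
    v <- ready[1]
    ready <- ready[-1]
    order <- c(order, v)
    for (w in edges$to[edges$from == v]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- c(ready, w)
    }
  }
  order
}

# full joint distribution as a flat vector; var i appended most
# significant, state code 0 = TRUE
oracle_joint <- function(model) {
  nodes <- character()
  vals <- 1
  for (v in oracle_topo(model$graph)) {
    cp <- model$cpts[[v]]
    n_cells <- length(vals)
    cells <- seq_len(n_cells) - 1
    if (length(cp$parents)) {
      k <- length(cp$parents)
      combo <- rep(1, n_cells)
      for (j in seq_len(k)) {
        pos <- match(cp$parents[j], nodes)
        combo <- combo + ((cells %/% 2^(pos - 1)) %% 2) * 2^(k - j)
      }
      pt <- cp$p[combo]
    } else {
      pt <- rep(cp$p, n_cells)
    }
    vals <- c(vals * pt, vals * (1 - pt))
    nodes <- c(nodes, v)
  }
  list(vars = nodes, vals = vals)
}

oracle_posterior <- function(model, query, evidence = NULL, joint = NULL) {
  j <- if (is.null(joint)) oracle_joint(model) else joint
  cells <- seq_along(j$vals) - 1
  keep <- rep(TRUE, length(j$vals))
  for (v in names(evidence)) {
    pos <- match(v, j$vars)
    code <- (cells %/% 2^(pos - 1)) %% 2
    keep <- keep & (code == if (isTRUE(evidence[[v]])) 0 else 1)
  }
  qpos <- match(query, j$vars)
  qtrue <- ((cells %/% 2^(qpos - 1)) %% 2) == 0
  sum(j$vals[keep & qtrue]) / sum(j$vals[keep])
}

# d-separation by exhaustive enumeration of undirected simple paths
oracle_d_separated <- function(graph, x, y, z = character()) {
  edges <- graph$edges
  has_edge <- function(a, b) any(edges$from == a & edges$to == b)
  nbrs <- function(v) unique(c(edges$to[edges$from == v],
                               edges$from[edges$to == v]))
  desc <- function(v) {
    res <- character()
    frontier <- v
    while (length(frontier)) {
      ch <- unique(edges$to[edges$from %in% frontier])
      frontier <- setdiff(ch, res)
      res <- union(res, frontier)
    }
    res
  }
  path_active <- function(path) {
    if (length(path) == 2) return(TRUE)
    for (i in 2:(length(path) - 1)) {
      a <- path[i - 1]; m <- path[i]; b <- path[i + 1]
      collider <- has_edge(a, m) && has_edge(b, m)
      if (collider) {
        if (!any(c(m, desc(m)) %in% z)) return(FALSE)
      } else {
        if (m %in% z) return(FALSE)
      }
    }
    TRUE
  }
  found_active <- FALSE
  walk <- function(path) {
    if (found_active) return()
    v <- path[length(path)]
    if (v == y) {
      if (path_active(path)) found_active <<- TRUE
      return()
    }
    for (w in setdiff(nbrs(v), path)) walk(c(path, w))
  }
  walk(x)
  !found_active
}

# plug-in CMI by scalar triple loop over the 8 joint cells
oracle_cmi <- function(matrix, x, y, z, log_base = 2) {
  n <- nrow(matrix)
  total <- 0
  for (xi in 0:1) for (yi in 0:1) for (zi in 0:1) {
    nxyz <- sum(matrix[, x] == xi & matrix[, y] == yi & matrix[, z] == zi)
    if (nxyz == 0) next
    nz <- sum(matrix[, z] == zi)
    nxz <- sum(matrix[, x] == xi & matrix[, z] == zi)
    nyz <- sum(matrix[, y] == yi & matrix[, z] == zi)
    total <- total + (nxyz / n) * log(nxyz * nz / (nxz * nyz), log_base)
  }
  total
}

# random DAG over n nodes: edges respect a shuffled total order
random_dag <- function(n_nodes, p_edge = 0.3, seed = 1) {
  set.seed(seed)
  ids <- paste0("V", seq_len(n_nodes))
  ord <- sample(ids)
  from <- character(); to <- character()
  for (i in seq_len(n_nodes - 1)) for (j in (i + 1):n_nodes) {
    if (stats::runif(1) < p_edge) {
      from <- c(from, ord[i]); to <- c(to, ord[j])
    }
  }
  assemble_graph(data.frame(from = from, to = to,
                            stringsAsFactors = FALSE),
                 nodes = ids)
}

# randomly parameterized model on a random DAG
random_model <- function(n_nodes, p_edge = 0.3, seed = 1) {
  g <- random_dag(n_nodes, p_edge, seed)
  make_ground_truth(topology = g, cpt_source = "random",
                    seed = seed + 1000L, outcome = "none")
}

# look up P(node = TRUE | parent states) by named combo, independent of
# the parent order stored in the CPT
cpt_prob <- function(model, node, states = NULL) {
  cp <- model$cpts[[node]]
  if (!length(cp$parents)) return(cp$p)
  idx <- 1L
  k <- length(cp$parents)
  for (j in seq_len(k))
    if (!isTRUE(states[[cp$parents[j]]])) idx <- idx + 2L^(k - j)
  cp$p[idx]
}
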