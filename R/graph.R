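#' Assemble a directed acyclic graph from an edge list
#'
#' @param edges A data frame (or 2-column matrix) with columns `from` and
#'   `to`; duplicate edges are rejected, as are self-loops and cycles.
#' @param nodes Optional extra node ids to include even if isolated.
#' @return An object of class `risk_dag`: a list with character `nodes`
#'   (in first-appearance order) and an `edges` data frame.
#' @examples
#' g <- assemble_graph(data.frame(from = c("A", "B"), to = c("B", "C")))
#' parents(g, "C")
#' @export
assemble_graph <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || !NROW(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(names(edges)) || !all(c("from", "to") %in% names(edges)))
      names(edges)[1:2] <- c("from", "to")
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        stringsAsFactors = FALSE)
  }
  if (any(edges$from == edges$to))
    stop("self-loop on node ", edges$from[edges$from == edges$to][1],
         call. = FALSE)
  if (anyDuplicated(paste(edges$from, edges$to, sep = "\r")))
    stop("duplicate edge in edge list", call. = FALSE)
  all_nodes <- unique(c(nodes, edges$from, edges$to))
  g <- structure(list(nodes = all_nodes, edges = edges), class = "risk_dag")
  if (nrow(edges)) {
    ig <- as_igraph(g)
    if (!igraph::is_dag(ig))
      stop("edge set contains a directed cycle: ",
           paste(find_cycle(g), collapse = " -> "), call. = FALSE)
  }
  g
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = graph$nodes)
}

# depth-first search for one directed cycle, for error reporting
find_cycle <- function(graph) {
  adj <- split(graph$edges$to, factor(graph$edges$from, graph$nodes))
  state <- stats::setNames(rep(0L, length(graph$nodes)), graph$nodes)
  path <- character()
  res <- NULL
  visit <- function(v) {
    if (!is.null(res)) return()
    state[v] <<- 1L
    path <<- c(path, v)
    for (w in adj[[v]]) {
      if (state[w] == 1L) {
        res <<- c(path[which(path == w)[1]:length(path)], w)
        return()
      }
      if (state[w] == 0L) visit(w)
    }
    state[v] <<- 2L
    path <<- path[-length(path)]
  }
  for (v in graph$nodes) if (state[v] == 0L) visit(v)
  res
}

#' @export
print.risk_dag <- function(x, ...) {
  cat("Directed acyclic graph:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges))
    cat(paste(x$edges$from, "->", x$edges$to), sep = "\n")
  invisible(x)
}

#' Graph accessors
#'
#' @param graph A `risk_dag`.
#' @param node A node id.
#' @return `parents()`/`children()` return character vectors;
#'   `topological_order()` the nodes sorted parents-before-children;
#'   `root_nodes()` the parentless nodes.
#' @export
parents <- function(graph, node) {
  stopifnot(node %in% graph$nodes)
  graph$edges$from[graph$edges$to == node]
}

#' @rdname parents
#' @export
children <- function(graph, node) {
  stopifnot(node %in% graph$nodes)
  graph$edges$to[graph$edges$from == node]
}

#' @rdname parents
#' @export
topological_order <- function(graph) {
  if (!nrow(graph$edges)) return(graph$nodes)
  names(igraph::topo_sort(as_igraph(graph), mode = "out"))
}

#' @rdname parents
#' @export
root_nodes <- function(graph) {
  setdiff(graph$nodes, unique(graph$edges$to))
}

ancestors_of <- function(graph, nodes) {
  res <- character()
  frontier <- nodes
  while (length(frontier)) {
    pa <- unique(graph$edges$from[graph$edges$to %in% frontier])
    frontier <- setdiff(pa, res)
    res <- union(res, frontier)
  }
  res
}

#' Test d-separation in a DAG
#'
#' Standard d-separation semantics: a path is blocked given `z` at a chain
#' or fork whose middle node is in `z`, and at a collider whose node and
#' descendants are all outside `z`. Implemented via the
#' moralized-ancestral-graph criterion: X and Y are d-separated by Z iff
#' they are disconnected after removing Z in the moralization of the
#' subgraph induced by the ancestors of X, Y and Z.
#'
#' @param graph A `risk_dag`.
#' @param x,y Node ids (not in `z`).
#' @param z Character vector of conditioning node ids (may be empty).
#' @return `TRUE` iff `x` and `y` are d-separated given `z`.
#' @examples
#' chain <- assemble_graph(data.frame(from = c("A", "B"), to = c("B", "C")))
#' d_separated(chain, "A", "C", "B")  # TRUE
#' @export
d_separated <- function(graph, x, y, z = character()) {
  z <- as.character(z)
  unknown <- setdiff(c(x, y, z), graph$nodes)
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (x %in% z || y %in% z)
    stop("x and y must not be members of z", call. = FALSE)
  keep <- union(c(x, y, z), ancestors_of(graph, c(x, y, z)))
  sub <- graph$edges[graph$edges$from %in% keep & graph$edges$to %in% keep, ]
  # moralize: undirect all edges, marry co-parents
  und <- rbind(sub[, c("from", "to")],
               stats::setNames(sub[, c("to", "from")], c("from", "to")))
  for (v in unique(sub$to)) {
    pa <- unique(sub$from[sub$to == v])
    if (length(pa) > 1) {
      prs <- utils::combn(pa, 2)
      und <- rbind(und,
                   data.frame(from = c(prs[1, ], prs[2, ]),
                              to = c(prs[2, ], prs[1, ])))
    }
  }
  # drop Z and test undirected reachability x ~> y
  und <- und[!(und$from %in% z) & !(und$to %in% z), ]
  frontier <- x
  seen <- x
  while (length(frontier)) {
    nxt <- unique(und$to[und$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, frontier)
    if (y %in% seen) return(FALSE)
  }
  TRUE
}

#' Export a graph in GraphViz DOT format
#'
#' @param graph A `risk_dag`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(graph, path) {
  lines <- c("digraph risk {",
             paste0("  \"", graph$nodes, "\";"),
             if (nrow(graph$edges))
               paste0("  \"", graph$edges$from, "\" -> \"",
                      graph$edges$to, "\";"),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an edge-list CSV
#'
#' @param path CSV file path with columns `from`, `to`.
#' @return `read_edges()` returns a `risk_dag`.
#' @export
read_edges <- function(path) {
  assemble_graph(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_edges
#' @param graph A `risk_dag`.
#' @export
write_edges <- function(graph, path) {
  utils::write.csv(graph$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reference topologies of the FFH risk network
#'
#' `stage = "preliminary"` returns the 26-edge expert-knowledge graph
#' (the 25 published fused links plus B3 -> A2, the additional candidate
#' retained by its conditional-mutual-information test);
#' `stage = "final"` removes the two links found conditionally independent
#' on the report data (B2 -> C3 and B7 -> C3), leaving 24 edges over
#' 21 nodes with outcome parents \{A2, D1, C3, E1, E2, E3, C1\}.
#'
#' @param stage `"final"` (default) or `"preliminary"`.
#' @return A `risk_dag`.
#' @export
ffh_topology <- function(stage = c("final", "preliminary")) {
  stage <- match.arg(stage)
  sup <- ffh_edge_support()
  edges <- rbind(sup[, c("from", "to")],
                 data.frame(from = "B3", to = "A2"))
  if (stage == "final")
    edges <- edges[!(paste(edges$from, edges$to) %in%
                       c("B2 C3", "B7 C3")), ]
  assemble_graph(edges)
}
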