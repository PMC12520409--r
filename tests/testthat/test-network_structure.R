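test_that("graph assembly validates structure", {
  g <- assemble_graph(ffh_edge_support()[, c("from", "to")])
  expect_equal(length(g$nodes), 21)
  expect_equal(nrow(g$edges), 25)
  expect_error(assemble_graph(data.frame(from = c("A", "B"),
                                         to = c("B", "A"))),
               "cycle")
  expect_error(assemble_graph(data.frame(from = "A", to = "A")),
               "self-loop")
  expect_error(assemble_graph(data.frame(from = c("A", "A"),
                                         to = c("B", "B"))),
               "duplicate")
  empty <- assemble_graph()
  expect_equal(length(empty$nodes), 0)
  # reference topologies
  expect_equal(nrow(ffh_topology("preliminary")$edges), 26)
  fin <- ffh_topology("final")
  expect_equal(nrow(fin$edges), 24)
  expect_setequal(parents(fin, "FFHA"), ffh_scenario_parents())
})

test_that("d-separation follows chain, fork and collider semantics", {
  chain <- assemble_graph(data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_true(d_separated(chain, "A", "C", "B"))
  expect_false(d_separated(chain, "A", "C"))
  collider <- assemble_graph(data.frame(from = c("A", "B"),
                                        to = c("C", "C")))
  expect_true(d_separated(collider, "A", "B"))
  expect_false(d_separated(collider, "A", "B", "C"))
  # conditioning on a collider's descendant also opens the path
  desc <- assemble_graph(data.frame(from = c("A", "B", "C"),
                                    to = c("C", "C", "D")))
  expect_false(d_separated(desc, "A", "B", "D"))
  expect_error(d_separated(chain, "A", "Z"), "unknown node")
  expect_error(d_separated(chain, "A", "B", "A"), "members of z")
})

test_that("on the final topology the pruned pair stays separated", {
  g <- ffh_topology("final")
  expect_true(d_separated(g, "B2", "C3", c("B1", "D3")))
  expect_true(oracle_d_separated(g, "B2", "C3", c("B1", "D3")))
  expect_false(d_separated(g, "B2", "C3", "B1"))  # open via B7 -> D3
})

test_that("d-separation agrees with a path-enumeration oracle", {
  for (seed in 1:6) {
    g <- random_dag(8, p_edge = 0.3, seed = seed)
    set.seed(seed + 100)
    for (case in 1:15) {
      pair <- sample(g$nodes, 2)
      z <- sample(setdiff(g$nodes, pair),
                  sample(0:3, 1))
      expect_equal(
        d_separated(g, pair[1], pair[2], z),
        oracle_d_separated(g, pair[1], pair[2], z),
        info = sprintf("seed %d: %s vs %s | {%s}", seed, pair[1], pair[2],
                       paste(z, collapse = ",")))
    }
  }
})

test_that("candidate CMI tests find single-mediator shortcuts", {
  g <- assemble_graph(data.frame(from = c("B2", "B1", "B2"),
                                 to = c("B1", "C3", "C3")))
  cand <- candidate_cmi_tests(g)
  expect_equal(nrow(cand), 1)
  expect_equal(unlist(cand[1, ]), c(from = "B2", to = "C3", z = "B1"))
  # a pure chain has no shortcut to test
  chain <- assemble_graph(data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_equal(nrow(candidate_cmi_tests(chain)), 0)
  # both mediators on the same shortcut are emitted
  g2 <- assemble_graph(data.frame(
    from = c("B2", "B1", "B2", "B2", "B7"),
    to   = c("B1", "C3", "C3", "B7", "C3")))
  cand2 <- candidate_cmi_tests(g2)
  expect_setequal(paste(cand2$from, cand2$to, cand2$z),
                  c("B2 C3 B1", "B2 C3 B7"))
  # user triples pass through; absent edges warn
  expect_warning(
    out <- candidate_cmi_tests(chain,
                               extra = data.frame(from = "A", to = "C",
                                                  z = "B")),
    "absent")
  expect_equal(nrow(out), 1)
})

test_that("the CMI estimator matches a triple-loop oracle", {
  set.seed(3)
  for (rep in 1:10) {
    m <- incidence_matrix(matrix(rbinom(60, 1, runif(1, 0.2, 0.8)),
                                 ncol = 3,
                                 dimnames = list(NULL, c("X", "Y", "Z"))))
    expect_equal(conditional_mutual_information(m, "X", "Y", "Z"),
                 oracle_cmi(m, "X", "Y", "Z"), tolerance = 1e-12)
    expect_equal(conditional_mutual_information(m, "X", "Y", "Z",
                                                log_base = exp(1)),
                 oracle_cmi(m, "X", "Y", "Z", log_base = exp(1)),
                 tolerance = 1e-12)
    # symmetric in X and Y
    expect_equal(conditional_mutual_information(m, "X", "Y", "Z"),
                 conditional_mutual_information(m, "Y", "X", "Z"),
                 tolerance = 1e-12)
  }
})

test_that("CMI is zero on factorized counts and one bit on a copy", {
  # product joint by construction: all 8 cells equally frequent
  grid <- as.matrix(expand.grid(X = 0:1, Y = 0:1, Z = 0:1))
  cells <- grid[rep(1:8, 5), ]
  rownames(cells) <- NULL
  m <- incidence_matrix(cells)
  expect_equal(conditional_mutual_information(m, "X", "Y", "Z"), 0)
  # X = Y balanced with an independent fair Z: I = H(X) = 1 bit
  x <- rep(c(0, 1), each = 4)
  z <- rep(c(0, 1), times = 4)
  m2 <- incidence_matrix(cbind(X = x, Y = x, Z = z))
  expect_equal(conditional_mutual_information(m2, "X", "Y", "Z"), 1.0)
  expect_equal(conditional_mutual_information(m2, "X", "Y", "Z",
                                              log_base = exp(1)),
               log(2))
  # degenerate margin warns and returns zero
  m3 <- incidence_matrix(cbind(X = x, Y = x, Z = rep(1, 8)))
  expect_warning(v <- conditional_mutual_information(m3, "X", "Y", "Z"),
                 "degenerate")
  expect_equal(v, 0)
  expect_error(conditional_mutual_information(m2[0, ], "X", "Y", "Z"),
               "no rows")
})

test_that("pruning removes shortcut edges that the data calls independent", {
  # ground truth: X -> Z -> Y with strong links, no direct X -> Y
  truth <- make_ground_truth(
    topology = data.frame(from = c("X", "Z"), to = c("Z", "Y")),
    cpt_source = list(X = list(p = 0.5),
                      Z = list(parents = "X", p = c(0.9, 0.1)),
                      Y = list(parents = "Z", p = c(0.85, 0.15))),
    outcome = "none")
  spurious <- assemble_graph(data.frame(from = c("X", "Z", "X"),
                                        to = c("Z", "Y", "Y")))
  removed <- 0L
  kept_zy <- TRUE
  for (seed in 1:20) {
    m <- sample_reports(truth, 368, seed = seed)
    res <- prune_edges(spurious, m, threshold = 0.02)
    keys <- paste(res$graph$edges$from, res$graph$edges$to)
    if (!("X Y" %in% keys)) removed <- removed + 1L
    if (!("Z Y" %in% keys)) kept_zy <- FALSE
  }
  expect_gte(removed, 18)  # >= 90% of seeds
  expect_true(kept_zy)
})

test_that("pruning is idempotent and respects the any-conditioner rule", {
  set.seed(9)
  g <- assemble_graph(data.frame(
    from = c("B2", "B1", "B2", "B2", "B7"),
    to   = c("B1", "C3", "C3", "B7", "C3")))
  truth <- make_ground_truth(topology = g$edges, cpt_source = "random",
                             seed = 2, outcome = "none")
  m <- sample_reports(truth, 368, seed = 4)
  once <- prune_edges(g, m)
  twice <- prune_edges(once$graph, m)
  expect_equal(twice$graph$edges, once$graph$edges)
  # with an empty test list the graph is unchanged
  chain <- assemble_graph(data.frame(from = "A", to = "B"))
  mm <- incidence_matrix(cbind(A = c(0, 1), B = c(1, 0)))
  same <- prune_edges(chain, mm)
  expect_equal(same$graph$edges, chain$edges)
  expect_equal(nrow(same$tests), 0)
})

test_that("graph CSV and DOT exports round-trip or parse", {
  g <- ffh_topology("final")
  path <- withr::local_tempfile(fileext = ".csv")
  write_edges(g, path)
  back <- read_edges(path)
  expect_setequal(paste(back$edges$from, back$edges$to),
                  paste(g$edges$from, g$edges$to))
  dot <- withr::local_tempfile(fileext = ".dot")
  write_dot(g, dot)
  lines <- readLines(dot)
  expect_equal(lines[1], "digraph risk {")
  expect_equal(sum(grepl("->", lines, fixed = TRUE)), nrow(g$edges))
})
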