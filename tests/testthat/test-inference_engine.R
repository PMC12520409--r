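hand_chain <- function() {
  # X -> Y with hand-set CPTs for closed-form checks
  make_ground_truth(
    topology = data.frame(from = "X", to = "Y"),
    cpt_source = list(X = list(p = 0.3),
                      Y = list(parents = "X", p = c(0.9, 0.2))),
    outcome = "none")
}

test_that("joint probability is the product of CPT entries", {
  one <- make_ground_truth(topology = assemble_graph(nodes = "X"),
                           cpt_source = list(X = list(p = 0.3)),
                           outcome = "none")
  expect_equal(joint_probability(one, c(X = TRUE)), 0.3)
  m <- hand_chain()
  # P(X=T, Y=F) = 0.3 * 0.1
  expect_equal(joint_probability(m, c(X = TRUE, Y = FALSE)), 0.03)
  expect_equal(joint_probability(m, c(X = FALSE, Y = TRUE)), 0.7 * 0.2)
  # all assignments sum to one
  total <- 0
  for (x in c(TRUE, FALSE)) for (y in c(TRUE, FALSE))
    total <- total + joint_probability(m, c(X = x, Y = y))
  expect_equal(total, 1, tolerance = 1e-12)
  expect_error(joint_probability(m, c(X = TRUE)), "cover exactly")
})

test_that("posteriors match hand computations on small networks", {
  m <- hand_chain()
  # law of total probability: P(Y=T) = .9*.3 + .2*.7
  expect_equal(posterior(m, "Y")$p_true, 0.9 * 0.3 + 0.2 * 0.7,
               tolerance = 1e-12)
  # Bayes: P(X=T | Y=T)
  expect_equal(posterior(m, "X", c(Y = TRUE))$p_true,
               0.9 * 0.3 / (0.9 * 0.3 + 0.2 * 0.7), tolerance = 1e-12)
  # explaining away on a collider
  coll <- make_ground_truth(
    topology = data.frame(from = c("A", "B"), to = c("C", "C")),
    cpt_source = list(A = list(p = 0.4), B = list(p = 0.4),
                      C = list(parents = c("A", "B"),
                               p = c(0.99, 0.9, 0.9, 0.05))),
    outcome = "none")
  pa_c <- posterior(coll, "A", c(C = TRUE))$p_true
  pa_cb <- posterior(coll, "A", c(C = TRUE, B = TRUE))$p_true
  expect_lt(pa_cb, pa_c)  # learning B=T explains C away from A
  expect_equal(pa_c, oracle_posterior(coll, "A", list(C = TRUE)),
               tolerance = 1e-10)
  expect_equal(pa_cb, oracle_posterior(coll, "A", list(C = TRUE, B = TRUE)),
               tolerance = 1e-10)
})

test_that("variable elimination equals enumeration on random models", {
  for (seed in 1:25) {
    n <- sample(3:12, 1)
    mod <- random_model(n, p_edge = 0.35, seed = seed)
    nodes <- mod$graph$nodes
    set.seed(seed + 500)
    query <- sample(nodes, 1)
    n_ev <- sample(0:min(3, length(nodes) - 1), 1)
    ev_nodes <- sample(setdiff(nodes, query), n_ev)
    ev <- stats::setNames(sample(c(TRUE, FALSE), n_ev, replace = TRUE),
                          ev_nodes)
    got <- tryCatch(posterior(mod, query, ev)$p_true,
                    error = function(e) NA_real_)
    want <- oracle_posterior(mod, query, as.list(ev))
    if (is.na(got)) {
      expect_true(is.nan(want) || want == 0)  # impossible evidence
    } else {
      expect_equal(got, want, tolerance = 1e-10,
                   info = sprintf("seed %d, n %d", seed, n))
    }
  }
})

test_that("posteriors are invariant to the elimination order", {
  mod <- random_model(10, p_edge = 0.35, seed = 42)
  nodes <- mod$graph$nodes
  ev <- stats::setNames(c(TRUE, FALSE), nodes[c(2, 5)])
  query <- nodes[1]
  base <- posterior(mod, query, ev)$p_true
  set.seed(7)
  for (i in 1:5) {
    ord <- sample(setdiff(nodes, c(query, names(ev))))
    expect_equal(posterior(mod, query, ev, order = ord)$p_true, base,
                 tolerance = 1e-10)
  }
})

test_that("degenerate and consistent evidence behave as specified", {
  m <- hand_chain()
  # conditioning on a probability-one event changes nothing
  sure <- make_ground_truth(
    topology = data.frame(from = "X", to = "Y"),
    cpt_source = list(X = list(p = 1 - 1e-15),
                      Y = list(parents = "X", p = c(0.6, 0.2))),
    outcome = "none")
  expect_equal(posterior(sure, "Y", c(X = TRUE))$p_true,
               posterior(sure, "Y")$p_true, tolerance = 1e-10)
  # empty evidence equals the marginal
  expect_equal(posterior(m, "Y")$p_true, marginal_all(m)[["Y"]])
  expect_error(posterior(m, "X", c(X = TRUE)), "query node")
  expect_error(posterior(m, "Q"), "unknown node")
  # structurally impossible evidence errors
  det <- make_ground_truth(
    topology = data.frame(from = "X", to = "Y"),
    cpt_source = list(X = list(p = 0.5),
                      Y = list(parents = "X", p = c(0.9, 0.1))),
    outcome = "none")
  # force an exact zero: hand-edit the CPT
  det$cpts$Y$p <- c(1, 0)
  expect_error(posterior(det, "X", c(X = FALSE, Y = TRUE)), "query node")
  expect_error(posterior(det, "Q", c(Y = TRUE)), "unknown")
  det$cpts$X$p <- 1
  expect_error(posterior(det, "Y", c(X = FALSE)), "zero probability")
})

test_that("marginals and diagnostics agree with direct reasoning", {
  m <- hand_chain()
  marg <- marginal_all(m)
  expect_equal(marg[["X"]], 0.3)  # root marginal is its prior
  expect_equal(marg[["Y"]], 0.9 * 0.3 + 0.2 * 0.7)
  # two-node diagnostic via Bayes' rule by hand
  mo <- make_ground_truth(
    topology = data.frame(from = "X", to = "O"),
    cpt_source = list(X = list(p = 0.25),
                      O = list(parents = "X", p = c(0.8, 0.1))),
    outcome = "O")
  d <- diagnostic_probabilities(mo)
  expect_equal(d[["X"]], 0.8 * 0.25 / (0.8 * 0.25 + 0.1 * 0.75),
               tolerance = 1e-12)
  # a node disconnected from the outcome keeps its marginal
  iso <- make_ground_truth(
    topology = assemble_graph(data.frame(from = "X", to = "O"),
                              nodes = "W"),
    cpt_source = list(X = list(p = 0.25),
                      O = list(parents = "X", p = c(0.8, 0.1)),
                      W = list(p = 0.65)),
    outcome = "O")
  d2 <- diagnostic_probabilities(iso)
  expect_equal(d2[["W"]], 0.65, tolerance = 1e-12)
})
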