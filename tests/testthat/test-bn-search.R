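test_that("a fully blacklisted search returns the empty graph", {
  d <- rand_sem_data(3, 100, seed = 31)
  nodes <- names(d)
  all_pairs <- expand.grid(from = nodes, to = nodes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  cs <- constraint_set(nodes, blacklist = as.matrix(all_pairs))
  dag <- hill_climb(d, cs)
  expect_equal(nrow(dag_edges(dag)), 0L)
})

test_that("DAG enumeration counts match the labelled-DAG sequence", {
  d1 <- rand_sem_data(1, 50, seed = 32)
  ex1 <- exhaustive_search(d1)
  expect_equal(attr(ex1, "n_enumerated"), 1L)
  expect_equal(nrow(dag_edges(ex1)), 0L)
  d3 <- rand_sem_data(3, 50, seed = 33)
  expect_equal(attr(exhaustive_search(d3), "n_enumerated"), 25L)
  d4 <- rand_sem_data(4, 50, seed = 34)
  expect_equal(attr(exhaustive_search(d4), "n_enumerated"), 543L)
  d6 <- rand_sem_data(6, 20, seed = 35)
  expect_error(exhaustive_search(d6), "5 nodes")
})

test_that("whitelisted edges appear in every candidate and the optimum", {
  d <- rand_sem_data(3, 100, seed = 36)
  cs <- constraint_set(names(d), whitelist = cbind("V1", "V2"))
  ex <- exhaustive_search(d, cs)
  expect_true(ex$amat["V1", "V2"])
  expect_equal(attr(ex, "n_enumerated"), 8L)  # 25-DAG family pruned to V1->V2
  hc <- hill_climb(d, cs)
  expect_true(hc$amat["V1", "V2"])
})

test_that("random restarts recover the exhaustive optimum on seeded fixtures", {
  set.seed(99)
  for (s in 1:15) {
    p <- if (s %% 2) 3 else 4
    d <- rand_sem_data(p, 200, seed = 300 + s)
    hc <- hill_climb(d, restarts = 10)
    ex <- exhaustive_search(d)
    expect_lt(abs(attr(hc, "score") - attr(ex, "score")), 1e-9)
  }
})

test_that("a plain climb is a true local optimum bounded by the global one", {
  for (s in 1:10) {
    d <- rand_sem_data(4, 200, seed = 400 + s)
    hc <- hill_climb(d)
    ex <- exhaustive_search(d)
    expect_lte(attr(hc, "score"), attr(ex, "score") + 1e-9)
    # no single legal move improves the returned graph
    base <- network_score(hc, d)$total
    nodes <- hc$nodes
    amat <- hc$amat
    best_nb <- -Inf
    for (f in 1:4) for (t in 1:4) {
      if (f == t) next
      if (!amat[f, t] && !amat[t, f]) {
        a2 <- amat; a2[f, t] <- TRUE
        if (!anchorbn:::has_cycle(a2))
          best_nb <- max(best_nb, network_score(
            structure(list(nodes = nodes, amat = a2), class = "bn_dag"),
            d)$total)
      } else if (amat[f, t]) {
        a2 <- amat; a2[f, t] <- FALSE
        best_nb <- max(best_nb, network_score(
          structure(list(nodes = nodes, amat = a2), class = "bn_dag"),
          d)$total)
        a3 <- a2; a3[t, f] <- TRUE
        if (!anchorbn:::has_cycle(a3))
          best_nb <- max(best_nb, network_score(
            structure(list(nodes = nodes, amat = a3), class = "bn_dag"),
            d)$total)
      }
    }
    expect_lte(best_nb, base + 1e-9)
  }
})

test_that("scores are monotone along the climb and the result respects anchors", {
  d <- simulate_study1(study1_params(model = 1, beta_xy = 0.5), seed = 37)
  cs <- no_incoming(constraint_set(c("G", "Z", "X", "Y")), c("G", "Z"))
  dag <- hill_climb(d[, c("G", "Z", "X", "Y")], cs)
  traj <- attr(dag, "trajectory")
  expect_true(all(diff(traj) > 0))
  expect_false(any(dag$amat[, "G"]))
  expect_false(any(dag$amat[, "Z"]))
  expect_false(anchorbn:::has_cycle(dag$amat))
})

test_that("cached and uncached scores of the learned graph agree exactly", {
  d <- rand_sem_data(4, 150, seed = 38)
  dag <- hill_climb(d)
  expect_equal(attr(dag, "score"), network_score(dag, d)$total,
               tolerance = 1e-12)
})

test_that("constraint sets reject contradictions and cyclic whitelists", {
  expect_error(constraint_set(c("A", "B"), blacklist = cbind("A", "B"),
                              whitelist = cbind("A", "B")), "overlap")
  expect_error(constraint_set(c("A", "B"),
                              whitelist = rbind(c("A", "B"), c("B", "A"))),
               "cyclic")
  cs <- single_outgoing(constraint_set(c("S", "M", "Y")), "S", "M")
  expect_true(cs$white["S", "M"])
  expect_true(all(cs$black["S", c("S", "Y")]))
  expect_true(all(cs$black[c("M", "Y"), "S"]))
})
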