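# build an averaged_network by hand from directed counts
fake_net <- function(counts, B) {
  structure(list(nodes = rownames(counts), B = as.integer(B),
                 counts = counts, redraws = 0L),
            class = "averaged_network")
}

test_that("strength and direction are exact counting identities", {
  counts <- matrix(0L, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  counts["A", "B"] <- 80L; counts["B", "A"] <- 20L
  counts["B", "C"] <- 50L
  net <- fake_net(counts, 100)
  expect_equal(edge_strength(net, "A", "B"), 1)
  expect_equal(edge_direction(net, "A", "B"), 0.8)
  expect_equal(edge_probability(net, "A", "B"), 0.8)
  expect_equal(edge_strength(net, "B", "C"), 0.5)
  expect_equal(edge_direction(net, "B", "C"), 1)
  expect_true(is.na(edge_direction(net, "A", "C")))
  expect_equal(edge_direction(net, "A", "B") +
                 edge_direction(net, "B", "A"), 1)
})

test_that("an anchored strong effect appears in every bootstrap network", {
  set.seed(41)
  n <- 400
  x <- rnorm(n); y <- 0.9 * x + rnorm(n)
  d <- as_dataset(data.frame(X = x, Y = y))
  cs <- no_incoming(constraint_set(c("X", "Y")), "X")
  net <- bootstrap_average(d, cs, B = 50, seed = 5)
  expect_equal(edge_strength(net, "X", "Y"), 1)
  expect_equal(edge_direction(net, "X", "Y"), 1)
})

test_that("the study-scale default of 1000 bootstrap replicates is kept", {
  expect_equal(eval(formals(bootstrap_average)$B), 1000)
})

test_that("averaging is reproducible under a fixed seed", {
  d <- simulate_study1(study1_params(model = 1, beta_xy = 0.5, n = 300), 42)
  cs <- no_incoming(constraint_set(c("G", "X", "Y")), "G")
  n1 <- bootstrap_average(d[, c("G", "X", "Y")], cs, B = 25, seed = 77)
  n2 <- bootstrap_average(d[, c("G", "X", "Y")], cs, B = 25, seed = 77)
  expect_identical(n1$counts, n2$counts)
  n3 <- bootstrap_average(d[, c("G", "X", "Y")], cs, B = 25, seed = 78)
  expect_false(identical(n3$counts, n1$counts))
})

test_that("the L1 strength threshold matches a numerical-integration oracle", {
  strengths <- c(1, 1, 0.9, 0.1, 0.05)
  # oracle: integrate |ecdf(s) - ecdf(idealized s)| on a fine grid for
  # every candidate cut; idealized strengths collapse to 0 or 1 at the cut
  grid <- seq(0, 1, length.out = 20001)
  l1 <- function(cut) {
    ideal <- ifelse(strengths < cut, 0, 1)
    f1 <- ecdf(strengths)(grid); f2 <- ecdf(ideal)(grid)
    mean(abs(f1 - f2)[-length(grid)])
  }
  cands <- sort(unique(strengths))
  oracle <- cands[which.min(vapply(cands, l1, numeric(1)))]
  expect_equal(anchorbn:::l1_threshold(strengths), oracle)
})

test_that("degenerate strength profiles behave at the boundaries", {
  counts <- matrix(0L, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  counts["A", "B"] <- 100L; counts["B", "C"] <- 100L; counts["A", "C"] <- 100L
  net_all <- fake_net(counts, 100)
  expect_lte(edge_strength_threshold(net_all), 1)
  expect_equal(nrow(averaged_dag(net_all)), 3L)
  net_none <- fake_net(matrix(0L, 3, 3,
                              dimnames = rep(list(c("A", "B", "C")), 2)), 100)
  expect_equal(nrow(averaged_dag(net_none)), 0L)
  # threshold 1 with no edge at exactly 1
  counts2 <- matrix(0L, 2, 2, dimnames = rep(list(c("A", "B")), 2))
  counts2["A", "B"] <- 90L
  expect_equal(nrow(averaged_dag(fake_net(counts2, 100), threshold = 1)), 0L)
})

test_that("an exact 0.5 direction split is tie-broken canonically and flagged", {
  counts <- matrix(0L, 2, 2, dimnames = rep(list(c("A", "B")), 2))
  counts["A", "B"] <- 48L; counts["B", "A"] <- 48L
  tab <- averaged_dag(fake_net(counts, 100), threshold = 0.5)
  expect_equal(tab$from, "A")
  expect_equal(tab$to, "B")
  expect_true(tab$ambiguous)
  expect_equal(tab$strength, 0.96)
  expect_equal(tab$direction_prob, 0.5)
})

test_that("annotated edge tables carry strength and direction", {
  counts <- matrix(0L, 2, 2, dimnames = rep(list(c("A", "B")), 2))
  counts["A", "B"] <- 893L; counts["B", "A"] <- 67L
  tab <- averaged_dag(fake_net(counts, 1000), threshold = 0.9)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$strength, 0.96)
  expect_equal(tab$direction_prob, 893 / 960, tolerance = 1e-12)
})

test_that("score nodes keep exactly their whitelisted edge in every network", {
  set.seed(43)
  n <- 300
  sm <- rnorm(n); sy <- rnorm(n)
  m <- 0.5 * sm + rnorm(n)
  y <- 0.4 * m + 0.5 * sy + rnorm(n)
  d <- as_dataset(data.frame(SM = sm, SY = sy, M = m, Y = y))
  cs <- single_outgoing(single_outgoing(constraint_set(names(d)),
                                        "SM", "M"), "SY", "Y")
  net <- bootstrap_average(d, cs, B = 40, seed = 6)
  expect_equal(net$counts["SM", "M"], 40L)
  expect_equal(net$counts["SY", "Y"], 40L)
  expect_equal(sum(net$counts["SM", ]), 40L)
  expect_equal(sum(net$counts["SY", ]), 40L)
  expect_equal(sum(net$counts[, "SM"]), 0L)
  expect_equal(sum(net$counts[, "SY"]), 0L)
})

test_that("binary scenario C yields unit strengths for the strong edges", {
  for (s in c(2, 7)) {
    d <- simulate_study2(study2_scenario("C"), seed = s)
    cs <- no_incoming(constraint_set(names(d)), "Q")
    net <- bootstrap_average(d, cs, B = 150, seed = 50 + s)
    expect_equal(edge_strength(net, "Q", "Y"), 1)
    expect_equal(edge_strength(net, "Y", "W"), 1)
  }
})

test_that("degenerate resamples are redrawn, not fatal", {
  # a rare level forces some all-constant resamples
  set.seed(44)
  q <- c(rep(1L, 3), rep(0L, 37))
  y <- rbinom(40, 1, 0.3 + 0.4 * q)
  d <- as_dataset(data.frame(Q = q, Y = y), kind = "categorical")
  net <- bootstrap_average(d, B = 60, seed = 9)
  expect_equal(net$B, 60L)
  expect_gt(net$redraws, 0)
})
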