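test_that("an empty edge set gives identity precision and zero partials", {
  spec <- network_spec(p = 4, labels = letters[1:4],
                       communities = rep(c("x", "y"), each = 2),
                       within_density = 0, anchor_edges = NULL,
                       bridge_edges = NULL, backbone = FALSE)
  tn <- build_true_network(spec, seed = 1)
  expect_equal(tn$partial, matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4])))
  expect_equal(unname(tn$sigma), diag(4))
  expect_equal(tn$shrink, 1)
})

test_that("a single edge between two nodes gives marginal correlation equal to its weight", {
  spec <- network_spec(p = 2, labels = c("A", "B"), communities = c("x", "y"),
                       within_density = 0, anchor_edges = NULL,
                       bridge_edges = tibble::tibble(from = "A", to = "B",
                                                     weight = 0.3),
                       backbone = FALSE)
  tn <- build_true_network(spec, seed = 1)
  expect_equal(tn$sigma["A", "B"], 0.3, tolerance = 1e-12)
  expect_equal(tn$partial["A", "B"], 0.3, tolerance = 1e-12)
})

test_that("a 3-node chain matches the matrix-inversion oracle", {
  a <- 0.35; b <- 0.2
  spec <- network_spec(p = 3, labels = c("x", "y", "z"),
                       communities = c("c1", "c1", "c2"),
                       within_density = 0, anchor_edges =
                         tibble::tibble(from = "x", to = "y", weight = a),
                       bridge_edges = tibble::tibble(from = "y", to = "z",
                                                     weight = b),
                       backbone = FALSE)
  tn <- build_true_network(spec, seed = 1)
  # oracle: invert the unit-diagonal precision implied by the partials
  Omega <- diag(3)
  Omega[1, 2] <- Omega[2, 1] <- -a
  Omega[2, 3] <- Omega[3, 2] <- -b
  Sigma <- stats::cov2cor(solve(Omega))
  expect_equal(unname(tn$sigma), unname(Sigma), tolerance = 1e-12)
  # the non-adjacent marginal equals the product of the adjacent marginals
  expect_equal(tn$sigma["x", "z"], tn$sigma["x", "y"] * tn$sigma["y", "z"],
               tolerance = 1e-12)
})

test_that("non-PD planted weights are repaired by logged uniform shrinkage", {
  # equal partials of 0.7 on all three pairs are jointly infeasible
  spec <- network_spec(p = 3, labels = c("x", "y", "z"),
                       communities = c("c1", "c1", "c2"),
                       within_density = 0, anchor_edges = tibble::tibble(
                         from = c("x", "x", "y"), to = c("y", "z", "z"),
                         weight = c(0.7, 0.7, 0.7)),
                       bridge_edges = NULL, backbone = FALSE)
  tn <- build_true_network(spec, seed = 1)
  expect_lt(tn$shrink, 1)
  ev <- eigen(tn$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # shrunk partials keep their sign and relative size
  expect_gt(tn$partial["x", "y"], 0)
  expect_equal(tn$partial["x", "y"], tn$partial["y", "z"], tolerance = 1e-12)
})

test_that("ordinal sampling is deterministic under a seed and respects thresholds", {
  tn <- toy_truth(seed = 2)
  d1 <- sample_ordinal(tn, n = 200, seed = 9)
  d2 <- sample_ordinal(tn, n = 200, seed = 9)
  expect_identical(d1, d2)
  d3 <- sample_ordinal(tn, n = 200, seed = 10)
  expect_false(identical(d1, d3))
  expect_true(all(as.matrix(d1) %in% 0:3))
})

test_that("marginal category frequencies match the threshold-implied probabilities", {
  spec <- network_spec(p = 2, labels = c("A", "B"), communities = c("x", "y"),
                       within_density = 0, anchor_edges = NULL,
                       bridge_edges = NULL, backbone = FALSE)
  tn <- build_true_network(spec, seed = 1)
  th <- matrix(qnorm(c(0.3, 0.6, 0.85)), 3, 2)
  n <- 20000
  dat <- sample_ordinal(tn, n = n, thresholds = th, seed = 4)
  expected <- diff(c(0, 0.3, 0.6, 0.85, 1))
  for (col in names(dat)) {
    freq <- tabulate(dat[[col]] + 1, nbins = 4) / n
    # binomial sampling bound, ~4 SE
    expect_true(all(abs(freq - expected) <
                      4 * sqrt(expected * (1 - expected) / n)))
  }
})

test_that("independent items show near-zero pairwise polychoric correlations", {
  spec <- network_spec(p = 4, labels = letters[1:4],
                       communities = rep(c("x", "y"), each = 2),
                       within_density = 0, anchor_edges = NULL,
                       bridge_edges = NULL, backbone = FALSE)
  tn <- build_true_network(spec, seed = 1)
  dat <- sample_ordinal(tn, n = 5000, seed = 5)
  R <- correlation_matrix(dat, method = "polychoric", items = letters[1:4])
  expect_true(all(abs(R[upper.tri(R)]) < 0.05))
})

test_that("degenerate thresholds flag a constant column in metadata", {
  spec <- network_spec(p = 2, labels = c("A", "B"), communities = c("x", "y"),
                       within_density = 0, anchor_edges = NULL,
                       bridge_edges = NULL, backbone = FALSE)
  tn <- build_true_network(spec, seed = 1)
  th <- cbind(c(-12, -11, -10), qnorm(c(0.25, 0.5, 0.75)))
  dat <- sample_ordinal(tn, n = 100, thresholds = th, seed = 6)
  expect_equal(attr(dat, "degenerate"), "A")
  expect_true(all(dat$A == 3))
})

test_that("two-group sampling shares nodes, splits sizes, and refuses mismatches", {
  tn_a <- toy_truth(seed = 3)
  tn_b <- set_edge(tn_a, "A1", "S1", 0.25)
  both <- sample_two_groups(tn_a, tn_b, n_a = 120, n_b = 80, seed = 2)
  expect_equal(sum(both$group == "A"), 120)
  expect_equal(sum(both$group == "B"), 80)
  # same config twice with one seed -> groups differ (independent substreams)
  null_pair <- sample_two_groups(tn_a, tn_a, 60, 60, seed = 2)
  ga <- null_pair[null_pair$group == "A", 1:6]
  gb <- null_pair[null_pair$group == "B", 1:6]
  expect_false(identical(ga, gb))
  tn_other <- toy_truth(seed = 1, p = 4)
  expect_error(sample_two_groups(tn_a, tn_other, 50, 50), "node set")
  # degenerate n = 1 per group: downstream estimation refuses
  tiny <- sample_two_groups(tn_a, tn_a, 1, 1, seed = 3)
  expect_error(nct(tiny[tiny$group == "A", 1:6], tiny[tiny$group == "B", 1:6]),
               "at least 50")
})

test_that("true-network edge lists round-trip through the TSV export", {
  tn <- toy_truth(seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_true_edges(tn, path)
  el <- utils::read.delim(path)
  expect_true(all(c("from", "to", "weight") %in% names(el)))
  expect_equal(nrow(el), sum(tn$partial[upper.tri(tn$partial)] != 0))
  for (r in seq_len(nrow(el))) {
    expect_equal(el$weight[r], tn$partial[el$from[r], el$to[r]])
  }
})
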