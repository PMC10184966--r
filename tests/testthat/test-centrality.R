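test_that("expected influence is the signed row sum", {
  W <- triangle_weights()
  ei <- expected_influence(W)
  expect_equal(unname(ei), c(0.5, 0.1, 0.2))
  # empty network
  expect_equal(unname(expected_influence(matrix(0, 3, 3))), rep(0, 3))
  # adding a positive edge strictly increases the node's EI
  W2 <- W; W2["b", "c"] <- W2["c", "b"] <- 0.3
  expect_gt(expected_influence(W2)["b"], ei["b"])
  # linearity in the weights
  expect_equal(expected_influence(2.5 * W), 2.5 * ei)
  # two-step adds the neighbour term
  expect_equal(unname(expected_influence(W, two_step = TRUE)),
               unname(ei + as.numeric(W %*% ei)))
})

test_that("bridge EI sums cross-community weights and partitions total EI", {
  W <- triangle_weights()
  cm <- c(a = "anx", b = "anx", c = "slp")
  bei <- bridge_expected_influence(W, cm)
  expect_equal(unname(bei), c(0.3, -0.1, 0.2))
  # partition identity to machine precision
  within <- expected_influence(W) - bei
  expect_equal(bei + within, expected_influence(W), tolerance = 1e-15)
  # no cross-community edges -> all zero
  W0 <- W; W0["a", "c"] <- W0["c", "a"] <- 0; W0["b", "c"] <- W0["c", "b"] <- 0
  expect_equal(unname(bridge_expected_influence(W0, cm)), rep(0, 3))
  # a single bridge edge contributes its weight to both endpoints
  W1 <- matrix(0, 2, 2, dimnames = list(c("GAD.1", "PSQI.7"), c("GAD.1", "PSQI.7")))
  W1[1, 2] <- W1[2, 1] <- 0.16
  bei1 <- bridge_expected_influence(W1, c(GAD.1 = "anxiety", PSQI.7 = "sleep"))
  expect_equal(unname(bei1), c(0.16, 0.16))
  expect_error(bridge_expected_influence(W, c(a = "anx", b = "anx")), "community")
})

test_that("path centralities match the exhaustive oracle on small graphs", {
  fixtures <- list(triangle_weights(), star_weights(4), path_weights(),
                   random_weights(6, seed = 31), random_weights(7, seed = 32))
  for (W in fixtures) {
    got <- path_centralities(W)
    oracle <- brute_path_metrics(W)
    expect_equal(got$betweenness, oracle$betweenness, tolerance = 1e-10)
    expect_equal(got$closeness, oracle$closeness, tolerance = 1e-10)
  }
})

test_that("star and path graphs have the expected betweenness pattern", {
  s <- path_centralities(star_weights(4))
  expect_equal(s$betweenness[1], choose(4, 2))
  expect_equal(s$betweenness[-1], rep(0, 4))
  expect_true(all(s$closeness[1] > s$closeness[-1]))
  p <- path_centralities(path_weights())
  expect_equal(p$betweenness[2], 1)
})

test_that("predictability is the nodewise R^2 on network neighbours", {
  set.seed(41)
  n <- 600
  x1 <- rnorm(n); x2 <- rnorm(n)
  x3 <- 0.8 * x1 + 0.6 * x2          # exact linear combination of neighbours
  d <- data.frame(a = x1, b = x2, c = x3)
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "c"] <- W["c", "a"] <- 0.5
  W["b", "c"] <- W["c", "b"] <- 0.5
  pr <- predictability(d, as_net(W))
  expect_equal(pr$predictability[pr$node == "c"], 1, tolerance = 1e-12)
  # node with no neighbours -> 0
  W0 <- matrix(0, 3, 3, dimnames = dimnames(W))
  W0["a", "b"] <- W0["b", "a"] <- 0.3
  pr0 <- predictability(d, as_net(W0))
  expect_equal(pr0$predictability[pr0$node == "c"], 0)
  # pure noise -> near-zero average R^2
  dn <- as.data.frame(matrix(rnorm(3 * n), n, 3))
  names(dn) <- c("a", "b", "c")
  prn <- predictability(dn, as_net(W))
  expect_lt(attr(prn, "average"), 0.03)
})

test_that("predictability approaches the analytic value implied by the truth", {
  tn <- toy_truth(seed = 10)
  dat <- sample_ordinal(tn, n = 10000, seed = 14)
  # analytic R^2 of each latent node on all others: 1 - 1/(K_ii * Sigma_ii)
  K <- tn$precision
  analytic <- 1 - 1 / (diag(K) * diag(tn$sigma))
  net <- as_net(tn$partial, tn$communities)
  pr <- predictability(dat, net)
  # ordinal discretization attenuates; allow a generous one-sided gap
  expect_true(all(pr$predictability < analytic + 0.05))
  expect_gt(cor(pr$predictability, analytic), 0.8)
})

test_that("the centrality table carries all indices with community labels", {
  tn <- toy_truth(seed = 11)
  dat <- sample_ordinal(tn, n = 900, seed = 15)
  fit <- ebic_glasso(dat, cor_method = "pearson",
                     communities = tn$communities)
  ct <- centrality_table(fit, data = dat, z_score = TRUE)
  expect_s3_class(ct, "centrality_table")
  expect_equal(nrow(ct), 6)
  expect_true(all(c("node", "community", "ei", "bridge_ei", "strength",
                    "betweenness", "closeness", "predictability", "ei_z") %in%
                    names(ct)))
  expect_equal(ct$bridge_ei + (ct$ei - ct$bridge_ei), ct$ei, tolerance = 1e-15)
  # for an all-positive network EI equals strength
  if (all(fit$weights >= 0)) expect_equal(ct$ei, ct$strength)
})
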