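test_that("the edge bootstrap runs end-to-end at tiny B and is seed-reproducible", {
  tn <- toy_truth(seed = 21)
  dat <- sample_ordinal(tn, n = 300, seed = 22)
  b1 <- bootstrap_edges(dat, B = 2, seed = 5, cor_method = "pearson")
  expect_s3_class(b1, "edge_bootstrap")
  expect_equal(nrow(b1$edges), choose(6, 2))
  expect_true(all(b1$edges$ci_low <= b1$edges$ci_high))
  b2 <- bootstrap_edges(dat, B = 25, seed = 9, cor_method = "pearson")
  b3 <- bootstrap_edges(dat, B = 25, seed = 9, cor_method = "pearson")
  expect_identical(b2$edges, b3$edges)
  expect_identical(b2$edge_diff, b3$edge_diff)
  expect_identical(b2$ei_diff, b3$ei_diff)
  expect_true(isSymmetric(b2$edge_diff))
})

test_that("a strong edge's bootstrap interval excludes zero", {
  spec <- network_spec(p = 3, labels = c("A1", "A2", "S1"),
                       communities = c("anx", "anx", "slp"),
                       within_density = 0,
                       anchor_edges = tibble::tibble(from = "A1", to = "A2",
                                                     weight = 0.6),
                       bridge_edges = NULL, backbone = FALSE)
  tn <- build_true_network(spec, seed = 1)
  dat <- sample_ordinal(tn, n = 5000, seed = 23)
  bs <- bootstrap_edges(dat, B = 100, seed = 7, cor_method = "pearson")
  strong <- bs$edges[bs$edges$from == "A1" & bs$edges$to == "A2", ]
  expect_gt(strong$ci_low, 0)
})

test_that("duplicating the data keeps the point estimate and narrows the intervals", {
  tn <- toy_truth(seed = 24)
  dat <- sample_ordinal(tn, n = 400, seed = 25)
  doubled <- rbind(dat, dat)
  # identical correlations -> identical partials at a fixed penalty (the
  # EBIC-selected penalty itself shifts with n through the log n edge cost)
  S1 <- matrix(correlation_matrix(dat, method = "pearson"), 6, 6)
  S2 <- matrix(correlation_matrix(doubled, method = "pearson"), 6, 6)
  expect_equal(S2, S1, tolerance = 1e-12)
  g1 <- glasso_fit(S1, lambda = 0.05)
  g2 <- glasso_fit(S2, lambda = 0.05)
  expect_equal(g2$partial, g1$partial, tolerance = 1e-8)
  b1 <- bootstrap_edges(dat, B = 80, seed = 3, cor_method = "pearson")
  b2 <- bootstrap_edges(doubled, B = 80, seed = 3, cor_method = "pearson")
  expect_lt(mean(b2$edges$ci_high - b2$edges$ci_low),
            mean(b1$edges$ci_high - b1$edges$ci_low))
})

test_that("bootstrap edge intervals cover the generator truth at the nominal rate", {
  spec3 <- network_spec(p = 3, labels = c("A", "B", "C"),
                        communities = c("x", "x", "y"),
                        within_density = 0,
                        anchor_edges = tibble::tibble(from = "A", to = "B",
                                                      weight = 0.3),
                        bridge_edges = tibble::tibble(from = "B", to = "C",
                                                      weight = 0.25),
                        backbone = FALSE)
  tn3 <- build_true_network(spec3, seed = 1)
  tru <- tn3$partial[upper.tri(tn3$partial)]
  cover <- matrix(NA, 200, 3)
  for (r in 1:200) {
    dat <- sample_ordinal(tn3, 500, seed = 1000 + r)
    bs <- bootstrap_edges(dat, B = 100, seed = r, cor_method = "polychoric")
    cover[r, ] <- bs$edges$ci_low <= tru & tru <= bs$edges$ci_high
  }
  coverage <- mean(cover)
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.99)
})

test_that("CS coefficients follow the grid semantics and threshold monotonicity", {
  record <- tidyr::expand_grid(index = "ei", drop = c(0.1, 0.25, 0.5, 0.75),
                               replicate = 1:20)
  # correlations degrade with drop: all pass at 0.10/0.25, fail later
  record$correlation <- dplyr::case_when(
    record$drop <= 0.25 ~ 0.95,
    record$drop == 0.5 ~ ifelse(record$replicate <= 18, 0.85, 0.3),
    TRUE ~ 0.5
  )
  expect_equal(cs_from_record(record, 0.7, 0.95)$cs_coefficient, 0.25)
  # at 90% target the 0.5 level passes too
  expect_equal(cs_from_record(record, 0.7, 0.90)$cs_coefficient, 0.5)
  # raising the threshold can only lower CS
  cs_05 <- cs_from_record(record, 0.5, 0.95)$cs_coefficient
  cs_07 <- cs_from_record(record, 0.7, 0.95)$cs_coefficient
  expect_gte(cs_05, cs_07)
  # a failed low level breaks the run even if higher levels pass
  record2 <- record
  record2$correlation[record2$drop == 0.1] <- 0.2
  expect_equal(cs_from_record(record2, 0.7, 0.95)$cs_coefficient, 0)
})

test_that("case-dropping bootstrap is reproducible and structured data stay stable", {
  tn <- toy_truth(seed = 26)
  dat <- sample_ordinal(tn, n = 2000, seed = 27)
  cs1 <- case_drop_cs(dat, indices = "ei", drop_grid = c(0.1, 0.5), B = 20,
                      seed = 4, cor_method = "pearson")
  cs2 <- case_drop_cs(dat, indices = "ei", drop_grid = c(0.1, 0.5), B = 20,
                      seed = 4, cor_method = "pearson")
  expect_identical(cs1$record, cs2$record)
  expect_s3_class(tidy(cs1), "tbl_df")
  expect_true(cs1$cs$cs_coefficient %in% c(0, 0.1, 0.5))
  expect_error(case_drop_cs(dat[1:60, ], drop_grid = c(0.5), B = 5), "fewer than 50")
})
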