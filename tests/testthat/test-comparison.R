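test_that("identical groups give zero structure difference and p-values of 1", {
  tn <- toy_truth(seed = 28)
  dat <- sample_ordinal(tn, n = 200, seed = 31)
  res <- nct(dat, dat, n_perm = 50, seed = 2)
  expect_equal(res$m_stat, 0)
  expect_equal(res$s_stat, 0)
  expect_equal(res$p_m, 1)
  expect_equal(res$p_s, 1)
})

test_that("swapping the group labels leaves all statistics and p-values unchanged", {
  tn <- toy_truth(seed = 33)
  dat <- sample_two_groups(tn, tn, 150, 150, seed = 3)
  a <- dat[dat$group == "A", 1:6]
  b <- dat[dat$group == "B", 1:6]
  r1 <- nct(a, b, n_perm = 200, seed = 9)
  r2 <- nct(b, a, n_perm = 200, seed = 9)
  # the statistics are symmetric in |.|, so they swap exactly
  expect_equal(r1$m_stat, r2$m_stat)
  expect_equal(r1$s_stat, r2$s_stat)
  expect_equal(abs(r1$edge_tests$diff), abs(r2$edge_tests$diff))
  # the permutation draws select different pooled rows after the swap, so the
  # p-values agree up to Monte-Carlo error
  expect_equal(r1$p_m, r2$p_m, tolerance = 0.12)
  expect_equal(r1$p_s, r2$p_s, tolerance = 0.12)
})

test_that("global p-values use the add-one convention; edge p-values can hit zero", {
  tn <- toy_truth(seed = 34)
  tn_b <- set_edge(tn, "A1", "S1", 0.45)
  dat <- sample_two_groups(tn, tn_b, 1500, 1500, seed = 4)
  res <- nct(dat[dat$group == "A", 1:6], dat[dat$group == "B", 1:6],
             n_perm = 100, seed = 5)
  # add-one floor for the global tests
  expect_gte(res$p_m, 1 / 101)
  expect_gte(res$p_s, 1 / 101)
  # the planted strong difference dominates every permutation
  et <- res$edge_tests
  expect_equal(et$p_raw[et$from == "A1" & et$to == "S1"], 0)
  expect_true(all(et$p_holm >= et$p_raw, na.rm = TRUE))
})

test_that("Holm adjustment matches a brute-force step-down implementation", {
  set.seed(6)
  for (i in 1:5) {
    p <- runif(sample(3:10, 1))
    expect_equal(p.adjust(p, method = "holm"), brute_holm(p), tolerance = 1e-12)
  }
  tn <- toy_truth(seed = 35)
  dat <- sample_two_groups(tn, tn, 100, 100, seed = 7)
  res <- nct(dat[dat$group == "A", 1:6], dat[dat$group == "B", 1:6],
             n_perm = 60, seed = 8)
  expect_equal(res$edge_tests$p_holm, brute_holm(res$edge_tests$p_raw),
               tolerance = 1e-12)
})

test_that("the observed-edge family restricts the Holm correction", {
  tn <- toy_truth(seed = 36)
  dat <- sample_two_groups(tn, tn, 400, 400, seed = 9)
  res <- nct(dat[dat$group == "A", 1:6], dat[dat$group == "B", 1:6],
             n_perm = 40, seed = 10, edge_family = "observed")
  et <- res$edge_tests
  expect_true(any(!et$in_family) || all(et$in_family))
  expect_true(all(is.na(et$p_holm[!et$in_family])))
  expect_equal(et$p_holm[et$in_family], brute_holm(et$p_raw[et$in_family]),
               tolerance = 1e-12)
})

test_that("the spearman fallback loop agrees with its own add-one contract", {
  tn <- toy_truth(seed = 37)
  dat <- sample_two_groups(tn, tn, 120, 120, seed = 11)
  res <- nct(dat[dat$group == "A", 1:6], dat[dat$group == "B", 1:6],
             n_perm = 30, seed = 12, cor_method = "spearman")
  expect_equal(length(res$m_perm), 30)
  expect_gte(res$p_m, 1 / 31)
  expect_lte(res$p_m, 1)
})

test_that("group splitting follows an explicit rule and guards small arms", {
  set.seed(13)
  d <- data.frame(x = rnorm(300),
                  edu = sample(c("primary", "secondary", "university", NA),
                               300, replace = TRUE))
  rule <- c(primary = "below", secondary = "below", university = "above")
  arms <- group_split_arms(d, "edu", rule)
  expect_named(arms, c("below", "above"))
  n_mapped <- sum(!is.na(d$edu))
  expect_equal(nrow(arms$below) + nrow(arms$above), n_mapped)
  expect_true(all(arms$above$edu == "university"))

  d$one <- "all_same"
  expect_error(group_split_arms(d, "one", c(all_same = "A")), "two arms")
  d$rare <- c(rep("big", 290), rep("small", 10))
  expect_error(group_split_arms(d, "rare", c(big = "A", small = "B")), "< 50")
  expect_error(group_split_arms(d, "nope", rule), "not in data")
})
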