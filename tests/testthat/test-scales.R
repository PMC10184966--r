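test_that("GAD-7 scoring sums items and applies the >= 5 cutoff", {
  expect_equal(score_gad7(rep(0, 7))$gad_total, 0L)
  expect_false(score_gad7(rep(0, 7))$anxiety)
  expect_equal(score_gad7(rep(3, 7))$gad_total, 21L)
  expect_true(score_gad7(rep(3, 7))$anxiety)
  # boundary: 5 flags, 4 does not
  expect_true(score_gad7(c(1, 1, 1, 1, 1, 0, 0))$anxiety)
  expect_false(score_gad7(c(1, 1, 1, 1, 0, 0, 0))$anxiety)

  df <- data.frame(matrix(rep(1, 14), 2, 7))
  names(df) <- paste0("gad", 1:7)
  out <- score_gad7(df)
  expect_s3_class(out, "tbl_df")
  expect_equal(out$gad_total, c(7L, 7L))
})

test_that("PSQI scoring applies the poor-sleep (> 7) and clinical (>= 10) cutoffs", {
  z <- score_psqi(rep(0, 7))
  expect_equal(z$psqi_global, 0L)
  expect_false(z$poor_sleep)
  expect_false(z$clinical_sleep)
  ten <- score_psqi(c(2, 2, 2, 2, 1, 0, 1))
  expect_equal(ten$psqi_global, 10L)
  expect_true(ten$clinical_sleep)
  eight <- score_psqi(c(1, 1, 1, 1, 1, 1, 2))
  expect_equal(eight$psqi_global, 8L)
  expect_true(eight$poor_sleep)
  expect_false(eight$clinical_sleep)
  seven <- score_psqi(c(1, 1, 1, 1, 1, 1, 1))
  expect_false(seven$poor_sleep)
})

test_that("item validation names the offending item", {
  bad <- data.frame(matrix(1, 1, 7)); names(bad) <- paste0("gad", 1:7)
  bad$gad3 <- 4
  expect_error(score_gad7(bad), "gad3")
  bad$gad3 <- NA
  expect_error(score_gad7(bad), "gad3")
  expect_error(score_gad7(c(1, 1, 1)), "7 item")
})

test_that("totals are invariant to item order", {
  set.seed(11)
  items <- sample(0:3, 7, replace = TRUE)
  perm <- sample(7)
  expect_equal(score_gad7(items)$gad_total, score_gad7(items[perm])$gad_total)
  expect_equal(score_psqi(items)$psqi_global, score_psqi(items[perm])$psqi_global)
})

test_that("descriptives match hand-computed moments and an independent oracle", {
  d <- data.frame(x = c(0, 0, 3, 3), y = c(0, 0, 0, 3), z = c(2, 2, 2, 2))
  out <- describe_items(d, items = c("x", "y", "z"))
  expect_equal(out$mean[1], 1.5)
  expect_equal(out$sd[1], sqrt(3))
  expect_equal(out$skewness[1], 0)
  expect_gt(out$skewness[2], 0)
  # constant column: SD 0, undefined higher moments, no error
  expect_equal(out$sd[3], 0)
  expect_true(is.na(out$skewness[3]))
  expect_true(is.na(out$kurtosis[3]))

  skip_if_not_installed("e1071")
  set.seed(3)
  x <- sample(0:3, 200, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  row <- describe_items(data.frame(v = x), items = "v")
  expect_equal(row$skewness, e1071::skewness(x, type = 2), tolerance = 1e-12)
  expect_equal(row$kurtosis, e1071::kurtosis(x, type = 2), tolerance = 1e-12)
})

test_that("prevalence intervals are Wald by default and clip to [0, 1]", {
  pe <- prevalence_ci(5, 10)
  expect_equal(pe$proportion, 0.5)
  expect_equal(pe$ci_high - pe$proportion, 0.3099, tolerance = 1e-4)
  expect_equal(pe$proportion - pe$ci_low, 0.3099, tolerance = 1e-4)
  zero <- prevalence_ci(0, 100)
  expect_equal(zero$proportion, 0)
  expect_equal(zero$ci_low, 0)
  expect_error(prevalence_ci(5, 0))
  expect_error(prevalence_ci(11, 10))
  # Wilson stays inside (0, 1) without clipping
  w <- prevalence_ci(0, 100, method = "wilson")
  expect_gte(w$ci_low, 0)
  expect_gt(w$ci_high, 0)
})

test_that("prevalence CI width shrinks like 1/sqrt(n)", {
  widths <- vapply(c(100, 400, 1600), function(n) {
    pe <- prevalence_ci(round(0.3 * n), n)
    pe$ci_high - pe$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.01)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.01)
})

test_that("group rates use the column-wise convention and sum to the flagged total", {
  d <- data.frame(
    anx = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    g = c("a", "a", "b", "b", NA)
  )
  gr <- group_rates(d, "anx", "g")
  expect_setequal(gr$group, c("a", "b", "Missing"))
  expect_equal(sum(gr$count), sum(d$anx))
  expect_equal(gr$count[gr$group == "a"], 2L)
  expect_equal(gr$percent[gr$group == "Missing"], 25)
  # single group -> 100%; two equal groups -> 50/50
  one <- group_rates(data.frame(f = c(TRUE, TRUE), g = c("x", "x")), "f", "g")
  expect_equal(one$percent, 100)
  two <- group_rates(data.frame(f = rep(TRUE, 4), g = c("x", "x", "y", "y")),
                     "f", "g")
  expect_equal(sort(two$percent), c(50, 50))
})
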