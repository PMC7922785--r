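test_that("pearson_r matches the direct covariance formula", {
  crit <- c(1, 2, 3, 4, 5)
  test <- c(2.2, 1.4, 4.1, 3.3, 7.2)
  # brute-force product-moment formula
  r_direct <- sum((crit - mean(crit)) * (test - mean(test))) /
    sqrt(sum((crit - mean(crit))^2) * sum((test - mean(test))^2))
  got <- pearson_r(crit, test)
  expect_equal(got$r, r_direct, tolerance = 1e-12)
  expect_equal(pearson_r(crit, crit)$r, 1)
  expect_equal(pearson_r(crit, -crit)$r, -1)
  expect_error(pearson_r(crit, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("mean differences reproduce the published free-living and lab cells", {
  # group means in, criterion - test out
  expect_equal(mean_difference(c(237.1, 237.1), c(242.8, 242.8))$mean_diff,
               -5.7, tolerance = 1e-9)
  expect_equal(mean_difference(c(15.3, 15.3), c(8.5, 8.5))$mean_diff,
               6.8, tolerance = 1e-9)
  ident <- mean_difference(c(3, 4, 5), c(3, 4, 5))
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$se_diff, 0)
})

test_that("MAPE is the participant-level mean absolute percent error", {
  expect_equal(mape(c(10, 20), c(10, 20)), 0)
  expect_equal(mape(c(10, 20, 30), 1.1 * c(10, 20, 30)), 10,
               tolerance = 1e-12)
  expect_equal(mape(c(10, 20), c(5, 30)), 50)
  expect_warning(v <- mape(c(10, 0), c(5, 3)), "zero criterion")
  expect_equal(v, 50)
  expect_error(mape(c(0, 0), c(1, 2)), "undefined")
  # mape == 0 iff all pairs identical
  expect_gt(mape(c(10, 20), c(10, 21)), 0)
})

test_that("Bland-Altman limits follow bias +/- 1.96 SD and mirror under sign flip", {
  ba <- bland_altman(c(2, 4), c(3, 3)) # differences -1, 1
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$points$mean, c(2.5, 3.5))
  same <- bland_altman(c(5, 7, 9), c(4, 6, 8))
  expect_equal(same$loa_high - same$loa_low, 0)
  set.seed(1)
  crit <- rnorm(20, 100, 10); test <- rnorm(20, 95, 12)
  a <- bland_altman(crit, test)
  b <- bland_altman(test, crit) # swap = sign flip of all differences
  expect_equal(a$bias, -b$bias)
  expect_equal(a$loa_high - a$loa_low, b$loa_high - b$loa_low)
  # bias is identically the paired mean difference
  expect_equal(a$bias, mean_difference(crit, test)$mean_diff)
})

test_that("the t-based 90% CI matches hand computation and covers the mean", {
  ci <- ci90_mean(c(1, 2, 3, 4))
  half <- 2.3534 * sd(1:4) / 2 # t(0.95, 3) = 2.3534
  expect_equal(unname(ci["low"]), 2.5 - half, tolerance = 1e-4)
  expect_equal(unname(ci["high"]), 2.5 + half, tolerance = 1e-4)
  const <- ci90_mean(rep(7, 5))
  expect_equal(unname(const), c(7, 7))
  set.seed(3)
  for (i in 1:20) {
    v <- rnorm(sample(2:30, 1))
    ci <- ci90_mean(v)
    expect_true(ci["low"] <= mean(v) && mean(v) <= ci["high"])
  }
})

test_that("minimum equivalence zones reproduce hand-checkable cases", {
  expect_equal(minimum_equivalence_zone(100, 90, 105)$ez_pct, 10)
  ez <- minimum_equivalence_zone(100, 100, 100)
  expect_equal(ez$ez_pct, 0)
  expect_equal(ez$ez_low, 100)
  ez2 <- minimum_equivalence_zone(38.6, 29.51, 40.7)
  expect_equal(ez2$ez_pct, 23.6)
  expect_equal(ez2$ez_low, 38.6 * (1 - 0.236), tolerance = 1e-9)
  expect_error(minimum_equivalence_zone(-1, 0, 1), "positive")
  expect_error(minimum_equivalence_zone(0, 0, 0), "positive")
})

test_that("equivalence_at certifies containment and minimality", {
  expect_true(equivalence_at(237.1, 198.18, 275.7, 16.5))
  expect_false(equivalence_at(237.1, 198.18, 275.7, 16.4))
  expect_true(equivalence_at(50, 10, 90, 100)) # CI within [0, 2 * mean]
})

test_that("agreement statistics are invariant to participant ordering", {
  set.seed(17)
  crit <- rnorm(15, 200, 30); test <- crit + rnorm(15, -5, 10)
  perm <- sample(15)
  a <- validate_methods(tibble::tibble(criterion = crit, test = test))
  b <- validate_methods(tibble::tibble(criterion = crit[perm],
                                       test = test[perm]))
  expect_equal(tidy(a), tidy(b), tolerance = 1e-12)
})

test_that("the agreement object supports tidy, glance, autoplot and NA fallback", {
  pairs <- tibble::tibble(
    class = rep(c("SED", "MVPA"), each = 5),
    criterion = c(200, 220, 250, 210, 190, 30, 25, 40, 35, 20),
    test = c(195, 225, 245, 205, 200, 33, 22, 41, 30, 24)
  )
  fit <- validate_methods(pairs)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_true(all(c("r", "mape", "ba_bias", "ez_pct") %in% names(td)))
  expect_equal(td$ba_bias, td$mean_diff)
  gl <- glance(fit)
  expect_equal(gl$n_pairs, 10)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  # single participant: SE-based cells are NA rather than errors
  solo <- validate_methods(tibble::tibble(criterion = 100, test = 90))
  expect_true(is.na(tidy(solo)$r))
  expect_true(is.na(tidy(solo)$se_diff))
  expect_equal(tidy(solo)$mape, 10)
})
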