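# Independent naive oracles for every statistic, written from the defining
# formulas only.
naive <- list(
  accuracy = function(m, a) 100 - mean(abs(m - a) / abs(a)) * 100,
  rmse = function(m, a) sqrt(sum((a - m)^2) / length(m)),
  r = function(m, a) {
    mm <- mean(m); ma <- mean(a)
    sum((m - mm) * (a - ma)) /
      sqrt(sum((m - mm)^2) * sum((a - ma)^2))
  },
  t = function(m, a) {
    d <- m - a; n <- length(d)
    tt <- mean(d) / (stats::sd(d) / sqrt(n))
    list(t = tt, p = 2 * stats::pt(-abs(tt), n - 1))
  },
  ba = function(m, a) {
    d <- m - a
    s <- sqrt(sum((d - mean(d))^2) / (length(d) - 1))
    c(mean(d), mean(d) - 1.96 * s, mean(d) + 1.96 * s)
  })

test_that("statistics match the naive closed forms on random fixtures", {
  set.seed(33)
  for (rep in 1:10) {
    a <- stats::rnorm(20, 1, 0.3)
    m <- a * stats::runif(1, 0.8, 1.2) + stats::rnorm(20, 0, 0.1)
    expect_equal(accuracy_mape(m, a), naive$accuracy(m, a), tolerance = 1e-12)
    expect_equal(rmse(m, a), naive$rmse(m, a), tolerance = 1e-12)
    pr <- pearson_r(m, a)
    expect_equal(pr$r, naive$r(m, a), tolerance = 1e-12)
    tt <- paired_t(m, a)
    or <- naive$t(m, a)
    expect_equal(tt$t, or$t, tolerance = 1e-12)
    expect_equal(tt$p, or$p, tolerance = 1e-12)
    ba <- bland_altman(m, a)
    expect_equal(c(ba$mean_diff, ba$loa_low, ba$loa_high), naive$ba(m, a),
                 tolerance = 1e-12)
    expect_equal(ba$mean_diff, mean(m) - mean(a), tolerance = 1e-12)
  }
})

test_that("identical systems give the identity statistics exactly", {
  x <- c(1.1, 0.9, 1.3, 1.0, 1.2)
  expect_equal(accuracy_mape(x, x), 100)
  expect_equal(rmse(x, x), 0)
  expect_equal(pearson_r(x, x)$r, 1)
  tt <- paired_t(x, x)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
})

test_that("accuracy follows the 100 - MAPE arithmetic", {
  a <- c(1.0, 1.0, 1.0)
  expect_equal(accuracy_mape(1.1 * a, a), 90)
  expect_equal(accuracy_mape(c(1.0, 0.9, 1.2), a), 90)  # (0+10+20)/3 = 10%
  # scale invariance
  m <- c(1.05, 0.97, 1.1)
  expect_equal(accuracy_mape(7 * m, 7 * a), accuracy_mape(m, a))
  expect_error(accuracy_mape(c(1, 1), c(1, 0)), "pair 2")
})

test_that("rmse is homogeneous and matches hand arithmetic", {
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(25 / 2))
  expect_equal(rmse(c(3, 4), c(0, 0)), 3.5355339, tolerance = 1e-7)
  m <- c(1, 2, 3); a <- c(1.5, 1.8, 3.3)
  expect_equal(rmse(3 * m, 3 * a), 3 * rmse(m, a))
})

test_that("pearson r is invariant to positive affine transforms", {
  set.seed(4)
  m <- stats::rnorm(15); a <- m + stats::rnorm(15, 0, 0.5)
  expect_equal(pearson_r(2 * m + 5, a)$r, pearson_r(m, a)$r, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "3 pairs")
})

test_that("paired t handles degenerate difference patterns", {
  d <- c(0.1, -0.1, 0.1, -0.1, 0.1, -0.1)
  base <- stats::rnorm(6)
  expect_equal(paired_t(base + d, base)$t, 0, tolerance = 1e-9)
  expect_error(paired_t(base + 1, base), "degenerate")
  expect_error(paired_t(1, 1), "2 pairs")
})

test_that("Bland-Altman limits and coverage behave as specified", {
  base <- c(1, 2, 3, 4)
  ba_const <- bland_altman(base + 0.3, base)
  expect_equal(ba_const$mean_diff, 0.3)
  expect_equal(ba_const$loa_low, 0.3)
  expect_equal(ba_const$loa_high, 0.3)
  # diffs (-1, +1): sample SD sqrt(2), LoA +-1.96*sqrt(2)
  ba2 <- bland_altman(c(0, 2), c(1, 1))
  expect_equal(ba2$mean_diff, 0)
  expect_equal(ba2$loa_high, 1.96 * sqrt(2))
  expect_equal(ba2$loa_high, 2.7718586, tolerance = 1e-7)
  set.seed(77)
  a <- stats::rnorm(1000, 10, 1)
  m <- a + stats::rnorm(1000, 0.2, 0.5)
  frac <- bland_altman(m, a)$inside_fraction
  expect_gte(frac, 0.93)
  expect_lte(frac, 0.97)
})

test_that("KS normality check separates normal from exponential data", {
  set.seed(12)
  x <- stats::rnorm(1000)
  expect_gt(ks_normality(x), 0.05)
  y <- stats::rexp(1000)
  expect_lt(ks_normality(y), 0.001)
  expect_lt(ks_normality(y, variant = "classic"), 0.001)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "5 values")
})

test_that("agreement table pools groups and flags correlation significance", {
  set.seed(8)
  pairs <- do.call(rbind, lapply(c("stride_length", "cadence"), function(p) {
    a <- stats::rnorm(30, 1, 0.2)
    data.frame(parameter = p, group = rep(c("stroke", "healthy"), each = 15),
               measured = a, actual = a, stringsAsFactors = FALSE)
  }))
  tab <- agreement_table(pairs)
  expect_setequal(tab$group, c("all", "stroke", "healthy"))
  expect_true(all(tab$accuracy_pct == 100))
  expect_true(all(abs(tab$pearson_r - 1) < 1e-12))
  expect_true(all(tab$rmse == 0))
  expect_true(all(tab$t_p == 1))
  expect_true(all(tab$r_significant))
  # permuting group labels leaves the pooled rows unchanged
  perm <- pairs
  perm$group <- sample(perm$group)
  tab_p <- agreement_table(perm)
  expect_equal(tab_p[tab_p$group == "all", ], tab[tab$group == "all", ],
               ignore_attr = TRUE)
  # undersized cells are omitted with a warning per empty cell
  small <- pairs[c(1:30, 31), ]
  warns <- capture_warnings(tab_s <- agreement_table(small))
  expect_true(any(grepl("omitted", warns)))
  expect_false(any(tab_s$parameter == "cadence" & tab_s$group == "healthy"))
})
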