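test_that("one_way_anova matches hand computation and the formula oracle", {
  av <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(av$F, 13.5)
  expect_equal(av$df_between, 1L)
  expect_equal(av$df_within, 4L)
  # identical groups: F = 0, p = 1
  av0 <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(av0$F, 0)
  expect_equal(av0$p, 1)
  # constant identical groups degenerate to F = 0
  avc <- one_way_anova(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(avc$F, 0)
  set.seed(81)
  for (i in 1:200) {
    g <- rep(letters[1:sample(2:4, 1)], each = sample(3:6, 1))
    v <- rnorm(length(g), as.integer(factor(g)), 1)
    got <- one_way_anova(v, g)
    want <- oracle_anova(v, g)
    expect_equal(got$F, want$F)
    expect_equal(got$p, want$p)
  }
  expect_error(one_way_anova(1:2, c("a", "b")), class = "ect_invalid_input")
})

test_that("tukey_hsd controls pairs via the studentized range", {
  # two identical groups: adjusted p = 1, no rejection
  hsd0 <- tukey_hsd(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(hsd0$p_adj, 1, tolerance = 1e-8)
  expect_false(any(hsd0$reject))
  # with exactly two groups the decision agrees with the pooled t test
  set.seed(82)
  for (i in 1:25) {
    v <- c(rnorm(6, 0), rnorm(6, runif(1, 0, 3)))
    g <- rep(c("a", "b"), each = 6)
    hsd <- tukey_hsd(v, g)
    tt <- t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
    # ptukey is evaluated by numerical quadrature; allow its ~1e-8 accuracy
    expect_equal(hsd$p_adj, tt$p.value, tolerance = 1e-6)
  }
  # one far-shifted group: only its two pairs rejected
  set.seed(83)
  v <- c(rnorm(8, 0, 0.5), rnorm(8, 0, 0.5), rnorm(8, 50, 0.5))
  g <- rep(c("a", "b", "c"), each = 8)
  hsd <- tukey_hsd(v, g)
  involving_c <- hsd$group1 == "c" | hsd$group2 == "c"
  expect_true(all(hsd$reject[involving_c]))
  expect_false(any(hsd$reject[!involving_c]))
})

test_that("two_way_anova uses type-II sums of squares with interaction", {
  # balanced design: type II equals the classical sequential decomposition
  set.seed(84)
  a <- rep(rep(c("a1", "a2"), each = 6), 2)
  b <- rep(c("b1", "b2"), each = 12)
  y <- rnorm(24, 2 * (a == "a2") + 1 * (b == "b2"))
  res <- two_way_anova(y, a, b)
  seq_aov <- anova(lm(y ~ factor(a) * factor(b)))
  expect_equal(res$ss[1:3], seq_aov$`Sum Sq`[1:3], tolerance = 1e-9)
  expect_equal(res$F[1:3], seq_aov$`F value`[1:3], tolerance = 1e-9)
  expect_equal(res$p[1:3], seq_aov$`Pr(>F)`[1:3], tolerance = 1e-9)
  # injected main effect on A only: F_A dominates, interaction stays null
  set.seed(85)
  pa <- replicate(60, {
    a <- rep(rep(c("a1", "a2"), each = 5), 2)
    b <- rep(c("b1", "b2"), each = 10)
    y <- rnorm(20, 3 * (a == "a2"))
    r <- two_way_anova(y, a, b)
    c(r$F[1], r$p[3])
  })
  expect_true(mean(pa[1, ] > 10) > 0.9) # strong A effect detected
  expect_gt(mean(pa[2, ]), 0.3) # interaction p roughly uniform
  # empty cell is named in the error
  expect_error(
    two_way_anova(1:6, c("a", "a", "a", "b", "b", "b"), c("x", "x", "y", "x", "x", "x")),
    "b x y"
  )
})

test_that("chi_squared_contingency matches the direct formula", {
  r0 <- chi_squared_contingency(matrix(10, 2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  tab <- matrix(c(20, 10, 10, 20), 2)
  expect_equal(chi_squared_contingency(tab)$statistic, 5.4)
  expect_equal(chi_squared_contingency(tab, yates = FALSE)$statistic, 20 / 3)
  set.seed(86)
  for (i in 1:50) {
    t3 <- matrix(sample(5:40, 6), 2, 3)
    got <- chi_squared_contingency(t3)
    expect_equal(got$statistic, oracle_chisq(t3)) # no correction beyond 2x2
    expect_equal(got$df, 2L)
  }
  expect_error(chi_squared_contingency(matrix(c(0, 0, 5, 5), 2)),
    class = "ect_invalid_input")
})

test_that("linear_fit matches the normal-equation oracle", {
  lf <- linear_fit(c(0, 1, 2), c(0, 2, 4))
  expect_equal(lf$slope, 2)
  expect_equal(lf$intercept, 0, tolerance = 1e-12)
  expect_equal(lf$r, 1)
  cst <- linear_fit(c(0, 1, 2, 3), rep(5, 4))
  expect_equal(cst$slope, 0)
  expect_equal(cst$r, 0)
  set.seed(87)
  for (i in 1:200) {
    x <- rnorm(sample(5:20, 1))
    y <- 2 * x + rnorm(length(x))
    got <- linear_fit(x, y)
    want <- oracle_linfit(x, y)
    expect_equal(got$slope, want$slope)
    expect_equal(got$intercept, want$intercept)
  }
  expect_error(linear_fit(rep(1, 5), rnorm(5)), class = "ect_invalid_input")
})

test_that("t_test_bonferroni multiplies and caps the p value", {
  same <- list(list(treatment = c(1, 2, 3), control = c(1, 2, 3)))
  r <- t_test_bonferroni(same, m = 44)
  expect_equal(r$t, 0)
  expect_equal(r$p_adj, 1)
  set.seed(88)
  comps <- lapply(1:6, function(i) {
    list(treatment = rnorm(5, i / 2), control = rnorm(5))
  })
  res <- t_test_bonferroni(comps, m = 44)
  expect_true(all(res$p_adj >= res$p_raw))
  expect_true(all(res$p_adj <= 1))
  expect_equal(res$p_adj, pmin(1, 44 * res$p_raw))
  # matches the pooled t test directly
  tt <- t.test(comps[[1]]$treatment, comps[[1]]$control, var.equal = TRUE)
  expect_equal(res$t[1], unname(tt$statistic))
  expect_error(t_test_bonferroni(comps, m = 2), class = "ect_invalid_input")
})

test_that("weighted_clone_mean and delta_delta_ct follow their formulas", {
  expect_equal(weighted_clone_mean(c(10, 20), c(95, 5)), 10.5)
  expect_equal(weighted_clone_mean(c(3, 7, 11), rep(2, 3)), mean(c(3, 7, 11)))
  expect_equal(
    weighted_clone_mean(c(3, 7), c(1, 3)),
    weighted_clone_mean(c(3, 7), c(10, 30))
  )
  expect_error(weighted_clone_mean(numeric(0), numeric(0)), class = "ect_invalid_input")

  rec <- data.frame(
    sample = c("t1", "c1"), group = c("treated", "control"),
    ct_target = c(22, 20), ct_reference = c(15, 15)
  )
  out <- delta_delta_ct(rec, "control")
  expect_equal(out$fold_change[out$group == "treated"], 0.25)
  expect_equal(out$fold_change[out$group == "control"], 1)
  # fold strictly decreasing in ct_target
  rec2 <- rec
  rec2$ct_target[1] <- 23
  expect_lt(delta_delta_ct(rec2, "control")$fold_change[1], 0.25)
  expect_error(delta_delta_ct(rec, "vehicle"), class = "ect_invalid_input")
})
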