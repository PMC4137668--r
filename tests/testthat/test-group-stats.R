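test_that("pearson_chi2 matches closed forms and the stats oracle", {
  expect_equal(pearson_chi2(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  res <- pearson_chi2(rbind(c(20, 0), c(0, 20)))
  expect_equal(res$statistic, 40)
  expect_equal(res$df, 1L)

  # 4x3 laterality-by-age-group shaped table vs chisq.test and a loop oracle
  tab <- contingency_table(rbind(c(26, 6, 4), c(12, 3, 5), c(12, 2, 3),
                                 c(9, 2, 3)))
  got <- pearson_chi2(tab)
  ora <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_lt(abs(got$statistic - unname(ora$statistic)), 1e-9)
  expect_equal(got$df, unname(ora$parameter))
  loop <- 0
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  for (i in 1:4) for (j in 1:3) {
    e <- rs[i] * cs[j] / n
    loop <- loop + (tab[i, j] - e)^2 / e
  }
  expect_lt(abs(got$statistic - loop), 1e-9)

  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "degenerate margin")
  expect_error(contingency_table(rbind(c(-1, 2), c(1, 2))), "non-negative")
})

test_that("linear_by_linear reproduces the trend statistic and its oracle", {
  tab <- rbind(typical = c(29, 9, 8), impaired = c(3, 4, 4))
  res <- linear_by_linear(tab)
  expect_equal(res$df, 1L)
  expect_lt(abs(res$statistic - 4.03), 0.005)

  expect_equal(linear_by_linear(rbind(c(5, 7), c(5, 7)))$statistic, 0)

  # expansion oracle: (N-1) * cor over N scored individuals
  set.seed(61)
  for (i in 1:8) {
    t2 <- matrix(rpois(6, 8) + 1, 2, 3)
    got <- linear_by_linear(t2)$statistic
    rows <- rep(rep(1:2, 3), as.vector(t2))
    cols <- rep(rep(1:3, each = 2), as.vector(t2))
    expect_lt(abs(got - (sum(t2) - 1) * cor(rows, cols)^2), 1e-9)
  }
  expect_error(linear_by_linear(rbind(c(3, 0, 0))), "zero variance")
})

test_that("linear_by_linear is invariant to affine scores and transposition", {
  tab <- rbind(c(29, 9, 8), c(3, 4, 4))
  base <- linear_by_linear(tab)$statistic
  expect_equal(linear_by_linear(tab, row_scores = c(10, 30),
                                col_scores = c(-1, 1, 3))$statistic, base)
  expect_equal(linear_by_linear(t(tab))$statistic, base)
  expect_equal(pearson_chi2(t(tab))$statistic, pearson_chi2(tab)$statistic)
})

test_that("one_sample_t reproduces the in-paper summary tests", {
  imp <- one_sample_t(mean = -0.2, sd = 3.31, n = 11)
  expect_equal(round(imp$t, 2), -0.20)
  expect_equal(imp$df, 10)
  expect_gt(imp$p, 0.8)

  typ <- one_sample_t(mean = 2.2, sd = 3.95, n = 46)
  expect_lt(abs(typ$t - 3.78), 0.005)
  expect_equal(typ$df, 45)

  expect_equal(one_sample_t(mean = 5, sd = 2, n = 10, mu0 = 5)$t, 0)

  set.seed(62)
  x <- rnorm(20, 1)
  got <- one_sample_t(x)
  ora <- stats::t.test(x)
  expect_lt(abs(got$t - unname(ora$statistic)), 1e-9)
  expect_lt(abs(got$p - ora$p.value), 1e-12)

  expect_error(one_sample_t(mean = 1, sd = 0, n = 5), "infinite")
})

test_that("two_sample_t, oneway_anova and rank tests match base-R oracles", {
  set.seed(63)
  x <- rnorm(15, 0.5); y <- rnorm(12)
  got <- two_sample_t(x, y)
  ora <- stats::t.test(x, y, var.equal = TRUE)
  expect_lt(abs(got$t - unname(ora$statistic)), 1e-9)
  expect_lt(abs(got$p - ora$p.value), 1e-12)
  gw <- two_sample_t(x, y, var_equal = FALSE)
  ow <- stats::t.test(x, y)
  expect_lt(abs(gw$t - unname(ow$statistic)), 1e-9)
  expect_lt(abs(gw$df - unname(ow$parameter)), 1e-9)
  expect_equal(two_sample_t(x, x)$t, 0)

  groups <- list(rnorm(10), rnorm(12, 0.3), rnorm(9, 0.6), rnorm(11))
  ga <- oneway_anova(groups)
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(seq_along(groups), lengths(groups))))
  oa <- anova(stats::lm(y ~ g, df))
  expect_lt(abs(ga$F - oa$`F value`[1]), 1e-9)
  expect_lt(abs(ga$p - oa$`Pr(>F)`[1]), 1e-12)
  expect_equal(oneway_anova(list(x, x))$F, 0)

  # hand-countable rank sum
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$W, 6)
  # tie-corrected z^2 equals the Kruskal-Wallis statistic for two groups
  xr <- c(rnorm(14), 1, 1); yr <- c(rnorm(10), 1)
  gm <- mann_whitney(xr, yr)
  kw <- stats::kruskal.test(list(xr, yr))
  expect_lt(abs(gm$z^2 - unname(kw$statistic)), 1e-9)
  expect_error(mann_whitney(rep(1, 4), rep(1, 3)), "tied")
})

test_that("correlations match cor.test", {
  set.seed(64)
  x <- rnorm(25); y <- 0.4 * x + rnorm(25)
  gp <- pearson_r(x, y)
  op <- stats::cor.test(x, y)
  expect_lt(abs(gp$r - unname(op$estimate)), 1e-12)
  expect_lt(abs(gp$p - op$p.value), 1e-12)
  gs <- spearman_rho(x, y)
  os <- stats::cor.test(x, y, method = "spearman")
  expect_lt(abs(gs$rho - unname(os$estimate)), 1e-12)
})

test_that("icc_oddeven behaves across agreement structure", {
  perfect <- cbind(1:4, 1:4)
  expect_equal(icc_oddeven(perfect)$icc, 1)

  # no pairing structure -> ICC near zero on a large simulated cohort
  set.seed(65)
  a <- rnorm(400, 0, 3)
  none <- cbind(a, sample(a))
  expect_lt(abs(icc_oddeven(none)$icc), 0.15)

  # cohort with true SD 3, split noise SD 1: population ICC = 9/10; at
  # n = 36 the estimate spreads roughly +/- 0.05, so individual estimates
  # get a generous band and the 10-seed mean a tight one
  iccs <- vapply(1:10, function(s) {
    set.seed(70 + s)
    li <- rnorm(36, 2, 3)
    pairs <- cbind(li + rnorm(36), li + rnorm(36))
    res <- icc_oddeven(pairs)
    expect_true(res$ci[1] < res$icc && res$icc < res$ci[2])
    res$icc
  }, numeric(1))
  expect_true(all(iccs > 0.75 & iccs < 0.99))
  expect_gt(mean(iccs), 0.85)
  expect_lt(mean(iccs), 0.95)

  # consistency form matches an aov-based oracle
  set.seed(66)
  m <- cbind(rnorm(20, 0, 2), rnorm(20, 0, 2)) + rnorm(20, 0, 3)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(1:20, 2)), rater = factor(rep(1:2, each = 20)))
  ms <- anova(stats::lm(y ~ subj + rater, d))$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_c <- icc_oddeven(m, form = "consistency")$icc
  expect_lt(abs(icc_c - (msr - mse) / (msr + mse)), 1e-9)
  icc_a <- icc_oddeven(m)$icc
  expect_lt(abs(icc_a - (msr - mse) /
                  (msr + mse + 2 / 20 * (msc - mse))), 1e-9)
})

test_that("handedness quotients follow the stated formulas and are odd", {
  expect_equal(ehi_quotient(handedness_record(9, 0, 21, 21)), 100)
  expect_equal(ehi_quotient(handedness_record(0, 9, 0, 21)), -100)
  expect_equal(ehi_quotient(handedness_record(5, 4, 10, 21)), 100 / 9)
  expect_equal(qhp_lq(handedness_record(5, 4, 21, 21)), 0.5)
  expect_equal(qhp_lq(handedness_record(5, 4, 0, 21)), -0.5)
  expect_equal(qhp_lq(handedness_record(5, 4, 10, 20)), 0)
  # odd under left/right exchange
  for (r in 0:9) {
    h <- handedness_record(r, 9 - r, r, 9)
    hm <- handedness_record(9 - r, r, 9 - r, 9)
    expect_equal(ehi_quotient(h), -ehi_quotient(hm))
    expect_equal(qhp_lq(h), -qhp_lq(hm))
  }
  expect_error(ehi_quotient(handedness_record(0, 0, 1, 2)), "undefined")
})

test_that("language-status classification uses a strict threshold", {
  expect_true(classify_language_status(c(-1.2, -1.5, 0, 0, 0, 0)))
  expect_false(classify_language_status(c(-1.2, 0, 0, 0, 0, 0)))
  expect_false(classify_language_status(c(-1.0, -1.0, 0, 0, 0, 0)))
  expect_error(classify_language_status(numeric()), "no language measures")
})

test_that("subgroup labels cross the two booleans", {
  expect_equal(subgroup_label(TRUE, FALSE), "late_bloomer")
  expect_equal(subgroup_label(FALSE, TRUE), "plateau")
  expect_equal(subgroup_label(FALSE, FALSE), "typical")
  expect_equal(subgroup_label(TRUE, TRUE), "persistent_sli")
})

test_that("composite language score has the right moments and recovers a factor", {
  set.seed(67)
  # degenerate: six copies of one column
  col <- rnorm(30, 50, 8)
  comp <- composite_language_score(matrix(col, 30, 6))
  expect_lt(abs(mean(comp) - 100), 1e-9)
  expect_lt(abs(sd(comp) - 15), 1e-9)
  expect_gt(cor(comp, col), 0.999)

  x <- matrix(rnorm(40 * 6), 40, 6)
  comp2 <- composite_language_score(x)
  expect_lt(abs(mean(comp2) - 100), 1e-9)
  expect_lt(abs(sd(comp2) - 15), 1e-9)

  # one-factor model, loadings 0.8, noise variance 0.36
  f <- rnorm(200)
  obs <- sapply(1:6, function(j) 0.8 * f + rnorm(200, 0, 0.6))
  comp3 <- composite_language_score(obs)
  expect_gt(cor(comp3, f), 0.95)

  expect_error(composite_language_score(matrix(1:12, 2, 6)), "more subjects")
})

test_that("laterality_table reports counts and percentages", {
  cats <- c(rep("left", 26), rep("bilateral", 6), rep("right", 4))
  tab <- laterality_table(cats)
  expect_equal(unname(tab$counts), c(26L, 6L, 4L))
  expect_equal(unname(round(tab$percent["left"])), 72)
  expect_equal(tab$n, 36L)
  tab2 <- laterality_table(c(cats, "insufficient"))
  expect_equal(tab2$n_insufficient, 1L)
  expect_equal(tab2$n, 36L)
})

test_that("one_sample_t holds its nominal size under the null", {
  set.seed(68)
  reps <- 2000
  p <- replicate(reps, one_sample_t(rnorm(30))$p)
  rate <- mean(p <= 0.05)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
  expect_true(all(p >= 0 & p <= 1))
})
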