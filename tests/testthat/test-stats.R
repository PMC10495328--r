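# Statistics: paired t, ICC, repeated-measures ANOVA + Mauchly, Friedman +
# Wilcoxon post-hocs, McNemar. Independent oracles: closed-form t CDF,
# stats::anova.mlm / stats::mauchly.test, exhaustive permutation enumeration,
# binomial enumeration.

test_that("paired t matches the closed-form t distribution and handles degeneracies", {
  d <- c(1, 2, 3, 4)
  res <- paired_t(d, rep(0, 4))
  t_oracle <- mean(d) / (sd(d) / 2)
  p_oracle <- 2 * (1 - pt(abs(t_oracle), df = 3))
  expect_equal(as.numeric(res$statistic), t_oracle, tolerance = 1e-9)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-9)
  # agreement with stats::t.test on random data
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(10)
    y <- rnorm(10)
    tt <- t.test(x, y, paired = TRUE)
    res <- paired_t(x, y)
    expect_equal(as.numeric(res$statistic), unname(tt$statistic), tolerance = 1e-9)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
  }
  expect_equal(paired_t(1:5, 1:5)$p_value, 1)
  expect_equal(paired_t(1:5 + 3, 1:5)$p_value, 0)
  expect_error(paired_t(1, 1), "insufficient")
})

test_that("ICC(3,1) is 1 on duplicated ratings and recovers variance components", {
  x <- rnorm(20)
  expect_equal(as.numeric(icc_agreement(cbind(x, x))$statistic), 1)
  # subject variance 9, error variance 1 => ICC = 0.9
  set.seed(5)
  subj <- rnorm(500, 0, 3)
  m <- cbind(subj + rnorm(500), subj + rnorm(500))
  expect_equal(as.numeric(icc_agreement(m)$statistic), 0.9, tolerance = 0.05)
  # no subject effect => ICC near 0
  m0 <- cbind(rnorm(500), rnorm(500))
  expect_lt(abs(as.numeric(icc_agreement(m0)$statistic)), 0.1)
  expect_error(icc_agreement(matrix(1, 5, 2)), "zero total variance")
  expect_error(icc_agreement(matrix(rnorm(4), 2, 2)), ">= 3 subjects")
})

test_that("repeated-measures ANOVA agrees with stats::anova.mlm", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    k <- sample(3:4, 1)
    m <- matrix(rnorm(n * k, sd = 2), n, k) + rnorm(n)
    res <- rm_anova(m)
    fit <- lm(m ~ 1)
    idata <- data.frame(cond = factor(seq_len(k)))
    av <- anova(fit, idata = idata, X = ~1, M = ~cond, test = "Spherical")
    expect_equal(as.numeric(res$statistic), av$F[1], tolerance = 1e-8)
    expect_equal(res$p_value, av$`Pr(>F)`[1], tolerance = 1e-8)
    mt <- mauchly.test(fit, idata = idata, X = ~1, M = ~cond)
    expect_equal(res$mauchly$W, unname(mt$statistic), tolerance = 1e-8)
    expect_equal(res$mauchly$p_value, mt$p.value, tolerance = 1e-8)
  }
})

test_that("k = 2 repeated-measures F equals the squared paired t statistic", {
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(12)
    y <- rnorm(12)
    f <- as.numeric(rm_anova(cbind(x, y))$statistic)
    t2 <- as.numeric(paired_t(x, y)$statistic)^2
    expect_equal(f, t2, tolerance = 1e-9)
  }
})

test_that("repeated-measures ANOVA degenerate and post-hoc behavior", {
  m <- matrix(rep(c(1, 2, 3), each = 3), 3, 3) * 0 + 5
  res <- rm_anova(m)
  expect_equal(as.numeric(res$statistic), 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$posthoc, "NA")
  # strong designed effect flags the right directions
  set.seed(6)
  base <- rnorm(16)
  m2 <- cbind(
    crown = base + 2 + rnorm(16, 0, 0.5),
    root1 = base + rnorm(16, 0, 0.5),
    root2 = base + rnorm(16, 0, 0.5)
  )
  res2 <- rm_anova(m2)
  expect_lt(res2$p_value, 0.05)
  expect_match(res2$posthoc, "^a > b,c$")
  # detection power for a 2-unit shift at sd 1, n = 16
  hits <- 0
  for (r in 1:200) {
    mm <- cbind(rnorm(16), rnorm(16), rnorm(16) + 2)
    if (rm_anova(mm)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("Friedman p equals exhaustive within-row permutation enumeration", {
  set.seed(10)
  m <- matrix(rnorm(15), 5, 3)
  res <- friedman_wilcoxon(m)
  expect_true(res$exact)
  # independent oracle: enumerate all (3!)^5 permutation assignments and
  # recompute the statistic with stats::friedman.test each time
  perms <- rbind(
    c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
  )
  obs <- unname(friedman.test(m)$statistic)
  idx <- expand.grid(1:6, 1:6, 1:6, 1:6, 1:6)
  stats_all <- apply(idx, 1, function(sel) {
    mm <- m
    for (r in 1:5) mm[r, ] <- m[r, perms[sel[r], ]]
    unname(friedman.test(mm)$statistic)
  })
  p_oracle <- mean(stats_all >= obs - 1e-12)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-9)
  expect_equal(as.numeric(res$statistic), obs, tolerance = 1e-9)
})

test_that("Friedman handles ties, identical columns, and large-n asymptotics", {
  m <- matrix(5, 8, 3)
  res <- friedman_wilcoxon(m)
  expect_equal(as.numeric(res$statistic), 0)
  expect_equal(res$p_value, 1)
  # large n falls back to the tie-corrected chi-square approximation
  set.seed(11)
  m2 <- matrix(sample(1:4, 90, TRUE), 30, 3)
  res2 <- friedman_wilcoxon(m2)
  expect_false(res2$exact)
  ft <- friedman.test(m2)
  expect_equal(as.numeric(res2$statistic), unname(ft$statistic), tolerance = 1e-9)
  expect_equal(res2$p_value, ft$p.value, tolerance = 1e-9)
})

test_that("Wilcoxon post-hocs flag a uniformly shifted condition after Bonferroni", {
  set.seed(12)
  base <- matrix(rnorm(32), 16, 2)
  m <- cbind(a = base[, 1], b = base[, 2], c = base[, 1] + 1)
  res <- friedman_wilcoxon(m)
  pw <- res$pairwise
  expect_lt(pw$p_adjusted[pw$from == "a" & pw$to == "c"], 0.05)
  expect_true(all(pw$p_adjusted >= pw$p_value))
  expect_true(all(pw$p_adjusted <= 1))
})

test_that("exact McNemar matches the binomial enumeration", {
  res <- mcnemar_paired(18, 0)
  expect_equal(res$p_value, 2 * 0.5^18, tolerance = 1e-12)
  expect_lt(res$p_value, 0.001) # the printed bound for 18 vs 0 discordance
  expect_equal(mcnemar_paired(0, 0)$p_value, 1)
  p_oracle <- 2 * sum(choose(15, 10:15)) / 2^15
  expect_equal(mcnemar_paired(10, 5)$p_value, p_oracle, tolerance = 1e-4)
  expect_equal(mcnemar_paired(5, 10)$p_value, mcnemar_paired(10, 5)$p_value)
  # above the exact limit: continuity-corrected chi-square
  res_big <- mcnemar_paired(30, 10)
  mt <- mcnemar.test(matrix(c(0, 30, 10, 0), 2, 2))
  expect_equal(res_big$p_value, mt$p.value, tolerance = 1e-9)
})

test_that("statistics are invariant under subject permutation", {
  set.seed(13)
  m <- matrix(rnorm(48), 16, 3)
  perm <- sample(16)
  expect_equal(rm_anova(m)$p_value, rm_anova(m[perm, ])$p_value, tolerance = 1e-12)
  expect_equal(
    friedman_wilcoxon(m)$p_value, friedman_wilcoxon(m[perm, ])$p_value,
    tolerance = 1e-12
  )
})

test_that("pooling gate pools iff no location shows a left/right difference", {
  set.seed(14)
  df <- tidyr::expand_grid(patient = sprintf("P%02d", 1:16), location = 1:7) %>%
    dplyr::mutate(left = rnorm(dplyr::n()), right = rnorm(dplyr::n())) %>%
    tidyr::pivot_longer(c("left", "right"), names_to = "side", values_to = "value")
  gate <- pool_left_right(df)
  expect_equal(nrow(gate$gate), 7)
  # identical sides: zero-variance differences give p = 1, pooled
  df_same <- df %>%
    tidyr::pivot_wider(names_from = "side", values_from = "value") %>%
    dplyr::mutate(right = .data$left) %>%
    tidyr::pivot_longer(c("left", "right"), names_to = "side", values_to = "value")
  g1 <- pool_left_right(df_same)
  expect_true(g1$pooled)
  expect_true(all(g1$gate$p == 1))
  # deterministic 3-degree offset: p = 0, not pooled
  df_off <- df %>%
    tidyr::pivot_wider(names_from = "side", values_from = "value") %>%
    dplyr::mutate(right = .data$left + 3) %>%
    tidyr::pivot_longer(c("left", "right"), names_to = "side", values_to = "value")
  g2 <- pool_left_right(df_off)
  expect_false(g2$pooled)
  expect_true(all(g2$gate$p == 0))
  # gate p matches the closed-form t CDF
  one <- df[df$location == 1, ]
  wide <- tidyr::pivot_wider(one, names_from = "side", values_from = "value")
  d <- wide$left - wide$right
  t_o <- mean(d) / (sd(d) / sqrt(length(d)))
  p_o <- 2 * (1 - pt(abs(t_o), length(d) - 1))
  expect_equal(gate$gate$p[gate$gate$location == 1], p_o, tolerance = 1e-9)
  expect_error(
    pool_left_right(df[df$patient == "P01", ]),
    "insufficient"
  )
})
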