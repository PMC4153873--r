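t1 <- table1_data()

test_that("p-value adjustment matches the definitional examples", {
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "bonferroni"),
               c(0.03, 0.12, 0.09))
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "holm"),
               c(0.03, 0.06, 0.06))
  expect_equal(adjust_pvalues(c(0.5, 0.6), "bonferroni"), c(1, 1))
  expect_error(adjust_pvalues(c(0.1, 1.2), "holm"), "\\[0, 1\\]")
})

test_that("adjustments match brute-force oracles and order among themselves", {
  set.seed(7)
  for (rep in 1:50) {
    p <- runif(sample(2:12, 1))
    bf <- adjust_pvalues(p, "bonferroni")
    hm <- adjust_pvalues(p, "holm")
    expect_equal(bf, brute_bonferroni(p), tolerance = 1e-12)
    expect_equal(hm, brute_holm(p), tolerance = 1e-12)
    expect_true(all(hm <= bf + 1e-12))
    expect_true(all(hm >= p - 1e-12) && all(bf >= p - 1e-12))
    expect_true(all(bf <= 1) && all(hm <= 1))
  }
})

test_that("LSD reproduces the reconstructed cholesterol comparison", {
  rs <- t1$summaries$Cholesterol
  a <- anova_from_summary(rs)
  # MSE reconstructed from the printed SEMs: mean of 6 * SEM_i^2
  expect_equal(a$mse, mean(6 * c(0.23, 0.24, 0.13)^2), tolerance = 1e-12)
  m <- lsd_test(rs, a, alpha = 0.05, adjust = "none")
  pair <- m$comparisons[m$comparisons$label_i == "4" &
                        m$comparisons$label_j == "8", ]
  expect_equal(pair$statistic, 0.71 / sqrt(a$mse * (2 / 6)), tolerance = 1e-12)
  expect_equal(pair$statistic, 2.44, tolerance = 0.01)
  expect_equal(pair$p_raw, 2 * pt(-abs(pair$statistic), 15), tolerance = 1e-12)
  expect_equal(pair$p_raw, 0.028, tolerance = 0.01)
  expect_true(pair$significant)
})

test_that("LSD basics: identical means give p = 1; bonferroni scales every pair", {
  rs <- response_summary("y", c("a", "b", "c"), 5, c(4, 4, 6), c(1, 1, 1), "SD")
  a <- anova_from_summary(rs)
  m0 <- lsd_test(rs, a)
  ab <- m0$comparisons[1, ]
  expect_equal(ab$statistic, 0)
  expect_equal(ab$p_raw, 1)
  expect_false(ab$significant)

  mb <- lsd_test(rs, a, adjust = "bonferroni")
  expect_equal(mb$comparisons$p_adjusted,
               pmin(1, 3 * m0$comparisons$p_raw), tolerance = 1e-12)
})

test_that("Tukey-Kramer reproduces the arginine decisions and q statistics", {
  rs <- t1$summaries$Arginine
  a <- anova_from_summary(rs)
  m <- tukey_kramer(rs, a, alpha = 0.05)
  cmp <- m$comparisons
  key <- paste(cmp$label_i, cmp$label_j)
  q <- cmp$statistic[match(c("0 4", "0 8", "4 8"), key)]
  expect_equal(q, abs(c(-5, -39, -34)) / sqrt(154 / 6), tolerance = 1e-12)
  expect_equal(round(q, 2), c(0.99, 7.70, 6.71))
  expect_equal(cmp$significant[match(c("0 4", "0 8", "4 8"), key)],
               c(FALSE, TRUE, TRUE))
})

test_that("Tukey-Kramer agrees with TukeyHSD on raw data and with LSD at k = 2", {
  set.seed(13)
  for (rep in 1:10) {
    k <- sample(3:5, 1)
    d <- random_raw(k, n = sample(4:9, k, replace = TRUE))
    rs <- summarize_raw(d$fac, d$y)
    a <- anova_from_summary(rs)
    m <- tukey_kramer(rs, a)
    ref <- TukeyHSD(aov(d$y ~ factor(d$fac)))[[1]]
    key_ref <- rownames(ref)
    for (r in seq_len(nrow(m$comparisons))) {
      cmp <- m$comparisons[r, ]
      nm1 <- paste0(cmp$label_j, "-", cmp$label_i)
      nm2 <- paste0(cmp$label_i, "-", cmp$label_j)
      i <- match(nm1, key_ref); flip <- -1
      if (is.na(i)) { i <- match(nm2, key_ref); flip <- 1 }
      expect_equal(cmp$estimate * flip, unname(ref[i, "diff"]),
                   tolerance = 1e-8)
      expect_equal(cmp$p_adjusted, unname(ref[i, "p adj"]), tolerance = 1e-6)
    }
  }
  # k = 2: single pair, TK p equals the unadjusted LSD p (q = sqrt(2) |t|)
  for (rep in 1:10) {
    d <- random_raw(2, n = sample(3:8, 2, replace = TRUE))
    rs <- summarize_raw(d$fac, d$y)
    a <- anova_from_summary(rs)
    expect_lt(abs(tukey_kramer(rs, a)$comparisons$p_adjusted -
                  lsd_test(rs, a)$comparisons$p_raw), 1e-8)
  }
})

test_that("TK adjusted p never falls below the unadjusted LSD p", {
  set.seed(17)
  for (rep in 1:30) {
    rs <- random_summary(sample(2:6, 1), balanced = sample(c(TRUE, FALSE), 1))
    a <- anova_from_summary(rs)
    expect_true(all(tukey_kramer(rs, a)$comparisons$p_adjusted >=
                    lsd_test(rs, a)$comparisons$p_raw - 1e-12))
  }
})

test_that("SNK reproduces the cholesterol stepwise decisions", {
  rs <- t1$summaries$Cholesterol
  a <- anova_from_summary(rs)
  m <- snk_test(rs, a, alpha = 0.05)
  cmp <- m$comparisons
  key <- paste(cmp$label_i, cmp$label_j)
  # (5.18, 4.94) span 2 not significant; (4.94, 4.23) span 2 significant;
  # (5.18, 4.23) span 3 significant
  expect_equal(cmp$span[match(c("0 4", "4 8", "0 8"), key)], c(2L, 2L, 3L))
  expect_equal(cmp$significant[match(c("0 4", "4 8", "0 8"), key)],
               c(FALSE, TRUE, TRUE))
  se <- sqrt(a$mse / 6)
  expect_equal(cmp$critical_range[match("0 4", key)],
               qtukey(0.95, 2, 15) * se, tolerance = 1e-12)
  expect_equal(cmp$critical_range[match("0 8", key)],
               qtukey(0.95, 3, 15) * se, tolerance = 1e-12)
})

test_that("SNK blocking suppresses all pairs when the widest span fails", {
  rs <- t1$summaries$Adiponectin
  a <- anova_from_summary(rs)
  q_max <- (2.94 - 2.64) / sqrt(a$mse / 6)
  expect_equal(q_max, 2.93, tolerance = 0.01)
  expect_lt(q_max, qtukey(0.95, 3, 15))
  m <- snk_test(rs, a)
  expect_false(any(m$comparisons$significant))
  # the span-2 pairs were never tested: blocked by the failed widest span
  expect_false(any(m$relation))
})

test_that("at two groups SNK matches the unadjusted LSD decision", {
  set.seed(19)
  for (rep in 1:20) {
    rs <- random_summary(2, balanced = sample(c(TRUE, FALSE), 1))
    a <- anova_from_summary(rs)
    expect_identical(snk_test(rs, a)$comparisons$significant,
                     lsd_test(rs, a)$comparisons$significant)
  }
})

test_that("Duncan protection levels relax with span and nest SNK decisions", {
  expect_equal(1 - 0.95^2, 0.0975)  # alpha_r at r = 3, alpha = 0.05
  rs <- t1$summaries$Cholesterol
  a <- anova_from_summary(rs)
  m <- duncan_test(rs, a, alpha = 0.05)
  cmp <- m$comparisons
  r3 <- cmp[cmp$span == 3L, ]
  expect_equal(r3$critical_range,
               qtukey(1 - 0.0975, 3, 15) * sqrt(a$mse / 6), tolerance = 1e-12)
  # at span 2 Duncan equals SNK
  snk <- snk_test(rs, a)
  expect_equal(cmp$critical_range[cmp$span == 2L],
               snk$comparisons$critical_range[snk$comparisons$span == 2L])

  set.seed(23)
  for (rep in 1:40) {
    rs <- random_summary(sample(3:6, 1), balanced = TRUE)
    a <- anova_from_summary(rs)
    s_snk <- sig_pairs(snk_test(rs, a))
    s_dc <- sig_pairs(duncan_test(rs, a))
    expect_true(all(s_snk %in% s_dc))
  }
})

test_that("every method returns a symmetric relation consistent with its decisions", {
  set.seed(29)
  for (rep in 1:15) {
    rs <- random_summary(sample(2:5, 1), balanced = sample(c(TRUE, FALSE), 1))
    a <- anova_from_summary(rs)
    for (m in list(lsd_test(rs, a, adjust = "holm"), tukey_kramer(rs, a),
                   snk_test(rs, a), duncan_test(rs, a))) {
      expect_true(all(m$relation == t(m$relation)))
      expect_false(any(diag(m$relation)))
      for (r in seq_len(nrow(m$comparisons)))
        expect_identical(m$relation[m$comparisons$label_i[r],
                                    m$comparisons$label_j[r]],
                         m$comparisons$significant[r])
    }
  }
})

test_that("decisions are invariant to the input order of groups", {
  set.seed(37)
  for (rep in 1:10) {
    rs <- random_summary(4, balanced = sample(c(TRUE, FALSE), 1))
    perm <- sample(4)
    g <- rs$groups[perm, ]
    rs_p <- response_summary("y", g$label, g$n, g$mean, g$dispersion, "SD")
    for (test_fn in list(lsd_test, tukey_kramer, snk_test, duncan_test)) {
      m1 <- test_fn(rs, anova_from_summary(rs))
      m2 <- test_fn(rs_p, anova_from_summary(rs_p))
      lab <- rs$groups$label
      expect_equal(m1$relation[lab, lab], m2$relation[lab, lab])
    }
  }
})

test_that("post-hoc tests reject zero within-group variance", {
  rs <- response_summary("y", c("a", "b"), 4, c(1, 1), c(0, 0), "SD")
  a <- suppressWarnings(anova_from_summary(rs))
  expect_error(lsd_test(rs, a), "zero within-group variance")
})
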