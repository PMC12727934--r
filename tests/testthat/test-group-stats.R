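test_that("one-way ANOVA matches direct sum-of-squares arithmetic", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  res <- one_way_anova(groups)
  # independent SS arithmetic
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  expect_equal(ssb, 6)
  expect_equal(ssw, 6)
  expect_equal(res$F, (ssb / 2) / (ssw / 6), tolerance = 1e-12)
  expect_equal(res$F, 3.0, tolerance = 1e-12)
  expect_equal(res$eta_squared, 0.5, tolerance = 1e-12)
  expect_equal(res$df, c(2, 6))
})

test_that("identical groups give F = 0 and all-identical values error", {
  g <- c(1.2, 3.4, 2.2, 0.7)
  res <- one_way_anova(list(g, g, g, g))
  expect_equal(res$F, 0)
  expect_equal(res$eta_squared, 0)
  expect_error(one_way_anova(list(rep(2, 5), rep(2, 5))), "zero variance")
  expect_error(one_way_anova(list(c(1, 2))), "at least 2 groups")
})

test_that("two-group F equals the squared pooled t statistic", {
  set.seed(70)
  x <- stats::rnorm(12)
  y <- stats::rnorm(15, mean = 0.8)
  res <- one_way_anova(list(x, y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("eta-squared equals R-squared of the group-indicator regression", {
  set.seed(71)
  groups <- lapply(1:4, function(k) stats::rnorm(8, mean = k / 3))
  res <- one_way_anova(groups)
  df <- data.frame(value = unlist(groups),
                   group = factor(rep(seq_along(groups), lengths(groups))))
  r2 <- summary(stats::lm(value ~ group, data = df))$r.squared
  expect_equal(res$eta_squared, r2, tolerance = 1e-12)
  expect_equal(res$eta_squared,
               1 - res$ss_within / (res$ss_between + res$ss_within),
               tolerance = 1e-12)
  # affine invariance of the effect size
  res2 <- one_way_anova(lapply(groups, function(g) 100 * g - 7))
  expect_equal(res2$eta_squared, res$eta_squared, tolerance = 1e-12)
})

test_that("assumption checks pass under a joint normal null and flag issues", {
  # under the null each individual test passes ~95% of the time; the joint
  # event over 4 Shapiro tests plus Levene has probability ~0.95^5 ~ 0.77
  res <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    chk <- assumption_checks(lapply(1:4, function(i) stats::rnorm(10)))
    c(joint = all(chk$normality_p > 0.05) && chk$levene_p > 0.05,
      levene = chk$levene_p > 0.05)
  }, logical(2))
  expect_gte(mean(res["joint", ]), 0.65)
  expect_gte(mean(res["levene", ]), 0.90)
  chk <- assumption_checks(list(a = rep(1, 5), b = stats::rnorm(5)))
  expect_true(is.na(chk$normality_p["a"]))
  expect_match(chk$flags, "constant")
  expect_error(assumption_checks(list(stats::rnorm(5))), "at least 2")
  expect_error(assumption_checks(list(stats::rnorm(2), stats::rnorm(5))),
               "n >= 3")
})

test_that("compare_groups summarizes per band with stars, order-invariantly", {
  coh <- make_test_cohort(n_per_group = 3, duration_s = 12, master_seed = 5)
  tab <- rp_table(coh)
  cmp <- compare_groups(tab)
  expect_equal(cmp$band, c("delta", "theta", "alpha", "beta"))
  expect_true(all(cmp$eta_squared >= 0 & cmp$eta_squared <= 1))
  expect_true(all(cmp$F >= 0))
  expect_true(all(cmp$stars %in% c("ns", "*", "**", "***")))
  expect_equal(cmp$stars,
               vapply(cmp$p, star_code, character(1)))
  # star thresholds
  expect_equal(vapply(c(0.2, 0.04, 0.009, 0.0009), star_code, character(1)),
               c("ns", "*", "**", "***"))
  # permuting subject rows changes nothing
  perm <- tab[sample(nrow(tab)), ]
  attr(perm, "metric_name") <- "RP"
  expect_equal(compare_groups(perm), cmp)
  # missing group is named
  expect_error(compare_groups(tab[tab$group != "MCAO", ]), "MCAO")
  # all-identical table: zero-variance error propagates
  flat <- tab
  flat$value <- 0.25
  expect_error(compare_groups(flat), "zero variance")
  # Holm adjustment is monotone and never smaller than raw p
  cmp_h <- compare_groups(tab, adjust = "holm")
  expect_true(all(cmp_h$p_adj >= cmp_h$p))
})
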