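test_that("baseline normalisation is exact percentage arithmetic", {
  tab <- data.frame(subject = "a", time_min = c(0, 30), value = c(200, 250))
  expect_equal(normalize_to_baseline(tab)$value, c(100, 125))
  tab2 <- data.frame(subject = "b", time_min = seq(0, 30, 5), value = rep(7, 7))
  expect_equal(normalize_to_baseline(tab2)$value, rep(100, 7))
})

test_that("subjects with a missing or zero baseline are excluded with a warning", {
  tab <- data.frame(subject = c("a", "a", "b", "b"),
                    time_min = c(0, 30, 0, 30),
                    value = c(100, 150, 0, 120))
  expect_warning(out <- normalize_to_baseline(tab), "zero baseline")
  expect_equal(unique(out$subject), "a")
  tab2 <- data.frame(subject = c("a", "a", "c"),
                     time_min = c(0, 30, 30), value = c(100, 150, 80))
  expect_warning(out2 <- normalize_to_baseline(tab2), "missing")
  expect_equal(unique(out2$subject), "a")
})

test_that("ROUT flags gross outliers and leaves well-behaved data alone", {
  expect_length(rout_outliers(1:5, Q = 0.01)$flagged, 0)
  expect_equal(rout_outliers(c(1, 2, 3, 4, 1000), Q = 0.01)$flagged, 5L)
  expect_length(rout_outliers(rep(4, 6))$flagged, 0)
  # robust scale matches the direct percentile computation
  v <- c(1, 2, 3, 4, 5)
  rep_ <- rout_outliers(v)
  res <- abs(v - median(v))
  expect_equal(rep_$rsdr, quantile(res, 0.6827, names = FALSE) * 5 / 4)
  expect_error(rout_outliers(c(1, 2)), "at least 3")
})

test_that("outlier removal works per group x time x measure cell", {
  set.seed(30)
  tab <- data.frame(subject = sprintf("s%02d", 1:24),
                    group = rep(c("g1", "g2"), each = 12),
                    time_min = 0, measure = "m",
                    value = rnorm(24, 100, 5))
  tab$value[1] <- 1e4
  out <- remove_outliers(tab, Q = 0.01)
  expect_equal(out$removed$subject, "s01")
  expect_equal(nrow(out$table), 23)
})

test_that("Sidak adjustment is exact, idempotent at m = 1 and monotone", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0, 7), 0)
  expect_equal(sidak_adjust(0.05, 2), 0.0975, tolerance = 1e-12)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sidak_adjust(p, 3)) >= 0))
  expect_true(all(sidak_adjust(p, 5) >= sidak_adjust(p, 2)))
  expect_true(all(sidak_adjust(p, 4) >= p))
})

test_that("mixed ANOVA reproduces the hand-derived toy decomposition exactly", {
  fit <- mixed_anova(toy_anova_table(), between = "group")
  tb <- fit$table
  get <- function(e, col) tb[tb$effect == e, col]
  # hand computation: grand mean 18; subject means 11/15/21/25;
  # group means 13/23; time means 17/19; parallel profiles
  expect_equal(get("between", "SS"), 200)
  expect_equal(get("subjects_within_groups", "SS"), 32)
  expect_equal(get("time", "SS"), 8)
  expect_equal(get("interaction", "SS"), 0)
  expect_equal(get("residual", "SS"), 0)
  expect_equal(sum(tb$SS), 240)   # total SS about the grand mean
  expect_equal(get("between", "F"), (200 / 1) / (32 / 2))  # 12.5
  expect_equal(get("interaction", "F"), 0)
  expect_equal(tb$df, c(1, 2, 1, 1, 2))
})

test_that("mixed ANOVA agrees with aov error strata on an unbalanced cohort", {
  tab <- simulate_measure_cohort(cohort_design(seed = 42))
  tab <- tab[tab$measure == "p2_peak_uV", ]
  fit <- mixed_anova(tab, between = "group")
  ref <- summary(stats::aov(value ~ group * factor(time_min) +
                              Error(factor(subject)), data = tab))
  btw <- ref[[1]][[1]]; wth <- ref[[2]][[1]]
  tb <- fit$table
  expect_equal(tb$SS[tb$effect == "between"], btw["group", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(tb$SS[tb$effect == "subjects_within_groups"],
               btw["Residuals", "Sum Sq"], tolerance = 1e-8)
  expect_equal(tb$SS[tb$effect == "time"],
               wth["factor(time_min)", "Sum Sq"], tolerance = 1e-8)
  expect_equal(tb$SS[tb$effect == "interaction"],
               wth["group:factor(time_min)", "Sum Sq"], tolerance = 1e-8)
  expect_equal(tb$SS[tb$effect == "residual"],
               wth["Residuals", "Sum Sq"], tolerance = 1e-8)
  expect_equal(tb$F[tb$effect == "between"], btw["group", "F value"],
               tolerance = 1e-8)
  expect_equal(tb$p[tb$effect == "interaction"],
               wth["group:factor(time_min)", "Pr(>F)"], tolerance = 1e-8)
})

test_that("ANOVA bookkeeping: SS additivity and df accounting hold", {
  for (s in 1:5) {
    tab <- simulate_null_measures(n_per_group = 6, seed = s)
    fit <- mixed_anova(tab, between = "group")
    tb <- fit$table
    y <- tab$value
    expect_equal(sum(tb$SS), sum((y - mean(y))^2), tolerance = 1e-8)
    expect_equal(sum(tb$df), nrow(tab) - 1)
    expect_true(all(tb$SS >= 0))
  }
})

test_that("incomplete subjects are listwise deleted; degenerate designs error", {
  tab <- simulate_null_measures(n_per_group = 5, seed = 2)
  drop <- tab$subject == "s001" & tab$time_min == 30
  expect_warning(fit <- mixed_anova(tab[!drop, ], between = "group"),
                 "listwise")
  expect_equal(fit$n_subjects, 9)
  expect_error(mixed_anova(tab[tab$time_min == 0, ], between = "group"),
               "within factor")
  expect_error(suppressWarnings(
    mixed_anova(tab[tab$subject %in% c("s001", "s006", "s007", "s008", "s009", "s010"), ],
                between = "group")), "at least 2 complete subjects")
  dup <- rbind(tab, tab[1, ])
  expect_error(mixed_anova(dup, between = "group"), "duplicate")
})

test_that("post hoc contrasts match a hand computation on the toy table", {
  fit <- mixed_anova(toy_anova_table(), between = "group")
  ph <- posthoc_by_time(fit, contrasts = list(c("g1", "g2")))
  expect_equal(nrow(ph), 2)
  # pooled error: (MS_subj + (T-1) MS_res)/T = (16 + 0)/2 = 8; se = sqrt(8 * (1/2 + 1/2))
  expect_equal(ph$estimate, c(12 - 22, 14 - 24))
  expect_equal(ph$se, rep(sqrt(8), 2))
  expect_equal(ph$df, rep(2, 2))   # Satterthwaite collapses to df_subj when MS_res = 0
  expect_equal(ph$t, c(-10, -10) / sqrt(8))
  expect_equal(ph$raw_p, rep(2 * pt(10 / sqrt(8), 2, lower.tail = FALSE), 2))
  # family of two comparisons
  expect_equal(ph$sidak_p, sidak_adjust(ph$raw_p, 2))
  # family of 1: adjusted equals raw
  ph1 <- posthoc_by_time(fit, contrasts = list(c("g1", "g2")), m = 1)
  expect_equal(ph1$sidak_p[1], ph1$raw_p[1])
  # adjusted p monotone in family size
  ph9 <- posthoc_by_time(fit, contrasts = list(c("g1", "g2")), m = 9)
  expect_true(all(ph9$sidak_p >= ph$sidak_p))
  expect_error(posthoc_by_time(fit, contrasts = list(c("g1", "gX"))),
               "undefined contrast")
})

test_that("group summaries compute SEM = SD/sqrt(n) and flag singletons", {
  tab <- data.frame(subject = c("a", "b", "c"), group = c("g", "g", "h"),
                    time_min = 0, value = c(100, 120, 50))
  s <- summarize_groups(tab)
  g <- s[s$group == "g", ]
  expect_equal(g$mean, 110)
  expect_equal(g$sem, 10)
  h <- s[s$group == "h", ]
  expect_true(is.na(h$sem))
  expect_equal(h$flag, "single_subject")
})
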