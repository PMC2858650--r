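# brute-force oracle: stats::aov with the classic Error() strata
aov_oracle <- function(data) {
  d <- data
  d$session <- factor(d$session)
  d$stimulus <- factor(d$stimulus)
  d$group <- factor(d$group)
  fit <- stats::aov(y ~ group * stimulus * session +
                      Error(subject / (stimulus * session)), data = d)
  s <- summary(fit)
  out <- list()
  for (stratum in s) {
    tab <- stratum[[1]]
    for (i in seq_len(nrow(tab))) {
      nm <- trimws(rownames(tab)[i])
      if (nm == "Residuals") next
      out[[nm]] <- c(ss = tab$`Sum Sq`[i], f = tab$`F value`[i],
                     df = tab$Df[i])
    }
  }
  out
}

test_that("SS and F match the aov stratified decomposition on balanced fixtures", {
  for (seed in c(1, 2, 3)) {
    d <- balanced_table(n_per = 4, seed = seed, effect = 0.3)
    fit <- fit_rm_anova(d, "y", between = "group",
                        within = c("stimulus", "session"))
    oracle <- aov_oracle(d)
    map <- c(group = "group", stimulus = "stimulus", session = "session",
             `group:stimulus` = "group:stimulus",
             `group:session` = "group:session",
             `stimulus:session` = "stimulus:session",
             `group:stimulus:session` = "group:stimulus:session")
    for (eff in names(map)) {
      row <- fit$table[fit$table$effect == eff, ]
      expect_equal(row$ss, unname(oracle[[map[eff]]]["ss"]),
                   tolerance = 1e-8, label = paste("SS", eff, "seed", seed))
      expect_equal(row$statistic, unname(oracle[[map[eff]]]["f"]),
                   tolerance = 1e-8, label = paste("F", eff, "seed", seed))
    }
  }
})

test_that("two-level within factor F equals the squared paired t", {
  set.seed(4)
  d <- tidyr::expand_grid(subject = sprintf("s%d", 1:6), session = 1:2)
  d$y <- rnorm(nrow(d)) + 0.4 * (d$session == 2)
  fit <- fit_rm_anova(d, "y", within = "session")
  wide <- tidyr::pivot_wider(d, names_from = session, values_from = y)
  tt <- t.test(wide$`2`, wide$`1`, paired = TRUE)
  row <- fit$table[fit$table$effect == "session", ]
  expect_equal(row$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(row$p_gg, tt$p.value, tolerance = 1e-10)
  expect_equal(row$epsilon, 1) # k = 2 -> epsilon always 1
})

test_that("constant responses give zero F everywhere", {
  d <- balanced_table(n_per = 3, seed = 1)
  d$y <- 7
  fit <- fit_rm_anova(d, "y", between = "group",
                      within = c("stimulus", "session"))
  expect_equal(fit$table$ss, rep(0, nrow(fit$table)))
  expect_equal(fit$table$statistic, rep(0, nrow(fit$table)))
})

test_that("Greenhouse-Geisser epsilon has its closed-form values", {
  expect_equal(as.numeric(gg_epsilon(matrix(2, 1, 1))), 1) # k = 2: single contrast
  # compound symmetry (spherical contrast covariance) at k = 3 -> 1
  expect_equal(as.numeric(gg_epsilon(diag(2) * 3)), 1)
  # rank-1 contrast covariance at k = 3 -> lower bound 0.5
  v <- c(1, 2)
  expect_equal(as.numeric(gg_epsilon(outer(v, v))), 0.5)
  # degenerate zero covariance clamps with a flag
  e <- gg_epsilon(matrix(0, 2, 2))
  expect_equal(as.numeric(e), 0.5)
  expect_true(attr(e, "clamped"))
  # epsilon bounded in [1/(k-1), 1] for random covariances
  set.seed(6)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3)
    eps <- as.numeric(gg_epsilon(crossprod(A)))
    expect_gte(eps, 1 / 3)
    expect_lte(eps, 1)
  }
})

test_that("adding a constant changes no F, epsilon, or partial eta squared", {
  d <- balanced_table(n_per = 4, seed = 7, effect = 0.2)
  f1 <- fit_rm_anova(d, "y", between = "group",
                     within = c("stimulus", "session"))
  d$y <- d$y + 42
  f2 <- fit_rm_anova(d, "y", between = "group",
                     within = c("stimulus", "session"))
  expect_equal(f1$table$statistic, f2$table$statistic, tolerance = 1e-8)
  expect_equal(f1$table$epsilon, f2$table$epsilon, tolerance = 1e-8)
  expect_equal(f1$table$partial_eta_sq, f2$table$partial_eta_sq,
               tolerance = 1e-8)
})

test_that("unbalanced or incomplete designs are rejected outright", {
  d <- balanced_table(n_per = 3, seed = 2)
  expect_error(fit_rm_anova(d[-1, ], "y", between = "group",
                            within = c("stimulus", "session")),
               "unbalanced")
  d2 <- d[d$subject != "s01" | d$group == 2, ]
  expect_error(fit_rm_anova(d2, "y", between = "group",
                            within = c("stimulus", "session")),
               "unbalanced")
})

test_that("partial eta squared equals SS_effect over SS_effect + SS_error", {
  d <- balanced_table(n_per = 5, seed = 9, effect = 0.4)
  fit <- fit_rm_anova(d, "y", between = "group",
                      within = c("stimulus", "session"))
  with(fit$table, expect_equal(partial_eta_sq, ss / (ss + ss_error),
                               tolerance = 1e-12))
})

test_that("post-hoc pairwise comparisons apply the Bonferroni family size", {
  d <- balanced_table(n_per = 5, seed = 10, effect = 0.5)
  fit <- fit_rm_anova(d, "y", between = "group",
                      within = c("stimulus", "session"))
  ph <- posthoc(fit, "session")
  expect_equal(nrow(ph$pairwise), 3) # 3 sessions -> 3 comparisons
  expect_equal(unique(ph$pairwise$n_comparisons), 3)
  expect_equal(ph$pairwise$p_adjusted,
               pmin(ph$pairwise$p_raw * 3, 1))
  expect_true(all(ph$pairwise$p_adjusted <= 1))
  # a single comparison (2-level factor) is returned unadjusted
  ph2 <- posthoc(fit, "stimulus")
  expect_equal(nrow(ph2$pairwise), 1)
  expect_equal(ph2$pairwise$p_adjusted, ph2$pairwise$p_raw)
})

test_that("simple effects slice the design and refit within each level", {
  d <- balanced_table(n_per = 6, seed = 11, effect = 0.8)
  fit <- fit_rm_anova(d, "y", between = "group",
                      within = c("stimulus", "session"))
  ph <- posthoc(fit, "session", by = "group")
  expect_equal(nrow(ph$simple_effects), 2)
  # oracle: within-group one-way repeated fit
  for (g in 1:2) {
    ref <- fit_rm_anova(d[d$group == g, ], "y",
                        within = c("stimulus", "session"))
    expect_equal(
      ph$simple_effects$statistic[ph$simple_effects$level == g],
      ref$table$statistic[ref$table$effect == "session"],
      tolerance = 1e-10
    )
  }
  # planted group-2-only growth: simple session effect stronger in group 2
  expect_gt(ph$simple_effects$statistic[ph$simple_effects$level == "2"],
            ph$simple_effects$statistic[ph$simple_effects$level == "1"])
})

test_that("retention-style two-level session ANOVA runs on sliced peak data", {
  d <- balanced_table(n_per = 4, k_sess = 4, seed = 12)
  ret <- fit_rm_anova(d[d$session %in% c(1, 4), ], "y", between = "group",
                      within = c("stimulus", "session"))
  row <- ret$table[ret$table$effect == "session", ]
  expect_equal(row$df1, 1)
  expect_equal(row$epsilon, 1)
})

test_that("a planted group-by-session interaction is reliably detected", {
  m <- reduced_montage()
  comps <- default_components(m)
  gains <- tidyr::expand_grid(group = 2, session = 2:3,
                              electrode = c("TP9", "IZ", "TP10"))
  gains$p2_gain <- ifelse(gains$session == 2, 1, 2)
  plan <- effect_plan(gains)
  hits <- vapply(1:20, function(r) {
    cfg <- sim_config(n_subjects_per_group = 10, sessions = 1:3,
                      trials_per_block = 8, stimuli = "mba",
                      artifact_rate = 0, seed = 400 + r)
    st <- simulate_study(cfg, plan, m, comps)
    ev <- preprocess_study(st, filter = FALSE)
    pk <- build_peak_table(ev, electrodes = c("TP9", "IZ", "TP10"),
                           components = "P2")
    fit <- fit_rm_anova(pk, "amplitude", between = "group",
                        within = c("session", "electrode"))
    fit$table$p_gg[fit$table$effect == "group:session"] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
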