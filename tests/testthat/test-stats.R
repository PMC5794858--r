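test_that("mixed ANOVA matches a brute-force sums-of-squares oracle", {
  df <- toy_table()
  fit <- mixed_anova(df, within = "w", between = "grp")
  tab <- tidy(fit)
  bf <- bruteforce_split_plot(df)
  expect_equal(tab$F[tab$effect == "grp"], bf$F_g, tolerance = 1e-9)
  expect_equal(tab$F[tab$effect == "w"], bf$F_a, tolerance = 1e-9)
  expect_equal(tab$F[tab$effect == "grp x w"], bf$F_ga, tolerance = 1e-9)
  expect_equal(tab$df_effect[tab$effect == "w"], 2)
  expect_equal(tab$df_error[tab$effect == "w"], 18)
  # partial eta squared consistent with its F-statistic form
  expect_equal(tab$partial_eta_sq,
               partial_eta_squared(tab$F, tab$df_effect, tab$df_error),
               tolerance = 1e-12)
})

test_that("sums of squares are conserved on balanced designs", {
  for (seed in 1:4) {
    df <- toy_table(seed, g = 2, n = 5, a = 4)
    fit <- mixed_anova(df, within = "w", between = "grp")
    tab <- tidy(fit)
    bf <- bruteforce_split_plot(df)
    decomposed <- sum(tab$ss_effect) + sum(unique(tab$ss_error))
    expect_equal(decomposed, bf$ss[["tot"]], tolerance = 1e-9)
  }
})

test_that("GG epsilon agrees with an independent implementation", {
  skip_if_not_installed("car")
  df <- toy_table(3, g = 3, n = 6, a = 4)
  fit <- mixed_anova(df, within = "w", between = "grp")
  eps <- tidy(fit)$gg_epsilon[tidy(fit)$effect == "w"]

  wide <- tidyr::pivot_wider(df, names_from = "w", values_from = "value")
  mlm <- stats::lm(as.matrix(wide[, paste0("w", 1:4)]) ~ grp, data = wide)
  av <- car::Anova(mlm, idata = data.frame(w = factor(paste0("w", 1:4))),
                   idesign = ~w, type = 3)
  s <- suppressWarnings(summary(av))  # car warns about HF eps > 1
  eps_car <- s$pval.adjustments["w", "GG eps"]
  expect_equal(eps, unname(eps_car), tolerance = 1e-8)
})

test_that("ANOVA handles degenerate and boundary cases", {
  # identical values across within levels: the within effect has exactly
  # zero sum of squares (its F is then 0/0, reported as NaN by aov)
  df <- toy_table(2)
  base <- df$value[df$w == "w1"][match(df$subject, df$subject[df$w == "w1"])]
  df$value <- base
  fit <- mixed_anova(df, within = "w", between = "grp")
  tab <- tidy(fit)
  expect_lt(tab$ss_effect[tab$effect == "w"], 1e-18)
  expect_gt(tab$ss_effect[tab$effect == "grp"], 0)

  # two within levels: sphericity holds trivially, epsilon is exactly 1
  df2 <- toy_table(4, a = 2)
  fit2 <- mixed_anova(df2, within = "w", between = "grp")
  expect_identical(tidy(fit2)$gg_epsilon[tidy(fit2)$effect == "w"], 1)

  # structurally unbalanced cells (replicated rows) raise rather than
  # silently aggregate or drop
  df3 <- toy_table(5)
  df3 <- rbind(df3, df3[1, ])
  expect_error(suppressMessages(mixed_anova(df3, within = "w",
                                            between = "grp")),
               "unbalanced")

  # subjects with missing cells are excluded listwise with a message
  df4 <- toy_table(6)
  df4$value[df4$subject == 1 & df4$w == "w2"] <- NA
  expect_message(fit4 <- mixed_anova(df4, within = "w", between = "grp"),
                 "listwise")
  expect_identical(fit4$n_subjects, 11L)
})

test_that("GG epsilon stays inside its theoretical bounds", {
  for (seed in 1:6) {
    set.seed(seed)
    a <- sample(3:5, 1)
    n <- 12
    # random covariance structure via random loadings
    L <- matrix(stats::rnorm(a * a), a)
    X <- matrix(stats::rnorm(n * a), n) %*% L
    df <- data.frame(subject = rep(seq_len(n), a),
                     w = rep(paste0("w", seq_len(a)), each = n),
                     value = as.numeric(X))
    fit <- mixed_anova(df, within = "w")
    eps <- tidy(fit)$gg_epsilon[tidy(fit)$effect == "w"]
    expect_gte(eps, 1 / (a - 1))
    expect_lte(eps, 1)
  }
})

test_that("partial eta squared reproduces published worked examples", {
  # F(2, 44) = 67.8 gives eta_p^2 = 0.7550; the reported effect size (0.75)
  # is consistent with it within the rounding uncertainty of the reported
  # F (F in [67.75, 67.85] maps eta to [0.75490, 0.75512])
  e1 <- partial_eta_squared(67.8, 2, 44)
  expect_equal(e1, 0.755, tolerance = 1e-3)
  expect_lt(abs(e1 - 0.75), 0.0052)
  expect_equal(round(partial_eta_squared(26.9, 3, 43), 2), 0.65)
  expect_identical(partial_eta_squared(0, 2, 40), 0)
  # monotone in F at fixed dfs
  f <- seq(0.1, 50, length.out = 20)
  expect_true(all(diff(partial_eta_squared(f, 2, 40)) > 0))
})

test_that("Bonferroni follow-ups match a closed-form paired-t oracle", {
  x <- c(5.1, 4.8, 6.0, 5.5, 5.2)
  y <- c(4.9, 4.5, 5.9, 5.6, 4.8)
  z <- c(5.0, 4.9, 5.8, 5.4, 5.1)
  df <- data.frame(subject = rep(1:5, 3),
                   cond = rep(c("a", "b", "c"), each = 5),
                   value = c(x, y, z))
  res <- pairwise_bonferroni(df, "cond", paired = TRUE)
  d <- x - y
  t_or <- mean(d) / (stats::sd(d) / sqrt(5))
  p_or <- 2 * stats::pt(-abs(t_or), 4)
  row <- res[res$level1 == "a" & res$level2 == "b", ]
  expect_equal(row$t, t_or, tolerance = 1e-12)
  expect_equal(row$p_raw, p_or, tolerance = 1e-12)
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * 3), tolerance = 1e-12)

  # identical samples give raw p = 1; zero variance flags degeneracy
  same <- data.frame(subject = rep(1:5, 2),
                     cond = rep(c("a", "b"), each = 5),
                     value = c(x, x + 0.5))
  expect_warning(out <- pairwise_bonferroni(same, "cond", paired = TRUE),
                 "degenerate")
  expect_true(out$degenerate[1])
})

test_that("Pearson correlation handles exact and degenerate inputs", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  out <- pearson_r(x, x + stats::rnorm(10, sd = 20))
  expect_true(out$p >= 0 && out$p <= 1)
  expect_error(pearson_r(x, rep(3, 10)), "constant")
})
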