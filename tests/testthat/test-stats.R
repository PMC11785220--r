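test_that("season linear model reduces to group-mean differences and zero reference", {
  roster <- rbind(roster_row(sprintf("h%d", 1:4), "housed"),
                  roster_row(sprintf("t%d", 1:4), "tent"))
  vals <- data.frame(participant_id = roster$participant_id,
                     value = c(480, 490, 500, 510, 420, 430, 440, 450))
  res <- fit_season_linear_model(vals, roster)
  expect_equal(res$estimate[res$label == "housed"], 0)
  expect_equal(res$estimate[res$label == "tent"], -60)  # 435 - 495
  expect_false("gender" %in% res$label)  # single gender: no gender effect
  expect_error(fit_season_linear_model(
    vals, transform(roster, community = "tent")), "housed")
})

test_that("season linear model recovers a simulated community shift", {
  set.seed(71)
  n <- 100
  roster <- rbind(
    roster_row(sprintf("h%d", 1:n), "housed",
               gender = sample(c("female", "male"), n, TRUE)),
    roster_row(sprintf("t%d", 1:n), "tiny_house",
               gender = sample(c("female", "male"), n, TRUE)))
  shift <- ifelse(roster$community == "tiny_house", 60, 0)
  vals <- data.frame(participant_id = roster$participant_id,
                     value = 700 + shift + rnorm(2 * n, 0, 40))
  res <- fit_season_linear_model(vals, roster)
  expect_equal(res$estimate[res$label == "tiny_house"], 60, tolerance = 10)
  expect_true("gender" %in% res$label)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
})

test_that("one-way ANOVA F matches the sums-of-squares oracle", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("housed", "tent", "tiny_house"), each = 3)
  res <- anova_with_control_comparisons(v, g)
  # oracle: SSB = 3*((2-5)^2 + 0 + (8-5)^2) = 54, SSW = 6, F = 27/1
  expect_equal(res$statistic[res$label == "anova"], 27)
  expect_equal(res$p_value[res$label == "anova"], pf(27, 2, 6, lower.tail = FALSE))
  expect_equal(sum(res$adjustment == "many_to_one"), 2)
})

test_that("with two groups the many-to-one contrast reduces to a pooled t-test", {
  set.seed(72)
  v <- c(rnorm(8, 10), rnorm(8, 11))
  g <- rep(c("housed", "tent"), each = 8)
  res <- anova_with_control_comparisons(v, g)
  tt <- t.test(v[g == "tent"], v[g == "housed"], var.equal = TRUE)
  p_dunnett <- res$p_value[res$adjustment == "many_to_one"]
  expect_equal(p_dunnett, tt$p.value, tolerance = 1e-4)
  expect_equal(res$estimate[res$adjustment == "many_to_one"],
               mean(v[g == "tent"]) - mean(v[g == "housed"]))
})

test_that("many-to-one adjusted p-values never fall below unadjusted ones", {
  set.seed(73)
  for (i in 1:10) {
    v <- rnorm(40)
    g <- rep(c("housed", "a", "b", "c"), each = 10)
    res <- anova_with_control_comparisons(v, g)
    mc <- res[res$adjustment == "many_to_one", ]
    p_unadj <- 2 * pt(abs(mc$statistic), df = mc$df, lower.tail = FALSE)
    expect_true(all(mc$p_value >= p_unadj - 1e-10))
    expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  }
})

test_that("Bartlett's statistic matches the textbook formula", {
  set.seed(74)
  x <- rnorm(10, 0, 1); y <- rnorm(12, 0, 3)
  res <- variance_homogeneity_test(c(x, y), rep(c("a", "b"), c(10, 12)))
  # textbook oracle
  k <- 2; n <- c(10, 12); N <- sum(n); s2 <- c(var(x), var(y))
  sp2 <- sum((n - 1) * s2) / (N - k)
  stat <- ((N - k) * log(sp2) - sum((n - 1) * log(s2))) /
    (1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1)))
  expect_equal(res$statistic, stat, tolerance = 1e-10)
  expect_equal(res$p_value, pchisq(stat, 1, lower.tail = FALSE))
  # identical sample variances give statistic 0, p = 1
  res0 <- variance_homogeneity_test(c(1, 2, 3, 11, 12, 13),
                                    rep(c("a", "b"), each = 3))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)
  expect_error(variance_homogeneity_test(c(1, 1, 2, 3),
                                         rep(c("a", "b"), each = 2)),
               "zero within-group variance")
})

test_that("the sleepless chi-squared matches the hand-computed statistic", {
  res <- sleepless_chi_squared(rbind(c(10, 90), c(30, 70)))
  expect_equal(res$statistic, 12.5)  # sum (O-E)^2/E with E = [20,80;20,80]
  expect_equal(res$df, 1)
  even <- rbind(c(10, 90), c(20, 180), c(5, 45))
  expect_equal(sleepless_chi_squared(even)$statistic, 0, tolerance = 1e-12)
  expect_error(sleepless_chi_squared(rbind(c(0, 0), c(10, 10))),
               "row totals")
  expect_warning(sleepless_chi_squared(rbind(c(1, 400), c(0, 400))),
                 "below 1")
})

test_that("the light mixed model collapses to ordinary least squares when degenerate", {
  set.seed(75)
  n <- 40
  d <- data.frame(participant_id = sprintf("p%d", 1:n),
                  community = rep(c("housed", "tent"), each = n / 2),
                  season = rep(c("summer", "winter"), times = n / 2),
                  gender = "female",
                  value = rnorm(n, 600, 50))
  res <- light_mixed_model(d)   # one observation per participant
  ols <- lm(value ~ community * season, data = d)
  emm_ols <- as.data.frame(summary(emmeans::contrast(
    emmeans::emmeans(ols, ~ community:season), method = "pairwise"),
    adjust = "tukey"))
  expect_equal(res$posthoc$estimate, emm_ols$estimate, tolerance = 1e-6)
  expect_length(res$residual_quantiles, n)
})

test_that("the light mixed model recovers a simulated season effect", {
  set.seed(76)
  n_pid <- 100; n_day <- 6
  pid <- rep(sprintf("p%d", 1:n_pid), each = n_day)
  season <- rep(rep(c("summer", "winter"), each = n_day), length.out = n_pid * n_day)
  season <- rep(ifelse(seq_len(n_pid) %% 2 == 0, "summer", "winter"),
                each = n_day)
  b <- rep(rnorm(n_pid, 0, 30), each = n_day)
  d <- data.frame(participant_id = pid,
                  community = rep(rep(c("housed", "tent"), length.out = n_pid),
                                  each = n_day),
                  season = season, gender = "female",
                  value = 500 + 120 * (season == "summer") + b +
                    rnorm(n_pid * n_day, 0, 40))
  res <- light_mixed_model(d)
  emm <- as.data.frame(emmeans::emmeans(res$fit, ~season))
  gap <- emm$emmean[emm$season == "summer"] - emm$emmean[emm$season == "winter"]
  expect_equal(gap, 120, tolerance = 15)
  expect_true("season" %in% res$fixed$label)
  expect_true(all(res$posthoc$adjustment == "all_pairs"))
})

mixed_anova_oracle <- function(values, subject, group, bin) {
  # explicit balanced two-way mixed ANOVA sums of squares
  GM <- mean(values)
  b <- length(unique(bin)); k <- length(unique(group))
  N <- length(unique(subject))
  ms <- tapply(values, subject, mean)
  SS_subj <- b * sum((ms - GM)^2)
  ga <- tapply(values, group, mean); na <- table(group[!duplicated(subject)])
  SS_A <- b * sum(as.numeric(na) * (ga[names(na)] - GM)^2)
  mb <- tapply(values, bin, mean)
  SS_B <- N * sum((mb - GM)^2)
  mab <- tapply(values, list(group, bin), mean)
  nab <- table(group[!duplicated(subject)])
  SS_cells <- sum(rep(as.numeric(nab), times = b) * (as.vector(mab) - GM)^2)
  SS_AB <- SS_cells - SS_A - SS_B
  SS_tot <- sum((values - GM)^2)
  SS_eb <- SS_subj - SS_A
  SS_ew <- SS_tot - SS_subj - SS_B - SS_AB
  list(
    F_A = (SS_A / (k - 1)) / (SS_eb / (N - k)),
    F_B = (SS_B / (b - 1)) / (SS_ew / ((N - k) * (b - 1))),
    F_AB = (SS_AB / ((k - 1) * (b - 1))) / (SS_ew / ((N - k) * (b - 1)))
  )
}

test_that("waveform mixed ANOVA matches the explicit sums-of-squares oracle", {
  set.seed(77)
  ids <- sprintf("p%d", 1:6)
  comm <- rep(c("housed", "tent"), each = 3)
  roster <- roster_row(ids, comm)
  wfs <- lapply(seq_along(ids), function(i)
    runif(4) + (comm[i] == "tent") * 0.5)
  names(wfs) <- ids
  res <- waveform_mixed_anova(wfs, roster)
  values <- unlist(wfs); subject <- rep(ids, each = 4)
  group <- rep(comm, each = 4); bin <- rep(1:4, times = 6)
  or <- mixed_anova_oracle(values, subject, group, bin)
  expect_equal(res$statistic[res$label == "community"], or$F_A, tolerance = 1e-8)
  expect_equal(res$statistic[res$label == "time"], or$F_B, tolerance = 1e-8)
  expect_equal(res$statistic[res$label == "community:time"], or$F_AB,
               tolerance = 1e-8)
  # location invariance
  res2 <- waveform_mixed_anova(lapply(wfs, `+`, 100), roster)
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-8)
  expect_error(waveform_mixed_anova(wfs, transform(roster, community = "tent")),
               "single community")
})

test_that("the waveform interaction p-value is uniform under the null", {
  set.seed(78)
  ids <- sprintf("p%d", 1:8)
  roster <- roster_row(ids, rep(c("housed", "tent"), each = 4))
  ps <- replicate(300, {
    wfs <- lapply(ids, function(i) rnorm(6))
    names(wfs) <- ids
    waveform_mixed_anova(wfs, roster)$p_value[3]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
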