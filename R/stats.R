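#' Group-comparison layer
#'
#' Per-season linear models against the housed reference, one-way ANOVA with
#' many-to-one (Dunnett) contrasts, Bartlett variance-homogeneity tests,
#' Pearson chi-squared on sleepless-night counts, linear mixed models for
#' daily light metrics with Tukey all-pairs post-hocs, and a two-way mixed
#' ANOVA on activity waveforms. Every result comes back in a common
#' `stat_result` data.frame shape. Clock-time outcomes enter these models on
#' a linear scale: noon-referenced for sleep timing, midnight-referenced for
#' light timing, so ordinary least squares applies without wrap artifacts.
#'
#' @name group_stats
NULL

stat_result <- function(label, estimate = NA_real_, standard_error = NA_real_,
                        statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, adjustment = "none") {
  data.frame(label = label, estimate = estimate,
             standard_error = standard_error, statistic = statistic,
             df = df, p_value = p_value, adjustment = adjustment,
             stringsAsFactors = FALSE)
}

#' Per-season linear model of a participant-level outcome
#'
#' Least squares on `value ~ community + gender` with housed as the
#' reference level; each community coefficient estimates that community's
#' difference from housed adjusted for gender, and gender is tested with an
#' overall (type II) F-test. Run it once per season.
#'
#' @param values data.frame with `participant_id` and `value` (one row per
#'   participant).
#' @param roster roster restricted to the same season.
#' @return data.frame of stat results: one row per community coefficient
#'   (housed = 0 by construction) plus a `gender` F row.
#' @export
fit_season_linear_model <- function(values, roster) {
  d <- merge(values, roster, by = "participant_id")
  d <- d[!is.na(d$value), , drop = FALSE]
  if (!"housed" %in% d$community) stop("housed reference group absent")
  d$community <- stats::relevel(factor(d$community), ref = "housed")
  d$gender <- factor(d$gender)
  small <- names(which(table(d$community) < 2))
  if (length(small)) {
    warning("community level(s) with < 2 participants retained: ",
            paste(small, collapse = ", "))
  }
  has_gender <- nlevels(d$gender) > 1L
  fit <- if (has_gender) stats::lm(value ~ community + gender, data = d) else
    stats::lm(value ~ community, data = d)
  cf <- summary(fit)$coefficients
  rows <- list(stat_result("housed", estimate = 0))
  for (lev in levels(d$community)[-1]) {
    nm <- paste0("community", lev)
    if (nm %in% rownames(cf)) {
      rows[[lev]] <- stat_result(lev, estimate = cf[nm, 1],
                                 standard_error = cf[nm, 2],
                                 statistic = cf[nm, 3],
                                 df = fit$df.residual, p_value = cf[nm, 4])
    }
  }
  if (has_gender) {
    aov2 <- car::Anova(fit, type = 2)
    g <- which(rownames(aov2) == "gender")
    rows$gender <- stat_result("gender", statistic = aov2$`F value`[g],
                               df = aov2$Df[g], p_value = aov2$`Pr(>F)`[g])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with many-to-one comparisons against a control group
#'
#' Omnibus F-test plus each non-control group compared to the control with
#' family-wise error controlled over the set of many-to-one contrasts
#' (Dunnett's multivariate-t single-step adjustment). With exactly two
#' groups the adjusted p equals the unadjusted pooled-variance comparison.
#'
#' @param values numeric outcome, one per participant.
#' @param groups group labels, same length.
#' @param control control group label (default "housed").
#' @return data.frame of stat results: `anova` row plus one row per
#'   many-to-one contrast (`<group> - <control>`).
#' @export
anova_with_control_comparisons <- function(values, groups,
                                           control = "housed") {
  ok <- !is.na(values) & !is.na(groups)
  d <- data.frame(value = values[ok], g = as.character(groups[ok]))
  small <- names(which(table(d$g) < 2))
  if (length(small)) {
    warning("dropping group(s) with n < 2: ", paste(small, collapse = ", "))
    d <- d[!d$g %in% small, , drop = FALSE]
  }
  if (!control %in% d$g) stop("control group '", control, "' absent")
  if (length(unique(d$g)) < 2L) stop("need at least 2 groups")
  d$g <- stats::relevel(factor(d$g), ref = control)
  fit <- stats::aov(value ~ g, data = d)
  an <- summary(fit)[[1]]
  out <- stat_result("anova", statistic = an$`F value`[1], df = an$Df[1],
                     p_value = an$`Pr(>F)`[1])
  mc <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(mc)  # single-step multivariate-t adjustment
  lab <- names(sm$test$coefficients)
  out <- rbind(out, stat_result(lab,
                                estimate = as.numeric(sm$test$coefficients),
                                standard_error = as.numeric(sm$test$sigma),
                                statistic = as.numeric(sm$test$tstat),
                                df = fit$df.residual,
                                p_value = as.numeric(sm$test$pvalues),
                                adjustment = "many_to_one"))
  rownames(out) <- NULL
  out
}

#' Bartlett's test of variance homogeneity across groups
#'
#' @param values numeric outcome.
#' @param groups group labels (each group n >= 2).
#' @return one-row stat-result data.frame (chi-squared statistic, k - 1 df).
#' @export
variance_homogeneity_test <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  v <- values[ok]; g <- factor(as.character(groups[ok]))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs n >= 2")
  vars <- tapply(v, g, stats::var)
  if (any(vars == 0)) stop("zero within-group variance: Bartlett statistic undefined")
  bt <- stats::bartlett.test(v, g)
  stat_result("bartlett", statistic = unname(bt$statistic),
              df = unname(bt$parameter), p_value = bt$p.value)
}

#' Pearson chi-squared test on sleepless vs. slept night counts
#'
#' @param counts matrix (or data.frame) with one row per community and two
#'   columns, sleepless and slept nights; no continuity correction.
#' @return one-row stat-result data.frame; carries an `expected_below_1`
#'   attribute-driven warning when any expected cell is below 1.
#' @export
sleepless_chi_squared <- function(counts) {
  m <- as.matrix(counts)
  if (any(rowSums(m) <= 0)) stop("all row totals must be positive")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 1)) {
    warning("expected cell count below 1; chi-squared approximation is poor")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  stat_result("sleepless_chi_squared", statistic = unname(ct$statistic),
              df = unname(ct$parameter), p_value = ct$p.value)
}

#' Linear mixed model for daily light metrics
#'
#' Fits `value ~ community * season + gender + (1 | participant)` on daily
#' observations of one light outcome (first time, last time, or duration),
#' tests the fixed effects (Satterthwaite F), and runs Tukey-adjusted
#' all-pairs comparisons among the community-by-season cells. Ordered
#' residual quantiles are returned for QQ normality diagnostics.
#'
#' @param data data.frame with columns `participant_id`, `community`,
#'   `season`, `gender`, `value` (one row per participant-day).
#' @return list: `fixed` (stat results per fixed effect), `posthoc` (stat
#'   results per pairwise cell contrast, Tukey-adjusted),
#'   `residual_quantiles` (sorted residuals, one per observation).
#' @export
light_mixed_model <- function(data) {
  d <- data[!is.na(data$value), , drop = FALSE]
  d$community <- factor(d$community)
  d$season <- factor(d$season)
  d$gender <- factor(d$gender)
  has_gender <- nlevels(d$gender) > 1L
  has_season <- nlevels(d$season) > 1L
  form <- if (has_season) "value ~ community * season" else "value ~ community"
  if (has_gender) form <- paste(form, "+ gender")
  form <- paste(form, "+ (1 | participant_id)")
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(stats::as.formula(form), data = d,
                   control = lme4::lmerControl(
                     check.nobs.vs.nlev = "ignore",
                     check.nobs.vs.nRE = "ignore"))))
  an <- suppressWarnings(stats::anova(fit))
  fixed <- stat_result(rownames(an), statistic = an$`F value`,
                       df = an$NumDF, p_value = an$`Pr(>F)`)
  spec <- if (has_season) ~ community:season else ~ community
  emm <- suppressMessages(emmeans::emmeans(fit, spec))
  pr <- as.data.frame(summary(
    emmeans::contrast(emm, method = "pairwise"), adjust = "tukey"))
  keep <- !is.na(pr$estimate)
  if (any(!keep)) warning("skipping inestimable cell contrast(s)")
  posthoc <- stat_result(pr$contrast[keep], estimate = pr$estimate[keep],
                         standard_error = pr$SE[keep],
                         statistic = pr$t.ratio[keep], df = pr$df[keep],
                         p_value = pr$p.value[keep], adjustment = "all_pairs")
  list(fixed = fixed, posthoc = posthoc,
       residual_quantiles = sort(stats::residuals(fit)),
       fit = fit)
}

#' Two-way mixed ANOVA on activity waveforms
#'
#' Community is the between-participants factor and time bin the
#' within-participants factor:
#' `aov(value ~ community * bin + Error(participant))`. Returns F and p for
#' community (between stratum), time, and the community-by-time interaction
#' (within stratum).
#'
#' @param waveforms named list of 48-bin participant waveforms.
#' @param roster roster mapping participants to communities.
#' @return data.frame of stat results: `community`, `time`,
#'   `community:time`.
#' @export
waveform_mixed_anova <- function(waveforms, roster) {
  ids <- names(waveforms)
  comm <- roster$community[match(ids, roster$participant_id)]
  if (length(unique(comm)) < 2L) {
    stop("between-participants factor undefined with a single community")
  }
  nb <- length(waveforms[[1]])
  d <- data.frame(
    value = unlist(waveforms, use.names = FALSE),
    participant = factor(rep(ids, each = nb)),
    community = factor(rep(comm, each = nb)),
    bin = factor(rep(seq_len(nb), times = length(ids)))
  )
  fit <- stats::aov(value ~ community * bin + Error(participant), data = d)
  s <- summary(fit)
  between <- s[["Error: participant"]][[1]]
  within <- s[["Error: Within"]][[1]]
  rn <- trimws(rownames(within))
  out <- rbind(
    stat_result("community",
                statistic = between$`F value`[trimws(rownames(between)) == "community"][1],
                df = between$Df[trimws(rownames(between)) == "community"][1],
                p_value = between$`Pr(>F)`[trimws(rownames(between)) == "community"][1]),
    stat_result("time", statistic = within$`F value`[rn == "bin"][1],
                df = within$Df[rn == "bin"][1],
                p_value = within$`Pr(>F)`[rn == "bin"][1]),
    stat_result("community:time",
                statistic = within$`F value`[rn == "community:bin"][1],
                df = within$Df[rn == "community:bin"][1],
                p_value = within$`Pr(>F)`[rn == "community:bin"][1])
  )
  rownames(out) <- NULL
  out
}
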