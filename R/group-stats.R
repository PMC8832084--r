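#' Two-sample t-test with Cohen's d
#'
#' Pooled-variance (Student) two-sample t-test by default, with Cohen's d
#' obtained from the t statistic as `d = t * sqrt(1/n1 + 1/n2)`. Welch's
#' unequal-variance test is available behind `var_equal = FALSE`.
#'
#' @param data Data frame.
#' @param value Name (string) of the numeric outcome column.
#' @param group Name (string) of the two-level grouping column; the reported
#'   t is for mean(level 1) - mean(level 2) in sorted/factor level order.
#' @param var_equal Pooled variance (default) or Welch.
#' @return One-row tibble: `t`, `df`, `p`, `cohens_d`, group means/SDs/ns.
#' @examples
#' d <- tibble::tibble(y = c(0, 1, 2, 2, 3, 4),
#'                     g = rep(c("a", "b"), each = 3))
#' two_sample_ttest(d, "y", "g")
#' @export
two_sample_ttest <- function(data, value, group, var_equal = TRUE) {
  check_columns(data, c(value, group), "data")
  g <- factor(data[[group]])
  if (nlevels(g) != 2) abort("group column must have exactly two levels")
  y <- data[[value]]
  y1 <- y[g == levels(g)[1]]
  y2 <- y[g == levels(g)[2]]
  if (length(y1) < 2 || length(y2) < 2) abort("need at least 2 per group")
  n1 <- length(y1); n2 <- length(y2)
  if (var_equal) {
    sp2 <- ((n1 - 1) * var(y1) + (n2 - 1) * var(y2)) / (n1 + n2 - 2)
    if (sp2 <= 0) abort("zero pooled variance; t-test undefined")
    tt <- stats::t.test(y1, y2, var.equal = TRUE)
  } else {
    tt <- stats::t.test(y1, y2, var.equal = FALSE)
  }
  t_stat <- unname(tt$statistic)
  tibble(group_1 = levels(g)[1], group_2 = levels(g)[2],
         t = t_stat, df = unname(tt$parameter), p = tt$p.value,
         cohens_d = t_stat * sqrt(1 / n1 + 1 / n2),
         mean_1 = mean(y1), mean_2 = mean(y2),
         sd_1 = sd(y1), sd_2 = sd(y2), n_1 = n1, n_2 = n2)
}

#' Covariate-adjusted group comparison
#'
#' Least-squares regression of the outcome on group plus covariates of no
#' interest; reports the group coefficient's t, df = n - (predictors + 1),
#' and a d-equivalent from the same t-to-d conversion as
#' [two_sample_ttest()].
#'
#' @param data Data frame.
#' @param value,group Column names as in [two_sample_ttest()].
#' @param covariates Character vector of covariate column names.
#' @return One-row tibble: `t`, `df`, `p`, `cohens_d`, `estimate` (adjusted
#'   group difference, level 1 minus level 2), `n_1`, `n_2`.
#' @export
adjusted_group_test <- function(data, value, group, covariates = character()) {
  check_columns(data, c(value, group, covariates), "data")
  g <- factor(data[[group]])
  if (nlevels(g) != 2) abort("group column must have exactly two levels")
  d <- data.frame(.y = data[[value]],
                  .g = as.numeric(g == levels(g)[1]),
                  as.data.frame(data)[, covariates, drop = FALSE])
  d <- d[complete.cases(d), ]
  fit <- lm(.y ~ ., data = d)
  if (anyNA(coef(fit))) {
    abort(paste("collinear predictors in adjusted group test:",
                paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  n1 <- sum(d$.g == 1); n2 <- sum(d$.g == 0)
  tibble(group_1 = levels(g)[1], group_2 = levels(g)[2],
         estimate = sm[".g", "Estimate"],
         t = sm[".g", "t value"], df = fit$df.residual,
         p = sm[".g", "Pr(>|t|)"],
         cohens_d = sm[".g", "t value"] * sqrt(1 / n1 + 1 / n2),
         n_1 = n1, n_2 = n2)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment of a vector of p-values, with rejection flags at
#' FDR level `q`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return Tibble with `p`, `p_adjusted` (monotone in `p`), `reject`.
#' @examples
#' bh_adjust(c(0.005, 0.03, 0.04))
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  tibble(p = p, p_adjusted = adj, reject = !is.na(adj) & adj <= q)
}

#' Pearson correlation test
#'
#' Pearson r with the exact t-based two-tailed test
#' (`t = r * sqrt(n - 2) / sqrt(1 - r^2)`) and the coefficient of
#' determination `R^2 = r^2`.
#'
#' @param data Data frame.
#' @param x,y Column names (strings) of the two numeric variables.
#' @return One-row tibble: `r`, `n`, `t`, `df`, `p`, `r_squared`.
#' @export
pearson_test <- function(data, x, y) {
  check_columns(data, c(x, y), "data")
  ok <- complete.cases(data[[x]], data[[y]])
  xv <- data[[x]][ok]; yv <- data[[y]][ok]
  if (length(xv) < 3) abort("pearson_test needs at least 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) abort("zero variance; correlation undefined")
  ct <- cor.test(xv, yv, method = "pearson")
  r <- unname(ct$estimate)
  tibble(r = r, n = length(xv), t = unname(ct$statistic),
         df = unname(ct$parameter), p = ct$p.value, r_squared = r^2)
}

#' Compare two independent correlations with Fisher's r-to-z test
#'
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-tailed p from the standard normal.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes (at least 4).
#' @return One-row tibble: `z`, `p`.
#' @examples
#' fisher_z_compare(0.439, 36, -0.12, 33)
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) abort("correlations must lie strictly in (-1, 1)")
  if (n1 < 4 || n2 < 4) abort("fisher_z_compare needs n >= 4 in both groups")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Greenhouse-Geisser corrected degrees of freedom
#'
#' Multiplies the numerator and denominator degrees of freedom of a
#' within-subject effect by the sphericity correction factor epsilon. For a
#' within factor with k levels and N subjects in g groups the uncorrected
#' dfs are `(k - 1, (k - 1) * (N - g))`; for the interaction of two
#' three-level within factors they are `(4, 4 * (N - g))`.
#'
#' @param epsilon Greenhouse-Geisser epsilon in \[1/df1, 1\].
#' @param df1,df2 Uncorrected numerator and denominator dfs.
#' @return One-row tibble with `df1_gg`, `df2_gg`.
#' @examples
#' gg_dfs(0.655, 2, 2 * 67) # the (1.31, 87.8) bookkeeping
#' @export
gg_dfs <- function(epsilon, df1, df2) {
  stopifnot(epsilon > 0, epsilon <= 1, df1 > 0, df2 > 0)
  tibble(df1_gg = epsilon * df1, df2_gg = epsilon * df2)
}

#' Mixed-design ANOVA on per-cell acceptance rates with GG correction
#'
#' Two-between-group x (3 reward x 3 effort)-within ANOVA on each subject's
#' per-cell acceptance rates. Sums of squares and Greenhouse-Geisser epsilon
#' come from a multivariate linear model (via \pkg{car}); the table reports,
#' per effect, the uncorrected dfs, epsilon (within effects only), corrected
#' dfs, F, GG-corrected p, and partial eta squared
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long data frame with one row per subject x cell: columns
#'   `subject_id`, `group`, `reward_level`, `effort_level`, and the value
#'   column named by `value` (default `"accept_rate"`). Each subject must
#'   have all 9 cells.
#' @param value Name of the per-cell value column.
#' @return A tibble with one row per effect.
#' @export
mixed_anova_gg <- function(data, value = "accept_rate") {
  check_columns(data, c("subject_id", "group", "reward_level",
                        "effort_level", value), "data")
  cells <- tidyr::pivot_wider(
    data,
    id_cols = c("subject_id", "group"),
    names_from = c("reward_level", "effort_level"),
    values_from = all_of(value), names_prefix = "c")
  cellcols <- setdiff(names(cells), c("subject_id", "group"))
  if (length(cellcols) != 9 || anyNA(cells[cellcols])) {
    abort("each subject needs a complete 3 x 3 grid of cell values")
  }
  if (min(table(cells$group)) < 2) abort("need at least 2 subjects per group")
  # sort cell columns by (reward, effort) so the within design lines up
  key <- do.call(rbind, strsplit(sub("^c", "", cellcols), "_"))
  ord <- order(as.numeric(key[, 1]), as.numeric(key[, 2]))
  cellcols <- cellcols[ord]
  Y <- as.matrix(cells[cellcols])
  grp <- factor(cells$group)
  idata <- tidyr::expand_grid(reward = factor(1:3), effort = factor(1:3)) %>%
    as.data.frame()
  mlm <- lm(Y ~ grp, contrasts = list(grp = "contr.sum"))
  an <- car::Anova(mlm, idata = idata, idesign = ~ reward * effort, type = 3)
  sm <- summary(an, multivariate = FALSE)
  ut <- sm$univariate.tests
  gg <- sm$pval.adjustments
  effects <- rownames(ut)
  out <- purrr::map_dfr(effects, function(ef) {
    eps <- if (ef %in% rownames(gg)) unname(gg[ef, "GG eps"]) else NA_real_
    tibble(
      effect = ef,
      ss = ut[ef, "Sum Sq"], error_ss = ut[ef, "Error SS"],
      df1 = ut[ef, "num Df"], df2 = ut[ef, "den Df"],
      F = ut[ef, "F value"], p_uncorrected = ut[ef, "Pr(>F)"],
      gg_epsilon = eps,
      df1_gg = ifelse(is.na(eps), ut[ef, "num Df"], eps * ut[ef, "num Df"]),
      df2_gg = ifelse(is.na(eps), ut[ef, "den Df"], eps * ut[ef, "den Df"]),
      p_gg = if (ef %in% rownames(gg)) unname(gg[ef, "Pr(>F[GG])"])
             else ut[ef, "Pr(>F)"],
      partial_eta2 = ut[ef, "Sum Sq"] / (ut[ef, "Sum Sq"] + ut[ef, "Error SS"])
    )
  })
  out %>% filter(.data$effect != "(Intercept)") %>%
    mutate(effect = gsub("grp", "group", .data$effect))
}

#' Per-subject, per-cell acceptance rates
#'
#' Helper turning a trial table into the subject x 9-cell acceptance-rate
#' table consumed by [mixed_anova_gg()].
#'
#' @param trials Trial records with `subject_id`, `group`, `reward_level`,
#'   `effort_level`, `accepted`.
#' @return Long tibble with one row per subject x cell and column
#'   `accept_rate`.
#' @export
acceptance_cell_means <- function(trials) {
  check_columns(trials, c("subject_id", "group", "reward_level",
                          "effort_level", "accepted"), "trials")
  trials %>%
    group_by(.data$subject_id, .data$group, .data$reward_level,
             .data$effort_level) %>%
    summarise(accept_rate = mean(.data$accepted), .groups = "drop")
}

#' Power of the two-sample pooled t-test
#'
#' Exact power via the noncentral t distribution with noncentrality
#' `ncp = d * sqrt(n1 * n2 / (n1 + n2))` and `df = n1 + n2 - 2`, two-tailed
#' rejection region at level `alpha`.
#'
#' @param n1,n2 Group sizes (at least 2 each).
#' @param d True standardized difference (Cohen's d).
#' @param alpha Two-tailed significance level.
#' @return Power (scalar in \[0, 1\]).
#' @examples
#' ttest_power(37, 33, d = 0.75) # about 0.87
#' @export
ttest_power <- function(n1, n2, d, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- qt(1 - alpha / 2, df)
  pt(tcrit, df, ncp = ncp, lower.tail = FALSE) + pt(-tcrit, df, ncp = ncp)
}
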