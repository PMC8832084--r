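test_that("pooled two-sample t-test matches hand arithmetic", {
  d0 <- tibble::tibble(y = rep(c(0, 1, 2), 2), g = rep(c("a", "b"), each = 3))
  r0 <- two_sample_ttest(d0, "y", "g")
  expect_equal(r0$t, 0)
  expect_equal(r0$cohens_d, 0)
  # {0,1,2} vs {2,3,4}: pooled SD = 1, SE = sqrt(2/3), t = -2/0.8165
  d1 <- tibble::tibble(y = c(0, 1, 2, 2, 3, 4), g = rep(c("a", "b"), each = 3))
  r1 <- two_sample_ttest(d1, "y", "g")
  expect_equal(r1$df, 4)
  expect_equal(r1$t, -2 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(round(r1$t, 3), -2.449)
  expect_equal(r1$cohens_d, r1$t * sqrt(1 / 3 + 1 / 3))
  # study-sized df bookkeeping
  d2 <- withr::with_seed(1, tibble::tibble(
    y = rnorm(69), g = rep(c("MT", "NMT"), c(36, 33))))
  expect_equal(two_sample_ttest(d2, "y", "g")$df, 67)
  # degenerate input
  expect_error(two_sample_ttest(
    tibble::tibble(y = rep(1, 6), g = rep(c("a", "b"), 3)), "y", "g"),
    "pooled variance")
})

test_that("covariate-adjusted test reduces to the plain t-test when orthogonal", {
  withr::with_seed(7, {
    n <- 40
    g <- rep(c("a", "b"), each = n / 2)
    # covariate exactly orthogonal to the group dummy and to the outcome
    cv <- rep(c(-1, 1), n / 2)
    y <- resid(lm(rnorm(n) ~ cv))
    d <- tibble::tibble(y = y, g = g, cv = cv)
    plain <- two_sample_ttest(d, "y", "g")
    adj <- adjusted_group_test(d, "y", "g", "cv")
    expect_equal(adj$estimate, plain$mean_1 - plain$mean_2, tolerance = 1e-10)
    # orthogonality leaves estimate and RSS unchanged, so t rescales with
    # the residual df only (projection argument)
    expect_equal(adj$t, plain$t * sqrt(adj$df / plain$df), tolerance = 1e-6)
  })
  # df counting: n = 69, group + 3 covariates
  d3 <- withr::with_seed(2, tibble::tibble(
    y = rnorm(69), g = rep(c("MT", "NMT"), c(36, 33)),
    c1 = rnorm(69), c2 = rnorm(69), c3 = rnorm(69)))
  expect_equal(adjusted_group_test(d3, "y", "g", c("c1", "c2", "c3"))$df, 64)
  # zero group effect in noiseless constructed data
  d4 <- tibble::tibble(y = rep(1:10, 2), g = rep(c("a", "b"), each = 10),
                       c1 = rep(1:10, 2))
  expect_lt(abs(adjusted_group_test(d4, "y", "g", "c1")$t), 1e-8)
  # collinearity is an error
  d5 <- d3 %>% dplyr::mutate(c4 = c1)
  expect_error(adjusted_group_test(d5, "y", "g", c("c1", "c4")), "collinear")
})

test_that("Benjamini-Hochberg step-up behaves as hand-computed", {
  expect_equal(bh_adjust(0.03)$p_adjusted, 0.03)
  expect_false(any(bh_adjust(rep(1, 5))$reject))
  # largest k with p(k) <= k q / m is k = 3: all rejected
  r <- bh_adjust(c(0.005, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  withr::with_seed(3, {
    for (i in 1:20) {
      p <- runif(12)^2
      a <- bh_adjust(p, q = 0.05)
      # adjusted p monotone in raw p
      expect_true(all(diff(a$p_adjusted[order(a$p)]) >= -1e-12))
      # BH rejections are a superset of Bonferroni rejections
      bonf <- p <= 0.05 / length(p)
      expect_true(all(a$reject[bonf]))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Pearson test matches hand covariance arithmetic", {
  d <- tibble::tibble(x = 1:4, y = 2 * (1:4) + 1)
  expect_equal(pearson_test(d, "x", "y")$r, 1)
  # hand arithmetic: deviation products sum 4, sqrt(5 * 5) = 5
  d2 <- tibble::tibble(x = 1:4, y = c(1, 3, 2, 4))
  r2 <- pearson_test(d2, "x", "y")
  expect_equal(r2$r, 0.8, tolerance = 1e-12)
  expect_equal(r2$r_squared, 0.64, tolerance = 1e-12)
  expect_equal(r2$df, 2)
  # the study's printed correlation implies its printed R^2
  expect_equal(round(0.439^2, 2), 0.19)
  expect_error(pearson_test(tibble::tibble(x = c(1, 1, 1), y = 1:3),
                            "x", "y"), "variance")
})

test_that("Fisher r-to-z comparison matches its closed form", {
  expect_equal(fisher_z_compare(0.3, 20, 0.3, 50)$z, 0)
  # atanh(0.5) / sqrt(2/27)
  expect_equal(fisher_z_compare(0.5, 30, 0, 30)$z,
               atanh(0.5) / sqrt(2 / 27), tolerance = 1e-12)
  expect_equal(round(fisher_z_compare(0.5, 30, 0, 30)$z, 3), 2.018)
  # antisymmetric under swapping the two correlations
  a <- fisher_z_compare(0.4, 25, -0.1, 40)
  b <- fisher_z_compare(-0.1, 40, 0.4, 25)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_error(fisher_z_compare(1, 30, 0, 30), "strictly")
  expect_error(fisher_z_compare(0.5, 3, 0, 30), "n >= 4")
})

make_anova_data <- function(n_per_group, seed, whiten = FALSE) {
  withr::with_seed(seed, {
    purrr::map_dfr(c("MT", "NMT"), function(gg) {
      n <- n_per_group
      Z <- matrix(rnorm(n * 9), n, 9)
      if (whiten) {
        Zc <- scale(Z, scale = FALSE)
        Z <- Zc %*% solve(chol(cov(Zc) * (n - 1) / n)) # exact sample cov
        Z <- scale(Z, scale = FALSE)
      }
      cells <- tidyr::expand_grid(reward_level = c(4, 8, 12),
                                  effort_level = c(0.2, 0.5, 0.8))
      purrr::map_dfr(seq_len(n), function(i) {
        cells %>% dplyr::mutate(
          subject_id = sprintf("%s%02d", gg, i), group = gg,
          accept_rate = Z[i, ] + 0.05 * reward_level - 0.3 * effort_level)
      })
    })
  })
}

test_that("mixed ANOVA epsilon is 1 under exact sphericity and >= 0.5 for k = 3", {
  d <- make_anova_data(14, seed = 5, whiten = TRUE)
  # whitening makes each group's sample covariance exactly spherical
  tab <- suppressWarnings(mixed_anova_gg(d))
  within <- tab[!is.na(tab$gg_epsilon), ]
  expect_true(all(abs(within$gg_epsilon - 1) < 1e-6))
  d2 <- make_anova_data(10, seed = 6)
  tab2 <- suppressWarnings(mixed_anova_gg(d2))
  eps3 <- tab2$gg_epsilon[tab2$effect %in% c("reward", "effort")]
  expect_true(all(eps3 >= 0.5 - 1e-12 & eps3 <= 1 + 1e-12))
})

test_that("uncorrected mixed ANOVA agrees with the base-R aov oracle", {
  d <- make_anova_data(9, seed = 8)
  tab <- suppressWarnings(mixed_anova_gg(d))
  oracle <- aov_mixed_oracle(d)
  for (ef in names(oracle)) {
    expect_equal(tab$F[tab$effect == ef], unname(oracle[[ef]]),
                 tolerance = 1e-8, info = ef)
  }
  # partial eta^2 consistency: SS / (SS + SS_error)
  expect_equal(tab$partial_eta2,
               tab$ss / (tab$ss + tab$error_ss))
  # corrected dfs are epsilon times the uncorrected dfs
  w <- !is.na(tab$gg_epsilon)
  expect_equal(tab$df1_gg[w], tab$gg_epsilon[w] * tab$df1[w])
  expect_equal(tab$df2_gg[w], tab$gg_epsilon[w] * tab$df2[w])
  # missing cells are an error
  expect_error(mixed_anova_gg(d[-1, ]), "complete")
})

test_that("GG df bookkeeping reproduces the study's printed dfs", {
  # within main effect: k = 3, N = 69, g = 2 -> (eps*2, eps*2*67)
  main <- gg_dfs(0.655, 2, 2 * 67)
  expect_equal(round(main$df1_gg, 2), 1.31)
  expect_equal(round(main$df2_gg, 1), 87.8)
  inter <- gg_dfs(0.6525, 4, 4 * 67)
  expect_equal(round(inter$df1_gg, 2), 2.61)
  expect_equal(round(inter$df2_gg, 1), 174.9)
})

test_that("t-test power matches theory and is monotone", {
  expect_equal(ttest_power(20, 20, 0), 0.05, tolerance = 1e-10)
  expect_gte(ttest_power(37, 33, 0.75), 0.80) # the study's design point
  # monotone in |d| and in group size
  ds <- seq(0, 2, by = 0.25)
  expect_true(all(diff(vapply(ds, function(d) ttest_power(30, 30, d),
                              numeric(1))) > 0))
  ns <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(vapply(ns, function(n) ttest_power(n, n, 0.5),
                              numeric(1))) > 0))
})

test_that("power agrees with a large Monte-Carlo simulation of the t-test", {
  n1 <- 37; n2 <- 33; d <- 0.75
  theory <- ttest_power(n1, n2, d)
  reps <- 100000
  rej <- withr::with_seed(123, {
    x1 <- matrix(rnorm(reps * n1, mean = d), reps, n1)
    x2 <- matrix(rnorm(reps * n2), reps, n2)
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- (rowSums(x1^2) - n1 * m1^2) / (n1 - 1)
    v2 <- (rowSums(x2^2) - n2 * m2^2) / (n2 - 1)
    sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
    tstat <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
    mean(abs(tstat) > qt(0.975, n1 + n2 - 2))
  })
  expect_lt(abs(theory - rej), 0.01)
})
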