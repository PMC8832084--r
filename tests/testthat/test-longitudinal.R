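make_long_data <- function(n, seed, b_base = 0.5, b_acc = -0.3,
                           noise_sd = 0, group = "MT") {
  withr::with_seed(seed, tibble::tibble(
    subject_id = sprintf("L%04d", seq_len(n)),
    group = group,
    baseline_symptoms = pmax(0, rnorm(n, 2.7, 2.2)),
    acc_beta = rnorm(n),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = runif(n, 10, 16),
    pubertal_status = sample(1:4, n, replace = TRUE),
    mt_severity = if (group[1] == "MT") sample(1:4, n, replace = TRUE) else 0,
    followup_symptoms = 1 + b_base * baseline_symptoms + b_acc * acc_beta +
      rnorm(n, 0, noise_sd)
  ))
}

test_that("noiseless generation is recovered to machine tolerance", {
  d <- make_long_data(30, seed = 1)
  fit <- fit_followup_regression(d)
  r <- tidy(fit)
  expect_equal(r$estimate[r$term == "baseline_symptoms"], 0.5,
               tolerance = 1e-10)
  expect_equal(r$estimate[r$term == "acc_beta"], -0.3, tolerance = 1e-10)
  expect_equal(r$estimate[r$term == "age"], 0, tolerance = 1e-10)
  expect_equal(glance(fit)$r_squared, 1, tolerance = 1e-10)
  # reported df is n - predictors - 1 exactly
  expect_equal(unique(r$df), 30 - 6 - 1)
})

test_that("standardized beta equals Pearson r in a single-predictor model", {
  d <- make_long_data(40, seed = 2, noise_sd = 1.5)
  fit <- effortdm:::fit_symptom_lm(d, "followup_symptoms", "acc_beta")
  r <- cor(d$followup_symptoms, d$acc_beta)
  expect_equal(fit$report$std_estimate[fit$report$term == "acc_beta"], r,
               tolerance = 1e-10)
})

test_that("a null ACC slope estimates to zero within 3 SEs at large n", {
  d <- make_long_data(5000, seed = 3, b_acc = 0, noise_sd = 1)
  fit <- fit_followup_regression(d)
  r <- tidy(fit)
  est <- r$estimate[r$term == "acc_beta"]
  se <- summary(fit$lm)$coefficients["acc_beta", "Std. Error"]
  expect_lt(abs(est), 3 * se)
})

test_that("interaction model isolates the group slope difference", {
  mt <- make_long_data(25, seed = 4, b_acc = -0.4)
  nmt <- make_long_data(25, seed = 5, b_acc = 0, group = "NMT")
  both <- dplyr::bind_rows(mt, nmt)
  fit <- fit_interaction_model(both)
  r <- tidy(fit)
  # MT coded 1: interaction = MT slope - NMT slope = -0.4 exactly
  expect_equal(r$estimate[r$term == "acc_beta:group_mt"], -0.4,
               tolerance = 1e-9)
  expect_equal(r$estimate[r$term == "acc_beta"], 0, tolerance = 1e-9)
  # identical slopes: interaction exactly zero
  nmt2 <- make_long_data(25, seed = 6, b_acc = -0.4, group = "NMT")
  fit2 <- fit_interaction_model(dplyr::bind_rows(mt, nmt2))
  expect_equal(tidy(fit2)$estimate[tidy(fit2)$term == "acc_beta:group_mt"],
               0, tolerance = 1e-9)
  # one group only violates the precondition
  expect_error(fit_interaction_model(mt), "both groups")
})

test_that("partial regression points obey the Frisch-Waugh-Lovell identity", {
  d <- make_long_data(35, seed = 7, noise_sd = 2)
  fit <- fit_followup_regression(d)
  pts <- partial_regression_points(fit, "acc_beta")
  full_coef <- tidy(fit)$estimate[tidy(fit)$term == "acc_beta"]
  expect_equal(attr(pts, "slope"), full_coef, tolerance = 1e-10)
  expect_equal(mean(pts$resid_focal), 0, tolerance = 1e-12)
  expect_equal(mean(pts$resid_outcome), 0, tolerance = 1e-12)
  # correlation of the cloud equals the matrix-inverse partial correlation
  num <- fit$data
  mat <- cbind(num$followup_symptoms, num$acc_beta,
               num$baseline_symptoms, num$sex, num$age,
               num$pubertal_status, num$mt_severity)
  expect_equal(cor(pts$resid_outcome, pts$resid_focal),
               partial_cor_matrix_inverse(mat), tolerance = 1e-10)
  expect_error(partial_regression_points(fit, "not_a_predictor"),
               "not a predictor")
})

test_that("delta R-squared matches the two-fit oracle and sums below R^2", {
  d <- make_long_data(60, seed = 8, noise_sd = 2)
  fit <- fit_followup_regression(d)
  r <- tidy(fit)
  r2 <- glance(fit)$r_squared
  preds <- r$term[-1]
  for (p in preds) {
    rest <- setdiff(preds, p)
    reduced <- lm(stats::reformulate(make.names(rest),
                                     response = "followup_symptoms"),
                  data = fit$data)
    expect_equal(r$delta_r2[r$term == p],
                 r2 - summary(reduced)$r.squared, tolerance = 1e-10,
                 info = p)
    expect_gte(r$delta_r2[r$term == p], -1e-12)
  }
  # with exactly orthogonal predictors the increments partition R^2
  withr::with_seed(11, {
    # columns orthogonal to each other and to the intercept
    Q <- qr.Q(qr(cbind(1, matrix(rnorm(50 * 3), 50, 3))))[, 2:4]
    d_orth <- tibble::tibble(
      followup_symptoms = as.numeric(Q %*% c(1, -0.5, 0.25)) +
        rnorm(50, 0, 0.1),
      baseline_symptoms = Q[, 1], acc_beta = Q[, 2], extra = Q[, 3])
  })
  f_orth <- effortdm:::fit_symptom_lm(d_orth, "followup_symptoms",
                                      c("baseline_symptoms", "acc_beta",
                                        "extra"))
  expect_equal(sum(f_orth$report$delta_r2[-1]), f_orth$r_squared,
               tolerance = 1e-10)
})

test_that("generator coefficients are recovered across replicates at n = 27", {
  # cohorts at the MT follow-up size; mean estimate within 3 SEs of truth
  ests <- purrr::map_dfr(1:200, function(i) {
    d <- make_long_data(27, seed = 1000 + i, b_base = 0.6, b_acc = -1,
                        noise_sd = 1.5)
    r <- tidy(fit_followup_regression(d))
    tibble::tibble(b_base = r$estimate[r$term == "baseline_symptoms"],
                   b_acc = r$estimate[r$term == "acc_beta"])
  })
  expect_lt(abs(mean(ests$b_base) - 0.6),
            3 * sd(ests$b_base) / sqrt(nrow(ests)))
  expect_lt(abs(mean(ests$b_acc) - (-1)),
            3 * sd(ests$b_acc) / sqrt(nrow(ests)))
})

test_that("too-small samples and rank deficiency are explicit errors", {
  d <- make_long_data(7, seed = 9)
  expect_error(fit_followup_regression(d), "too few")
  d2 <- make_long_data(30, seed = 10) %>%
    dplyr::mutate(age = pubertal_status) # collinear
  expect_error(fit_followup_regression(d2), "collinear|rank")
})
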