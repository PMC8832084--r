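test_that("canonical HRF has the expected shape", {
  tg <- seq(0, 32, by = 0.1)
  h <- canonical_hrf(tg)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  # peak location near 5 s on a dense grid
  expect_lt(abs(tg[which.max(h)] - 5.0), 0.15)
  # undershoot exists and is small relative to the peak
  expect_lt(min(h), 0)
  expect_gt(min(h), -0.3)
  expect_error(canonical_hrf(numeric(0)), "empty")
  expect_error(canonical_hrf(c(1, 0.5)), "increasing")
})

test_that("HRF integral and peak location are stable across grids", {
  for (dt in c(0.1, 0.5)) {
    tg <- seq(0, 32, by = dt)
    h <- canonical_hrf(tg)
    assign(paste0("int_", dt * 10), sum(h) * dt)
    assign(paste0("peak_", dt * 10), tg[which.max(h)])
  }
  expect_lt(abs(int_1 - int_5) / abs(int_1), 0.01)
  expect_lte(abs(peak_1 - peak_5), 0.5)
})

test_that("design matrix columns match a direct-summation convolution", {
  ev <- tibble::tibble(
    onset = c(2, 20, 40), duration = c(3.5, 4, 3),
    condition = "decision",
    subjective_reward = c(0.5, 1.5, 2.5))
  n_scans <- 40
  X <- build_design_matrix(ev, n_scans, tr = 2, dt = 0.1)
  expect_setequal(colnames(X), c("decision", "decision_subjective_reward",
                                 "intercept"))
  oracle_cond <- direct_convolution(ev$onset, ev$duration, rep(1, 3),
                                    n_scans, 2, 0.1)
  expect_equal(unname(X[, "decision"]), oracle_cond, tolerance = 1e-8)
  centered <- ev$subjective_reward - mean(ev$subjective_reward)
  oracle_mod <- direct_convolution(ev$onset, ev$duration, centered,
                                   n_scans, 2, 0.1)
  expect_equal(unname(X[, "decision_subjective_reward"]), oracle_mod,
               tolerance = 1e-8)
})

test_that("degenerate designs are handled explicitly", {
  # no events: only the intercept is nonzero
  empty <- tibble::tibble(onset = numeric(0), duration = numeric(0),
                          condition = character(0))
  X0 <- build_design_matrix(empty, 10)
  expect_equal(colnames(X0), "intercept")
  # constant modulator: centered to zero, dropped with a warning
  ev <- tibble::tibble(onset = c(2, 20), duration = 3, condition = "decision",
                       m = c(1, 1))
  expect_warning(X <- build_design_matrix(ev, 30), "constant")
  expect_false("decision_m" %in% colnames(X))
  # collinear columns are named in the rank-deficiency error
  ev2 <- tibble::tibble(onset = c(2, 20), duration = 3,
                        condition = "decision",
                        m1 = c(0, 2), m2 = c(0, 2))
  expect_error(build_design_matrix(ev2, 30), "decision_m2")
})

test_that("sphere voxel sets equal brute-force lattice enumeration", {
  expect_equal(nrow(sphere_voxel_set(c(0, 0, 0), radius = 0)), 1)
  expect_equal(nrow(sphere_voxel_set(c(0, 14, 46), 6, 2)), 123)
  ctr <- sphere_voxel_set(c(0, 14, 46), 6, 2)
  expect_true(any(ctr$x == 0 & ctr$y == 14 & ctr$z == 46))
  for (r in c(0, 2, 3, 5, 6, 8, 10)) {
    expect_equal(nrow(sphere_voxel_set(c(0, 0, 0), r, 2)),
                 brute_force_sphere_count(r, 2),
                 info = paste("radius", r))
  }
})

test_that("ROI masks render the sphere on the template grid", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_roi_mask(c(0, 14, 46), f)
  img <- RNifti::readNifti(f)
  expect_equal(sum(img), 123)
})

test_that("first-level OLS is exact on noiseless data and errors on rank loss", {
  ev <- tibble::tibble(
    onset = seq(5, 200, by = 15), duration = 3.5, condition = "decision",
    subjective_reward = sin(seq_len(14)),
    subjective_effort = cos(seq_len(14)))
  X <- build_design_matrix(ev, 120)
  b_true <- c(decision = 1.2, decision_subjective_reward = 0.8,
              decision_subjective_effort = -0.6, intercept = 10)
  y <- as.numeric(X %*% b_true[colnames(X)])
  fit <- fit_first_level(y, X)
  expect_equal(setNames(fit$betas$estimate, fit$betas$term),
               b_true[fit$betas$term], tolerance = 1e-10)
  expect_equal(sort(fit$contrasts$modulator), c("effort", "reward"))
  expect_equal(fit$contrasts$estimate[fit$contrasts$modulator == "reward"],
               0.8, tolerance = 1e-10)
  Xbad <- cbind(X, dup = X[, 1])
  expect_error(fit_first_level(y, Xbad), "dup")
  expect_error(fit_first_level(y[-1], X), "length")
})

test_that("orthonormal designs reduce OLS to projections", {
  n <- 64
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  colnames(Q) <- c("a", "b", "c")
  y <- rnorm(n)
  fit <- fit_first_level(y, Q)
  expect_equal(fit$betas$estimate, as.numeric(crossprod(Q, y)),
               tolerance = 1e-10)
})

test_that("OLS betas are unbiased under noise", {
  ev <- tibble::tibble(onset = seq(5, 150, by = 12), duration = 3.5,
                       condition = "decision",
                       subjective_effort = seq_len(13) - 7)
  X <- build_design_matrix(ev, 90)
  b_true <- c(decision = 1, decision_subjective_effort = 0.5, intercept = 0)
  mu <- as.numeric(X %*% b_true[colnames(X)])
  est <- withr::with_seed(14, vapply(1:200, function(i) {
    fit_first_level(mu + rnorm(length(mu)), X)$betas$estimate[
      which(colnames(X) == "decision_subjective_effort")]
  }, numeric(1)))
  se_mean <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5), 3 * se_mean)
})

test_that("bilateral combination is the arithmetic mean", {
  expect_equal(combine_bilateral(1, 1), 1)
  expect_equal(combine_bilateral(0.2, 0.6), 0.4)
  x <- rnorm(5)
  expect_equal(combine_bilateral(x, x), x)
  expect_error(combine_bilateral(1, NA), "finite")
})

test_that("noiseless ROI round trip through the full GLM path is exact", {
  sched <- build_offer_schedule(seed = 8)
  pars <- choice_params(1.5, 2, -1, -3, 0.03)
  tr <- simulate_choices(sched, pars, seed = 9)
  tr$subject_id <- "S1"
  tr <- subjective_modulators(tr, pars) %>% cost_benefit_weights()
  ev <- events_from_trials(tr)
  n_scans <- ceiling((max(ev$onset + ev$duration) + 32) / 2)
  X <- build_design_matrix(ev, n_scans)
  bt <- c(decision = 1, exertion = 0.8, outcome = 0.5,
          decision_subjective_reward = 0.35,
          decision_subjective_effort = -0.25)
  y <- simulate_roi_signal(X, bt, noise_sd = 0, seed = 1)
  fl <- fit_first_level(y, X)
  expect_equal(fl$contrasts$estimate[fl$contrasts$modulator == "effort"],
               -0.25, tolerance = 1e-9)
  expect_equal(fl$contrasts$estimate[fl$contrasts$modulator == "reward"],
               0.35, tolerance = 1e-9)
  expect_lt(fl$sigma2, 1e-18)
})
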