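# Independent oracles used across test files. Each is deliberately written
# with a different method from the implementation it checks.

# brute-force lattice enumeration of sphere voxel counts
brute_force_sphere_count <- function(radius, spacing) {
  k <- ceiling(radius / spacing) + 1
  cnt <- 0L
  for (dx in seq(-k, k)) for (dy in seq(-k, k)) for (dz in seq(-k, k)) {
    if ((dx^2 + dy^2 + dz^2) * spacing^2 <= radius^2) cnt <- cnt + 1L
  }
  cnt
}

# direct-summation convolution of an event stream with the HRF, sampled at
# scan times (O(n^2) reference for the FFT-based implementation)
direct_convolution <- function(onsets, durations, amplitudes, n_scans, tr, dt) {
  t_max <- n_scans * tr + 32
  grid_n <- ceiling(t_max / dt) + 1
  stick <- numeric(grid_n)
  for (k in seq_along(onsets)) {
    i0 <- floor(onsets[k] / dt) + 1
    i1 <- max(i0, floor((onsets[k] + durations[k]) / dt))
    stick[i0:min(i1, grid_n)] <- stick[i0:min(i1, grid_n)] + amplitudes[k]
  }
  h <- canonical_hrf(seq(0, 32, by = dt))
  out <- numeric(grid_n)
  for (i in seq_len(grid_n)) {
    jmax <- min(i, length(h))
    out[i] <- sum(stick[i - seq_len(jmax) + 1] * h[seq_len(jmax)]) * dt
  }
  scan_t <- (seq_len(n_scans) - 1) * tr
  out[pmin(grid_n, floor(scan_t / dt) + 1)]
}

# penalized maximum likelihood for the no-lapse choice model: direct
# numerical optimization of the Bernoulli log-likelihood plus log-prior
penalized_ml_choice <- function(trials, prior_sd) {
  nll <- function(th) {
    p <- choice_params(th[1], th[2], th[3], 0, 0)
    -(choice_log_likelihood(trials, p) +
        sum(dnorm(th, 0, prior_sd, log = TRUE)))
  }
  o <- optim(c(0, 0, 0), nll, method = "BFGS", control = list(maxit = 1000))
  setNames(o$par, c("intercept", "reward_lin", "effort_lin"))
}

# partial correlation of variables 1 and 2 given the rest, from the inverse
# correlation matrix
partial_cor_matrix_inverse <- function(mat) {
  P <- solve(cor(mat))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# uncorrected mixed-design repeated-measures ANOVA via base aov (independent
# engine from the car-based implementation); returns F per within effect
aov_mixed_oracle <- function(long) {
  long$subject_id <- factor(long$subject_id)
  long$reward <- factor(long$reward_level)
  long$effort <- factor(long$effort_level)
  long$group <- factor(long$group)
  fit <- stats::aov(accept_rate ~ group * reward * effort +
                      Error(subject_id / (reward * effort)), data = long)
  sm <- summary(fit)
  getF <- function(stratum, effect) {
    tab <- sm[[stratum]][[1]]
    tab[trimws(rownames(tab)) == effect, "F value"]
  }
  c(reward = getF("Error: subject_id:reward", "reward"),
    effort = getF("Error: subject_id:effort", "effort"),
    `reward:effort` = getF("Error: subject_id:reward:effort", "reward:effort"))
}

# subjects whose choices come from an intercept+noise-only process
make_null_subjects <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    subject_id = sprintf("N%03d", seq_len(n)),
    intercept = rnorm(n, 1.5, 1),
    reward_lin = 0, effort_lin = 0, effort_quad = 0,
    noise = plogis(rnorm(n, -3, 1))
  ))
}

# simulate a full trial table for a set of subject parameter rows
simulate_trials_for <- function(subjects, schedule, seed) {
  purrr::map_dfr(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    simulate_choices(schedule,
                     choice_params(s$intercept, s$reward_lin, s$effort_lin,
                                   s$effort_quad, s$noise),
                     seed = seed + i) |>
      dplyr::mutate(subject_id = s$subject_id, .before = 1)
  })
}

# small sampler settings used in tests to stay inside time budgets
fast_sampler <- function(seed = 1, chains = 1) {
  sampler_config(n_chains = chains, n_adapt = 300, n_warmup = 300,
                 n_iter = 500, seed = seed)
}
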