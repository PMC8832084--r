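#' Configuration of a synthetic effort-task cohort
#'
#' Bundles and validates everything the cohort generator needs: group sizes,
#' the group-level distributions of the five choice parameters, the ROI
#' effect structure, the longitudinal symptom model, and the task design.
#'
#' Defaults encode the study conditions this package emulates: 37 maltreated
#' (MT) and 33 non-maltreated (NMT) subjects; identical choice-parameter
#' distributions in both groups (no behavioural group difference), with
#' group-level means giving a mean acceptance rate near 70%; a standardized
#' MT-vs-NMT difference of `roi_effect = 0.52` in the anterior cingulate
#' (ACC) effort-modulation beta with NMT higher; within the MT group the ACC
#' beta is coupled to linear effort sensitivity with target correlation
#' `roi_coupling = 0.44`; and follow-up internalizing symptoms generated
#' linearly from baseline symptoms, the ACC beta (negative slope in the MT
#' group only), covariates and Gaussian noise.
#'
#' @param n_mt,n_nmt Group sizes (each at least 2).
#' @param param_means,param_sds Named numeric vectors over
#'   `intercept, reward_lin, effort_lin, effort_quad, noise_logit`; the lapse
#'   parameter is drawn on the logit scale. Used for both groups.
#' @param roi_effect Standardized ACC effort-modulation group difference
#'   (Cohen's d), NMT minus MT.
#' @param roi_coupling Target correlation between ACC effort beta and linear
#'   effort sensitivity within the MT group.
#' @param roi_beta_sd Within-group SD of ROI betas.
#' @param roi_means Named list of mean betas for the null ROIs/modulators.
#' @param success_prob Success probabilities of exertion at the three effort
#'   levels (low to high).
#' @param symptom_model Named list of coefficients of the follow-up symptom
#'   model: `intercept`, `b_base`, `b_acc_mt`, `b_acc_nmt`, `b_age`, `b_sex`,
#'   `b_pds`, `b_sev`, `noise_sd`.
#' @param n_runs,reps_per_cell Task design passed to [build_offer_schedule()].
#' @param master_seed Integer seed from which all stage seeds are derived.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_mt = 37, n_nmt = 33,
                          param_means = c(intercept = 1.5, reward_lin = 2,
                                          effort_lin = -1, effort_quad = -3,
                                          noise_logit = -3),
                          param_sds = c(intercept = 1, reward_lin = 1,
                                        effort_lin = 1.5, effort_quad = 2,
                                        noise_logit = 1),
                          roi_effect = 0.52,
                          roi_coupling = 0.44,
                          roi_beta_sd = 1,
                          roi_means = list(acc_effort_nmt = 0.5,
                                           acc_reward = 0.3,
                                           striatum_effort = 0.4,
                                           striatum_reward = 0.3),
                          success_prob = c(0.95, 0.85, 0.75),
                          symptom_model = list(intercept = 1, b_base = 0.6,
                                               b_acc_mt = -1, b_acc_nmt = 0,
                                               b_age = 0, b_sex = 0.3,
                                               b_pds = 0, b_sev = 0.2,
                                               noise_sd = 1.5),
                          n_runs = 3, reps_per_cell = 8,
                          master_seed = 1) {
  par_names <- c("intercept", "reward_lin", "effort_lin", "effort_quad",
                 "noise_logit")
  if (!all(par_names %in% names(param_means)) ||
      !all(par_names %in% names(param_sds))) {
    abort("param_means and param_sds must name all five choice parameters")
  }
  if (n_mt < 2 || n_nmt < 2) abort("group sizes must be at least 2")
  if (any(param_sds <= 0)) abort("parameter SDs must be positive")
  if (!is_scalar_number(roi_effect)) abort("roi_effect must be a finite number")
  if (abs(roi_coupling) >= 1) abort("roi_coupling must lie in (-1, 1)")
  if (length(success_prob) != 3 || any(success_prob < 0 | success_prob > 1)) {
    abort("success_prob must be three probabilities in [0, 1]")
  }
  if (symptom_model$noise_sd < 0) abort("symptom noise SD must be non-negative")
  if (!is_scalar_number(master_seed)) abort("master_seed must be an integer")
  structure(list(
    n_mt = n_mt, n_nmt = n_nmt,
    param_means = param_means[par_names], param_sds = param_sds[par_names],
    roi_effect = roi_effect, roi_coupling = roi_coupling,
    roi_beta_sd = roi_beta_sd, roi_means = roi_means,
    success_prob = success_prob, symptom_model = symptom_model,
    n_runs = n_runs, reps_per_cell = reps_per_cell,
    master_seed = master_seed
  ), class = "cohort_config")
}

#' Draw per-subject profiles from the group-level distributions
#'
#' Samples each subject's true choice parameters from normal group-level
#' distributions (lapse on the logit scale), together with covariates: age
#' uniform on 10-16 years, sex Bernoulli (60% female), pubertal status on an
#' ordinal 1-4 scale loosely tracking age, and, for MT subjects only, a
#' maltreatment severity rating on 1-4 (0 for NMT by definition).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (defaults to a stage seed derived from the
#'   config's master seed).
#' @return One row per subject: `subject_id`, `group`, covariates, the five
#'   true parameters (`intercept`, `reward_lin`, `effort_lin`, `effort_quad`,
#'   `noise`), and per-effort-level success probabilities.
#' @export
simulate_subject_profiles <- function(config,
                                      seed = derive_seed(config$master_seed,
                                                         "profiles")) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_mt + config$n_nmt
  mu <- config$param_means
  sdv <- config$param_sds
  withr::with_seed(seed, {
    age <- runif(n, 10, 16)
    pds <- pmin(4, pmax(1, round((age - 9) / 2 + rnorm(n, 0, 0.5))))
    tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = rep(c("MT", "NMT"), c(config$n_mt, config$n_nmt)),
      age = age,
      sex = ifelse(rbinom(n, 1, 0.6) == 1, "F", "M"),
      pubertal_status = pds,
      mt_severity = ifelse(rep(c(TRUE, FALSE), c(config$n_mt, config$n_nmt)),
                           sample(1:4, n, replace = TRUE), 0L),
      intercept = rnorm(n, mu["intercept"], sdv["intercept"]),
      reward_lin = rnorm(n, mu["reward_lin"], sdv["reward_lin"]),
      effort_lin = rnorm(n, mu["effort_lin"], sdv["effort_lin"]),
      effort_quad = rnorm(n, mu["effort_quad"], sdv["effort_quad"]),
      noise = plogis(rnorm(n, mu["noise_logit"], sdv["noise_logit"])),
      success_p_low = config$success_prob[1],
      success_p_mid = config$success_prob[2],
      success_p_high = config$success_prob[3]
    )
  })
}

#' Simulate one subject's choices on an offer schedule
#'
#' Draws each trial's accept/decline decision as a Bernoulli variable with
#' probability from [acceptance_probability()]. On accepted trials the
#' exertion succeeds with the effort-level-specific probability, the mean
#' applied force is the required MVC fraction plus small Gaussian wobble
#' (shifted up on success, down on failure), and `points_won` equals the
#' reward level on success. Points are never deducted. Declined trials carry
#' `NA` force/success and zero points.
#'
#' @param schedule A schedule from [build_offer_schedule()].
#' @param params A [choice_params()] row (the subject's true parameters).
#' @param success_prob Success probabilities at the three effort levels
#'   (ascending effort).
#' @param seed Integer seed.
#' @return The schedule as a tibble with added `accepted`, `mean_force`,
#'   `success`, `points_won` columns.
#' @export
simulate_choices <- function(schedule, params,
                             success_prob = c(0.95, 0.85, 0.75), seed = 1) {
  check_columns(schedule, c("reward_level", "effort_level"), "schedule")
  if (nrow(schedule) == 0) abort("schedule must contain at least one trial")
  validate_choice_params(params)
  p <- acceptance_probability(schedule, params)$accept_prob
  eff_rank <- match(schedule$effort_level, sort(unique(schedule$effort_level)))
  sp <- success_prob[pmin(eff_rank, length(success_prob))]
  withr::with_seed(seed, {
    accepted <- rbinom(nrow(schedule), 1, p) == 1
    success <- rbinom(nrow(schedule), 1, sp) == 1
    wobble <- abs(rnorm(nrow(schedule), 0, 0.05))
    force <- pmax(0, schedule$effort_level + ifelse(success, wobble, -wobble))
    dplyr::as_tibble(schedule) %>%
      mutate(
        accepted = accepted,
        mean_force = ifelse(accepted, force, NA_real_),
        success = ifelse(accepted, success, NA),
        points_won = ifelse(accepted & success, .data$reward_level, 0L)
      )
  })
}

#' Simulate per-subject ROI contrast estimates
#'
#' Draws effort- and reward-modulation betas for the ACC and the left/right
#' striatum. ACC effort betas differ between groups by `roi_effect` pooled
#' SDs (NMT above MT); within the MT group the ACC effort beta is coupled to
#' the subject's linear effort sensitivity with correlation `roi_coupling`.
#' All other ROI/modulator combinations have no group difference.
#'
#' @param subjects Profiles from [simulate_subject_profiles()].
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A tibble with columns `subject_id`, `roi` (`acc`,
#'   `striatum_left`, `striatum_right`), `modulator` (`effort`, `reward`)
#'   and `beta`.
#' @export
simulate_roi_contrasts <- function(subjects, config,
                                   seed = derive_seed(config$master_seed,
                                                      "roi_contrasts")) {
  stopifnot(inherits(config, "cohort_config"))
  check_columns(subjects, c("subject_id", "group", "effort_lin"), "subjects")
  n <- nrow(subjects)
  is_mt <- subjects$group == "MT"
  sdv <- config$roi_beta_sd
  mu_nmt <- config$roi_means$acc_effort_nmt
  mu_mt <- mu_nmt - config$roi_effect * sdv
  rho <- config$roi_coupling
  withr::with_seed(seed, {
    eps <- rnorm(n)
    acc_effort <- numeric(n)
    acc_effort[!is_mt] <- mu_nmt + sdv * eps[!is_mt]
    # standardize by the population (generator) parameters, not the sample,
    # so subjects stay independent and betas are marginally N(mu, sd^2)
    z_eff <- (subjects$effort_lin[is_mt] - config$param_means["effort_lin"]) /
      config$param_sds["effort_lin"]
    acc_effort[is_mt] <- mu_mt +
      sdv * (rho * z_eff + sqrt(1 - rho^2) * eps[is_mt])
    grid <- tidyr::expand_grid(
      subject_id = subjects$subject_id,
      roi = c("acc", "striatum_left", "striatum_right"),
      modulator = c("effort", "reward")
    )
    mu_map <- c(acc.reward = config$roi_means$acc_reward,
                striatum_left.effort = config$roi_means$striatum_effort,
                striatum_right.effort = config$roi_means$striatum_effort,
                striatum_left.reward = config$roi_means$striatum_reward,
                striatum_right.reward = config$roi_means$striatum_reward)
    grid <- grid %>%
      mutate(beta = rnorm(dplyr::n(),
                          mean = mu_map[paste(.data$roi, .data$modulator,
                                              sep = ".")] %>%
                            tidyr::replace_na(0),
                          sd = sdv))
    grid$beta[grid$roi == "acc" & grid$modulator == "effort"] <-
      acc_effort[match(grid$subject_id[grid$roi == "acc" &
                                         grid$modulator == "effort"],
                       subjects$subject_id)]
    grid
  })
}

#' Simulate baseline and follow-up internalizing symptom scores
#'
#' Baseline symptoms are drawn from group-specific normal distributions
#' (MT mean 2.7, SD 2.2; NMT mean 1.7, SD 1.9, floored at 0). Follow-up
#' symptoms are a linear function of baseline symptoms, the subject's ACC
#' effort-modulation beta (group-specific slope, negative in the MT group by
#' default, so lower ACC activation predicts more symptoms), covariates, and
#' Gaussian noise, per the config's `symptom_model`.
#'
#' @param subjects Profiles from [simulate_subject_profiles()].
#' @param contrasts Contrast table from [simulate_roi_contrasts()]; every
#'   subject must have an ACC effort beta.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A tibble of longitudinal records: `subject_id`, `group`,
#'   covariates, `acc_beta`, `baseline_symptoms`, `followup_symptoms`.
#' @export
simulate_symptom_panel <- function(subjects, contrasts, config,
                                   seed = derive_seed(config$master_seed,
                                                      "symptoms")) {
  stopifnot(inherits(config, "cohort_config"))
  acc <- contrasts %>%
    filter(.data$roi == "acc", .data$modulator == "effort") %>%
    select("subject_id", acc_beta = "beta")
  missing <- setdiff(subjects$subject_id, acc$subject_id)
  if (length(missing)) {
    abort(paste("subjects missing an ACC effort contrast:",
                paste(missing, collapse = ", ")))
  }
  sm <- config$symptom_model
  withr::with_seed(seed, {
    d <- subjects %>%
      select("subject_id", "group", "age", "sex", "pubertal_status",
             "mt_severity") %>%
      left_join(acc, by = "subject_id") %>%
      mutate(
        baseline_symptoms = pmax(0, ifelse(.data$group == "MT",
                                           rnorm(dplyr::n(), 2.7, 2.2),
                                           rnorm(dplyr::n(), 1.7, 1.9)))
      )
    b_acc <- ifelse(d$group == "MT", sm$b_acc_mt, sm$b_acc_nmt)
    d %>% mutate(
      followup_symptoms = sm$intercept + sm$b_base * .data$baseline_symptoms +
        b_acc * .data$acc_beta + sm$b_age * .data$age +
        sm$b_sex * (.data$sex == "F") + sm$b_pds * .data$pubertal_status +
        sm$b_sev * .data$mt_severity +
        rnorm(dplyr::n(), 0, sm$noise_sd)
    )
  })
}

#' Generate a complete synthetic cohort
#'
#' Composes the offer schedule, subject profiles, trial-by-trial choices,
#' ROI contrasts and longitudinal symptom panel into one object. All stage
#' seeds are derived deterministically from the config's master seed, so the
#' same config always yields a bit-identical cohort. Pure: writes nothing.
#'
#' @param config A [cohort_config()].
#' @return An object of class `effort_cohort`: a list with elements
#'   `schedule`, `subjects`, `trials`, `contrasts`, `longitudinal`, `config`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_mt = 3, n_nmt = 3, master_seed = 7))
#' nrow(coh$trials) # 6 x 72
#' }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  schedule <- build_offer_schedule(
    n_runs = config$n_runs, reps_per_cell = config$reps_per_cell,
    seed = derive_seed(config$master_seed, "schedule"))
  subjects <- simulate_subject_profiles(config)
  trials <- purrr::map(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    simulate_choices(schedule,
                     choice_params(s$intercept, s$reward_lin, s$effort_lin,
                                   s$effort_quad, s$noise),
                     success_prob = config$success_prob,
                     seed = derive_seed(config$master_seed,
                                        paste0("choices/", s$subject_id))) %>%
      mutate(subject_id = s$subject_id, group = s$group, .before = 1)
  }) %>% bind_rows()
  contrasts <- simulate_roi_contrasts(subjects, config)
  longitudinal <- simulate_symptom_panel(subjects, contrasts, config)
  structure(list(schedule = schedule, subjects = subjects, trials = trials,
                 contrasts = contrasts, longitudinal = longitudinal,
                 config = config),
            class = "effort_cohort")
}

#' @export
print.effort_cohort <- function(x, ...) {
  cat("<effort_cohort>\n",
      sprintf("  %d subjects (%d MT, %d NMT), %d trials each\n",
              nrow(x$subjects), sum(x$subjects$group == "MT"),
              sum(x$subjects$group == "NMT"), nrow(x$schedule)),
      sprintf("  mean acceptance rate: %.2f\n", mean(x$trials$accepted)),
      sprintf("  master seed: %s\n", format(x$config$master_seed)))
  invisible(x)
}
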