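#' Configuration of the end-to-end analysis pipeline
#'
#' Collects the cohort configuration, the choice-model family to fit, sampler
#' settings, the ROI set, first-level GLM settings and statistics settings
#' into one validated object. `master_seed` is required; every stage derives
#' its own sub-seed from it via [derive_seed()], so stages are independently
#' reproducible.
#'
#' @param master_seed Integer master seed (required).
#' @param cohort A [cohort_config()] or a list of its arguments.
#' @param models Character vector of model names from [choice_model_family()].
#' @param sampler A [sampler_config()] or a list of its arguments. The
#'   pipeline default uses 2 chains and reduced draws.
#' @param rois Data frame with `name`, `x`, `y`, `z`, `radius`.
#' @param glm List: `tr` (s), `dt` (s), `noise_sd` (ROI signal noise SD),
#'   `run_offset` (s between run starts), `grid_spacing` (mm).
#' @param stats List: `alpha`, `q` (FDR level), `covariates`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(master_seed,
                            cohort = list(),
                            models = c("intercept", "reward", "effort2",
                                       "full"),
                            sampler = list(n_chains = 2, n_adapt = 400,
                                           n_warmup = 400, n_iter = 600),
                            rois = tibble(
                              name = c("acc", "striatum_right",
                                       "striatum_left"),
                              x = c(0, 22, -14), y = c(14, 14, 6),
                              z = c(46, 6, 10), radius = 6),
                            glm = list(tr = 2, dt = 0.1, noise_sd = 0.5,
                                       run_offset = 400, grid_spacing = 2),
                            stats = list(alpha = 0.05, q = 0.05,
                                         covariates = c("age", "sex",
                                                        "pubertal_status"))) {
  if (missing(master_seed) || is.null(master_seed)) {
    abort("pipeline_config: required field 'master_seed' is missing")
  }
  if (!is_scalar_number(master_seed) || master_seed != round(master_seed)) {
    abort("pipeline_config: 'master_seed' must be a single integer")
  }
  if (is.list(cohort) && !inherits(cohort, "cohort_config")) {
    cohort$master_seed <- cohort$master_seed %||%
      derive_seed(master_seed, "cohort")
    cohort <- do.call(cohort_config, cohort)
  }
  if (is.list(sampler) && !inherits(sampler, "sampler_config")) {
    sampler$seed <- sampler$seed %||% derive_seed(master_seed, "sampler")
    sampler <- do.call(sampler_config, sampler)
  }
  bad <- setdiff(models, names(choice_model_family()))
  if (length(bad)) abort(paste("unknown model name(s):", paste(bad, collapse = ", ")))
  rois <- dplyr::as_tibble(rois)
  check_columns(rois, c("name", "x", "y", "z", "radius"), "rois")
  glm_defaults <- list(tr = 2, dt = 0.1, noise_sd = 0.5, run_offset = 400,
                       grid_spacing = 2)
  glm <- utils::modifyList(glm_defaults, glm)
  stats_defaults <- list(alpha = 0.05, q = 0.05,
                         covariates = c("age", "sex", "pubertal_status"))
  stats <- utils::modifyList(stats_defaults, stats)
  structure(list(master_seed = as.integer(master_seed), cohort = cohort,
                 models = models, sampler = sampler, rois = rois, glm = glm,
                 stats = stats),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The two formats share one schema: the top-level keys are the arguments of
#' [pipeline_config()].
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste("config file not found:", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config must be a .yaml/.yml or .json file")
  }
  if (!is.null(raw$cohort)) {
    for (nm in c("param_means", "param_sds")) {
      if (!is.null(raw$cohort[[nm]])) raw$cohort[[nm]] <- unlist(raw$cohort[[nm]])
    }
    if (!is.null(raw$cohort$success_prob)) {
      raw$cohort$success_prob <- unlist(raw$cohort$success_prob)
    }
  }
  if (!is.null(raw$rois)) {
    raw$rois <- dplyr::bind_rows(raw$rois)
    # YAML 1.1 parses a bare `y` key as boolean TRUE; map it back
    names(raw$rois)[names(raw$rois) %in% c("TRUE", "yes")] <- "y"
  }
  do.call(pipeline_config, raw)
}

# stable hash of a pipeline config (md5 of a canonical JSON rendering;
# integer/double storage differences do not change the hash)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  ser <- jsonlite::toJSON(canonicalize(config), auto_unbox = TRUE,
                          digits = 12, null = "null")
  writeLines(ser, tmp)
  unname(tools::md5sum(tmp))
}

canonicalize <- function(x) {
  if (inherits(x, "data.frame")) x <- as.list(as.data.frame(x))
  if (is.list(x)) {
    x <- lapply(unclass(x), canonicalize)
    if (!is.null(names(x)) && all(nzchar(names(x)))) x <- x[order(names(x))]
    return(x)
  }
  if (is.numeric(x)) return(as.numeric(x))
  x
}

#' Write a table as CSV with a provenance header
#'
#' The first line records the config hash as a comment so outputs from
#' different configurations cannot be silently mixed.
#'
#' @param table Data frame.
#' @param path Output path.
#' @param hash Config hash string (from the pipeline run).
#' @return `path`, invisibly.
#' @export
write_table_hashed <- function(table, path, hash = "unhashed") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# effortdm_config_hash: %s", hash), con)
  write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV, checking columns and provenance
#'
#' @param path CSV path (optionally with a provenance comment header).
#' @param required_cols Character vector; an error listing the missing
#'   columns is raised if any are absent.
#' @param expect_hash If non-NULL, refuse the file when its recorded config
#'   hash differs.
#' @return A tibble; attribute `"config_hash"` carries the recorded hash.
#' @export
read_table_checked <- function(path, required_cols = NULL,
                               expect_hash = NULL) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  first <- readLines(path, n = 1)
  hash <- if (grepl("^# effortdm_config_hash:", first)) {
    trimws(sub("^# effortdm_config_hash:", "", first))
  } else {
    NA_character_
  }
  if (!is.null(expect_hash) && !is.na(hash) && hash != expect_hash) {
    abort(sprintf("config hash mismatch for %s: file %s vs expected %s",
                  path, hash, expect_hash))
  }
  d <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) abort(paste("malformed CSV", path, ":",
                                    conditionMessage(e))))
  d <- dplyr::as_tibble(d)
  if (!is.null(required_cols)) check_columns(d, required_cols, path)
  attr(d, "config_hash") <- hash
  d
}

stage_log <- function(stage, quiet, ...) {
  if (!quiet) inform(sprintf("[effortdm] stage=%s %s", stage,
                             paste(sprintf(...), collapse = " ")))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation; hierarchical choice-model fits for
#' the configured model family; model comparison; per-trial subjective
#' modulators from the best model's posterior means; per-subject first-level
#' ROI GLMs on synthetic ROI-average signals (whose ground-truth modulator
#' effects are the cohort's simulated contrasts); group statistics
#' (choice-parameter group tests with Benjamini-Hochberg correction, the
#' reward x effort x group ANOVA with Greenhouse-Geisser correction, ROI
#' group tests, ACC-effort-sensitivity correlations per group with Fisher
#' r-to-z comparison, and the design's power curve point); and the
#' longitudinal symptom models. All tables are written under `out_dir` with
#' a provenance header; the returned report contains every stage's summary
#' plus an analytic block of self-contained recomputations.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` for no files.
#' @param quiet Suppress per-stage log lines.
#' @return A list of class `run_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  emit <- function(tb, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_table_hashed(tb, file.path(out_dir, paste0(name, ".csv")), hash)
    }
  }

  # -- simulate ---------------------------------------------------------
  cohort <- generate_cohort(config$cohort)
  stage_log("simulate", quiet, "subjects=%d trials=%d",
            nrow(cohort$subjects), nrow(cohort$trials))
  emit(cohort$trials, "trials")
  emit(cohort$subjects, "subjects")
  emit(cohort$contrasts, "contrasts_true")
  emit(cohort$longitudinal, "longitudinal")

  # -- fit choice models ------------------------------------------------
  fits <- lapply(config$models, function(nm) {
    f <- fit_hierarchical(cohort$trials, model_spec(nm), config$sampler)
    stage_log("fit", quiet, "model=%s elpd=%.1f rhat=%.3f", nm,
              f$elpd$elpd, f$diagnostics$max_rhat)
    f
  })
  names(fits) <- config$models

  # -- compare ----------------------------------------------------------
  comparison <- compare_models(fits)
  best_name <- comparison$model[1]
  best <- fits[[best_name]]
  stage_log("compare", quiet, "best=%s", best_name)
  emit(comparison, "model_comparison")
  param_means <- best$subjects %>%
    filter(.data$term != "noise_logit") %>%
    select("subject_id", "term", "mean") %>%
    tidyr::pivot_wider(names_from = "term", values_from = "mean")
  emit(best$subjects, "choice_parameters")

  # -- modulators -------------------------------------------------------
  trials_mod <- cohort$trials %>%
    dplyr::group_split(.data$subject_id) %>%
    purrr::map(function(tr) {
      subjective_modulators(tr, posterior_choice_params(best,
                                                        tr$subject_id[1]))
    }) %>%
    bind_rows() %>%
    cost_benefit_weights()
  stage_log("modulators", quiet, "trials=%d", nrow(trials_mod))
  emit(trials_mod, "trials_with_modulators")

  # -- ROI GLM ----------------------------------------------------------
  glm_seed <- derive_seed(config$master_seed, "roi_glm")
  roi_names <- config$rois$name
  roi_estimates <- trials_mod %>%
    dplyr::group_split(.data$subject_id) %>%
    purrr::imap(function(tr, i) {
      sid <- tr$subject_id[1]
      ev <- events_from_trials(tr, run_offset = config$glm$run_offset)
      n_scans <- ceiling((max(ev$onset + ev$duration) + 32) / config$glm$tr)
      X <- build_design_matrix(ev, n_scans, tr = config$glm$tr,
                               dt = config$glm$dt)
      true_b <- cohort$contrasts %>% filter(.data$subject_id == sid)
      purrr::imap_dfr(setNames(roi_names, roi_names), function(rn, j) {
        bt <- c(decision = 1, exertion = 0.8, outcome = 0.5,
                decision_subjective_reward =
                  true_b$beta[true_b$roi == rn & true_b$modulator == "reward"],
                decision_subjective_effort =
                  true_b$beta[true_b$roi == rn & true_b$modulator == "effort"])
        sig <- simulate_roi_signal(X, bt, noise_sd = config$glm$noise_sd,
                                   seed = derive_seed(glm_seed,
                                                      paste(sid, rn)))
        fl <- fit_first_level(sig, X)
        fl$contrasts %>% mutate(subject_id = sid, roi = rn, .before = 1)
      })
    }) %>% bind_rows()
  stage_log("glm", quiet, "fits=%d", nrow(roi_estimates) / 2)
  emit(roi_estimates, "roi_estimates")
  if (!is.null(out_dir)) {
    for (i in seq_len(nrow(config$rois))) {
      write_roi_mask(unlist(config$rois[i, c("x", "y", "z")]),
                     file.path(out_dir, paste0("roi_", config$rois$name[i],
                                               ".nii.gz")),
                     radius = config$rois$radius[i],
                     grid_spacing = config$glm$grid_spacing)
    }
  }

  # -- group statistics -------------------------------------------------
  grp_map <- cohort$subjects %>% select("subject_id", "group", "age", "sex",
                                        "pubertal_status")
  pm <- param_means %>% left_join(grp_map, by = "subject_id")
  param_terms <- setdiff(names(param_means), "subject_id")
  param_tests <- purrr::map_dfr(param_terms, function(tm) {
    two_sample_ttest(pm, tm, "group") %>% mutate(term = tm, .before = 1)
  })
  param_tests <- bind_cols(param_tests,
                           bh_adjust(param_tests$p, config$stats$q) %>%
                             select("p_adjusted", "reject"))

  anova_tab <- mixed_anova_gg(acceptance_cell_means(cohort$trials))

  # bilateral combination, then plain group tests per ROI/modulator
  wide <- roi_estimates %>%
    tidyr::pivot_wider(names_from = "roi", values_from = "estimate")
  if (all(c("striatum_left", "striatum_right") %in% names(wide))) {
    wide$striatum <- combine_bilateral(wide$striatum_left,
                                       wide$striatum_right)
  }
  roi_cols <- intersect(c("acc", "striatum"), names(wide))
  roi_long <- wide %>% left_join(grp_map, by = "subject_id")
  roi_tests <- purrr::map_dfr(roi_cols, function(rc) {
    purrr::map_dfr(unique(roi_long$modulator), function(md) {
      d <- roi_long %>% filter(.data$modulator == md)
      two_sample_ttest(d, rc, "group") %>%
        mutate(roi = rc, modulator = md, .before = 1)
    })
  })

  # ACC effort beta vs effort sensitivities, per group, compared with
  # Fisher's r-to-z
  acc_d <- roi_long %>% filter(.data$modulator == "effort")
  eff_terms <- intersect(c("effort_lin", "effort_quad"), param_terms)
  correlations <- purrr::map_dfr(eff_terms, function(tm) {
    byg <- purrr::map_dfr(c("MT", "NMT"), function(gg) {
      dd <- acc_d %>% filter(.data$group == gg)
      pearson_test(dplyr::rename(param_means, value = all_of(tm)) %>%
                     dplyr::inner_join(dd %>% select("subject_id", "acc"),
                                       by = "subject_id"),
                   "value", "acc") %>%
        mutate(group = gg, term = tm, .before = 1)
    })
    fz <- fisher_z_compare(byg$r[1], byg$n[1], byg$r[2], byg$n[2])
    byg %>% mutate(fisher_z = fz$z, fisher_p = fz$p)
  })

  power_tbl <- tibble(
    n_1 = config$cohort$n_mt, n_2 = config$cohort$n_nmt, d = 0.75,
    alpha = config$stats$alpha,
    power = ttest_power(config$cohort$n_mt, config$cohort$n_nmt, 0.75,
                        config$stats$alpha))
  stage_log("stats", quiet, "param_tests=%d roi_tests=%d", nrow(param_tests),
            nrow(roi_tests))
  emit(param_tests, "param_group_tests")
  emit(anova_tab, "acceptance_anova")
  emit(roi_tests, "roi_group_tests")
  emit(correlations, "acc_correlations")

  # -- longitudinal -----------------------------------------------------
  acc_est <- acc_d %>% select("subject_id", acc_beta_est = "acc")
  long_d <- cohort$longitudinal %>%
    select(-"acc_beta") %>%
    left_join(acc_est, by = "subject_id") %>%
    rename(acc_beta = "acc_beta_est")
  mt_fit <- fit_followup_regression(long_d %>% filter(.data$group == "MT"))
  int_fit <- fit_interaction_model(long_d)
  partial_pts <- partial_regression_points(mt_fit, "acc_beta")
  stage_log("longitudinal", quiet, "mt_r2=%.2f", mt_fit$r_squared)
  emit(mt_fit$report, "followup_regression_mt")
  emit(int_fit$report, "followup_interaction")
  emit(partial_pts, "partial_regression_points")

  # -- analytic block: self-contained recomputations from printed inputs -
  analytic <- list(
    schedule_total_trials = nrow(cohort$schedule),
    schedule_runs = length(unique(cohort$schedule$run)),
    schedule_trials_per_cell = nrow(cohort$schedule) / 9,
    power_d075 = ttest_power(37, 33, 0.75, 0.05),
    fisher_z_linear = fisher_z_compare(0.439, 36, -0.12, 33)$z,
    fisher_z_quadratic = fisher_z_compare(-0.437, 36, -0.14, 33)$z,
    r_squared_linear = 0.439^2,
    gg_reward = as.list(gg_dfs(0.655, 2, 2 * 67)),
    gg_interaction = as.list(gg_dfs(0.6525, 4, 4 * 67))
  )

  report <- structure(list(
    provenance = list(config_hash = hash, master_seed = config$master_seed,
                      package_version =
                        as.character(utils::packageVersion("effortdm"))),
    cohort_summary = tibble(n_mt = config$cohort$n_mt,
                            n_nmt = config$cohort$n_nmt,
                            n_trials = nrow(cohort$trials),
                            mean_acceptance = mean(cohort$trials$accepted)),
    model_comparison = comparison,
    best_model = best_name,
    fit_diagnostics = purrr::imap_dfr(fits, function(f, nm) {
      tibble(model = nm, max_rhat = f$diagnostics$max_rhat,
             converged = f$diagnostics$converged, elpd = f$elpd$elpd,
             elpd_se = f$elpd$se)
    }),
    param_group_tests = param_tests,
    acceptance_anova = anova_tab,
    roi_group_tests = roi_tests,
    acc_correlations = correlations,
    power = power_tbl,
    followup_mt = list(report = mt_fit$report, r_squared = mt_fit$r_squared,
                       f = mt_fit$f, df1 = mt_fit$df1, df2 = mt_fit$df2),
    interaction = list(report = int_fit$report,
                       r_squared = int_fit$r_squared),
    analytic = analytic
  ), class = "run_report")

  if (!is.null(out_dir)) {
    jsonlite::write_json(
      report_to_json(report), file.path(out_dir, "run_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_to_json <- function(report) {
  lapply(unclass(report), function(x) {
    if (inherits(x, "data.frame")) as.data.frame(x) else x
  })
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$provenance$master_seed,
      "hash", substr(x$provenance$config_hash, 1, 8), "\n")
  cat("  best model:", x$best_model, "\n")
  cat(sprintf("  ACC effort group test: t(%d) = %.2f, p = %.3f, d = %.2f\n",
              x$roi_group_tests$df[x$roi_group_tests$roi == "acc" &
                                     x$roi_group_tests$modulator == "effort"],
              x$roi_group_tests$t[x$roi_group_tests$roi == "acc" &
                                    x$roi_group_tests$modulator == "effort"],
              x$roi_group_tests$p[x$roi_group_tests$roi == "acc" &
                                    x$roi_group_tests$modulator == "effort"],
              x$roi_group_tests$cohens_d[x$roi_group_tests$roi == "acc" &
                                           x$roi_group_tests$modulator ==
                                           "effort"]))
  cat(sprintf("  MT follow-up model R^2 = %.2f\n", x$followup_mt$r_squared))
  invisible(x)
}
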