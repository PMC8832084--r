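#' Predict follow-up internalizing symptoms within one group
#'
#' Ordinary least squares of follow-up symptom scores on baseline symptoms,
#' the ACC effort-modulation beta, and covariates (sex, age, pubertal status,
#' maltreatment severity by default). Complete cases only. Standardized
#' coefficients come from z-scoring all continuous variables (binary
#' predictors are left 0/1). Each predictor's last-entry delta-R-squared
#' (squared semipartial correlation) is the drop in model R squared when that
#' predictor is removed.
#'
#' @param data Longitudinal records: `followup_symptoms`,
#'   `baseline_symptoms`, `acc_beta`, plus the covariates.
#' @param covariates Character vector of covariate column names.
#' @return A `followup_fit`: list with `report` (per-term tibble: `term`,
#'   `estimate`, `std_estimate`, `t`, `df`, `p`, `delta_r2`), `r_squared`,
#'   `f`, `df1`, `df2`, `n`, and the underlying `lm` object.
#' @export
fit_followup_regression <- function(data,
                                    covariates = c("sex", "age",
                                                   "pubertal_status",
                                                   "mt_severity")) {
  preds <- c("baseline_symptoms", "acc_beta", covariates)
  check_columns(data, c("followup_symptoms", preds), "data")
  fit_symptom_lm(data, "followup_symptoms", preds)
}

#' Group-by-ACC interaction model across both groups
#'
#' Fits `followup ~ baseline + acc_beta * group + covariates` on both groups
#' together, testing whether the slope of follow-up symptoms on ACC
#' activation differs by group. Group is coded 0/1 (MT = 1), so the
#' interaction coefficient is the MT-minus-NMT slope difference.
#'
#' @inheritParams fit_followup_regression
#' @return A `followup_fit`; the interaction term is `acc_beta:group_mt`.
#' @export
fit_interaction_model <- function(data,
                                  covariates = c("sex", "age",
                                                 "pubertal_status",
                                                 "mt_severity")) {
  check_columns(data, c("followup_symptoms", "baseline_symptoms", "acc_beta",
                        "group", covariates), "data")
  if (length(unique(data$group)) < 2) {
    abort("interaction model requires records from both groups")
  }
  d <- dplyr::as_tibble(data) %>%
    mutate(group_mt = as.numeric(.data$group == "MT"),
           `acc_beta:group_mt` = .data$acc_beta *
             as.numeric(.data$group == "MT"))
  fit_symptom_lm(d, "followup_symptoms",
                 c("baseline_symptoms", "acc_beta", "group_mt",
                   "acc_beta:group_mt", covariates))
}

# shared OLS engine for the symptom regressions
fit_symptom_lm <- function(data, outcome, preds) {
  d <- dplyr::as_tibble(data)
  if ("sex" %in% preds && !is.numeric(d$sex)) {
    d$sex <- as.numeric(d$sex == "F")
  }
  d <- d[, c(outcome, preds)]
  d <- d[complete.cases(d), ]
  n <- nrow(d)
  if (n <= length(preds) + 1) {
    abort(sprintf("too few complete cases (%d) for %d predictors",
                  n, length(preds)))
  }
  names(d) <- make.names(names(d)) # protect the interaction column name
  preds_safe <- make.names(preds)
  form <- as.formula(paste(make.names(outcome), "~",
                           paste(preds_safe, collapse = " + ")))
  fit <- lm(form, data = d)
  if (anyNA(coef(fit))) {
    abort(paste("rank-deficient symptom regression; drop collinear predictor(s):",
                paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  sm <- summary(fit)
  r2 <- sm$r.squared
  # standardized coefficients: z-score continuous variables, keep binaries 0/1
  zd <- d
  for (cn in names(zd)) {
    vals <- zd[[cn]]
    if (length(unique(vals)) > 2) zd[[cn]] <- as.numeric(scale(vals))
  }
  zfit <- lm(form, data = zd)
  # last-entry delta R^2 per predictor
  dr2 <- purrr::map_dbl(preds_safe, function(p) {
    rest <- setdiff(preds_safe, p)
    rhs <- if (length(rest)) paste(rest, collapse = " + ") else "1"
    reduced <- lm(as.formula(paste(make.names(outcome), "~", rhs)), data = d)
    r2 - summary(reduced)$r.squared
  })
  cf <- sm$coefficients
  report <- tibble(
    term = c("(Intercept)", preds),
    estimate = unname(cf[, "Estimate"]),
    std_estimate = unname(coef(zfit)),
    t = unname(cf[, "t value"]),
    df = fit$df.residual,
    p = unname(cf[, "Pr(>|t|)"]),
    delta_r2 = c(NA_real_, dr2)
  )
  structure(list(report = report, r_squared = r2,
                 f = unname(sm$fstatistic["value"]),
                 df1 = unname(sm$fstatistic["numdf"]),
                 df2 = unname(sm$fstatistic["dendf"]),
                 n = n, lm = fit, outcome = outcome, predictors = preds,
                 data = d),
            class = "followup_fit")
}

#' @export
print.followup_fit <- function(x, ...) {
  cat(sprintf("<followup_fit> n = %d, R^2 = %.3f, F(%d, %d) = %.2f\n",
              x$n, x$r_squared, x$df1, x$df2, x$f))
  print(x$report, n = nrow(x$report))
  invisible(x)
}

#' Partial-regression (added-variable) points for one predictor
#'
#' Returns the residuals of the outcome and of the focal predictor, each
#' regressed on all remaining predictors. By the Frisch-Waugh-Lovell theorem
#' the OLS slope of `resid_outcome` on `resid_focal` equals the focal
#' predictor's coefficient in the full model; that slope is attached as the
#' `"slope"` attribute.
#'
#' @param fit A `followup_fit`.
#' @param focal Name of the focal predictor (as in the fit's report).
#' @return Tibble with `resid_focal`, `resid_outcome`; attribute `slope`.
#' @export
partial_regression_points <- function(fit, focal = "acc_beta") {
  stopifnot(inherits(fit, "followup_fit"))
  if (!focal %in% fit$predictors) {
    abort(sprintf("'%s' is not a predictor of this fit", focal))
  }
  d <- fit$data
  others <- setdiff(make.names(fit$predictors), make.names(focal))
  rhs <- if (length(others)) paste(others, collapse = " + ") else "1"
  r_out <- resid(lm(as.formula(paste(make.names(fit$outcome), "~", rhs)),
                    data = d))
  r_foc <- resid(lm(as.formula(paste(make.names(focal), "~", rhs)), data = d))
  pts <- tibble(resid_focal = unname(r_foc), resid_outcome = unname(r_out))
  attr(pts, "slope") <- unname(coef(lm(r_out ~ r_foc))[2])
  attr(pts, "focal") <- focal
  pts
}
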