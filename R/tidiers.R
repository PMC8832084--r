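#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a hierarchical choice-model fit
#'
#' @param x An `effort_fit` from [fit_hierarchical()].
#' @param level `"subjects"` (default) for per-subject posterior summaries or
#'   `"hypers"` for the group-level hyperparameters.
#' @param ... Unused.
#' @return A tibble of posterior summaries.
#' @export
tidy.effort_fit <- function(x, level = c("subjects", "hypers"), ...) {
  level <- match.arg(level)
  if (level == "subjects") x$subjects else x$hypers
}

#' One-row summary of a hierarchical choice-model fit
#'
#' @param x An `effort_fit`.
#' @param ... Unused.
#' @return Tibble with model name, sizes, ELPD, effective parameter count
#'   and convergence diagnostics.
#' @export
glance.effort_fit <- function(x, ...) {
  tibble(model = x$spec$name, n_subjects = x$n_subjects,
         n_trials = x$n_trials, elpd = x$elpd$elpd, elpd_se = x$elpd$se,
         p_eff = x$elpd$p_eff, max_rhat = x$diagnostics$max_rhat,
         converged = x$diagnostics$converged)
}

#' Tidy a follow-up symptom regression
#'
#' @param x A `followup_fit`.
#' @param ... Unused.
#' @return The per-term report tibble (estimates, standardized estimates, t,
#'   df, p, last-entry delta R-squared).
#' @export
tidy.followup_fit <- function(x, ...) x$report

#' One-row summary of a follow-up symptom regression
#'
#' @param x A `followup_fit`.
#' @param ... Unused.
#' @return Tibble with R-squared, F and its dfs, and n.
#' @export
glance.followup_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, f = x$f, df1 = x$df1, df2 = x$df2, n = x$n)
}

#' Tidy a first-level GLM fit
#'
#' @param x A `first_level_fit`.
#' @param ... Unused.
#' @return Tibble of regressor estimates with SEs and t values.
#' @export
tidy.first_level_fit <- function(x, ...) x$betas

#' @rdname tidy.first_level_fit
#' @export
glance.first_level_fit <- function(x, ...) {
  tibble(sigma2 = x$sigma2, df = x$df, n_regressors = nrow(x$betas))
}
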