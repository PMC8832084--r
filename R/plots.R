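#' Plot mean acceptance rates by reward, effort and group
#'
#' The task's behavioural fingerprint: acceptance rises with reward and
#' falls with effort.
#'
#' @param trials Trial records with `reward_level`, `effort_level`,
#'   `accepted` and optionally `group`.
#' @return A ggplot object.
#' @export
plot_acceptance_rates <- function(trials) {
  check_columns(trials, c("reward_level", "effort_level", "accepted"),
                "trials")
  has_group <- "group" %in% names(trials)
  d <- trials %>%
    group_by(across(all_of(c(if (has_group) "group", "reward_level",
                             "effort_level")))) %>%
    summarise(accept_rate = mean(.data$accepted), .groups = "drop") %>%
    mutate(effort = factor(.data$effort_level))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$reward_level),
                                       y = .data$accept_rate,
                                       colour = .data$effort,
                                       group = .data$effort)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Reward level (points)", y = "Acceptance rate",
                  colour = "Effort (MVC)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (has_group) p <- p + ggplot2::facet_wrap(~ group)
  p
}

#' Plot the canonical HRF
#'
#' @param dt Sampling step (s).
#' @return A ggplot object.
#' @export
plot_hrf <- function(dt = 0.1) {
  tg <- seq(0, 32, by = dt)
  ggplot2::ggplot(tibble(t = tg, h = canonical_hrf(tg)),
                  ggplot2::aes(.data$t, .data$h)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Response (peak-normalized)") +
    ggplot2::theme_minimal()
}

#' Posterior interval plot of subject-level choice parameters
#'
#' @param object An `effort_fit` from [fit_hierarchical()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effort_fit <- function(object, ...) {
  d <- object$subjects %>% filter(.data$term != "noise_logit")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean,
                                  y = stats::reorder(.data$subject_id,
                                                     .data$mean))) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$q2.5,
                                          xmax = .data$q97.5),
                             size = 0.15) +
    ggplot2::facet_wrap(~ term, scales = "free_x") +
    ggplot2::labs(x = "Posterior mean (95% interval)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Partial-regression plot
#'
#' Added-variable plot of follow-up symptoms against the focal predictor
#' (both residualized on the remaining predictors), with the OLS line whose
#' slope equals the full-model coefficient.
#'
#' @param points Output of [partial_regression_points()].
#' @return A ggplot object.
#' @export
plot_partial_regression <- function(points) {
  check_columns(points, c("resid_focal", "resid_outcome"), "points")
  ggplot2::ggplot(points, ggplot2::aes(.data$resid_focal,
                                       .data$resid_outcome)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "black") +
    ggplot2::labs(
      x = paste0(attr(points, "focal") %||% "focal predictor",
                 " (residualized)"),
      y = "Follow-up symptoms (residualized)") +
    ggplot2::theme_minimal()
}
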