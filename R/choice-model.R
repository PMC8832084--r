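#' Construct a set of lapse-logistic choice parameters
#'
#' The choice model has five subject-level parameters: an intercept capturing
#' the general propensity to accept offers, a linear reward sensitivity, a
#' linear and a quadratic effort sensitivity (the quadratic term captures
#' disproportionate drops in acceptance at high effort), and a lapse/noise
#' parameter `noise` in \[0, 1\] giving the probability of responding at
#' random irrespective of the offer.
#'
#' @param intercept,reward_lin,effort_lin,effort_quad Real-valued
#'   sensitivities on the logit scale.
#' @param noise Lapse probability in \[0, 1\].
#' @return A one-row tibble of class `choice_params`.
#' @examples
#' choice_params(intercept = 1, reward_lin = 2, effort_lin = -3,
#'               effort_quad = -2, noise = 0.1)
#' @export
choice_params <- function(intercept = 0, reward_lin = 0, effort_lin = 0,
                          effort_quad = 0, noise = 0) {
  p <- tibble(intercept = intercept, reward_lin = reward_lin,
              effort_lin = effort_lin, effort_quad = effort_quad,
              noise = noise)
  validate_choice_params(p)
  class(p) <- c("choice_params", class(p))
  p
}

validate_choice_params <- function(p) {
  check_columns(p, c("intercept", "reward_lin", "effort_lin",
                     "effort_quad", "noise"), "choice parameters")
  vals <- unlist(p[1, c("intercept", "reward_lin", "effort_lin",
                        "effort_quad", "noise")])
  if (!all(is.finite(vals))) abort("choice parameters must all be finite")
  if (p$noise[1] < 0 || p$noise[1] > 1) {
    abort("noise (lapse) parameter must lie in [0, 1]")
  }
  invisible(p)
}

# internal: linear predictor on scaled inputs r~ = reward/12, e~ = MVC fraction
choice_linpred <- function(params, reward_level, effort_level) {
  r <- reward_level / 12
  e <- effort_level
  params$intercept[1] + params$reward_lin[1] * r +
    params$effort_lin[1] * e + params$effort_quad[1] * e^2
}

#' Acceptance probability of an offer under the lapse-logistic model
#'
#' Computes, for each offer row, the probability of accepting under
#' `p = nu/2 + (1 - nu) * logistic(b0 + br*r + be1*e + be2*e^2)`, where
#' `r = reward_level / 12` (so the largest reward scales to 1), `e` is the
#' effort level as an MVC fraction, and `nu` is the lapse probability. The
#' mixture bounds the probability in `[nu/2, 1 - nu/2]`.
#'
#' @param offers A data frame with columns `reward_level` and `effort_level`.
#' @param params A [choice_params()] row (or anything with those columns).
#' @return The input as a tibble with an added `accept_prob` column.
#' @examples
#' offers <- tibble::tibble(reward_level = 12, effort_level = 0.8)
#' acceptance_probability(offers, choice_params(1, 2, -3, -2, 0.1))
#' @export
acceptance_probability <- function(offers, params) {
  check_columns(offers, c("reward_level", "effort_level"), "offers")
  validate_choice_params(params)
  nu <- params$noise[1]
  eta <- choice_linpred(params, offers$reward_level, offers$effort_level)
  dplyr::as_tibble(offers) %>%
    mutate(accept_prob = nu / 2 + (1 - nu) * plogis(eta))
}

#' Bernoulli log-likelihood of observed choices
#'
#' Sums `log(p)` over accepted trials and `log(1 - p)` over declined trials,
#' with `p` from [acceptance_probability()]. An empty trial table yields 0.
#' A probability of exactly 0 or 1 contradicting the observed choice yields
#' `-Inf` (not an error).
#'
#' @param trials Data frame with `reward_level`, `effort_level`, `accepted`.
#' @param params A [choice_params()] row.
#' @return A single number.
#' @examples
#' tr <- tibble::tibble(reward_level = 8, effort_level = 0.5, accepted = TRUE)
#' choice_log_likelihood(tr, choice_params())  # log(0.5)
#' @export
choice_log_likelihood <- function(trials, params) {
  check_columns(trials, c("reward_level", "effort_level", "accepted"), "trials")
  if (nrow(trials) == 0) return(0)
  p <- acceptance_probability(trials, params)$accept_prob
  ll <- ifelse(trials$accepted, log(p), log1p(-p))
  sum(ll)
}

#' Per-trial subjective reward and effort modulators
#'
#' Converts fitted choice parameters into the per-trial parametric modulators
#' used in the first-level fMRI model: `subjective_reward = br * r` and
#' `subjective_effort = be1 * e + be2 * e^2`, on the same scaled inputs as
#' [acceptance_probability()].
#'
#' @param trials Data frame with `reward_level` and `effort_level`.
#' @param params A [choice_params()] row (typically posterior means).
#' @return The input as a tibble with `subjective_reward` and
#'   `subjective_effort` columns added.
#' @export
subjective_modulators <- function(trials, params) {
  check_columns(trials, c("reward_level", "effort_level"), "trials")
  validate_choice_params(params)
  e <- trials$effort_level
  dplyr::as_tibble(trials) %>%
    mutate(
      subjective_reward = params$reward_lin[1] * .data$reward_level / 12,
      subjective_effort = params$effort_lin[1] * e + params$effort_quad[1] * e^2
    )
}

#' Per-trial cost-benefit weights
#'
#' The cost-benefit weight of a trial is the absolute deviation of the
#' subject's acceptance rate in that trial's (reward, effort) cell from 0.5:
#' it is 0.5 when the decision is trivially easy (cell always accepted or
#' always declined) and 0 when the subject is maximally conflicted. If a
#' `subject_id` column is present, rates are computed within subject.
#'
#' @param trials Data frame with `reward_level`, `effort_level`, `accepted`
#'   (and optionally `subject_id`).
#' @return The input as a tibble with a `cost_benefit` column in \[0, 0.5\].
#' @export
cost_benefit_weights <- function(trials) {
  check_columns(trials, c("reward_level", "effort_level", "accepted"), "trials")
  if (nrow(trials) == 0) abort("cost_benefit_weights: no trials supplied")
  keys <- intersect(c("subject_id", "reward_level", "effort_level"),
                    names(trials))
  dplyr::as_tibble(trials) %>%
    group_by(across(all_of(keys))) %>%
    mutate(cost_benefit = abs(mean(.data$accepted) - 0.5)) %>%
    ungroup()
}

#' Specify a member of the choice-model family
#'
#' Models form a nested ladder of increasing complexity. The intercept is
#' always included; excluded sensitivities are fixed at zero and an excluded
#' noise term fixes the lapse probability at zero.
#'
#' @param name One of `"intercept"`, `"reward"`, `"effort"`, `"effort2"`,
#'   `"full"`, or `NULL` when `terms` is given directly.
#' @param terms Character vector of included terms, a subset of
#'   `c("intercept", "reward_lin", "effort_lin", "effort_quad", "noise")`.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("full")
#' model_spec(terms = c("intercept", "reward_lin"))
#' @export
model_spec <- function(name = NULL, terms = NULL) {
  all_terms <- c("intercept", "reward_lin", "effort_lin", "effort_quad", "noise")
  ladder <- list(
    intercept = "intercept",
    reward    = c("intercept", "reward_lin"),
    effort    = c("intercept", "reward_lin", "effort_lin"),
    effort2   = c("intercept", "reward_lin", "effort_lin", "effort_quad"),
    full      = all_terms
  )
  if (is.null(terms)) {
    if (is.null(name)) abort("supply either a model name or a terms vector")
    name <- match.arg(name, names(ladder))
    terms <- ladder[[name]]
  } else {
    bad <- setdiff(terms, all_terms)
    if (length(bad)) abort(paste("unknown model terms:", paste(bad, collapse = ", ")))
    terms <- union("intercept", terms) # intercept always included
    name <- name %||% paste(terms, collapse = "+")
  }
  structure(list(name = name, terms = terms), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$name, "\n  terms:", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' The nested family of choice models compared in this package
#'
#' @return A named list of [model_spec()] objects from intercept-only to the
#'   full five-parameter lapse-logistic model.
#' @export
choice_model_family <- function() {
  nms <- c("intercept", "reward", "effort", "effort2", "full")
  setNames(lapply(nms, model_spec), nms)
}
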