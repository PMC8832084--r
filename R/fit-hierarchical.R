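#' MCMC sampler settings for hierarchical choice-model fits
#'
#' @param n_chains Number of chains (default 4).
#' @param n_adapt Adaptation iterations (default 500).
#' @param n_warmup Post-adaptation burn-in iterations (default 1000).
#' @param n_iter Retained sampling iterations per chain (default 1000).
#' @param thin Thinning interval.
#' @param seed Integer seed; each chain gets a distinct RNG stream derived
#'   from it.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 4, n_adapt = 500, n_warmup = 1000,
                           n_iter = 1000, thin = 1, seed = 1) {
  stopifnot(n_chains >= 1, n_iter >= 100)
  structure(list(n_chains = n_chains, n_adapt = n_adapt, n_warmup = n_warmup,
                 n_iter = n_iter, thin = thin, seed = seed),
            class = "sampler_config")
}

# term bookkeeping shared by the model builder and the post-processing
.term_nodes <- c(intercept = "b0", reward_lin = "br", effort_lin = "be1",
                 effort_quad = "be2", noise = "lnu")

# build the JAGS model string for a given model spec.
# hyper_scale multiplies all hyperprior SDs (used for near-flat fits).
build_jags_model <- function(spec, hyper_scale = 1) {
  terms <- spec$terms
  eta <- c("b0[sub[i]]")
  if ("reward_lin" %in% terms) eta <- c(eta, "br[sub[i]] * r[i]")
  if ("effort_lin" %in% terms) eta <- c(eta, "be1[sub[i]] * e[i]")
  if ("effort_quad" %in% terms) eta <- c(eta, "be2[sub[i]] * e2[i]")
  p_line <- if ("noise" %in% terms) {
    "p[i] <- nu[sub[i]] / 2 + (1 - nu[sub[i]]) * ilogit(eta[i])"
  } else {
    "p[i] <- ilogit(eta[i])"
  }
  subj_lines <- character(0)
  hyper_lines <- character(0)
  # group means ~ Normal(0, 5), group SDs ~ Half-Normal(2.5): weakly
  # informative soft constraints; the lapse is modelled logit-normal with a
  # prior mean favouring small lapse rates.
  for (tm in setdiff(terms, "noise")) {
    nd <- .term_nodes[[tm]]
    subj_lines <- c(subj_lines,
                    sprintf("    %s[s] ~ dnorm(mu_%s, tau_%s)", nd, nd, nd))
    hyper_lines <- c(hyper_lines,
      sprintf("  mu_%s ~ dnorm(0, %.10g)", nd, 1 / (5 * hyper_scale)^2),
      sprintf("  sig_%s ~ dnorm(0, %.10g) T(0,)", nd, 1 / (2.5 * hyper_scale)^2),
      sprintf("  tau_%s <- pow(sig_%s, -2)", nd, nd))
  }
  if ("noise" %in% terms) {
    subj_lines <- c(subj_lines,
                    "    lnu[s] ~ dnorm(mu_lnu, tau_lnu)",
                    "    nu[s] <- ilogit(lnu[s])")
    hyper_lines <- c(hyper_lines,
      sprintf("  mu_lnu ~ dnorm(-3, %.10g)", 1 / (1.5 * hyper_scale)^2),
      sprintf("  sig_lnu ~ dnorm(0, %.10g) T(0,)", 1 / (2.5 * hyper_scale)^2),
      "  tau_lnu <- pow(sig_lnu, -2)")
  }
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    eta[i] <- ", paste(eta, collapse = " + "), "\n",
    "    ", p_line, "\n",
    "    y[i] ~ dbern(p[i])\n",
    "  }\n",
    "  for (s in 1:S) {\n",
    paste(subj_lines, collapse = "\n"), "\n",
    "  }\n",
    paste(hyper_lines, collapse = "\n"), "\n",
    "}\n")
}

# split-half R-hat (potential scale reduction) over an iterations x chains
# matrix of draws for one parameter
split_rhat <- function(draws_by_chain) {
  halves <- do.call(cbind, lapply(draws_by_chain, function(x) {
    n2 <- floor(length(x) / 2)
    cbind(x[seq_len(n2)], x[(length(x) - n2 + 1):length(x)])
  }))
  n <- nrow(halves)
  m <- ncol(halves)
  ch_means <- colMeans(halves)
  ch_vars <- apply(halves, 2, var)
  W <- mean(ch_vars)
  B <- n * var(ch_means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit a hierarchical Bayesian lapse-logistic choice model
#'
#' Estimates subject-level choice parameters under partial pooling: each
#' subject's parameters are drawn from group-level normal distributions (the
#' lapse parameter on the logit scale), with weakly informative hyperpriors
#' (means Normal(0, 5), SDs Half-Normal(2.5), logit-lapse mean Normal(-3,
#' 1.5)). Sampling is by MCMC through JAGS. The hierarchy pools all subjects
#' into a single population by default, since group comparisons are performed
#' afterwards on the per-subject estimates; `by_group = TRUE` fits separate
#' hyperparameters per group.
#'
#' The returned fit carries posterior summaries, split-R-hat and effective
#' sample size per free parameter (JAGS is a Gibbs-family sampler, so there
#' is no divergent-transition count), per-subject posterior-predictive
#' acceptance rates, and a WAIC-based expected log predictive density (ELPD)
#' with pointwise contributions used by [compare_models()]. If any R-hat
#' exceeds 1.05 the fit is flagged (`converged = FALSE`) with a warning, but
#' the result is still returned.
#'
#' @param trials Data frame with columns `subject_id`, `reward_level`,
#'   `effort_level`, `accepted` (and optionally `group` when
#'   `by_group = TRUE`).
#' @param spec A [model_spec()]; defaults to the full five-parameter model.
#' @param sampler A [sampler_config()].
#' @param hyper_scale Multiplier on all hyperprior SDs (1 = defaults; large
#'   values make the priors nearly flat).
#' @param by_group Fit separate group-level distributions per `group`.
#' @return An object of class `effort_fit`.
#' @export
fit_hierarchical <- function(trials, spec = model_spec("full"),
                             sampler = sampler_config(), hyper_scale = 1,
                             by_group = FALSE) {
  check_columns(trials, c("subject_id", "reward_level", "effort_level",
                          "accepted"), "trials")
  stopifnot(inherits(spec, "model_spec"), inherits(sampler, "sampler_config"))
  if (by_group) check_columns(trials, "group", "trials (by_group = TRUE)")
  subj <- sort(unique(trials$subject_id))
  S <- length(subj)
  if (S < 1 || nrow(trials) < 1) abort("need at least one subject with trials")
  sub_idx <- match(trials$subject_id, subj)
  dat <- list(N = nrow(trials), S = S, y = as.integer(trials$accepted),
              sub = sub_idx)
  if ("reward_lin" %in% spec$terms) dat$r <- trials$reward_level / 12
  if ("effort_lin" %in% spec$terms) dat$e <- trials$effort_level
  if ("effort_quad" %in% spec$terms) dat$e2 <- trials$effort_level^2
  if (by_group) {
    g <- group_index_of(trials, subj)
    model_str <- build_jags_model_grouped(spec, hyper_scale, g, dat)
    dat$g <- g
  } else {
    model_str <- build_jags_model(spec, hyper_scale)
  }

  nodes <- .term_nodes[spec$terms]
  inits <- lapply(seq_len(sampler$n_chains), function(ch) {
    ini <- list(.RNG.name = "base::Wichmann-Hill",
                .RNG.seed = (sampler$seed * 1009 + ch) %% 2147483647)
    for (nd in nodes) ini[[nd]] <- rep(if (nd == "lnu") -3 else 0, S)
    ini
  })
  monitors <- c(nodes, paste0("mu_", nodes), paste0("sig_", nodes))
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          inits = inits, n.chains = sampler$n_chains,
                          n.adapt = sampler$n_adapt, quiet = TRUE)
  if (sampler$n_warmup > 0) update(jm, sampler$n_warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitors,
                              n.iter = sampler$n_iter, thin = sampler$thin,
                              progress.bar = "none")
  chains <- lapply(samp, as.matrix)
  all_draws <- do.call(rbind, chains)
  cols <- colnames(all_draws)

  summarise_param <- function(cn) {
    x <- all_draws[, cn]
    tibble(mean = mean(x), sd = sd(x),
           q2.5 = unname(quantile(x, 0.025)),
           q97.5 = unname(quantile(x, 0.975)),
           rhat = split_rhat(lapply(chains, function(m) m[, cn])),
           n_eff = unname(coda::effectiveSize(coda::mcmc(x))))
  }

  term_of_node <- setNames(names(.term_nodes), .term_nodes)
  # with a single subject JAGS drops the [1] index from node names
  subj_cols <- cols[grepl("^(b0|br|be1|be2|lnu)(\\[\\d+\\])?$", cols)]
  parse_idx <- function(cn) {
    if (grepl("\\[", cn)) as.integer(sub(".*\\[(\\d+)\\]", "\\1", cn)) else 1L
  }
  subjects_tbl <- purrr::map_dfr(subj_cols, function(cn) {
    nd <- sub("\\[.*", "", cn)
    idx <- parse_idx(cn)
    out <- summarise_param(cn)
    out$subject_id <- subj[idx]
    out$term <- term_of_node[[nd]]
    out
  }) %>%
    mutate(term = ifelse(.data$term == "noise", "noise_logit", .data$term)) %>%
    select("subject_id", "term", "mean", "sd", "q2.5", "q97.5", "rhat",
           "n_eff") %>%
    arrange(.data$subject_id, .data$term)
  # report the lapse on the probability scale as well
  if ("noise" %in% spec$terms) {
    nu_rows <- purrr::map_dfr(which(grepl("^lnu(\\[\\d+\\])?$", cols)),
                              function(j) {
      cn <- cols[j]
      x <- plogis(all_draws[, cn])
      idx <- parse_idx(cn)
      tibble(subject_id = subj[idx], term = "noise", mean = mean(x),
             sd = sd(x), q2.5 = unname(quantile(x, 0.025)),
             q97.5 = unname(quantile(x, 0.975)),
             rhat = split_rhat(lapply(chains, function(m) plogis(m[, cn]))),
             n_eff = unname(coda::effectiveSize(coda::mcmc(x))))
    })
    subjects_tbl <- bind_rows(subjects_tbl, nu_rows) %>%
      arrange(.data$subject_id, .data$term)
  }
  hyper_cols <- cols[grepl("^(mu|sig)_", cols)]
  hypers_tbl <- purrr::map_dfr(hyper_cols, function(cn) {
    out <- summarise_param(cn)
    out$parameter <- cn
    out
  }) %>% select("parameter", "mean", "sd", "q2.5", "q97.5", "rhat", "n_eff")

  # pointwise log-likelihood, WAIC-based ELPD and posterior-predictive
  # acceptance rates, computed subject-by-subject to bound memory
  D <- nrow(all_draws)
  lpd <- pwaic <- numeric(nrow(trials))
  pp_rate <- numeric(S)
  for (s in seq_len(S)) {
    rows <- which(sub_idx == s)
    getd <- function(nd) {
      cn <- sprintf("%s[%d]", nd, s)
      if (cn %in% cols) return(all_draws[, cn])
      if (S == 1 && nd %in% cols) return(all_draws[, nd])
      rep(0, D)
    }
    eta <- outer(getd("b0"), rep(1, length(rows)))
    if ("reward_lin" %in% spec$terms)
      eta <- eta + outer(getd("br"), dat$r[rows])
    if ("effort_lin" %in% spec$terms)
      eta <- eta + outer(getd("be1"), dat$e[rows])
    if ("effort_quad" %in% spec$terms)
      eta <- eta + outer(getd("be2"), dat$e2[rows])
    pm <- plogis(eta)
    if ("noise" %in% spec$terms) {
      nu <- plogis(getd("lnu"))
      pm <- nu / 2 + (1 - nu) * pm
    }
    y <- matrix(dat$y[rows], D, length(rows), byrow = TRUE)
    ll <- log(ifelse(y == 1, pm, 1 - pm))
    lpd[rows] <- apply(ll, 2, log_mean_exp)
    pwaic[rows] <- apply(ll, 2, var)
    pp_rate[s] <- mean(pm)
  }
  elpd_i <- lpd - pwaic
  elpd <- tibble(elpd = sum(elpd_i), se = sqrt(length(elpd_i) * var(elpd_i)),
                 p_eff = sum(pwaic))

  max_rhat <- max(c(subjects_tbl$rhat, hypers_tbl$rhat), na.rm = TRUE)
  converged <- is.finite(max_rhat) && max_rhat <= 1.05
  if (!converged) {
    warn(sprintf("fit_hierarchical: max split R-hat = %.3f exceeds 1.05; treat estimates with caution",
                 max_rhat))
  }

  structure(list(
    spec = spec,
    subjects = subjects_tbl,
    hypers = hypers_tbl,
    elpd = elpd,
    elpd_pointwise = elpd_i,
    ppred = tibble(subject_id = subj, ppred_accept_rate = pp_rate),
    diagnostics = list(max_rhat = max_rhat, converged = converged,
                       n_divergent = NA_integer_),
    sampler = sampler,
    n_trials = nrow(trials),
    n_subjects = S,
    data_fingerprint = data_fingerprint(trials)
  ), class = "effort_fit")
}

# group-indexed variant of the model (separate hypers per group)
group_index_of <- function(trials, subj) {
  gmap <- trials %>% dplyr::distinct(.data$subject_id, .data$group)
  as.integer(factor(gmap$group[match(subj, gmap$subject_id)]))
}

build_jags_model_grouped <- function(spec, hyper_scale, g, dat) {
  base <- build_jags_model(spec, hyper_scale)
  # index every hyperparameter by the subject's group
  for (nd in .term_nodes[spec$terms]) {
    base <- gsub(sprintf("mu_%s,", nd), sprintf("mu_%s[g[s]],", nd), base,
                 fixed = TRUE)
    base <- gsub(sprintf("tau_%s\\)", nd), sprintf("tau_%s[g[s]])", nd), base)
    ng <- length(unique(g))
    hyper_block <- sprintf(
      "  for (k in 1:%d) {\n    mu_%s[k] ~ %s\n    sig_%s[k] ~ %s\n    tau_%s[k] <- pow(sig_%s[k], -2)\n  }",
      ng, nd,
      if (nd == "lnu") sprintf("dnorm(-3, %.10g)", 1 / (1.5 * hyper_scale)^2)
      else sprintf("dnorm(0, %.10g)", 1 / (5 * hyper_scale)^2),
      nd, sprintf("dnorm(0, %.10g) T(0,)", 1 / (2.5 * hyper_scale)^2),
      nd, nd)
    base <- sub(sprintf("  mu_%s ~ [^\n]+\n  sig_%s ~ [^\n]+\n  tau_%s <- [^\n]+", nd, nd, nd),
                hyper_block, base)
  }
  structure(base, g = g)
}

# order-invariant fingerprint of a trial table, used to refuse comparing
# fits made on different data
data_fingerprint <- function(trials) {
  d <- trials %>%
    select("subject_id", "reward_level", "effort_level", "accepted") %>%
    arrange(.data$subject_id, .data$reward_level, .data$effort_level,
            .data$accepted)
  paste(nrow(d), length(unique(d$subject_id)), sum(d$accepted),
        format(sum(d$reward_level * d$effort_level), digits = 12),
        sep = "|")
}

#' @export
print.effort_fit <- function(x, ...) {
  cat("<effort_fit>", x$spec$name, "model\n",
      sprintf("  %d subjects, %d trials\n", x$n_subjects, x$n_trials),
      sprintf("  ELPD (WAIC) = %.1f (SE %.1f), p_eff = %.1f\n",
              x$elpd$elpd, x$elpd$se, x$elpd$p_eff),
      sprintf("  max split R-hat = %.3f (%s)\n", x$diagnostics$max_rhat,
              if (x$diagnostics$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Posterior-mean choice parameters of one subject
#'
#' Convenience accessor turning an [fit_hierarchical()] result into a
#' [choice_params()] row for a given subject (posterior means; excluded
#' terms are zero).
#'
#' @param fit An `effort_fit`.
#' @param subject_id Subject identifier.
#' @return A `choice_params` tibble row.
#' @export
posterior_choice_params <- function(fit, subject_id) {
  stopifnot(inherits(fit, "effort_fit"))
  d <- fit$subjects %>% filter(.data$subject_id == !!subject_id)
  if (nrow(d) == 0) abort(paste("no such subject in fit:", subject_id))
  g <- function(tm) if (tm %in% d$term) d$mean[d$term == tm] else 0
  choice_params(g("intercept"), g("reward_lin"), g("effort_lin"),
                g("effort_quad"), g("noise"))
}

#' Compare fitted choice models by expected log predictive density
#'
#' Ranks fits of different model specifications on the same data by their
#' WAIC-based ELPD and reports each model's difference from the best model
#' with the standard error of that difference (from the pointwise ELPD
#' contributions). Fits made on different data are refused.
#'
#' @param fits A list of `effort_fit` objects (optionally named).
#' @return A tibble with one row per model: `model`, `elpd`, `se`, `p_eff`,
#'   `elpd_diff` (best minus this model's ELPD, 0 for the best), `se_diff`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(purrr::map_lgl(fits, inherits, "effort_fit")))
  fps <- purrr::map_chr(fits, "data_fingerprint")
  if (length(unique(fps)) != 1) {
    abort("compare_models: fits were made on different data (fingerprints differ)")
  }
  nms <- names(fits) %||% purrr::map_chr(fits, ~ .x$spec$name)
  if (is.null(names(fits))) names(fits) <- nms
  tab <- purrr::imap_dfr(fits, function(f, nm) {
    tibble(model = nm, elpd = f$elpd$elpd, se = f$elpd$se,
           p_eff = f$elpd$p_eff)
  }) %>% arrange(dplyr::desc(.data$elpd))
  best <- fits[[tab$model[1]]]
  tab$elpd_diff <- tab$elpd[1] - tab$elpd
  tab$se_diff <- purrr::map_dbl(tab$model, function(nm) {
    di <- best$elpd_pointwise - fits[[nm]]$elpd_pointwise
    sqrt(length(di) * var(di))
  })
  tab
}
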