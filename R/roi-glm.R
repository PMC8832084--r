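#' Canonical double-gamma hemodynamic response function
#'
#' The synthetic HRF used throughout first-level modelling: a gamma density
#' peaking around 5-6 s minus a scaled gamma undershoot peaking around 16 s
#' (peak delay 6 s, undershoot delay 16 s, both dispersions 1, peak:undershoot
#' ratio 6, support truncated at 32 s), peak-normalized to 1.
#'
#' @param time_grid Non-negative, increasing vector of times (s).
#' @param peak_delay,undershoot_delay,peak_disp,undershoot_disp,ratio
#'   Shape parameters of the two gamma components.
#' @param length_s Support; the response is 0 beyond this time.
#' @param normalize Peak-normalize to max 1 (default TRUE).
#' @return Numeric vector of responses, same length as `time_grid`.
#' @examples
#' h <- canonical_hrf(seq(0, 32, 0.1))
#' @export
canonical_hrf <- function(time_grid, peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1, ratio = 6,
                          length_s = 32, normalize = TRUE) {
  if (length(time_grid) == 0) abort("canonical_hrf: empty time grid")
  if (any(time_grid < 0) || is.unsorted(time_grid)) {
    abort("canonical_hrf: time grid must be non-negative and increasing")
  }
  h <- stats::dgamma(time_grid, shape = peak_delay / peak_disp,
                     rate = 1 / peak_disp) -
    stats::dgamma(time_grid, shape = undershoot_delay / undershoot_disp,
                  rate = 1 / undershoot_disp) / ratio
  h[time_grid > length_s] <- 0
  if (normalize && max(h) > 0) h <- h / max(h)
  h
}

# convolve a (onset, duration, amplitude) event stream with the HRF on a
# fine grid of step dt, then sample at the scan times
convolve_events <- function(onsets, durations, amplitudes, n_scans, tr, dt) {
  t_max <- n_scans * tr + 32
  grid_n <- ceiling(t_max / dt) + 1
  stick <- numeric(grid_n)
  for (k in seq_along(onsets)) {
    i0 <- floor(onsets[k] / dt) + 1
    i1 <- max(i0, floor((onsets[k] + durations[k]) / dt))
    idx <- i0:min(i1, grid_n)
    stick[idx] <- stick[idx] + amplitudes[k]
  }
  h <- canonical_hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(stick, rev(h), type = "open")[seq_len(grid_n)] * dt
  scan_t <- (seq_len(n_scans) - 1) * tr
  conv[pmin(grid_n, floor(scan_t / dt) + 1)]
}

#' Build a first-level fMRI design matrix with parametric modulators
#'
#' Takes a BIDS-events-style table and returns an HRF-convolved design
#' matrix. Each distinct `condition` contributes one unmodulated boxcar
#' regressor. Every additional numeric column that is non-missing within a
#' condition contributes one parametric-modulator regressor for that
#' condition, mean-centered across that condition's events *before*
#' convolution. Modulators are not serially orthogonalized. A constant
#' modulator centers to zero and is dropped with a warning. An intercept
#' column is appended last.
#'
#' For the effort task the canonical events table carries a `decision`
#' condition with `subjective_reward`, `subjective_effort` and `cost_benefit`
#' modulators, an `exertion` condition modulated by `mean_force`, and an
#' `outcome` condition modulated by `points_won` (see [events_from_trials()]).
#'
#' @param events Data frame with `onset`, `duration`, `condition`, plus
#'   numeric modulator columns (NA outside their condition).
#' @param n_scans Number of volumes.
#' @param tr Repetition time (s), default 2.
#' @param dt Microtime resolution (s) of the convolution grid, default 0.1.
#' @return A numeric matrix (`n_scans` rows) with named columns; attribute
#'   `"dropped"` lists any dropped constant modulators.
#' @export
build_design_matrix <- function(events, n_scans, tr = 2, dt = 0.1) {
  check_columns(events, c("onset", "duration", "condition"), "events")
  stopifnot(tr > 0, dt > 0)
  if (is.unsorted(events$onset)) events <- events[order(events$onset), ]
  conds <- unique(events$condition)
  mod_cols <- setdiff(names(events), c("onset", "duration", "condition"))
  mod_cols <- mod_cols[purrr::map_lgl(events[mod_cols], is.numeric)]
  cols <- list()
  dropped <- character(0)
  for (cd in conds) {
    ev <- events[events$condition == cd, ]
    cols[[cd]] <- convolve_events(ev$onset, ev$duration,
                                  rep(1, nrow(ev)), n_scans, tr, dt)
    for (mc in mod_cols) {
      vals <- ev[[mc]]
      if (all(is.na(vals))) next
      if (anyNA(vals)) {
        abort(sprintf("modulator '%s' is partially missing within condition '%s'",
                      mc, cd))
      }
      centered <- vals - mean(vals)
      nm <- paste(cd, mc, sep = "_")
      if (all(abs(centered) < 1e-12)) {
        warn(sprintf("modulator '%s' is constant within condition '%s'; column dropped",
                     mc, cd))
        dropped <- c(dropped, nm)
        next
      }
      cols[[nm]] <- convolve_events(ev$onset, ev$duration, centered,
                                    n_scans, tr, dt)
    }
  }
  cols[["intercept"]] <- rep(1, n_scans)
  X <- do.call(cbind, cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    abort(paste("design matrix is rank deficient; collinear column(s):",
                paste(colnames(X)[drop_idx], collapse = ", ")))
  }
  attr(X, "dropped") <- dropped
  attr(X, "tr") <- tr
  X
}

#' Assemble a BIDS-events-style table from one subject's trials
#'
#' Produces the three-condition event timeline of the task: the combined
#' decision/choice phase (modulated by subjective reward, subjective effort
#' and the cost-benefit weight), the effort-exertion phase on accepted trials
#' (modulated by mean applied force), and the outcome phase on accepted
#' trials (modulated by points obtained). Onsets are shifted by
#' `run_offset * (run - 1)` so multiple runs can be concatenated into one
#' time series.
#'
#' @param trials One subject's trial records (with the modulator columns from
#'   [subjective_modulators()] and [cost_benefit_weights()]).
#' @param run_offset Time (s) between run starts when concatenating runs.
#' @return Events tibble for [build_design_matrix()].
#' @export
events_from_trials <- function(trials, run_offset = 400) {
  check_columns(trials, c("run", "onset_decision", "duration_decision",
                          "onset_exertion", "duration_exertion",
                          "onset_outcome", "duration_outcome", "accepted",
                          "subjective_reward", "subjective_effort",
                          "cost_benefit"), "trials")
  off <- (trials$run - 1) * run_offset
  dec <- tibble(onset = trials$onset_decision + off,
                duration = trials$duration_decision,
                condition = "decision",
                subjective_reward = trials$subjective_reward,
                subjective_effort = trials$subjective_effort,
                cost_benefit = trials$cost_benefit,
                mean_force = NA_real_, points_won = NA_real_)
  acc <- trials[trials$accepted, ]
  offa <- (acc$run - 1) * run_offset
  exe <- tibble(onset = acc$onset_exertion + offa,
                duration = acc$duration_exertion,
                condition = "exertion",
                subjective_reward = NA_real_, subjective_effort = NA_real_,
                cost_benefit = NA_real_,
                mean_force = acc$mean_force, points_won = NA_real_)
  out <- tibble(onset = acc$onset_outcome + offa,
                duration = acc$duration_outcome,
                condition = "outcome",
                subjective_reward = NA_real_, subjective_effort = NA_real_,
                cost_benefit = NA_real_,
                mean_force = NA_real_, points_won = as.numeric(acc$points_won))
  bind_rows(dec, exe, out) %>% arrange(.data$onset)
}

#' Voxel set of a spherical ROI on a regular grid
#'
#' Enumerates all grid points (spacing `grid_spacing` mm, centered on
#' `center`) whose Euclidean distance from the sphere center is at most
#' `radius` (inclusive boundary).
#'
#' @param center Length-3 numeric, MNI mm coordinates of the sphere center.
#' @param radius Sphere radius in mm (default 6).
#' @param grid_spacing Grid spacing in mm (default 2).
#' @return A tibble of voxel-center coordinates `x`, `y`, `z` (mm).
#' @examples
#' nrow(sphere_voxel_set(c(0, 14, 46))) # 123 voxels at r = 6, 2 mm grid
#' @export
sphere_voxel_set <- function(center, radius = 6, grid_spacing = 2) {
  stopifnot(length(center) == 3, radius >= 0, grid_spacing > 0)
  k <- floor(radius / grid_spacing)
  offs <- seq(-k, k) * grid_spacing
  g <- tidyr::expand_grid(dx = offs, dy = offs, dz = offs) %>%
    filter(.data$dx^2 + .data$dy^2 + .data$dz^2 <= radius^2)
  tibble(x = center[1] + g$dx, y = center[2] + g$dy, z = center[3] + g$dz)
}

#' Write a spherical ROI mask as a NIfTI volume
#'
#' Renders the sphere from [sphere_voxel_set()] as a binary mask on an
#' MNI152-like grid (91 x 109 x 91 voxels at 2 mm, origin at mm
#' (-90, -126, -72) with x mirrored as in the MNI template).
#'
#' @param center,radius,grid_spacing As in [sphere_voxel_set()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_roi_mask <- function(center, path, radius = 6, grid_spacing = 2) {
  vox <- sphere_voxel_set(center, radius, grid_spacing)
  dims <- c(91, 109, 91)
  arr <- array(0L, dims)
  # MNI152 2 mm convention: mm = M %*% voxel(0-based); x flipped
  i <- round((90 - vox$x) / 2) + 1
  j <- round((vox$y + 126) / 2) + 1
  k <- round((vox$z + 72) / 2) + 1
  keep <- i >= 1 & i <= dims[1] & j >= 1 & j <= dims[2] & k >= 1 & k <= dims[3]
  arr[cbind(i[keep], j[keep], k[keep])] <- 1L
  img <- RNifti::asNifti(arr)
  affine <- rbind(c(-2, 0, 0, 90), c(0, 2, 0, -126), c(0, 0, 2, -72),
                  c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(affine, code = 4L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Simulate an ROI-average BOLD signal from a design
#'
#' @param design Design matrix from [build_design_matrix()].
#' @param betas Named numeric vector of true effects; names must match design
#'   columns (missing names default to 0).
#' @param noise_sd SD of white Gaussian noise added to the signal.
#' @param seed Integer seed.
#' @return Numeric signal of length `nrow(design)`.
#' @export
simulate_roi_signal <- function(design, betas, noise_sd = 1, seed = 1) {
  b <- setNames(numeric(ncol(design)), colnames(design))
  known <- intersect(names(betas), names(b))
  b[known] <- betas[known]
  withr::with_seed(seed,
    as.numeric(design %*% b) + rnorm(nrow(design), 0, noise_sd))
}

#' Fit the first-level GLM to an ROI signal
#'
#' Ordinary least squares of the ROI-average signal on the design matrix.
#' The decision-phase subjective-reward and subjective-effort modulator betas
#' are exposed as the subject's contrast estimates.
#'
#' @param signal Numeric vector, one value per scan.
#' @param design Matrix from [build_design_matrix()] (same number of rows).
#' @return A `first_level_fit`: list with `betas` tibble (term, estimate,
#'   se, t), `sigma2`, `df`, and `contrasts` (the decision-phase modulator
#'   betas).
#' @export
fit_first_level <- function(signal, design) {
  if (length(signal) != nrow(design)) {
    abort("signal length must equal the number of design rows")
  }
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    drop_idx <- setdiff(seq_len(ncol(design)), qrX$pivot[seq_len(qrX$rank)])
    abort(paste("rank-deficient design; collinear column(s):",
                paste(colnames(design)[drop_idx], collapse = ", ")))
  }
  beta <- qr.coef(qrX, signal)
  res <- signal - design %*% beta
  df <- nrow(design) - ncol(design)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  betas <- tibble(term = colnames(design), estimate = as.numeric(beta),
                  se = se, t = as.numeric(beta) / se)
  cn <- c("decision_subjective_reward", "decision_subjective_effort")
  contrasts <- betas %>% filter(.data$term %in% cn) %>%
    mutate(modulator = ifelse(.data$term == cn[1], "reward", "effort")) %>%
    select("modulator", "estimate")
  structure(list(betas = betas, sigma2 = sigma2, df = df,
                 contrasts = contrasts),
            class = "first_level_fit")
}

#' @export
print.first_level_fit <- function(x, ...) {
  cat("<first_level_fit>", nrow(x$betas), "regressors, residual df", x$df, "\n")
  print(x$betas, n = nrow(x$betas))
  invisible(x)
}

#' Combine bilateral ROI betas
#'
#' Bilateral structures are combined as the unweighted arithmetic mean of the
#' left and right betas. Vectorized.
#'
#' @param left_beta,right_beta Finite numerics.
#' @return `(left_beta + right_beta) / 2`.
#' @examples
#' combine_bilateral(0.2, 0.6) # 0.4
#' @export
combine_bilateral <- function(left_beta, right_beta) {
  if (!all(is.finite(left_beta)) || !all(is.finite(right_beta))) {
    abort("combine_bilateral: betas must be finite")
  }
  (left_beta + right_beta) / 2
}
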