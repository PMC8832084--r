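#' Build a balanced reward-by-effort offer schedule
#'
#' Constructs the trial schedule for the effort-based decision-making task:
#' a full crossing of three reward levels (4, 8, 12 points) with three effort
#' levels (0.2, 0.5, 0.8 of maximum voluntary contraction, MVC), each cell
#' repeated `reps_per_cell` times, split over `n_runs` runs. With the defaults
#' (3 runs, 8 repetitions) this is the 72-trial design. Trial order is a
#' seeded permutation; when `reps_per_cell` is divisible by `n_runs` the
#' design is balanced within run (each cell appears equally often per run).
#'
#' Event timing follows the task structure: a jittered decision/choice phase
#' (uniform 3-4.5 s), a fixed 4 s effort-exertion phase, and a jittered
#' outcome phase (uniform 1.5-2.5 s), separated by a fixed 1 s inter-trial
#' interval. Onsets restart at 0 in each run.
#'
#' @param n_runs Number of runs (default 3).
#' @param reps_per_cell Repetitions of each of the 9 offer cells (default 8).
#' @param seed Integer seed for the order permutation and timing jitters.
#' @param reward_levels,effort_levels The three reward and effort levels.
#' @param decision_jitter,outcome_jitter Length-2 ranges (s) for the uniform
#'   duration jitters of the decision and outcome phases.
#' @param exertion_duration Duration (s) of the effort-exertion phase.
#' @param iti Inter-trial interval (s).
#' @return A tibble with one row per trial: `run`, `trial` (1..total across
#'   runs), `reward_level`, `effort_level`, and onset/duration columns for the
#'   decision, exertion and outcome phases (seconds, within run).
#' @examples
#' sched <- build_offer_schedule(seed = 1)
#' nrow(sched) # 72
#' table(sched$reward_level, sched$effort_level) # 8 per cell
#' @export
build_offer_schedule <- function(n_runs = 3, reps_per_cell = 8, seed = 1,
                                 reward_levels = c(4, 8, 12),
                                 effort_levels = c(0.2, 0.5, 0.8),
                                 decision_jitter = c(3, 4.5),
                                 exertion_duration = 4,
                                 outcome_jitter = c(1.5, 2.5),
                                 iti = 1) {
  stopifnot(n_runs >= 1, reps_per_cell >= 1,
            length(reward_levels) == 3, length(effort_levels) == 3)
  n_cells <- length(reward_levels) * length(effort_levels)
  total <- n_cells * reps_per_cell
  if (total %% n_runs != 0) {
    abort(sprintf(
      "total trial count (%d cells x %d reps = %d) is not divisible by n_runs = %d",
      n_cells, reps_per_cell, total, n_runs))
  }
  per_run <- total %/% n_runs
  cells <- tidyr::expand_grid(reward_level = reward_levels,
                              effort_level = effort_levels)

  withr::with_seed(seed, {
    if (reps_per_cell %% n_runs == 0) {
      # balanced within run: each cell reps_per_cell / n_runs times per run
      per_run_cells <- cells[rep(seq_len(n_cells), reps_per_cell %/% n_runs), ]
      runs <- purrr::map(seq_len(n_runs), function(r) {
        per_run_cells[sample.int(nrow(per_run_cells)), ]
      })
    } else {
      # overall balance only: permute the full multiset, cut into runs
      full <- cells[rep(seq_len(n_cells), reps_per_cell), ]
      full <- full[sample.int(nrow(full)), ]
      runs <- purrr::map(seq_len(n_runs), function(r) {
        full[((r - 1) * per_run + 1):(r * per_run), ]
      })
    }
    sched <- purrr::imap(runs, function(offers, r) {
      d_dec <- runif(per_run, decision_jitter[1], decision_jitter[2])
      d_out <- runif(per_run, outcome_jitter[1], outcome_jitter[2])
      trial_len <- d_dec + exertion_duration + d_out + iti
      onset0 <- cumsum(c(0, trial_len[-per_run]))
      tibble(
        run = r,
        reward_level = offers$reward_level,
        effort_level = offers$effort_level,
        onset_decision = onset0,
        duration_decision = d_dec,
        onset_exertion = onset0 + d_dec,
        duration_exertion = exertion_duration,
        onset_outcome = onset0 + d_dec + exertion_duration,
        duration_outcome = d_out
      )
    }) %>% bind_rows()
    sched$trial <- seq_len(nrow(sched))
    dplyr::relocate(sched, "run", "trial")
  })
}
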