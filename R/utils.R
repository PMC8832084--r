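#' Derive a reproducible stage seed from a master seed
#'
#' Stages of the simulation/analysis pipeline draw their randomness from
#' sub-seeds that are a pure function of the master seed and the stage name,
#' so any stage can be rerun independently and bit-identically.
#'
#' @param master_seed Integer master seed.
#' @param stage Character scalar naming the stage (e.g. `"choices"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "choices")
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, Park-Miller modulus
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 31 + cc) %% m
  out <- ((abs(master_seed) %% m) * 48271 + h) %% m
  as.integer(out %/% 1 + 1L)
}

# numerically stable log(mean(exp(x)))
log_mean_exp <- function(x) {
  mx <- max(x)
  mx + log(mean(exp(x - mx)))
}

# check a data frame has the listed columns; error names the missing ones
check_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
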