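#' Generate a counterbalanced IPAST trial schedule
#'
#' Builds the ordered list of (condition, side) pairs for one session. Within
#' every block each of the four condition x side combinations occurs exactly
#' `trials_per_block / 4` times, in a seeded pseudo-random order, so PRO and
#' ANTI trials (and left/right stimuli) are interleaved with equal frequency.
#'
#' @param config a [task_config()].
#' @param seed integer seed; the same seed always yields the same schedule.
#' @return A data.frame with columns `block`, `trial`, `condition`
#'   (`"pro"`/`"anti"`) and `side` (`"left"`/`"right"`), one row per trial in
#'   presentation order.
#' @export
generate_schedule <- function(config = task_config(), seed = 1L) {
  if (config$trials_per_block %% 4L != 0L)
    stop("`trials_per_block` must be divisible by 4")
  per_cell <- config$trials_per_block %/% 4L
  cells <- expand.grid(condition = c("pro", "anti"),
                       side = c("left", "right"),
                       stringsAsFactors = FALSE)
  blocks <- withr_seed(seed, {
    lapply(seq_len(config$n_blocks), function(b) {
      idx <- sample.int(config$trials_per_block)
      cell <- rep(seq_len(4L), each = per_cell)[idx]
      data.frame(block = b,
                 trial = seq_len(config$trials_per_block),
                 condition = cells$condition[cell],
                 side = cells$side[cell],
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, blocks)
  out$trial_id <- seq_len(nrow(out))
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps schedule/cohort generation
# reproducible without clobbering the global stream.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
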