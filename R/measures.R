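#' Mean viable correct saccadic reaction time
#'
#' Arithmetic mean SRT (ms from STIM appearance to saccade onset) over the
#' viable correct trials of one condition.
#'
#' @param results per-trial classification data.frame (`condition`,
#'   `category`, `srt_ms`).
#' @param condition `"pro"` or `"anti"`.
#' @return Mean SRT in ms; NA (with a warning) when the participant has no
#'   viable correct trial in that condition.
#' @export
mean_viable_correct_srt <- function(results, condition) {
  keep <- results$condition == condition &
    results$category %in% c("viable_correct_express", "viable_correct_regular")
  if (!any(keep)) {
    warning("no viable correct trials in condition '", condition, "'")
    return(NA_real_)
  }
  mean(results$srt_ms[keep])
}

#' Express/regular latency ratios
#'
#' Category counts divided by the condition's viable trial count: the
#' proportions of viable trials that were express-latency correct responses,
#' regular-latency correct responses, express-latency direction errors and
#' regular-latency direction errors.
#'
#' @param results per-trial classification data.frame.
#' @param condition `"pro"` or `"anti"`.
#' @return Named numeric vector `express_correct`, `regular_correct`,
#'   `express_error`, `regular_error`; all NA (with a warning) when the
#'   condition has no viable trials.
#' @export
latency_ratios <- function(results, condition) {
  cat <- results$category[results$condition == condition]
  viable <- sum(cat %in% c("viable_correct_express", "viable_correct_regular",
                           "viable_error_express", "viable_error_regular"))
  out <- c(express_correct = NA_real_, regular_correct = NA_real_,
           express_error = NA_real_, regular_error = NA_real_)
  if (viable == 0) {
    warning("no viable trials in condition '", condition, "'")
    return(out)
  }
  out["express_correct"] <- sum(cat == "viable_correct_express") / viable
  out["regular_correct"] <- sum(cat == "viable_correct_regular") / viable
  out["express_error"] <- sum(cat == "viable_error_express") / viable
  out["regular_error"] <- sum(cat == "viable_error_regular") / viable
  out
}

#' Cumulative SRT distribution
#'
#' At each grid time t, the number of SRTs at or below t divided by the
#' viable trial count. With the viable count (rather than the category
#' count) as denominator, the curve asymptotes at the category's ratio, so
#' correct and error curves of one condition are directly comparable.
#'
#' @param srts SRTs (ms) of one trial category; all must lie in the viable
#'   window.
#' @param viable_count the condition's viable trial count (>= length(srts)).
#' @param grid evaluation grid in ms.
#' @return Numeric vector of the curve on `grid`.
#' @export
cumulative_srt_distribution <- function(srts, viable_count,
                                        grid = seq(90, 800, by = 1)) {
  if (length(srts) > 0 && (min(srts) < 90 || max(srts) > 800))
    stop("SRTs must lie within the viable window (90-800 ms)")
  if (viable_count < length(srts))
    stop("`viable_count` cannot be smaller than the number of SRTs")
  if (length(srts) == 0) return(numeric(length(grid)))
  findInterval(grid, sort(srts)) / viable_count
}

# box smoothing with shrink-to-valid edge handling: near the ends the kernel
# shrinks to the available overlap instead of zero-padding, avoiding
# spurious boundary minima
box_smooth <- function(x, k = 7L) {
  stopifnot(k %% 2L == 1L)
  h <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  i0 <- pmax(seq_len(n) - h, 1L)
  i1 <- pmin(seq_len(n) + h, n)
  (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)
}

#' Voluntary override time
#'
#' The time at which voluntary processes begin to overcome automated
#' processes on ANTI trials: the cumulative SRT distribution of ANTI
#' direction errors is subtracted from that of ANTI correct responses (both
#' on a 1 ms grid over the viable window, with the viable count as common
#' denominator), the difference is smoothed with a 7-point box kernel
#' (shrinking to the valid overlap at the edges), and VOT is the earliest
#' minimum of the smoothed difference within 90-400 ms.
#'
#' @param anti_correct_srts SRTs of ANTI viable correct responses (>= 1
#'   required).
#' @param anti_error_srts SRTs of ANTI viable direction errors.
#' @param anti_viable_count ANTI viable trial count.
#' @param params a [vot_params()].
#' @return VOT in ms.
#' @export
voluntary_override_time <- function(anti_correct_srts, anti_error_srts,
                                    anti_viable_count,
                                    params = vot_params()) {
  if (length(anti_correct_srts) < 1)
    stop("VOT is undefined without at least one ANTI viable correct response")
  grid <- seq(90, 800, by = params$grid_step)
  cc <- cumulative_srt_distribution(anti_correct_srts, anti_viable_count, grid)
  ce <- cumulative_srt_distribution(anti_error_srts, anti_viable_count, grid)
  # rounding to 9 significant digits makes the earliest-minimum tie rule
  # robust to float associativity on plateaus of the difference curve
  sm <- signif(box_smooth(cc - ce, params$kernel_points), 9)
  in_win <- grid >= params$search_window[1] & grid <= params$search_window[2]
  grid[in_win][which.min(sm[in_win])]
}

#' Seven IPAST measures for one participant
#'
#' Computes the participant's full measure set from their per-trial
#' classifications: PRO and ANTI viable correct SRT, the four express/
#' regular latency ratios (PRO correct, ANTI direction error), and VOT,
#' together with the per-condition counts carried forward for QC.
#'
#' @param results per-trial classification data.frame.
#' @param vot a [vot_params()].
#' @param participant_id optional identifier.
#' @param counts optional precomputed [tally_counts()] result (avoids
#'   recomputation in cohort loops).
#' @return A single-row data.frame: `participant_id`, `pro_srt`, `anti_srt`,
#'   `pro_express_ratio`, `pro_regular_ratio`, `anti_express_error_ratio`,
#'   `anti_regular_error_ratio`, `vot`, `pro_viable`, `anti_viable`,
#'   `anti_correct_count`.
#' @export
participant_measures <- function(results, vot = vot_params(),
                                 participant_id = NA_character_,
                                 counts = NULL) {
  pro_ratios <- latency_ratios(results, "pro")
  anti_ratios <- latency_ratios(results, "anti")
  if (is.null(counts)) counts <- tally_counts(results)
  anti_row <- counts[counts$condition == "anti", ]
  pro_row <- counts[counts$condition == "pro", ]
  anti_correct <- anti_row$viable_correct_express + anti_row$viable_correct_regular
  is_anti_cor <- results$condition == "anti" &
    results$category %in% c("viable_correct_express", "viable_correct_regular")
  is_anti_err <- results$condition == "anti" &
    results$category %in% c("viable_error_express", "viable_error_regular")
  vot_ms <- if (anti_correct >= 1)
    voluntary_override_time(results$srt_ms[is_anti_cor],
                            results$srt_ms[is_anti_err],
                            anti_row$viable, vot)
  else NA_real_
  data.frame(
    participant_id = participant_id,
    pro_srt = mean_viable_correct_srt(results, "pro"),
    anti_srt = if (anti_correct >= 1) mean_viable_correct_srt(results, "anti")
               else NA_real_,
    pro_express_ratio = unname(pro_ratios["express_correct"]),
    pro_regular_ratio = unname(pro_ratios["regular_correct"]),
    anti_express_error_ratio = unname(anti_ratios["express_error"]),
    anti_regular_error_ratio = unname(anti_ratios["regular_error"]),
    vot = vot_ms,
    pro_viable = pro_row$viable,
    anti_viable = anti_row$viable,
    anti_correct_count = anti_correct,
    stringsAsFactors = FALSE
  )
}
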