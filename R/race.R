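#' Sample latent trial outcomes from the race model
#'
#' Draws the latent fate of each trial before any gaze trace is rendered.
#' Each trial is first assigned a fate (eye-tracking loss, one of the three
#' non-compliance modes, an anticipatory guess, or a behavioral response).
#' Behavioral responses are generated by the two-suppression race: with
#' probability `p_express[condition]` the express pathway fires (a
#' stimulus-directed saccade with truncated-normal latency on 90-139 ms;
#' correct on PRO, a direction error on ANTI); otherwise the automated and
#' voluntary commands race. On PRO trials both commands are
#' stimulus-directed, so the earlier finishing time gives a correct
#' pro-saccade. On ANTI trials a finishing automated command triggers a
#' regular-latency direction error toward the stimulus, while a finishing
#' voluntary command triggers a correct anti-saccade away from it.
#'
#' @param conditions character vector of `"pro"`/`"anti"` per trial.
#' @param sides character vector of `"left"`/`"right"` stimulus sides.
#' @param params a [behavior_params()].
#' @return A data.frame with one row per trial: `condition`, `side`, `fate`
#'   (`eye_loss`, `no_fixation`, `random_saccade`, `no_saccade`,
#'   `anticipatory`, `express`, `regular`), `latency_ms` (NA for fates with
#'   no response saccade), `toward_stim` (logical; NA likewise) and `correct`
#'   (logical; NA for non-response fates).
#' @export
sample_trial_outcomes <- function(conditions, sides, params = behavior_params()) {
  stopifnot(length(conditions) == length(sides),
            all(conditions %in% c("pro", "anti")),
            all(sides %in% c("left", "right")))
  n <- length(conditions)
  p <- params
  # trial fate by inverse-CDF on a single uniform per trial
  cuts <- cumsum(c(p$p_eyeloss,
                   p$p_noncompliance[["no_fixation"]],
                   p$p_noncompliance[["random_saccade"]],
                   p$p_noncompliance[["no_saccade"]],
                   p$p_anticipatory))
  u <- stats::runif(n)
  fate <- rep("response", n)
  fate[u < cuts[5]] <- "anticipatory"
  fate[u < cuts[4]] <- "no_saccade"
  fate[u < cuts[3]] <- "random_saccade"
  fate[u < cuts[2]] <- "no_fixation"
  fate[u < cuts[1]] <- "eye_loss"

  latency <- rep(NA_real_, n)
  toward <- rep(NA, n)

  ant <- fate == "anticipatory"
  latency[ant] <- stats::runif(sum(ant), -110, 89)
  toward[ant] <- stats::runif(sum(ant)) < 0.5

  beh <- fate == "response"
  n_beh <- sum(beh)
  if (n_beh > 0) {
    is_anti <- conditions[beh] == "anti"
    p_exp <- ifelse(is_anti, p$p_express[["anti"]], p$p_express[["pro"]])
    express <- stats::runif(n_beh) < p_exp
    lat <- numeric(n_beh)
    twd <- logical(n_beh)
    if (any(express)) {
      lat[express] <- rtrunc_norm(sum(express), p$express_mean, p$express_sd,
                                  90, 139)
      twd[express] <- TRUE  # express pathway is always stimulus-directed
    }
    if (any(!express)) {
      m <- sum(!express)
      t_auto <- p$auto_shift + stats::rgamma(m, shape = p$auto_shape,
                                             scale = p$auto_scale)
      t_vol <- p$vol_shift + stats::rgamma(m, shape = p$vol_shape,
                                           scale = p$vol_scale)
      anti_r <- is_anti[!express]
      # on ANTI trials the automated command is cancelled outright with
      # probability 1 - p_automatic; a cancelled command cannot win
      cancelled <- anti_r & stats::runif(m) >= p$p_automatic
      auto_wins <- !cancelled & t_auto < t_vol
      # PRO: both commands stimulus-directed, earlier one wins and is correct
      lat[!express] <- ifelse(anti_r,
                              ifelse(auto_wins, t_auto, t_vol),
                              pmin(t_auto, t_vol))
      twd[!express] <- !anti_r | auto_wins
    }
    fate[beh] <- ifelse(express, "express", "regular")
    latency[beh] <- lat
    toward[beh] <- twd
  }

  correct <- rep(NA, n)
  resp <- fate %in% c("express", "regular")
  correct[resp] <- ifelse(conditions[resp] == "pro", toward[resp], !toward[resp])

  data.frame(condition = conditions, side = sides, fate = fate,
             latency_ms = latency, toward_stim = toward, correct = correct,
             stringsAsFactors = FALSE)
}

# inverse-CDF truncated normal sampler
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# truncated normal density / CDF on [lo, hi]
dtrunc_norm <- function(x, mean, sd, lo, hi) {
  z <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  ifelse(x >= lo & x <= hi, stats::dnorm(x, mean, sd) / z, 0)
}

ptrunc_norm <- function(x, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  z <- stats::pnorm(hi, mean, sd) - plo
  pmin(pmax((stats::pnorm(x, mean, sd) - plo) / z, 0), 1)
}

#' Analytic ANTI error probabilities under the race model
#'
#' Computes, by numerical integration of the race densities, the probability
#' that a behavioral ANTI trial ends in a direction error: the express
#' pathway fires (express-latency error), or the automated command survives
#' suppression and finishes before the voluntary command (regular-latency
#' error).
#'
#' @param params a [behavior_params()].
#' @return A named list: `p_express_error`, `p_regular_error`, `p_error`
#'   (their sum) and `p_auto_wins` (the race-win probability of a surviving
#'   automated process).
#' @export
race_anti_error_probability <- function(params = behavior_params()) {
  p <- params
  integrand <- function(t) {
    stats::dgamma(t - p$auto_shift, shape = p$auto_shape, scale = p$auto_scale) *
      stats::pgamma(t - p$vol_shift, shape = p$vol_shape, scale = p$vol_scale,
                    lower.tail = FALSE)
  }
  p_auto_wins <- stats::integrate(integrand, lower = p$auto_shift,
                                  upper = Inf, rel.tol = 1e-10)$value
  pe <- p$p_express[["anti"]]
  list(p_express_error = pe,
       p_regular_error = (1 - pe) * p$p_automatic * p_auto_wins,
       p_error = pe + (1 - pe) * p$p_automatic * p_auto_wins,
       p_auto_wins = p_auto_wins)
}

#' Analytic ANTI sub-densities and cumulative curves of the race model
#'
#' Evaluates, on a latency grid, the sub-densities of correct anti-saccade
#' and direction-error latencies implied by the race parameters, and the
#' corresponding cumulative distributions normalized by the viable
#' probability (so each curve asymptotes at its category ratio, matching the
#' empirical convention of using the viable trial count as denominator).
#'
#' @param params a [behavior_params()].
#' @param grid latency grid in ms.
#' @return A data.frame with columns `t`, `dens_correct`, `dens_error`,
#'   `cum_correct`, `cum_error`.
#' @export
race_anti_curves <- function(params = behavior_params(),
                             grid = seq(0, 800, by = 1)) {
  p <- params
  pe <- p$p_express[["anti"]]
  f_a <- stats::dgamma(grid - p$auto_shift, shape = p$auto_shape, scale = p$auto_scale)
  S_a <- stats::pgamma(grid - p$auto_shift, shape = p$auto_shape, scale = p$auto_scale,
                       lower.tail = FALSE)
  f_v <- stats::dgamma(grid - p$vol_shift, shape = p$vol_shape, scale = p$vol_scale)
  S_v <- stats::pgamma(grid - p$vol_shift, shape = p$vol_shape, scale = p$vol_scale,
                       lower.tail = FALSE)
  pa <- p$p_automatic
  dens_err <- pe * dtrunc_norm(grid, p$express_mean, p$express_sd, 90, 139) +
    (1 - pe) * pa * f_a * S_v
  # correct latency is the voluntary finishing time; it loses only to a
  # surviving automated command that finished earlier
  dens_cor <- (1 - pe) * f_v * ((1 - pa) + pa * S_a)
  dt <- diff(grid)
  trap <- function(d) c(0, cumsum((d[-1] + d[-length(d)]) / 2 * dt))
  # express component integrated exactly (its density is discontinuous at
  # the truncation bounds, where the trapezoid rule loses half a cell)
  cum_err <- pe * ptrunc_norm(grid, p$express_mean, p$express_sd, 90, 139) +
    trap((1 - pe) * pa * f_a * S_v)
  cum_cor <- trap(dens_cor)
  viable <- cum_err[length(grid)] + cum_cor[length(grid)]
  data.frame(t = grid,
             dens_correct = dens_cor, dens_error = dens_err,
             cum_correct = cum_cor / viable, cum_error = cum_err / viable)
}

#' Analytic voluntary override time of the race model
#'
#' Applies the VOT definition to the exact race-model cumulative curves:
#' difference the analytic cumulative distributions of ANTI correct responses
#' and direction errors on a 1 ms grid over the viable window, smooth with
#' the box kernel, and take the earliest minimum within the search window.
#' Serves as the ground-truth crossover time against which pipeline VOT
#' estimates from finite trial counts can be validated.
#'
#' @param params a [behavior_params()].
#' @param vot a [vot_params()].
#' @return VOT in ms.
#' @export
race_analytic_vot <- function(params = behavior_params(), vot = vot_params()) {
  grid <- seq(90, 800, by = vot$grid_step)
  cv <- race_anti_curves(params, grid = grid)
  d <- cv$cum_correct - cv$cum_error
  sm <- signif(box_smooth(d, vot$kernel_points), 9)
  in_win <- grid >= vot$search_window[1] & grid <= vot$search_window[2]
  grid[in_win][which.min(sm[in_win])]
}
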