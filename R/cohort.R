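#' Piecewise-linear age trajectory
#'
#' Convenience constructor for trajectory curves: a continuous
#' piecewise-linear function through (age, value) knots, constant beyond the
#' outer knots.
#'
#' @param ages,values knot coordinates (same length, ages increasing).
#' @return A function age -> value.
#' @export
piecewise_linear <- function(ages, values) {
  stopifnot(length(ages) == length(values), !is.unsorted(ages))
  stats::approxfun(ages, values, rule = 2)
}

#' Cross-sectional trajectory specification
#'
#' Describes how the generative behavioral parameters vary with age across a
#' cohort, together with the ground-truth change points of each varying
#' parameter (ages at which its trajectory changes slope) so that
#' change-point recovery can be validated. Curve names address
#' [behavior_params()] fields; the express probabilities are addressed as
#' `p_express_pro` / `p_express_anti`.
#'
#' @param curves named list of functions age -> parameter value.
#' @param noise_sdlog named numeric: lognormal between-participant
#'   variability (sd of log) applied multiplicatively to each curve's value;
#'   parameters without an entry get no between-participant noise.
#'   Lognormal noise keeps positive parameters positive.
#' @param change_points named list of true change-point ages per curve.
#' @param age_range closed age interval of the cohort.
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(curves = list(), noise_sdlog = numeric(0),
                              change_points = list(),
                              age_range = c(5, 93)) {
  if (age_range[1] >= age_range[2]) stop("empty age range")
  for (cp in change_points) {
    if (any(cp <= age_range[1] | cp >= age_range[2]))
      stop("true change points must lie strictly inside the age range")
  }
  structure(list(curves = curves, noise_sdlog = noise_sdlog,
                 change_points = change_points, age_range = age_range),
            class = "trajectory_params")
}

#' Default lifespan trajectory
#'
#' A U-shaped study-condition trajectory motivated by the qualitative form
#' of lifespan saccade data: the voluntary-process shift (which drives ANTI
#' correct SRT and VOT) improves by 7 ms/year from age 5 to a change point
#' at 18, plateaus through mid-adulthood, then declines by 2 ms/year from a
#' change point at 60; the PRO express-pathway probability declines linearly
#' across the whole lifespan; the ANTI express-error probability declines
#' until 26 and then plateaus. Between-participant variability is lognormal.
#'
#' @return A [trajectory_params()].
#' @export
default_lifespan_trajectory <- function() {
  trajectory_params(
    curves = list(
      vol_shift = piecewise_linear(c(5, 18, 60, 93), c(241, 150, 150, 216)),
      p_express_pro = piecewise_linear(c(5, 93), c(0.35, 0.10)),
      p_express_anti = piecewise_linear(c(5, 26, 93), c(0.25, 0.05, 0.05))
    ),
    noise_sdlog = c(vol_shift = 0.12, p_express_pro = 0.25,
                    p_express_anti = 0.25),
    change_points = list(vol_shift = c(18, 60), p_express_anti = 26),
    age_range = c(5, 93)
  )
}

#' Constant (null) trajectory
#'
#' All participants share the base behavioral parameters (up to optional
#' between-participant noise); no true change points. Used for
#' false-detection calibration of the change-point analysis.
#'
#' @param noise_sdlog as in [trajectory_params()].
#' @param age_range cohort age interval.
#' @return A [trajectory_params()].
#' @export
constant_trajectory <- function(noise_sdlog = c(vol_shift = 0.12),
                                age_range = c(5, 93)) {
  trajectory_params(curves = list(), noise_sdlog = noise_sdlog,
                    change_points = list(), age_range = age_range)
}

# evaluate the trajectory at one age and apply between-participant noise;
# returns a behavior_params object
trajectory_at_age <- function(traj, age, base = behavior_params()) {
  fields <- unclass(base)
  keys <- union(names(traj$curves), names(traj$noise_sdlog))
  for (key in keys) {
    value <- if (!is.null(traj$curves[[key]])) traj$curves[[key]](age)
    else get_param(fields, key)
    sdlog <- traj$noise_sdlog[key]
    if (!is.na(sdlog) && sdlog > 0)
      value <- value * exp(stats::rnorm(1, 0, sdlog))
    fields <- set_param(fields, key, value)
  }
  # keep the race invariants valid under noise
  fields$vol_shift <- max(fields$vol_shift, fields$auto_shift)
  fields$p_express <- pmin(pmax(fields$p_express, 0), 0.95)
  do.call(behavior_params, fields[setdiff(names(fields), character(0))])
}

get_param <- function(fields, key) {
  switch(key,
         p_express_pro = fields$p_express[["pro"]],
         p_express_anti = fields$p_express[["anti"]],
         fields[[key]])
}

set_param <- function(fields, key, value) {
  switch(key,
         p_express_pro = { fields$p_express[["pro"]] <- value; fields },
         p_express_anti = { fields$p_express[["anti"]] <- value; fields },
         { fields[[key]] <- value; fields })
}

# deterministic counter-based per-participant substream seed, so cohorts are
# reproducible regardless of generation order
participant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483629)
}

#' Simulate one participant's session
#'
#' Generates the counterbalanced schedule and latent trial outcomes (and,
#' optionally, rendered gaze traces) for one participant under fixed
#' behavioral parameters.
#'
#' @param params a [behavior_params()].
#' @param config a [task_config()].
#' @param seed integer substream seed.
#' @param trace_level render full 500 Hz gaze traces (slow) instead of
#'   stopping at latent outcomes.
#' @return A list with `schedule`, `outcomes`, and `traces` (NULL unless
#'   `trace_level`).
#' @export
simulate_participant <- function(params = behavior_params(),
                                 config = task_config(), seed = 1L,
                                 trace_level = FALSE) {
  schedule <- generate_schedule(config, seed)
  withr_seed(seed + 1L, {
    outcomes <- sample_trial_outcomes(schedule$condition, schedule$side, params)
    traces <- NULL
    if (trace_level)
      traces <- lapply(seq_len(nrow(outcomes)), function(i)
        render_gaze_trace(outcomes[i, ], config, params))
    list(schedule = schedule, outcomes = outcomes, traces = traces)
  })
}

#' Generate a cross-sectional cohort
#'
#' Draws participant ages uniformly over the trajectory's age range
#' (a deliberately simple sampling scheme that gives the change-point
#' analysis even coverage of the lifespan), assigns sex at equal frequency,
#' MoCA scores to participants aged 18+ (with a realistic missingness rate)
#' and eye-tracker validation accuracies, evaluates the trajectory at each
#' participant's age with between-participant noise, and simulates each
#' participant's session from a counter-based substream of the global seed.
#'
#' @param traj a [trajectory_params()].
#' @param n_participants cohort size (>= 1).
#' @param seed global integer seed.
#' @param config a [task_config()].
#' @param base a [behavior_params()]; trajectory curves override its fields.
#' @param trace_level render full gaze traces (memory- and time-intensive;
#'   intended for small cohorts).
#' @param p_poor_compliance fraction of participants with strongly elevated
#'   eye-loss and non-compliance rates (unable or unwilling to do the task),
#'   so that the outlier-rejection stage has realistic work to do; cohort
#'   studies of this kind typically lose a few percent of recruits.
#' @return A list of class `ipast_cohort`: `manifest` (participant_id, age,
#'   sex, moca, validation_error, seed), `participants` (list of
#'   [simulate_participant()] results), `params` (per-participant
#'   [behavior_params()]), `truth` (the trajectory, with its change points),
#'   `config`, and `usable_for_gam` (FALSE for cohorts too small to model).
#' @export
generate_cohort <- function(traj = default_lifespan_trajectory(),
                            n_participants = 100L, seed = 1L,
                            config = task_config(),
                            base = behavior_params(),
                            trace_level = FALSE,
                            p_poor_compliance = 0.04) {
  if (n_participants < 1) stop("`n_participants` must be >= 1")
  manifest <- withr_seed(seed, {
    age <- stats::runif(n_participants, traj$age_range[1], traj$age_range[2])
    sex <- sample(c("F", "M"), n_participants, replace = TRUE)
    # MoCA declines mildly with age; occasional adults fall below cutoff
    moca <- ifelse(age >= 18,
                   pmin(30, round(stats::rnorm(n_participants,
                                               28 - 0.05 * pmax(age - 18, 0),
                                               1.8))),
                   NA_real_)
    moca[age >= 18 & stats::runif(n_participants) < 0.2] <- NA_real_
    validation <- round(abs(stats::rnorm(n_participants, 0.45, 0.25)), 2)
    poor <- stats::runif(n_participants) < p_poor_compliance
    data.frame(participant_id = sprintf("P%04d", seq_len(n_participants)),
               age = age, sex = sex, moca = moca,
               validation_error = validation, poor_compliance = poor,
               seed = vapply(seq_len(n_participants),
                             function(i) participant_seed(seed, i), integer(1)),
               stringsAsFactors = FALSE)
  })
  params <- vector("list", n_participants)
  participants <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    params[[i]] <- withr_seed(manifest$seed[i] + 2L, {
      pp <- trajectory_at_age(traj, manifest$age[i], base)
      if (manifest$poor_compliance[i]) {
        pp$p_eyeloss <- stats::runif(1, 0.10, 0.35)
        pp$p_noncompliance[] <- stats::runif(3, 0.03, 0.12)
      }
      pp
    })
    participants[[i]] <- simulate_participant(params[[i]], config,
                                              manifest$seed[i],
                                              trace_level = trace_level)
  }
  structure(list(manifest = manifest, participants = participants,
                 params = params,
                 truth = list(trajectory = traj),
                 config = config,
                 usable_for_gam = n_participants >= 10),
            class = "ipast_cohort")
}

#' Compute per-participant measures for a whole cohort
#'
#' Classifies every participant's trials (from latent outcomes, or through
#' the full detection pipeline when traces were rendered), computes the
#' seven measures and QC tallies, and applies the outlier-rejection
#' procedure.
#'
#' @param cohort an `ipast_cohort` from [generate_cohort()].
#' @param use_traces run detection + classification on rendered traces
#'   instead of mapping latent outcomes directly.
#' @param qc a [qc_params()].
#' @param vot a [vot_params()].
#' @return A data.frame of class `ipast_measures`: manifest columns joined
#'   with the seven measures, counts, and QC columns `included`, `reasons`.
#' @export
cohort_measures <- function(cohort, use_traces = FALSE, qc = qc_params(),
                            vot = vot_params()) {
  rows <- lapply(seq_along(cohort$participants), function(i) {
    p <- cohort$participants[[i]]
    id <- cohort$manifest$participant_id[i]
    results <- if (use_traces) {
      if (is.null(p$traces)) stop("cohort was generated without traces")
      do.call(rbind, lapply(p$traces, process_trial))
    } else latent_to_results(p$outcomes)
    counts <- tally_counts(results)
    anti_cor <- counts$viable_correct_express[counts$condition == "anti"] +
      counts$viable_correct_regular[counts$condition == "anti"]
    m <- suppressWarnings(participant_measures(results, vot, id,
                                               counts = counts))
    dec <- apply_qc(counts,
                    moca = cohort$manifest$moca[i],
                    validation_error = cohort$manifest$validation_error[i],
                    anti_correct_count = anti_cor,
                    qc_params_or_default(qc), participant_id = id)
    cbind(m, dec[c("included", "reasons")])
  })
  out <- cbind(cohort$manifest[c("participant_id", "age", "sex", "moca",
                                 "validation_error")],
               do.call(rbind, rows)[-1])
  class(out) <- c("ipast_measures", "data.frame")
  out
}

qc_params_or_default <- function(qc) if (is.null(qc)) qc_params() else qc
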