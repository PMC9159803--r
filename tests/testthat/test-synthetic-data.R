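test_that("schedules are exactly counterbalanced within every block", {
  cfg <- task_config()
  for (seed in c(1L, 7L, 123L, 99991L)) {
    sched <- generate_schedule(cfg, seed)
    expect_equal(nrow(sched), 240)
    for (b in 1:2) {
      tab <- table(sched$condition[sched$block == b],
                   sched$side[sched$block == b])
      expect_true(all(tab == 30))
    }
  }
})

test_that("minimal schedule has one trial per condition x side cell", {
  sched <- generate_schedule(task_config(n_blocks = 1, trials_per_block = 4), 5)
  expect_equal(sort(paste(sched$condition, sched$side)),
               c("anti left", "anti right", "pro left", "pro right"))
})

test_that("schedules are deterministic in the seed", {
  expect_identical(generate_schedule(seed = 11), generate_schedule(seed = 11))
  expect_false(identical(generate_schedule(seed = 11)$condition,
                         generate_schedule(seed = 12)$condition))
})

test_that("non-counterbalanceable trial counts are rejected", {
  expect_error(task_config(trials_per_block = 10), "divisible by 4")
})

test_that("forced race pathways produce the forced outcomes", {
  # only the voluntary process can win: every ANTI trial correct, voluntary latency
  p <- behavior_params(p_express = c(pro = 0, anti = 0), p_automatic = 0,
                       p_anticipatory = 0,
                       p_noncompliance = c(no_fixation = 0, random_saccade = 0,
                                           no_saccade = 0),
                       p_eyeloss = 0)
  set.seed(1)
  o <- sample_trial_outcomes(rep("anti", 500), rep("left", 500), p)
  expect_true(all(o$correct))
  expect_true(all(o$latency_ms >= p$vol_shift))

  # forced express pathway: every ANTI trial is an express-latency error
  p2 <- behavior_params(p_express = c(pro = 1, anti = 1), p_anticipatory = 0,
                        p_noncompliance = c(no_fixation = 0, random_saccade = 0,
                                            no_saccade = 0),
                        p_eyeloss = 0)
  o2 <- sample_trial_outcomes(rep("anti", 500), rep("right", 500), p2)
  expect_true(all(o2$fate == "express"))
  expect_true(all(!o2$correct))
  expect_true(all(o2$latency_ms >= 90 & o2$latency_ms <= 139))
})

test_that("empirical ANTI error ratio matches the analytic race-win probability", {
  p <- behavior_params(p_anticipatory = 0,
                       p_noncompliance = c(no_fixation = 0, random_saccade = 0,
                                           no_saccade = 0),
                       p_eyeloss = 0)
  ana <- race_anti_error_probability(p)
  n <- 10000
  set.seed(77)
  o <- sample_trial_outcomes(rep("anti", n), rep("left", n), p)
  emp <- mean(!o$correct)
  se <- sqrt(ana$p_error * (1 - ana$p_error) / n)
  expect_lt(abs(emp - ana$p_error), 3 * se)
  # express and regular components separately
  emp_exp <- mean(o$fate == "express")
  se_exp <- sqrt(ana$p_express_error * (1 - ana$p_express_error) / n)
  expect_lt(abs(emp_exp - ana$p_express_error), 3 * se_exp)
})

test_that("analytic cumulative curves asymptote at the category ratios", {
  p <- behavior_params()
  cv <- race_anti_curves(p)
  ana <- race_anti_error_probability(p)
  # curves are normalized by the viable probability, so they asymptote at
  # the category ratios among viable (<= 800 ms) trials
  expect_equal(max(cv$cum_correct) + max(cv$cum_error), 1, tolerance = 1e-6)
  # independent quadrature of the error sub-density restricted to 800 ms
  pe <- p$p_express[["anti"]]
  err800 <- pe + (1 - pe) * p$p_automatic * stats::integrate(function(t)
    stats::dgamma(t - p$auto_shift, p$auto_shape, scale = p$auto_scale) *
      stats::pgamma(t - p$vol_shift, p$vol_shape, scale = p$vol_scale,
                    lower.tail = FALSE), p$auto_shift, 800)$value
  cor800 <- (1 - pe) * stats::integrate(function(t)
    stats::dgamma(t - p$vol_shift, p$vol_shape, scale = p$vol_scale) *
      ((1 - p$p_automatic) + p$p_automatic *
         stats::pgamma(t - p$auto_shift, p$auto_shape, scale = p$auto_scale,
                       lower.tail = FALSE)), p$vol_shift, 800)$value
  expect_equal(max(cv$cum_error), err800 / (err800 + cor800), tolerance = 1e-4)
  expect_gt(ana$p_error, 0.2)  # adult-typical error rate regime
  expect_true(all(diff(cv$cum_correct) >= -1e-12))
  expect_true(all(diff(cv$cum_error) >= -1e-12))
})

test_that("rendered correct PRO trial round-trips through detection", {
  cfg <- task_config()
  p <- behavior_params()
  out <- data.frame(condition = "pro", side = "right", fate = "regular",
                    latency_ms = 200, toward_stim = TRUE, correct = TRUE)
  set.seed(3)
  for (i in 1:5) {
    tr <- render_gaze_trace(out, cfg, p)
    ev <- detect_saccades(tr)
    expect_gte(nrow(ev), 1)
    primary <- first_stimulus_directed_saccade(ev)
    expect_lt(abs(primary$onset_ms - 200), 4)
    expect_lt(sqrt((primary$end_x - 10)^2 + primary$end_y^2), 2)
  }
})

test_that("no-saccade traces never exceed the detection floor after STIM onset", {
  cfg <- task_config()
  p <- behavior_params()
  out <- data.frame(condition = "anti", side = "left", fate = "no_saccade",
                    latency_ms = NA_real_, toward_stim = NA, correct = NA)
  set.seed(4)
  tr <- render_gaze_trace(out, cfg, p)
  sp <- compute_speed(tr)
  post <- tr$time_ms >= 0
  expect_true(all(sp[post] <= 20, na.rm = TRUE))
})

test_that("zero fixation noise gives zero speed during fixation", {
  cfg <- task_config()
  p <- behavior_params(fixation_noise_sd = 0)
  out <- data.frame(condition = "pro", side = "right", fate = "regular",
                    latency_ms = 300, toward_stim = TRUE, correct = TRUE)
  tr <- render_gaze_trace(out, cfg, p)
  sp <- compute_speed(tr)
  fix <- tr$time_ms > -1190 & tr$time_ms < -210
  expect_true(all(sp[fix] == 0))
})

test_that("latency outside the trial window is a generation error", {
  out <- data.frame(condition = "pro", side = "right", fate = "regular",
                    latency_ms = 5000, toward_stim = TRUE, correct = TRUE)
  expect_error(render_gaze_trace(out), "outside the trial window")
})

test_that("traces round-trip through CSV exactly", {
  set.seed(9)
  p <- behavior_params()
  o <- sample_trial_outcomes(c("pro", "anti"), c("left", "right"), p)
  traces <- lapply(1:2, function(i) render_gaze_trace(o[i, ], task_config(), p))
  sf <- tempfile(fileext = ".csv"); ef <- tempfile(fileext = ".csv")
  write_traces_csv(traces, sf, ef)
  back <- read_traces_csv(sf, ef)
  for (i in 1:2) {
    expect_equal(back[[i]]$x_deg, traces[[i]]$x_deg)
    expect_equal(back[[i]]$time_ms, traces[[i]]$time_ms)
    expect_equal(attr(back[[i]], "events"), attr(traces[[i]], "events"),
                 ignore_attr = TRUE)
  }
  unlink(c(sf, ef))
})

test_that("cohort generation is seed-reproducible and flags tiny cohorts", {
  traj <- default_lifespan_trajectory()
  c1 <- generate_cohort(traj, n_participants = 5, seed = 21)
  c2 <- generate_cohort(traj, n_participants = 5, seed = 21)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$participants[[3]]$outcomes, c2$participants[[3]]$outcomes)
  c3 <- generate_cohort(traj, n_participants = 1, seed = 2)
  expect_false(c3$usable_for_gam)
  expect_equal(nrow(c3$manifest), 1)
  expect_error(trajectory_params(age_range = c(50, 50)), "empty age range")
})

test_that("trajectory evaluation respects curves and ground truth is carried", {
  traj <- default_lifespan_trajectory()
  expect_equal(traj$change_points$vol_shift, c(18, 60))
  # without noise the curve value is returned exactly
  traj0 <- trajectory_params(
    curves = list(vol_shift = piecewise_linear(c(5, 93), c(240, 160))),
    noise_sdlog = numeric(0), change_points = list(), age_range = c(5, 93))
  p49 <- ipastr:::trajectory_at_age(traj0, 49)
  expect_equal(p49$vol_shift, piecewise_linear(c(5, 93), c(240, 160))(49))
})
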