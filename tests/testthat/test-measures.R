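results_from <- function(condition, category, srt = NA_real_) {
  data.frame(condition = condition, side = "right", category = category,
             srt_ms = srt, stringsAsFactors = FALSE)
}

test_that("mean viable correct SRT is the filtered arithmetic mean", {
  r <- results_from(rep("pro", 4),
                    c("viable_correct_regular", "viable_correct_regular",
                      "viable_correct_express", "viable_error_regular"),
                    c(100, 200, 300, 500))
  expect_equal(mean_viable_correct_srt(r, "pro"), 200)
  r1 <- results_from("pro", "viable_correct_express", 90)
  expect_equal(mean_viable_correct_srt(r1, "pro"), 90)
  expect_warning(out <- mean_viable_correct_srt(r1, "anti"), "no viable correct")
  expect_true(is.na(out))
})

test_that("latency ratios use the viable count as denominator", {
  r <- results_from(rep("pro", 10),
                    c(rep("viable_correct_express", 1),
                      rep("viable_correct_regular", 8),
                      "noncompliant_random_saccade"),
                    c(rep(120, 1), rep(200, 8), NA))
  lr <- latency_ratios(r, "pro")
  expect_equal(unname(lr["express_correct"]), 1 / 9)
  expect_equal(unname(lr["regular_correct"]), 8 / 9)
  expect_equal(unname(lr["express_error"]), 0)
  # zero errors on ANTI: both error ratios zero
  ra <- results_from(rep("anti", 4), rep("viable_correct_regular", 4),
                     rep(250, 4))
  la <- latency_ratios(ra, "anti")
  expect_equal(unname(la["express_error"]), 0)
  expect_equal(unname(la["regular_error"]), 0)
  expect_warning(latency_ratios(ra, "pro"), "no viable")
})

test_that("random result sets match a filter-then-mean / group-by oracle", {
  set.seed(6)
  p <- behavior_params()
  s <- generate_schedule(seed = 31)
  r <- latent_to_results(sample_trial_outcomes(s$condition, s$side, p))
  for (cond in c("pro", "anti")) {
    keep <- r$condition == cond &
      r$category %in% c("viable_correct_express", "viable_correct_regular")
    expect_equal(mean_viable_correct_srt(r, cond), mean(r$srt_ms[keep]))
    lr <- latency_ratios(r, cond)
    viable <- sum(r$condition == cond & grepl("^viable", r$category))
    expect_equal(unname(lr["express_error"]),
                 sum(r$condition == cond & r$category == "viable_error_express") / viable)
  }
})

test_that("cumulative SRT distributions match the empirical-CDF oracle", {
  grid <- seq(90, 800, by = 1)
  expect_equal(cumulative_srt_distribution(numeric(0), 50, grid),
               numeric(length(grid)))
  # all mass at one latency: a step to the category ratio
  c150 <- cumulative_srt_distribution(rep(150, 20), 100, grid)
  expect_equal(c150[grid < 150], rep(0, sum(grid < 150)))
  expect_equal(c150[grid >= 150], rep(0.2, sum(grid >= 150)))
  set.seed(13)
  srts <- round(stats::runif(60, 90, 800))
  got <- cumulative_srt_distribution(srts, 80, grid)
  expect_equal(got, oracle_cumulative(srts, 80, grid))
  expect_true(all(diff(got) >= 0))
  expect_error(cumulative_srt_distribution(c(50, 200), 10, grid), "viable window")
  expect_error(cumulative_srt_distribution(c(100, 200), 1, grid), "cannot be smaller")
})

test_that("VOT of an error-free participant is the window start", {
  expect_equal(voluntary_override_time(c(200, 300, 400), numeric(0), 10), 90)
})

test_that("VOT matches the brute-force 1 ms bin oracle", {
  # 40 errors at 150 ms, 60 corrects at 300 ms, viable 100
  correct <- rep(300, 60); error <- rep(150, 40)
  got <- voluntary_override_time(correct, error, 100)
  expect_equal(got, oracle_vot(correct, error, 100))
  # the minimum sits on the plateau opened by the error mass at 150
  expect_gte(got, 150)
  expect_lt(got, 300)
  set.seed(21)
  for (rep in 1:20) {
    nc <- sample(5:80, 1); ne <- sample(0:40, 1)
    correct <- round(stats::runif(nc, 90, 800))
    error <- round(stats::runif(ne, 90, 500))
    viable <- nc + ne + sample(0:10, 1)
    expect_equal(voluntary_override_time(correct, error, viable),
                 oracle_vot(correct, error, viable))
  }
})

test_that("VOT requires at least one ANTI correct response", {
  expect_error(voluntary_override_time(numeric(0), rep(200, 5), 10),
               "undefined")
})

test_that("VOT is invariant to extra trials with SRT beyond the kernel reach", {
  set.seed(33)
  correct <- round(stats::runif(40, 95, 390))
  error <- round(stats::runif(20, 95, 390))
  base <- voluntary_override_time(correct, error, 70)
  # add late trials (> 407 ms): both curves shift only beyond the search
  # window's kernel footprint, and the common denominator rescales d(t)
  more_correct <- c(correct, rep(500, 15))
  expect_equal(voluntary_override_time(more_correct, error, 85), base)
  more_error <- c(error, rep(650, 10))
  expect_equal(voluntary_override_time(correct, more_error, 80), base)
})

test_that("participant measures bundle the seven measures with counts", {
  set.seed(14)
  p <- behavior_params()
  s <- generate_schedule(seed = 41)
  r <- latent_to_results(sample_trial_outcomes(s$condition, s$side, p))
  m <- participant_measures(r, participant_id = "x")
  expect_equal(m$participant_id, "x")
  ratios <- c(m$pro_express_ratio, m$pro_regular_ratio,
              m$anti_express_error_ratio, m$anti_regular_error_ratio)
  expect_true(all(ratios >= 0 & ratios <= 1))
  expect_lte(m$pro_express_ratio + m$pro_regular_ratio, 1 + 1e-12)
  expect_true(m$vot >= 90 && m$vot <= 400)
  expect_true(m$pro_srt >= 90 && m$pro_srt <= 800)
  # ANTI ratio identity: correct + error ratios over viable trials sum to 1
  anti_correct_ratio <- m$anti_correct_count / m$anti_viable
  expect_equal(anti_correct_ratio + m$anti_express_error_ratio +
                 m$anti_regular_error_ratio, 1)
})
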