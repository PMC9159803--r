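test_that("empirical logit transform squeezes, orders and inverts", {
  expect_equal(logit_transform(0.5, 100), 0, tolerance = 1e-10)
  z0 <- logit_transform(0, 120)
  expect_true(is.finite(z0) && z0 < 0)
  z1 <- logit_transform(1, 120)
  expect_true(is.finite(z1) && z1 > 0)
  p <- seq(0, 1, by = 0.05)
  z <- logit_transform(p, 120)
  expect_true(all(diff(z) > 0))
  expect_equal(inverse_logit_transform(z, 120), p, tolerance = 1e-12)
  expect_error(logit_transform(1.2, 100), "must lie in")
})

test_that("a linear response is recovered with near-null-space effective df", {
  set.seed(61)
  age <- runif(300, 5, 93)
  y <- 100 + 2 * age + rnorm(300, 0, 5)
  fit <- fit_lifespan_gam(age, y)
  expect_lt(abs(fit$edf - 2), 0.7)   # intercept + line
  grid <- seq(10, 90, by = 5)
  pred <- predict(fit$gam, newdata = data.frame(age = grid))
  expect_equal(as.numeric(pred), 100 + 2 * grid, tolerance = 0.02)
})

test_that("fixed-lambda fit equals the direct penalized normal-equations solve", {
  set.seed(62)
  age <- runif(150, 5, 93)
  y <- 250 - 2 * age + 0.03 * age^2 + rnorm(150, 0, 15)
  for (sp in c(0.01, 1, 100)) {
    fit <- fit_lifespan_gam(age, y, k = 10, sp = sp)
    X <- predict(fit$gam, type = "lpmatrix")
    sm <- fit$gam$smooth[[1]]
    S <- matrix(0, ncol(X), ncol(X))
    S[sm$first.para:sm$last.para, sm$first.para:sm$last.para] <- sm$S[[1]]
    beta <- solve(t(X) %*% X + sp * S, t(X) %*% y)
    rel <- max(abs(drop(beta) - fit$coefficients)) / max(abs(fit$coefficients))
    expect_lt(rel, 1e-8)
  }
})

test_that("REML-selected lambda matches a dense grid search", {
  set.seed(63)
  age <- runif(200, 5, 93)
  y <- 250 - 2 * age + 0.03 * age^2 + rnorm(200, 0, 15)
  fit <- fit_lifespan_gam(age, y, k = 10)
  # offset grid (not centered on the optimizer's answer)
  lg <- seq(log(fit$lambda) - 2.7, log(fit$lambda) + 3.3, length.out = 41)
  scores <- vapply(lg, function(l)
    fit_lifespan_gam(age, y, k = 10, sp = exp(l))$reml_score, numeric(1))
  step <- diff(lg)[1]
  expect_lt(abs(log(fit$lambda) - lg[which.min(scores)]), step + 1e-9)
  expect_lte(fit$reml_score, min(scores) + 1e-6)
})

test_that("BIC equals an independent recomputation from log-likelihood", {
  set.seed(64)
  age <- runif(150, 5, 93)
  y <- 200 - age + rnorm(150, 0, 10)
  fit <- fit_lifespan_gam(age, y, k = 10)
  rss <- sum((y - fit$fitted)^2)
  n <- 150
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  expect_equal(fit$bic, -2 * ll + log(n) * (fit$edf + 1), tolerance = 1e-10)
})

test_that("by-sex model comparison behaves as expected at both extremes", {
  set.seed(65)
  n <- 600
  age <- runif(n, 5, 93)
  sex <- rep(c("F", "M"), length.out = n)
  # identical trajectories: extra parameters, no signal
  y_same <- 300 - 1.5 * age + 0.015 * age^2 + rnorm(n, 0, 12)
  f1 <- fit_lifespan_gam(age, y_same, k = 10)
  f2 <- fit_lifespan_gam_by_sex(age, y_same, sex, k = 10)
  expect_lt(f1$bic, f2$bic)
  # strongly divergent trajectories
  y_div <- y_same + ifelse(sex == "M", 2.5 * age, 0)
  f3 <- fit_lifespan_gam(age, y_div, k = 10)
  f4 <- fit_lifespan_gam_by_sex(age, y_div, sex, k = 10)
  expect_lt(f4$bic, f3$bic)
  expect_error(fit_lifespan_gam_by_sex(age, y_same, rep("F", n)),
               "two levels")
})

test_that("posterior draw means converge to the point fit", {
  set.seed(66)
  age <- runif(250, 5, 93)
  y <- 250 - 2 * age + 0.03 * age^2 + rnorm(250, 0, 15)
  fit <- fit_lifespan_gam(age, y, k = 10)
  post <- posterior_simulate(fit, n_draws = 10000, step = 1, seed = 5)
  m <- rowMeans(post$fitted_draws)
  se <- apply(post$fitted_draws, 1, sd) / sqrt(10000)
  expect_true(all(abs(m - post$fitted_mean) < 3.5 * se + 1e-9))
  # bit-reproducible under the same seed
  post2 <- posterior_simulate(fit, n_draws = 100, step = 1, seed = 5)
  post3 <- posterior_simulate(fit, n_draws = 100, step = 1, seed = 5)
  expect_identical(post2$deriv_draws, post3$deriv_draws)
})

test_that("zero posterior covariance collapses every draw onto the point fit", {
  set.seed(67)
  age <- runif(120, 5, 93)
  y <- 150 + age + rnorm(120, 0, 5)
  fit <- fit_lifespan_gam(age, y, k = 10)
  fit$Vp <- matrix(0, length(fit$coefficients), length(fit$coefficients))
  expect_warning(post <- posterior_simulate(fit, n_draws = 50, step = 5),
                 "positive definite")
  expect_equal(max(abs(post$fitted_draws - post$fitted_mean)), 0)
})

test_that("finite-difference derivatives are step-size stable (O(h^2))", {
  set.seed(68)
  age <- runif(200, 5, 93)
  y <- sin(age / 10) * 50 + rnorm(200, 0, 5)
  fit <- fit_lifespan_gam(age, y)
  g <- seq(10, 88, by = 1)
  d1 <- posterior_simulate(fit, n_draws = 2, grid = g, h = 1e-2, seed = 1)$deriv_mean
  d2 <- posterior_simulate(fit, n_draws = 2, grid = g, h = 1e-3, seed = 1)$deriv_mean
  expect_lt(max(abs(d1 - d2)), 1e-4 * max(abs(d1)))
  # and consistent with a coarse secant of the fitted curve itself
  mu <- function(a) drop(predict(fit$gam, newdata = data.frame(age = a)))
  secant <- (mu(g + 0.5) - mu(g - 0.5)) / 1
  expect_lt(max(abs(d1 - secant)), 0.05 * max(abs(d1)))
})

test_that("simultaneous bands contain pointwise bands and degrade gracefully", {
  set.seed(69)
  draws <- matrix(rnorm(40 * 2000), 40, 2000) * seq(0.5, 2, length.out = 40)
  sim <- simultaneous_interval(draws, 0.95)
  pw <- pointwise_interval(draws, 0.95)
  expect_true(all(sim$lower <= pw$lower + 1e-12))
  expect_true(all(sim$upper >= pw$upper - 1e-12))
  # single-point grid: simultaneous equals pointwise
  one <- draws[1, , drop = FALSE]
  s1 <- simultaneous_interval(one, 0.95)
  p1 <- pointwise_interval(one, 0.95)
  expect_equal(s1$lower, p1$lower)
  expect_equal(s1$upper, p1$upper)
  # degenerate sd: zero-width band with a warning
  dg <- rbind(draws[1:3, ], 0)
  expect_warning(sdg <- simultaneous_interval(dg, 0.95), "degenerate")
  expect_equal(sdg$lower[4], 0)
  expect_equal(sdg$upper[4], 0)
})

test_that("significant periods equal a brute-force scan of the exclusion mask", {
  set.seed(70)
  for (rep in 1:50) {
    n <- 80
    grid <- seq(5, 93, length.out = n)
    band <- data.frame(mean = rnorm(n),
                       lower = rnorm(n, -0.5, 1), upper = NA_real_)
    band$upper <- band$lower + abs(rnorm(n, 1, 0.5))
    band$mean <- (band$lower + band$upper) / 2
    pd <- significant_periods(grid, band)
    # oracle: scan the mask directly
    mask <- band$lower > 0 | band$upper < 0
    runs <- oracle_runs(as.numeric(mask), 0.5, 2L)
    expect_equal(nrow(pd), length(runs))
    if (length(runs)) {
      expect_equal(pd$start, vapply(runs, function(r) grid[r[1]], numeric(1)))
      expect_equal(pd$end, vapply(runs, function(r) grid[r[2]], numeric(1)))
    }
  }
})

test_that("periods are labeled developmental before 23 and aging after", {
  grid <- seq(5, 93, by = 0.5)
  lower <- rep(-1, length(grid)); upper <- rep(1, length(grid))
  # a decrease period starting at 18 and an increase period starting at 40
  dev <- grid >= 18 & grid <= 21
  ag <- grid >= 40 & grid <= 45
  upper[dev] <- -0.1; lower[dev] <- -1
  lower[ag] <- 0.1; upper[ag] <- 1
  band <- data.frame(mean = ifelse(dev, -0.5, ifelse(ag, 0.5, 0)),
                     lower = lower, upper = upper)
  pd <- significant_periods(grid, band)
  expect_equal(nrow(pd), 2)
  expect_equal(pd$label, c("developmental", "aging"))
  expect_equal(pd$direction, c("decrease", "increase"))
  expect_equal(pd$start, c(18, 40))
})

test_that("infinite smoothing collapses the fit onto the least-squares line", {
  set.seed(71)
  age <- runif(200, 5, 93)
  y <- 300 - 2 * age + 0.02 * age^2 + rnorm(200, 0, 10)
  fit <- fit_lifespan_gam(age, y, k = 10, sp = 1e9)
  ols <- lm(y ~ age)
  grid <- seq(10, 90, by = 10)
  pred_gam <- drop(predict(fit$gam, newdata = data.frame(age = grid)))
  pred_ols <- drop(predict(ols, newdata = data.frame(age = grid)))
  expect_equal(pred_gam, pred_ols, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("percentile curves are ordered and track the fit and residual law", {
  set.seed(72)
  n <- 800
  age <- runif(n, 5, 93)
  y <- 250 - 2 * age + 0.025 * age^2 + rnorm(n, 0, 20)
  fit <- fit_lifespan_gam(age, y)
  pc <- percentile_curves(fit, step = 1)
  # ordering at every grid age
  mat <- as.matrix(pc[, -1])
  expect_true(all(apply(mat, 1, function(r) all(diff(r) >= 0))))
  # median curve approximates the GAM mean fit for symmetric residuals
  mu <- drop(predict(fit$gam, newdata = data.frame(age = pc$age)))
  inner <- pc$age > 15 & pc$age < 85
  expect_lt(max(abs(pc$p50[inner] - mu[inner])), 6)
  # spacing of the 5th/95th curves approximates the injected z-spacing
  spread <- mean(mat[inner, 7] - mat[inner, 1])
  expect_lt(abs(spread - 2 * qnorm(0.95) * 20), 8)
  expect_error(percentile_curves(fit, percentiles = c(0, 50)), "strictly between")
  expect_warning(percentile_curves(fit_lifespan_gam(age[1:150], y[1:150], k = 10)),
                 "fewer than 200")
})
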