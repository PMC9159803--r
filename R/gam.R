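#' Empirical logit transform for ratio measures
#'
#' The ratio measures are naturally zero- and one-inflated, so before GAM
#' fitting they are squeezed into the open unit interval with the empirical
#' logit adjustment p' = (p (n - 1) + 0.5) / n, where n is the participant's
#' viable trial count, and then logit-transformed. Strictly increasing in p;
#' [inverse_logit_transform()] recovers p exactly.
#'
#' @param p ratio(s) in `[0, 1]`.
#' @param n viable trial count(s) used as the squeeze denominator.
#' @return Transformed value(s) on the real line.
#' @export
logit_transform <- function(p, n) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("ratios must lie in [0, 1]")
  if (any(n <= 1, na.rm = TRUE)) stop("`n` must exceed 1")
  stats::qlogis((p * (n - 1) + 0.5) / n)
}

#' @rdname logit_transform
#' @param z transformed value(s).
#' @export
inverse_logit_transform <- function(z, n) {
  (stats::plogis(z) * n - 0.5) / (n - 1)
}

#' Fit a penalized-spline GAM of a measure on age
#'
#' Gaussian GAM with a single penalized regression-spline smooth of age
#' (cubic regression spline, basis dimension `k`), with the smoothing
#' parameter selected by REML (or fixed via `sp`). Fitting is done with
#' mgcv; the returned wrapper carries the quantities the downstream
#' change-point analysis needs: coefficients, the Bayesian posterior
#' covariance, the smoothing parameter, effective degrees of freedom, fit
#' statistics (Wald-type F for the smooth, R^2, deviance explained) and a
#' Gaussian BIC computed at the penalized fit with the total effective
#' degrees of freedom (plus the scale) as the parameter count.
#'
#' @param age,y numeric vectors (no missing values).
#' @param k basis dimension.
#' @param bs basis type (`"cr"` cubic regression spline, `"tp"` thin plate).
#' @param sp optional fixed smoothing parameter; NULL for REML selection.
#' @return An object of class `lifespan_gam`.
#' @export
fit_lifespan_gam <- function(age, y, k = 20, bs = "cr", sp = NULL) {
  if (length(age) != length(y)) stop("`age` and `y` must have equal length")
  if (anyNA(age) || anyNA(y)) stop("missing values are not allowed")
  dat <- data.frame(age = age, y = y)
  fit <- mgcv::gam(y ~ s(age, k = k, bs = bs), data = dat,
                   method = "REML", sp = sp)
  new_lifespan_gam(fit, dat, by_sex = FALSE)
}

#' Fit a GAM with the age smooth split by sex
#'
#' Separate penalized smooths of age per sex level plus sex intercepts
#' (factor `by` smooths); no age-by-sex tensor. BIC is computed the same way
#' as for the age-only model, so the two are directly comparable.
#'
#' @param age,y numeric vectors.
#' @param sex factor (or coercible) with exactly two levels, both present.
#' @inheritParams fit_lifespan_gam
#' @return An object of class `lifespan_gam`.
#' @export
fit_lifespan_gam_by_sex <- function(age, y, sex, k = 20, bs = "cr", sp = NULL) {
  sex <- factor(sex)
  if (nlevels(sex) != 2 || any(table(sex) == 0))
    stop("`sex` must have two levels, both present")
  dat <- data.frame(age = age, y = y, sex = sex)
  fit <- mgcv::gam(y ~ sex + s(age, by = sex, k = k, bs = bs), data = dat,
                   method = "REML", sp = sp)
  new_lifespan_gam(fit, dat, by_sex = TRUE)
}

new_lifespan_gam <- function(fit, dat, by_sex) {
  smry <- summary(fit)
  n <- nrow(dat)
  rss <- sum(stats::residuals(fit)^2)
  edf_total <- sum(fit$edf)
  loglik <- -n / 2 * (log(2 * pi * rss / n) + 1)
  structure(list(
    gam = fit, data = dat, by_sex = by_sex,
    coefficients = stats::coef(fit),
    Vp = fit$Vp,
    lambda = fit$sp,
    edf = edf_total,
    smooth_table = smry$s.table,
    reml_score = fit$gcv.ubre,
    sig2 = fit$sig2,
    fitted = stats::fitted(fit),
    r_squared = smry$r.sq,
    deviance_explained = smry$dev.expl,
    bic = -2 * loglik + log(n) * (edf_total + 1)
  ), class = "lifespan_gam")
}

#' @export
print.lifespan_gam <- function(x, ...) {
  cat(sprintf("<lifespan_gam%s> n = %d, edf = %.2f, lambda = %s\n",
              if (x$by_sex) " by sex" else "", nrow(x$data), x$edf,
              paste(signif(x$lambda, 3), collapse = ", ")))
  cat(sprintf("  R^2 = %.3f, deviance explained = %.1f%%, BIC = %.1f\n",
              x$r_squared, 100 * x$deviance_explained, x$bic))
  invisible(x)
}

#' Posterior simulation of the fitted trend and its first derivative
#'
#' Draws coefficient vectors from the Gaussian posterior N(beta, Vp) implied
#' by the penalized fit (Vp is the Bayesian covariance of the coefficients)
#' and maps each draw through the spline basis evaluated on an age grid,
#' yielding simulated fitted curves; first derivatives are obtained by
#' central finite differences of the basis on the grid (step `h`), which for
#' the cubic spline basis is accurate to O(h^2). A non-positive-definite
#' covariance is repaired by eigenvalue clipping (with a warning).
#'
#' @param fit a [fit_lifespan_gam()] result (age-only model).
#' @param n_draws number of posterior draws.
#' @param step age grid step in years.
#' @param grid optional explicit age grid (overrides `step`).
#' @param h finite-difference half-step in years.
#' @param seed optional integer seed; draws are bit-reproducible under a
#'   fixed seed.
#' @return An object of class `gam_posterior`: `grid`, `fitted_mean`,
#'   `deriv_mean` (point-estimate curves), and matrices `fitted_draws`,
#'   `deriv_draws` (grid x draws).
#' @export
posterior_simulate <- function(fit, n_draws = 10000, step = 0.1, grid = NULL,
                               h = 0.01, seed = NULL) {
  stopifnot(inherits(fit, "lifespan_gam"))
  if (fit$by_sex)
    stop("posterior simulation is implemented for the age-only model")
  if (is.null(grid))
    grid <- seq(min(fit$data$age), max(fit$data$age), by = step)
  gam <- fit$gam
  Xp <- stats::predict(gam, newdata = data.frame(age = grid), type = "lpmatrix")
  Xd <- (stats::predict(gam, newdata = data.frame(age = grid + h),
                        type = "lpmatrix") -
           stats::predict(gam, newdata = data.frame(age = grid - h),
                          type = "lpmatrix")) / (2 * h)
  beta <- fit$coefficients
  V <- fit$Vp
  L <- tryCatch(chol(V), error = function(e) {
    warning("posterior covariance not positive definite; clipping eigenvalues")
    eg <- eigen(V, symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    t(eg$vectors %*% (t(eg$vectors) * sqrt(vals)))
  })
  draw <- function() {
    Z <- matrix(stats::rnorm(length(beta) * n_draws), nrow = length(beta))
    beta + t(L) %*% Z
  }
  B <- if (is.null(seed)) draw() else withr_seed(seed, draw())
  structure(list(grid = grid,
                 fitted_mean = drop(Xp %*% beta),
                 deriv_mean = drop(Xd %*% beta),
                 fitted_draws = Xp %*% B,
                 deriv_draws = Xd %*% B),
            class = "gam_posterior")
}

#' Simultaneous confidence band from posterior draws
#'
#' Critical value = the `level` quantile, across draws, of the maximum over
#' the grid of the standardized absolute deviation |draw - mean| / sd; the
#' band mean +/- crit * sd then has simultaneous coverage `level` over the
#' whole grid by construction. Grid points with degenerate (zero) sd fall
#' back to a zero-width band with a warning.
#'
#' @param draws grid x draws matrix (e.g. `deriv_draws` from
#'   [posterior_simulate()]).
#' @param level coverage level.
#' @param center optional center curve; defaults to the draw mean per grid
#'   point.
#' @return A data.frame with `mean`, `lower`, `upper` and attribute `crit`.
#' @export
simultaneous_interval <- function(draws, level = 0.95, center = NULL) {
  if (ncol(draws) < 2) stop("need at least 2 draws")
  m <- if (is.null(center)) rowMeans(draws) else center
  s <- sqrt(rowMeans((draws - m)^2))
  degenerate <- s == 0
  if (any(degenerate)) {
    warning("degenerate (zero-sd) grid points; zero-width band there")
    s[degenerate] <- Inf   # excluded from the max statistic
  }
  A <- abs(draws - m) / s
  # column maxima via max.col on the transpose (C-level, no per-column loop)
  ti <- max.col(t(A), ties.method = "first")
  dev <- A[cbind(ti, seq_len(ncol(A)))]
  crit <- unname(stats::quantile(dev, level, names = FALSE))
  s[degenerate] <- 0
  out <- data.frame(mean = m, lower = m - crit * s, upper = m + crit * s)
  attr(out, "crit") <- crit
  out
}

#' Pointwise interval from posterior draws
#'
#' Per-grid-point counterpart of [simultaneous_interval()] (the critical
#' value is the `level` quantile of the standardized absolute deviation at
#' that point alone). The simultaneous band always contains the pointwise
#' band at the same level.
#'
#' @inheritParams simultaneous_interval
#' @return A data.frame with `mean`, `lower`, `upper`.
#' @export
pointwise_interval <- function(draws, level = 0.95, center = NULL) {
  m <- if (is.null(center)) rowMeans(draws) else center
  s <- sqrt(rowMeans((draws - m)^2))
  dev <- abs(draws - m) / ifelse(s == 0, Inf, s)
  crit <- apply(dev, 1, function(r) stats::quantile(r, level, names = FALSE))
  data.frame(mean = m, lower = m - crit * s, upper = m + crit * s)
}

#' Significant periods of change
#'
#' Maximal runs of consecutive grid ages where the simultaneous confidence
#' band of the first derivative excludes zero. Each run is reported with its
#' direction (increase/decrease, from the sign of the mean derivative over
#' the run) and labeled developmental when it begins before the boundary
#' age (23 years) and aging otherwise. Runs of a single grid point (below
#' the grid's resolution) are dropped.
#'
#' @param grid age grid.
#' @param band data.frame from [simultaneous_interval()] applied to the
#'   derivative draws.
#' @param boundary_age developmental/aging boundary in years.
#' @return A data.frame with zero or more rows: `start`, `end`, `direction`,
#'   `label`.
#' @export
significant_periods <- function(grid, band, boundary_age = 23) {
  mask <- band$lower > 0 | band$upper < 0
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L
  if (!any(keep))
    return(data.frame(start = numeric(0), end = numeric(0),
                      direction = character(0), label = character(0),
                      stringsAsFactors = FALSE))
  i0 <- starts[keep]; i1 <- ends[keep]
  direction <- vapply(seq_along(i0), function(j)
    if (mean(band$mean[i0[j]:i1[j]]) > 0) "increase" else "decrease",
    character(1))
  start <- grid[i0]
  data.frame(start = start, end = grid[i1], direction = direction,
             label = ifelse(start < boundary_age, "developmental", "aging"),
             stringsAsFactors = FALSE)
}

#' Change-point analysis of one measure
#'
#' Convenience wrapper: fit the age-only GAM, simulate the posterior,
#' build the simultaneous band of the first derivative, and extract the
#' significant periods of change.
#'
#' @inheritParams fit_lifespan_gam
#' @inheritParams posterior_simulate
#' @param level band coverage level.
#' @param boundary_age developmental/aging boundary.
#' @return A list: `fit`, `posterior`, `band` (derivative band), `periods`.
#' @export
change_point_analysis <- function(age, y, k = 20, bs = "cr",
                                  n_draws = 10000, step = 0.1,
                                  level = 0.95, boundary_age = 23,
                                  seed = NULL) {
  fit <- fit_lifespan_gam(age, y, k = k, bs = bs)
  post <- posterior_simulate(fit, n_draws = n_draws, step = step, seed = seed)
  band <- simultaneous_interval(post$deriv_draws, level = level,
                                center = post$deriv_mean)
  periods <- significant_periods(post$grid, band, boundary_age)
  list(fit = fit, posterior = post, band = band, periods = periods)
}

#' Percentile growth curves
#'
#' Builds a family of percentile-vs-age curves ("cognitive growth curve")
#' for a measure: the GAM mean fit evaluated on the grid plus empirical
#' quantiles of the fit residuals in a sliding age window. Quantiles at each
#' age come from one residual sample, so the family is non-decreasing in
#' percentile at every age by construction.
#'
#' @param fit a [fit_lifespan_gam()] result.
#' @param percentiles percentiles in (0, 100).
#' @param step grid step in years.
#' @param window sliding age-window width in years.
#' @return A data.frame with `age` and one column `p<q>` per percentile.
#' @export
percentile_curves <- function(fit, percentiles = c(5, 10, 25, 50, 75, 90, 95),
                              step = 0.1, window = 10) {
  stopifnot(inherits(fit, "lifespan_gam"))
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must lie strictly between 0 and 100")
  if (nrow(fit$data) < 200)
    warning("fewer than 200 observations; extreme percentile curves are unstable")
  age <- fit$data$age
  resid <- fit$data$y - fit$fitted
  grid <- seq(min(age), max(age), by = step)
  mu <- drop(stats::predict(fit$gam, newdata = data.frame(age = grid)))
  half <- window / 2
  qmat <- t(vapply(grid, function(a) {
    r <- resid[abs(age - a) <= half]
    stats::quantile(r, percentiles / 100, names = FALSE)
  }, numeric(length(percentiles))))
  out <- data.frame(age = grid)
  for (j in seq_along(percentiles))
    out[[paste0("p", percentiles[j])]] <- mu + qmat[, j]
  out
}

#' Standardized residuals of a lifespan GAM
#'
#' (y - fitted) / sigma, with sigma the REML residual scale estimate; used
#' to control for age before correlating measures.
#'
#' @param fit a [fit_lifespan_gam()] result.
#' @param y response; defaults to the fitted data.
#' @return Numeric vector of standardized residuals.
#' @export
standardized_residuals <- function(fit, y = fit$data$y) {
  scale <- sqrt(fit$sig2)
  if (!is.finite(scale) || scale <= 0) stop("degenerate residual scale")
  (y - fit$fitted) / scale
}
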