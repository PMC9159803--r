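# Independent oracles and small fixture builders shared across tests.

# Brute-force saccade-run oracle: enumerate every maximal run of consecutive
# supra-threshold samples by direct scanning, then filter by length.
oracle_runs <- function(speed, threshold, min_samples) {
  above <- !is.na(speed) & speed > threshold
  runs <- list()
  i <- 1L
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_samples) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

# Spearman's rho by definition: Pearson correlation of average ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# Empirical CDF oracle at given grid points.
oracle_cumulative <- function(srts, denom, grid) {
  vapply(grid, function(t) sum(srts <= t), numeric(1)) / denom
}

# Brute-force smoothed-difference VOT oracle over all 1 ms bins.
oracle_vot <- function(correct, error, viable, window = c(90, 400)) {
  grid <- 90:800
  d <- oracle_cumulative(correct, viable, grid) -
    oracle_cumulative(error, viable, grid)
  sm <- signif(vapply(seq_along(grid), function(i) {
    idx <- max(1, i - 3):min(length(grid), i + 3)
    mean(d[idx])
  }, numeric(1)), 9)
  ok <- grid >= window[1] & grid <= window[2]
  grid[ok][which.min(sm[ok])]
}

# A flat trace with optional rectangular speed bumps, for detection tests.
# `bumps` is a list of c(start_index, n_samples, step_deg_per_sample).
flat_trace <- function(n = 1100, dt = 2, bumps = list(), noise_sd = 0,
                       t_start = -1200) {
  time <- seq(t_start, by = dt, length.out = n)
  x <- stats::rnorm(n, 0, noise_sd)
  for (b in bumps) {
    idx <- seq(b[1], length.out = b[2])
    x[idx[1]:n] <- x[idx[1]:n] + cumsum(c(rep(b[3], b[2]),
                                          rep(0, n - idx[1] + 1 - b[2])))[seq_len(n - idx[1] + 1)]
  }
  gaze_trace(time, x, rep(0, n),
             events = list(fp_on = -1200, fp_off = -200, stim_on = 0,
                           stim_off = 1000),
             condition = "pro", side = "right")
}

# Quick per-condition counts row set for QC tests.
qc_counts <- function(pro_viable = 100, anti_viable = 100,
                      pro_eyeloss = 2, anti_eyeloss = 2,
                      pro_noncomp = 5, anti_noncomp = 5,
                      anti_correct = 80) {
  data.frame(
    condition = c("pro", "anti"),
    viable = c(pro_viable, anti_viable),
    eye_loss = c(pro_eyeloss, anti_eyeloss),
    noncompliance = c(pro_noncomp, anti_noncomp),
    viable_correct_express = c(0, 0),
    viable_correct_regular = c(pro_viable, anti_correct),
    stringsAsFactors = FALSE
  )
}

# Single-saccade event row for classification tests.
event_row <- function(onset, dx = 10, start_x = 0, dy = 0) {
  data.frame(onset_ms = onset, offset_ms = onset + 50,
             start_x = start_x, start_y = 0,
             end_x = start_x + dx, end_y = dy,
             amplitude = sqrt(dx^2 + dy^2), peak_speed = 300)
}
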