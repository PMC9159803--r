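MEASURE_COLUMNS <- c("pro_srt", "anti_srt",
                     "pro_express_ratio", "pro_regular_ratio",
                     "anti_express_error_ratio", "anti_regular_error_ratio",
                     "vot")
RATIO_COLUMNS <- c("pro_express_ratio", "pro_regular_ratio",
                   "anti_express_error_ratio", "anti_regular_error_ratio")

#' Lifespan analysis of the seven IPAST measures
#'
#' Runs the full modeling stage on a QC-passed measures table: per measure,
#' the ratio variables are empirical-logit transformed (using each
#' participant's viable count in the relevant condition as the squeeze
#' denominator), an age-only GAM is fitted, the posterior-simulation
#' change-point analysis is run, and an age-by-sex model is fitted for BIC
#' comparison; finally age-controlled Spearman correlations between the
#' measures' standardized residuals are computed.
#'
#' @param measures an `ipast_measures` data.frame from [cohort_measures()]
#'   (or any data.frame with the seven measure columns, `age`, `sex`,
#'   `pro_viable`, `anti_viable`, and optionally `included`).
#' @param k basis dimension for the age smooth.
#' @param n_draws posterior draws per measure.
#' @param step age grid step in years.
#' @param boundary_age developmental/aging boundary.
#' @param seed integer seed for the posterior draws.
#' @return A list of class `ipast_analysis`: `measures` (the analyzed rows),
#'   `fits` (named list of change-point analyses per measure), `fit_table`
#'   (per-measure ref_df, F, p, R^2, deviance explained, BIC age-only and
#'   by-sex), `periods` (stacked significant periods), `correlations`, and
#'   `percentiles` (growth-curve table for VOT).
#' @export
analyze_lifespan <- function(measures, k = 20, n_draws = 10000, step = 0.1,
                             boundary_age = 23, seed = 1L) {
  dat <- as.data.frame(measures)
  if ("included" %in% names(dat)) dat <- dat[dat$included, ]
  dat <- dat[stats::complete.cases(dat[MEASURE_COLUMNS]), ]

  fits <- list()
  fit_rows <- list()
  period_rows <- list()
  resid_tab <- data.frame(row.names = seq_len(nrow(dat)))
  for (mi in seq_along(MEASURE_COLUMNS)) {
    mname <- MEASURE_COLUMNS[mi]
    y <- dat[[mname]]
    if (mname %in% RATIO_COLUMNS) {
      denom <- if (startsWith(mname, "pro")) dat$pro_viable else dat$anti_viable
      y <- logit_transform(y, denom)
    }
    cpa <- change_point_analysis(dat$age, y, k = k, n_draws = n_draws,
                                 step = step, boundary_age = boundary_age,
                                 seed = seed + mi)
    by_sex <- fit_lifespan_gam_by_sex(dat$age, y, dat$sex, k = k)
    fits[[mname]] <- cpa
    st <- cpa$fit$smooth_table
    fit_rows[[mname]] <- data.frame(
      measure = mname,
      ref_df = st[1, "Ref.df"], f_statistic = st[1, "F"],
      p_value = st[1, "p-value"],
      r_squared = cpa$fit$r_squared,
      deviance_explained = cpa$fit$deviance_explained,
      bic_age = cpa$fit$bic, bic_age_by_sex = by_sex$bic,
      stringsAsFactors = FALSE)
    if (nrow(cpa$periods) > 0)
      period_rows[[mname]] <- cbind(measure = mname, cpa$periods)
    resid_tab[[mname]] <- standardized_residuals(cpa$fit, y)
  }
  correlations <- spearman_matrix(resid_tab)
  percentiles <- percentile_curves(fits[["vot"]]$fit, step = step)

  structure(list(
    measures = dat,
    fits = fits,
    fit_table = do.call(rbind, fit_rows),
    periods = if (length(period_rows)) do.call(rbind, period_rows)
              else data.frame(),
    residuals = resid_tab,
    correlations = correlations,
    percentiles = percentiles
  ), class = "ipast_analysis")
}

#' Write the analysis outputs to disk
#'
#' Writes the tidy per-participant measures CSV, the per-measure fit-summary
#' CSV, the change-period table CSV, the percentile growth-curve CSV, the
#' correlation matrix CSV, and a JSON report bundling cohort demographics
#' (age histogram in 3-5-year bins: 3-year bins before age 20, 5-year bins
#' after), the QC summary, fit summaries and change periods.
#'
#' @param analysis an `ipast_analysis` from [analyze_lifespan()].
#' @param dir output directory (created if needed).
#' @param qc_summary optional result of [summarize_exclusions()].
#' @return The directory path, invisibly.
#' @export
write_analysis <- function(analysis, dir, qc_summary = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(analysis$measures, "measures.csv")
  w(analysis$fit_table, "fit_summary.csv")
  w(analysis$periods, "change_periods.csv")
  w(analysis$percentiles, "percentile_curves.csv")
  utils::write.csv(analysis$correlations$rho, file.path(dir, "correlations.csv"))

  age <- analysis$measures$age
  breaks <- c(seq(5, 20, by = 3), seq(25, 95, by = 5))
  hist_counts <- table(cut(age, breaks, right = FALSE))
  report <- list(
    n_participants = nrow(analysis$measures),
    age_range = range(age),
    age_histogram = list(breaks = breaks,
                         counts = as.integer(hist_counts)),
    sex_counts = as.list(table(analysis$measures$sex)),
    qc = qc_summary,
    fit_summary = analysis$fit_table,
    change_periods = analysis$periods
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
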