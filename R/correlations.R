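#' Age-controlled Spearman correlation matrix
#'
#' Pairwise Spearman rank correlations between measures (typically the
#' standardized GAM residuals, so that age is controlled), with average
#' ranks for ties, two-sided p-values (exact null distribution for n <= 30
#' without ties, t-approximation otherwise), and a significance mask at the
#' display threshold. A constant column yields NA for its pairs and a
#' warning.
#'
#' @param residuals data.frame or matrix, one column per measure, rows
#'   aligned on participants (complete cases required, >= 10 rows).
#' @param alpha display threshold for the significance mask.
#' @param p_adjust multiplicity adjustment passed to [stats::p.adjust()]
#'   (`"none"` by default, mirroring an unadjusted p < alpha display rule;
#'   `"holm"` available).
#' @return An object of class `ipast_correlations`: list with matrices
#'   `rho`, `p`, `significant` (logical mask with NA diagonal untouched).
#' @export
spearman_matrix <- function(residuals, alpha = 0.05, p_adjust = "none") {
  x <- as.data.frame(residuals)
  if (anyNA(x)) stop("complete cases required")
  if (nrow(x) < 10) stop("need at least 10 complete rows")
  m <- ncol(x)
  rho <- matrix(NA_real_, m, m, dimnames = list(names(x), names(x)))
  pval <- rho
  diag(rho) <- 1
  diag(pval) <- 0
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      if (stats::sd(x[[i]]) == 0 || stats::sd(x[[j]]) == 0) {
        warning("constant column; correlation undefined for ",
                names(x)[i], " / ", names(x)[j])
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[[i]], x[[j]], method = "spearman",
                        exact = nrow(x) <= 30))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pval[i, j] <- pval[j, i] <- ct$p.value
    }
  }
  if (p_adjust != "none") {
    up <- upper.tri(pval)
    pval[up] <- stats::p.adjust(pval[up], method = p_adjust)
    pval[lower.tri(pval)] <- t(pval)[lower.tri(pval)]
  }
  structure(list(rho = rho, p = pval,
                 significant = !is.na(pval) & pval < alpha & row(pval) != col(pval)),
            class = "ipast_correlations")
}

#' @export
print.ipast_correlations <- function(x, digits = 2, ...) {
  cat("<ipast_correlations>\n")
  shown <- ifelse(x$significant | row(x$rho) == col(x$rho),
                  format(round(x$rho, digits)), ".")
  dimnames(shown) <- dimnames(x$rho)
  print(shown, quote = FALSE)
  invisible(x)
}
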