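#' Chi-square goodness-of-fit test for a Mendelian segregation ratio
#'
#' Tests observed phenotype class counts against expected Mendelian
#' proportions (e.g. 3:1 for a monogenic recessive trait in an F2).
#' For one degree of freedom the Yates continuity correction is applied
#' by default: each \eqn{|O_i - E_i|} is reduced by 0.5 and clamped at
#' zero before squaring, so a perfect fit scores exactly 0 and the
#' statistic is never inflated by the discreteness of small counts.
#'
#' @param observed Integer vector of observed class counts (all >= 0,
#'   total > 0).
#' @param ratio Expected ratio of the classes, e.g. `c(3, 1)`; rescaled
#'   internally to proportions.
#' @param continuity_correction Apply the Yates correction? Default `NULL`
#'   means on when `df = 1`, off otherwise.
#' @param alpha Significance level for the critical value (default 0.05).
#' @return An object of class `segregation_test`: a list with `observed`,
#'   `expected`, `ratio`, `chi2`, `df`, `p_value`, `alpha`, `critical`,
#'   `continuity_correction` and `consistent` (`chi2 <= critical`, i.e.
#'   the counts are compatible with the ratio at level `alpha`).
#' @examples
#' chi_square_ratio(c(237, 70), c(3, 1))
#' @export
chi_square_ratio <- function(observed, ratio, continuity_correction = NULL,
                             alpha = 0.05) {
  observed <- as.numeric(observed)
  ratio <- as.numeric(ratio)
  if (length(observed) != length(ratio) || length(observed) < 2) {
    stop("`observed` and `ratio` must have equal length >= 2")
  }
  if (any(observed < 0) || any(!is.finite(observed))) {
    stop("all observed counts must be finite and >= 0")
  }
  total <- sum(observed)
  if (total <= 0) stop("total observed count must be > 0")
  if (any(ratio < 0) || sum(ratio) <= 0) {
    stop("`ratio` must be non-negative with positive sum")
  }
  p <- ratio / sum(ratio)
  expected <- total * p
  if (any(expected == 0)) stop("expected count of zero in some class")
  df <- length(observed) - 1L
  if (is.null(continuity_correction)) continuity_correction <- df == 1L
  dev <- abs(observed - expected)
  if (continuity_correction) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  critical <- critical_value(df, alpha)
  structure(
    list(
      observed = observed,
      expected = expected,
      ratio = ratio,
      chi2 = chi2,
      df = df,
      p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
      alpha = alpha,
      critical = critical,
      continuity_correction = continuity_correction,
      consistent = chi2 <= critical
    ),
    class = "segregation_test"
  )
}

#' Upper critical value of the chi-square distribution
#'
#' @param df Degrees of freedom (integer >= 1).
#' @param alpha Upper tail probability, in (0, 1).
#' @return The upper-`alpha` quantile of the chi-square distribution
#'   with `df` degrees of freedom (3.84 for `df = 1`, `alpha = 0.05`).
#' @export
critical_value <- function(df, alpha) {
  if (length(df) != 1 || !is.finite(df) || df < 1 || df != round(df)) {
    stop("`df` must be a single integer >= 1")
  }
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single probability in (0, 1)")
  }
  stats::qchisq(alpha, df = df, lower.tail = FALSE)
}

#' @export
print.segregation_test <- function(x, ...) {
  cat("Segregation chi-square test\n")
  cat("  observed:", paste(x$observed, collapse = " : "), "\n")
  cat("  expected ratio:", paste(x$ratio, collapse = " : "), "\n")
  cat(sprintf("  chi2 = %.4f (df = %d%s), critical value at alpha = %g: %.4f\n",
              x$chi2, x$df,
              if (x$continuity_correction) ", Yates-corrected" else "",
              x$alpha, x$critical))
  cat(sprintf("  p = %.4g -> %s with the %s ratio\n", x$p_value,
              if (x$consistent) "consistent" else "inconsistent",
              paste(x$ratio, collapse = ":")))
  invisible(x)
}
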