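#' Welch's unpaired two-sample t-test
#'
#' The unpaired t-test with Welch's correction for unequal variances:
#' `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p-value from the
#' t distribution. Degenerate inputs are handled explicitly: both samples
#' constant with equal means gives t = 0, p = 1; constant samples with
#' unequal means report the smallest representable p with a flag.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return An object of class `welch_test`: `t_statistic`, `df`,
#'   `p_two_tailed`, `mean_a`, `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`,
#'   `degenerate` flag.
#' @export
welch_test <- function(sample_a, sample_b) {
  sample_a <- as.numeric(sample_a)
  sample_b <- as.numeric(sample_b)
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop_spatsig("both samples need at least 2 observations")
  }
  if (!all(is.finite(sample_a)) || !all(is.finite(sample_b))) {
    stop_spatsig("samples must be finite")
  }
  n_a <- length(sample_a); n_b <- length(sample_b)
  m_a <- mean(sample_a); m_b <- mean(sample_b)
  v_a <- stats::var(sample_a); v_b <- stats::var(sample_b)
  se2 <- v_a / n_a + v_b / n_b
  degenerate <- FALSE
  if (se2 == 0) {
    if (m_a == m_b) {
      t_stat <- 0; df <- n_a + n_b - 2; p <- 1
    } else {
      t_stat <- sign(m_a - m_b) * Inf
      df <- n_a + n_b - 2
      p <- .Machine$double.xmin
      degenerate <- TRUE
    }
  } else {
    t_stat <- (m_a - m_b) / sqrt(se2)
    df <- se2^2 / ((v_a / n_a)^2 / (n_a - 1) + (v_b / n_b)^2 / (n_b - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(
    list(t_statistic = t_stat, df = df, p_two_tailed = p,
         mean_a = m_a, mean_b = m_b, sd_a = sqrt(v_a), sd_b = sqrt(v_b),
         n_a = n_a, n_b = n_b, degenerate = degenerate),
    class = "welch_test"
  )
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t-test: t = %.4g, df = %.2f, p = %.4g\n",
              x$t_statistic, x$df, x$p_two_tailed))
  cat(sprintf("  group A: mean %.4g (sd %.4g, n %d); group B: mean %.4g (sd %.4g, n %d)\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  invisible(x)
}

#' Spearman rank correlation with a two-tailed p-value
#'
#' Average ranks are assigned to ties; rho is the Pearson correlation of the
#' ranks and the two-tailed p-value comes from the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return A list with `rho`, `p`, `n`; `rho` is `NA` (flagged via
#'   `degenerate = TRUE`) when either variable has zero rank variance.
#' @export
spearman_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_spatsig("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 4L) stop_spatsig("need at least 4 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop_spatsig("values must be finite")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), n - 2)
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}
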