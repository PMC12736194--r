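#' Pearson correlation with two-sided significance
#'
#' Standard product-moment correlation; the p-value comes from the
#' t-transform `t = r sqrt((n-2)/(1-r^2))` with n - 2 degrees of freedom
#' (delegated to [stats::cor.test()]).  Used to relate docking binding
#' energies Eb to graded inhibition endpoints.  The p-value is returned at
#' full precision; truncation such as "p < 0.0001" belongs in report text
#' only.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, each with nonzero
#'   variance.
#' @return An object of class `correlation_result`: list with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  ptxt <- if (x$p < 1e-4) sprintf("p < 0.0001 (p = %.3g)", x$p)
          else sprintf("p = %.4f", x$p)
  cat(sprintf("Pearson r = %.3f, %s, n = %d\n", x$r, ptxt, x$n))
  invisible(x)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' `K^2 = Z(g1)^2 + Z(g2)^2`, combining D'Agostino's z-approximation for
#' sample skewness with the Anscombe-Glynn z-approximation for sample
#' kurtosis; under normality K^2 is approximately chi-square with 2 df.
#' The moment z-approximations are unreliable in small samples, so inputs
#' below n = 20 are rejected.
#'
#' @param x Numeric vector, n >= 20.
#' @return List with `k2`, `p`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (anyNA(x)) stop("missing values are not allowed")
  if (n < 20L)
    stop("the D'Agostino-Pearson test requires at least n = 20 (got ", n, ")")
  if (stats::sd(x) == 0) stop("zero variance; normality test undefined")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # D'Agostino (1970) transformed skewness
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * asinh(y / alpha)
  # Anscombe-Glynn (1983) transformed kurtosis
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
               ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z_skew^2 + z_kurt^2
  list(k2 = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

#' Compare two dependent overlapping correlations (Steiger's z)
#'
#' Tests whether two correlations that share one variable — e.g. inhibition
#' correlated with monomer binding energies (`r1`) versus dimer binding
#' energies (`r2`), with `r12` the correlation between the two energy sets —
#' differ significantly.  Steiger's (1980) modification of Dunn-Clark's z is
#' used: Fisher-transformed correlations compared with a covariance term
#' built from the mean correlation.  Antisymmetric: swapping `r1` and `r2`
#' flips the sign of z and leaves p unchanged.
#'
#' @param r1,r2 The two correlations sharing a variable, each in (-1, 1).
#' @param r12 Correlation between the two non-shared variables, in (-1, 1).
#' @param n Sample size (>= 4).
#' @return List with `z`, `p` (two-sided), `n`.
#' @export
compare_dependent_r <- function(r1, r2, r12, n) {
  for (r in c(r1, r2, r12))
    if (!is.finite(r) || abs(r) >= 1)
      stop("correlations must lie strictly inside (-1, 1)")
  if (n < 4L) stop("need n >= 4")
  rbar <- (r1 + r2) / 2
  psi <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)
  s <- psi / (1 - rbar^2)^2
  z <- (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 - 2 * s))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Mean and standard error of the mean
#'
#' @param values Numeric vector (n >= 1; the SEM needs n >= 2 and is
#'   reported as `NA` for a single value).
#' @return List with `mean`, `sem` (sample sd / sqrt(n)) and `n`, of class
#'   `summary_stat`.
#' @examples
#' mean_sem(c(1, 2, 3))  # mean 2, sem 0.5774
#' @export
mean_sem <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty input")
  if (anyNA(values)) stop("missing values are not allowed")
  n <- length(values)
  structure(list(mean = mean(values),
                 sem = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_,
                 n = n),
            class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf("%.4g +/- %.4g (mean +/- SEM, n = %d)\n", x$mean, x$sem, x$n))
  invisible(x)
}
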