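# Descriptive statistics and the multivariate prerequisites checked before
# factor analysis: Spearman correlations, Shapiro-Wilk normality,
# Kaiser-Meyer-Olkin sampling adequacy and Bartlett's test of sphericity.

#' Adjusted Fisher-Pearson sample skewness
#'
#' The bias-adjusted form `g1 * sqrt(n(n-1))/(n-2)` with
#' `g1 = m3 / m2^(3/2)`, the convention used by mainstream statistics
#' software.
#'
#' @param x Numeric vector, `length(x) >= 3`.
#' @return Skewness (dimensionless); 0 for a constant vector.
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3) stop_soiltrace("insufficient samples for skewness (n >= 3)")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Per-element summary statistics
#'
#' Mean, median, sd (n-1 denominator), standard error `sd/sqrt(n)`,
#' coefficient of variation `100*sd/mean` (%), adjusted Fisher-Pearson
#' skewness, minimum and maximum, per element.
#'
#' @param table A `sample_table`.
#' @return Data frame of class `te_summary`, one row per element, with an
#'   `n` attribute. A constant column reports sd, cv and skewness of 0
#'   with a warning.
#' @export
#' @examples
#' tab <- emulate_study(seed = 1)
#' summarize_te(tab)
summarize_te <- function(table) {
  m <- te_matrix(table)
  n <- nrow(m)
  if (n < 3) stop_soiltrace("insufficient samples for skewness (n >= 3)")
  out <- data.frame(
    element = colnames(m),
    mean = colMeans(m),
    median = apply(m, 2, median),
    sd = apply(m, 2, sd),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (any(out$sd == 0)) {
    warning("degenerate data: constant element column(s): ",
            paste(out$element[out$sd == 0], collapse = ", "))
  }
  out$se <- out$sd / sqrt(n)
  out$cv_percent <- 100 * out$sd / out$mean
  out$skewness <- apply(m, 2, sample_skewness)
  out$min <- apply(m, 2, min)
  out$max <- apply(m, 2, max)
  attr(out, "n") <- n
  class(out) <- c("te_summary", "data.frame")
  out
}

#' Spearman correlation matrix
#'
#' Rank-based (mid-rank ties) correlation with two-sided p-values from the
#' t approximation `t = r*sqrt((n-2)/(1-r^2))`.
#'
#' @param table A `sample_table` with `n >= 4`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A `te_cor` list: `method`, symmetric `r` and `p` matrices with
#'   unit/zero diagonal, and `n`. Pairs involving a constant column are
#'   `NA`.
#' @export
spearman_matrix <- function(table, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- te_matrix(table)
  n <- nrow(m)
  if (n < 4) stop_soiltrace("need n >= 4 for correlation tests")
  constant <- apply(m, 2, function(v) sd(v) == 0)
  r <- suppressWarnings(cor(m, method = method))
  r[constant, ] <- NA
  r[, constant] <- NA
  diag(r) <- ifelse(constant, NA, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- ifelse(constant, NA, 0)
  structure(list(method = method, r = r, p = p, n = n), class = "te_cor")
}

#' Shapiro-Wilk normality flags
#'
#' @param table A `sample_table` with `3 <= n <= 5000`.
#' @param alpha Significance level; an element is flagged normal when the
#'   Shapiro-Wilk p-value exceeds it.
#' @return Data frame with `element`, `W`, `p_value`, `normal`.
#' @export
normality_flags <- function(table, alpha = 0.05) {
  m <- te_matrix(table)
  n <- nrow(m)
  if (n < 3 || n > 5000) stop_soiltrace("Shapiro-Wilk requires 3 <= n <= 5000")
  if (alpha <= 0 || alpha >= 1) stop_soiltrace("alpha must be in (0, 1)")
  res <- apply(m, 2, function(v) {
    sw <- shapiro.test(v)
    c(sw$statistic, sw$p.value)
  })
  data.frame(
    element = colnames(m),
    W = res[1, ],
    p_value = res[2, ],
    normal = res[2, ] > alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO: `sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal
#' entries, where `q` are the partial correlations obtained from the
#' scaled inverse of the correlation matrix.
#'
#' @param corr A `te_cor` object or a correlation matrix.
#' @param floor_r2 Degeneracy floor: below this total off-diagonal squared
#'   correlation the statistic is undefined.
#' @return KMO in `[0, 1]`.
#' @export
kmo_statistic <- function(corr, floor_r2 = 1e-10) {
  R <- if (inherits(corr, "te_cor")) corr$r else as.matrix(corr)
  if (any(!is.finite(R))) stop_soiltrace("KMO undefined: missing correlations")
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv)) stop_soiltrace("KMO undefined: singular correlation matrix")
  d <- 1 / sqrt(diag(inv))
  partial <- -inv * tcrossprod(d)
  off <- upper.tri(R)
  r2 <- sum(R[off]^2)
  q2 <- sum(partial[off]^2)
  if (r2 < floor_r2) stop_soiltrace("KMO undefined: correlations all ~ 0")
  r2 / (r2 + q2)
}

#' Bartlett's test of sphericity
#'
#' Tests the null hypothesis that the correlation matrix is the identity:
#' `chi2 = -(n - 1 - (2m + 5)/6) * log(det(R))` on `m(m-1)/2` degrees of
#' freedom.
#'
#' @param corr A `te_cor` object or a correlation matrix.
#' @param n Number of samples (taken from a `te_cor` if absent); must
#'   exceed the number of variables.
#' @return List with `chisq`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(corr, n = NULL) {
  R <- if (inherits(corr, "te_cor")) corr$r else as.matrix(corr)
  if (is.null(n) && inherits(corr, "te_cor")) n <- corr$n
  if (is.null(n)) stop_soiltrace("n is required")
  m <- ncol(R)
  if (n <= m) stop_soiltrace("need n > number of elements")
  detR <- det(R)
  if (!is.finite(detR) || detR <= 0) {
    stop_soiltrace("correlation matrix is not positive definite")
  }
  chisq <- -(n - 1 - (2 * m + 5) / 6) * log(detR)
  df <- m * (m - 1) / 2
  list(chisq = chisq, df = df, p_value = pchisq(chisq, df, lower.tail = FALSE))
}
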