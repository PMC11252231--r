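# APCS-MLR receptor model.
#
# Pipeline: standardize -> correlation-matrix PCA -> Kaiser retention
# (eigenvalue > 1) -> varimax rotation -> regression-method factor scores
# (exact zero mean, unit variance) -> absolute scores (APCS) by
# subtracting the score of the artificial all-zero-concentration sample
# -> per-element OLS of concentration on APCS -> contribution
# percentages by absolute-value normalization over retained components.

#' Correlation-matrix PCA with varimax rotation and Kaiser retention
#'
#' Warns (does not stop) when the factor-analysis prerequisites look
#' weak: KMO < 0.5, Bartlett sphericity p >= 0.05 or n < m + 50.
#'
#' @param table A `sample_table`.
#' @param kaiser Eigenvalue retention threshold (components with
#'   eigenvalue above it are kept).
#' @param eps Varimax convergence tolerance.
#' @return A `pca_varimax` list: `loadings` (rotated, sign-fixed so each
#'   component's largest-magnitude loading is positive, ordered by
#'   explained variance), `eigenvalues` (all, unrotated),
#'   `variance_explained` (% per retained component, after rotation),
#'   `scores` (regression-method, zero mean and unit variance),
#'   `weights` (score coefficient matrix), `means`, `sds`, `n`.
#' @export
fit_pca_varimax <- function(table, kaiser = 1, eps = 1e-12) {
  m <- te_matrix(table)
  n <- nrow(m); p <- ncol(m)
  if (n < 3 || p < 2) stop_soiltrace("need >= 3 sites and >= 2 elements")
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  if (any(sdv == 0)) stop_soiltrace("constant element column")
  Z <- scale(m)
  R <- cor(m)
  kmo <- tryCatch(kmo_statistic(R), error = function(e) NA_real_)
  if (is.finite(kmo) && kmo < 0.5) {
    warning(sprintf("KMO = %.3f < 0.5: weak sampling adequacy", kmo))
  }
  bart <- tryCatch(bartlett_sphericity(R, n), error = function(e) NULL)
  if (!is.null(bart) && bart$p_value >= 0.05) {
    warning("Bartlett sphericity not rejected: correlations may be too weak")
  }
  if (n < p + 50) {
    warning(sprintf("n = %d < m + 50 = %d: below the model's applicability rule",
                    n, p + 50))
  }
  e <- eigen(R, symmetric = TRUE)
  k <- sum(e$values > kaiser)
  if (k < 1) stop_soiltrace("no component with eigenvalue > %g", kaiser)
  A <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  if (k > 1) {
    rot <- varimax(A, normalize = TRUE, eps = eps)
    L <- A %*% rot$rotmat
  } else {
    L <- A
  }
  # sign convention: largest-|loading| element loads positively
  for (h in seq_len(k)) {
    if (L[which.max(abs(L[, h])), h] < 0) L[, h] <- -L[, h]
  }
  ssl <- colSums(L^2)
  ord <- order(ssl, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  ssl <- ssl[ord]
  dimnames(L) <- list(colnames(m), paste0("PC", seq_len(k)))
  W <- solve(R, L)                 # regression-method score coefficients
  S <- Z %*% W
  colnames(S) <- colnames(L)
  structure(
    list(loadings = L, eigenvalues = e$values,
         variance_explained = 100 * ssl / p,
         scores = S, weights = W, means = mu, sds = sdv, n = n,
         kmo = kmo, bartlett = bart),
    class = "pca_varimax"
  )
}

#' Absolute principal component scores
#'
#' Subtracts from every site's factor score the score of the artificial
#' sample whose raw concentrations are all zero (standardized values
#' `-mean/sd`), turning relative scores into absolute source activities.
#'
#' @param fit A `pca_varimax` fit.
#' @return Matrix `site x component` of APCS values.
#' @export
absolute_scores <- function(fit) {
  stopifnot(inherits(fit, "pca_varimax"))
  z0 <- -fit$means / fit$sds
  s0 <- drop(z0 %*% fit$weights)
  sweep(fit$scores, 2, s0)
}

#' OLS of one element on the APCS
#'
#' Ordinary least squares with intercept. The intercept identity makes
#' the predicted mean equal the measured mean exactly (M/P = 1).
#'
#' @param conc Numeric concentration column.
#' @param apcs APCS matrix from [absolute_scores()].
#' @return List with `b0` (intercept), `coef` (slopes per component),
#'   `r2`, `fitted`.
#' @export
regress_element <- function(conc, apcs) {
  n <- length(conc)
  if (n != nrow(apcs)) stop_soiltrace("length mismatch")
  if (n <= ncol(apcs) + 1) stop_soiltrace("n must exceed components + 1")
  X <- cbind(`(Intercept)` = 1, apcs)
  if (qr(X)$rank < ncol(X)) stop_soiltrace("degenerate regressors")
  fit <- lm.fit(X, conc)
  fitted <- drop(X %*% fit$coefficients)
  tss <- sum((conc - mean(conc))^2)
  r2 <- if (tss > 0) 1 - sum((conc - fitted)^2) / tss else NA_real_
  list(b0 = fit$coefficients[[1]], coef = fit$coefficients[-1],
       r2 = r2, fitted = fitted)
}

#' Source contribution percentages for one element
#'
#' The raw mean contribution of component h is `coef_h * mean(APCS_h)`;
#' percentages take absolute values normalized over the retained
#' components (intercept excluded), so each element's row sums to 100.
#'
#' @param coef Slope vector from [regress_element()].
#' @param apcs APCS matrix.
#' @return Named percentage vector summing to 100.
#' @export
source_contributions <- function(coef, apcs) {
  raw <- coef * colMeans(apcs)
  tot <- sum(abs(raw))
  if (tot == 0) stop_soiltrace("all-zero raw contributions")
  100 * abs(raw) / tot
}

#' Mean source contributions over elements
#'
#' @param contribution_pct Matrix `element x component` of percentages.
#' @return Unweighted column means (percentages summing to 100).
#' @export
mean_source_contributions <- function(contribution_pct) {
  colMeans(contribution_pct)
}

#' Fit the APCS-MLR receptor model
#'
#' Runs the full chain on a sample table and assembles the
#' model-adequacy diagnostics (M/P ratio and R-squared per element) and
#' the source contribution table.
#'
#' @inheritParams fit_pca_varimax
#' @return An `apcs_mlr` object: the `pca_varimax` fit (`pca`), `apcs`
#'   matrix, per-element coefficients `b0`/`coef`, `r2`, `summary` data
#'   frame (measured mean, predicted mean, M/P, R2, contributions),
#'   `contribution_pct` (element x component),
#'   `mean_contribution_pct` (per component) and `k`.
#' @export
#' @examples
#' g <- generate_mixing(seed = 1)
#' fit <- apcs_mlr(g$table)
#' fit$summary
apcs_mlr <- function(table, kaiser = 1, eps = 1e-12) {
  m <- te_matrix(table)
  pca <- fit_pca_varimax(table, kaiser = kaiser, eps = eps)
  apcs <- absolute_scores(pca)
  k <- ncol(apcs)
  els <- colnames(m)
  contribution <- matrix(NA_real_, length(els), k,
                         dimnames = list(els, colnames(apcs)))
  b0 <- setNames(numeric(length(els)), els)
  coefs <- matrix(NA_real_, length(els), k,
                  dimnames = list(els, colnames(apcs)))
  r2 <- setNames(numeric(length(els)), els)
  predicted_mean <- setNames(numeric(length(els)), els)
  for (el in els) {
    reg <- regress_element(m[, el], apcs)
    b0[el] <- reg$b0
    coefs[el, ] <- reg$coef
    r2[el] <- reg$r2
    predicted_mean[el] <- mean(reg$fitted)
    contribution[el, ] <- source_contributions(reg$coef, apcs)
  }
  measured_mean <- colMeans(m)
  summary_df <- data.frame(
    element = els,
    measured_mean = measured_mean,
    predicted_mean = predicted_mean,
    mp_ratio = measured_mean / predicted_mean,
    r2 = r2,
    contribution,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(pca = pca, apcs = apcs, b0 = b0, coef = coefs, r2 = r2,
         predicted_mean = predicted_mean, measured_mean = measured_mean,
         contribution_pct = contribution,
         mean_contribution_pct = mean_source_contributions(contribution),
         summary = summary_df, k = k),
    class = "apcs_mlr"
  )
}

#' @export
print.apcs_mlr <- function(x, digits = 3, ...) {
  cat("APCS-MLR receptor model:", x$k, "retained component(s), n =",
      x$pca$n, "\n")
  cat("variance explained (%):",
      paste(round(x$pca$variance_explained, 1), collapse = ", "), "\n")
  cat("mean source contributions (%):",
      paste(round(x$mean_contribution_pct, 1), collapse = ", "), "\n")
  df <- x$summary
  df[-1] <- lapply(df[-1], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
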