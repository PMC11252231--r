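# Hakanson ecological risk: Er per element, RI (sum over the six elements
# carrying a toxicity response coefficient) and the Nemerow risk index.

#' Ecological risk factor
#'
#' `Er = Tr * Cf`: the contamination factor weighted by the element's
#' toxicity response coefficient.
#'
#' @param cf Contamination factor (vectorized).
#' @param tr Toxicity response coefficient; must be defined (packaged
#'   values exist for Zn, Cu, Cd, Ni, Cr, Pb only).
#' @return Er (dimensionless, >= 0).
#' @export
#' @examples
#' ecological_risk_factor(1.96, 30)
ecological_risk_factor <- function(cf, tr) {
  if (any(is.na(tr))) stop_soiltrace("no toxicity coefficient")
  if (any(!is.finite(cf) | cf < 0)) stop_soiltrace("Cf must be >= 0")
  tr * cf
}

#' Ecological risk index
#'
#' `RI = sum(Er)` over the toxicity-bearing elements.
#'
#' @param er Named numeric vector of Er values; must contain exactly the
#'   elements named in `elements`.
#' @param elements The required element set (default: the six elements
#'   with packaged Tr values).
#' @return RI (dimensionless).
#' @export
risk_index <- function(er, elements = names(default_reference_set()$tr)) {
  if (!is.null(elements)) {
    if (is.null(names(er)) || !setequal(names(er), elements)) {
      stop_soiltrace("Er vector must cover exactly: %s",
                     paste(elements, collapse = ", "))
    }
  }
  sum(er)
}

#' Nemerow risk index
#'
#' `NRI = sqrt((mean(Er)^2 + max(Er)^2) / 2)`.
#'
#' @param er Numeric vector of Er values.
#' @return NRI (dimensionless).
#' @export
nemerow_risk_index <- function(er) {
  if (!length(er)) stop_soiltrace("empty Er vector")
  sqrt((mean(er)^2 + max(er)^2) / 2)
}

#' Per-element contribution shares to RI
#'
#' @param er_means Named per-element mean Er values, total > 0.
#' @return Named percentages summing to 100.
#' @export
#' @examples
#' ri_contributions(c(Cd = 58.8, Ni = 4.03, Cu = 3.41,
#'                    Pb = 2.6, Cr = 0.98, Zn = 0.52))
ri_contributions <- function(er_means) {
  tot <- sum(er_means)
  if (!is.finite(tot) || tot <= 0) stop_soiltrace("total Er must be > 0")
  100 * er_means / tot
}

#' Full ecological risk assessment of a sample table
#'
#' Per-sample Er for the toxicity-bearing elements, per-sample RI and NRI
#' (each sample's own Er mean and max), classifications, mean values and
#' RI contribution shares.
#'
#' @param table A `sample_table` containing the six Tr-bearing elements.
#' @param ref A `te_reference`.
#' @param schemes Classification schemes, see [default_schemes()].
#' @return An `ecological_risk` list: matrix `er` (sites x 6), vectors
#'   `ri`, `nri`, per-sample class labels, `mean_er`, `mean_ri`,
#'   `mean_nri`, `contribution_pct` and `distribution`.
#' @export
ecological_risk_assessment <- function(table, ref = default_reference_set(),
                                       schemes = default_schemes()) {
  tr <- ref$tr
  els <- names(tr)
  m <- te_matrix(table)
  missing_el <- setdiff(els, colnames(m))
  if (length(missing_el)) {
    stop_soiltrace("missing element(s) for RI: %s",
                   paste(missing_el, collapse = ", "))
  }
  cf <- sweep(m[, els, drop = FALSE], 2, ref$background[els], "/")
  er <- sweep(cf, 2, tr, "*")
  ri <- rowSums(er)
  nri <- apply(er, 1, nemerow_risk_index)
  classes <- list(
    er = apply(er, 2, classify, scheme = schemes$er),
    ri = classify(ri, schemes$ri),
    nri = classify(nri, schemes$nri)
  )
  distribution <- rbind(
    do.call(rbind, lapply(els, function(el) {
      d <- class_distribution(factor(classes$er[, el],
                                     levels = schemes$er$labels))
      cbind(index = "Er", element = el, d)
    })),
    cbind(index = "RI", element = "(all)", class_distribution(classes$ri)),
    cbind(index = "NRI", element = "(all)", class_distribution(classes$nri))
  )
  mean_er <- colMeans(er)
  structure(
    list(site_id = table$site_id, elements = els, er = er, ri = ri,
         nri = nri, classes = classes, mean_er = mean_er,
         mean_ri = mean(ri), mean_nri = mean(nri),
         contribution_pct = ri_contributions(mean_er),
         distribution = distribution),
    class = "ecological_risk"
  )
}

#' @export
print.ecological_risk <- function(x, ...) {
  cat("Ecological risk over", length(x$site_id), "sites\n")
  cat("mean Er:\n"); print(round(x$mean_er, 2))
  cat("mean RI:", round(x$mean_ri, 1), " mean NRI:", round(x$mean_nri, 1), "\n")
  cat("RI contributions (%):\n")
  print(round(x$contribution_pct, 1))
  invisible(x)
}
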