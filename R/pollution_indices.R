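# Pollution indices per sample: Cf, Igeo, EF (element-wise) and PLI, NPI
# (synergistic over elements).

#' Contamination factor
#'
#' `Cf = C / Cn`: concentration over geochemical background.
#'
#' @param conc Concentration, mg/kg (vectorized).
#' @param background Background value, mg/kg, > 0.
#' @return Cf (dimensionless, > 0).
#' @export
#' @examples
#' contamination_factor(0.176, 0.09)
contamination_factor <- function(conc, background) {
  check_positive(background, "background")
  check_positive(conc, "concentration")
  conc / background
}

#' Geoaccumulation index
#'
#' `Igeo = log2(C / (1.5 * B))`; the 1.5 factor absorbs natural
#' background fluctuation.
#'
#' @inheritParams contamination_factor
#' @return Igeo (unbounded).
#' @export
#' @examples
#' geoaccumulation_index(3 * 0.09, 0.09)  # = 1
geoaccumulation_index <- function(conc, background) {
  check_positive(background, "background")
  check_positive(conc, "concentration")
  log2(conc / (1.5 * background))
}

#' Enrichment factor
#'
#' Double ratio to a conservative reference element (Al by default in the
#' assessment wrappers): `EF = (C/Cref)_sample / (C/Cref)_background`.
#'
#' @param conc Element concentration in the sample, mg/kg.
#' @param ref_conc Reference-element concentration in the sample, mg/kg.
#' @param background Element background, mg/kg.
#' @param ref_background Reference-element background, mg/kg.
#' @return EF (dimensionless, > 0).
#' @export
enrichment_factor <- function(conc, ref_conc, background, ref_background) {
  check_positive(conc, "concentration")
  check_positive(ref_conc, "reference concentration")
  check_positive(background, "background")
  check_positive(ref_background, "reference background")
  (conc / ref_conc) / (background / ref_background)
}

#' Pollution load index
#'
#' Geometric mean of the contamination factors of all elements in a
#' sample.
#'
#' @param cf Numeric vector of Cf values (> 0).
#' @return PLI (dimensionless).
#' @export
pollution_load_index <- function(cf) {
  if (!length(cf)) stop_soiltrace("empty Cf vector")
  check_positive(cf, "Cf")
  exp(mean(log(cf)))
}

#' Nemerow pollution index
#'
#' `NPI = sqrt((mean(Cf)^2 + max(Cf)^2) / 2)`, weighting the average
#' contamination against the single worst element.
#'
#' @param cf Numeric vector of Cf values.
#' @return NPI (dimensionless).
#' @export
nemerow_pollution_index <- function(cf) {
  if (!length(cf)) stop_soiltrace("empty Cf vector")
  sqrt((mean(cf)^2 + max(cf)^2) / 2)
}

#' Full pollution-index assessment of a sample table
#'
#' Computes per-sample Cf, Igeo and EF matrices, per-sample PLI and NPI,
#' class labels under the packaged schemes, the mean of the per-sample
#' values of every index, and Table-style class-distribution percentages.
#'
#' @param table A `sample_table`.
#' @param ref A `te_reference` supplying backgrounds.
#' @param ref_element Conservative reference element for EF (default
#'   `"Al"`; must be a column of `table` with a defined background).
#' @param schemes Classification schemes, see [default_schemes()].
#' @return A `pollution_assessment` list: matrices `cf`, `igeo`, `ef`;
#'   vectors `pli`, `npi`; `mean_index` (per-element means of Cf/Igeo/EF
#'   plus mean PLI/NPI); `classes` (per-sample labels per index) and
#'   `distribution` (long data frame of class percentages per index and
#'   element).
#' @export
pollution_assessment <- function(table, ref = default_reference_set(),
                                 ref_element = "Al",
                                 schemes = default_schemes()) {
  m <- te_matrix(table)
  els <- colnames(m)
  bg <- ref$background[els]
  if (any(is.na(bg))) {
    stop_soiltrace("no background for element(s): %s",
                   paste(els[is.na(bg)], collapse = ", "))
  }
  cf <- sweep(m, 2, bg, "/")
  igeo <- log2(sweep(m, 2, 1.5 * bg, "/"))
  ef <- NULL
  if (ref_element %in% els) {
    ratio_s <- sweep(m, 1, m[, ref_element], "/")
    ratio_b <- bg / bg[[ref_element]]
    ef <- sweep(ratio_s, 2, ratio_b, "/")
  } else {
    warning("reference element ", ref_element,
            " not in table; EF not computed")
  }
  pli <- apply(cf, 1, pollution_load_index)
  npi <- apply(cf, 1, nemerow_pollution_index)

  classes <- list(
    cf = apply(cf, 2, classify, scheme = schemes$cf),
    igeo = apply(igeo, 2, classify, scheme = schemes$igeo),
    pli = classify(pli, schemes$pli),
    npi = classify(npi, schemes$npi)
  )
  if (!is.null(ef)) classes$ef <- apply(ef, 2, classify, scheme = schemes$ef)

  dist_element <- function(lbl_m, scheme, index) {
    do.call(rbind, lapply(colnames(lbl_m), function(el) {
      d <- class_distribution(factor(lbl_m[, el], levels = scheme$labels))
      cbind(index = index, element = el, d)
    }))
  }
  distribution <- rbind(
    dist_element(classes$cf, schemes$cf, "Cf"),
    dist_element(classes$igeo, schemes$igeo, "Igeo"),
    if (!is.null(ef)) dist_element(classes$ef, schemes$ef, "EF"),
    cbind(index = "PLI", element = "(all)",
          class_distribution(classes$pli)),
    cbind(index = "NPI", element = "(all)",
          class_distribution(classes$npi))
  )

  mean_index <- list(
    cf = colMeans(cf), igeo = colMeans(igeo),
    ef = if (!is.null(ef)) colMeans(ef),
    pli = mean(pli), npi = mean(npi)
  )

  structure(
    list(site_id = table$site_id, cf = cf, igeo = igeo, ef = ef,
         pli = pli, npi = npi, classes = classes,
         mean_index = mean_index, distribution = distribution,
         ref_element = ref_element),
    class = "pollution_assessment"
  )
}

#' @export
print.pollution_assessment <- function(x, ...) {
  cat("Pollution indices over", length(x$site_id), "sites\n")
  cat("mean Cf:\n"); print(round(x$mean_index$cf, 3))
  cat("mean PLI:", round(x$mean_index$pli, 3),
      " mean NPI:", round(x$mean_index$npi, 3), "\n")
  invisible(x)
}

#' Long-format export of a pollution assessment
#'
#' @param x A `pollution_assessment`.
#' @return Data frame `(site_id, element, index, value, class)`; the
#'   synergistic indices carry element `"(all)"`.
#' @export
pollution_long <- function(x) {
  stopifnot(inherits(x, "pollution_assessment"))
  melt_idx <- function(mat, lbl, index) {
    do.call(rbind, lapply(colnames(mat), function(el) {
      data.frame(site_id = x$site_id, element = el, index = index,
                 value = mat[, el], class = as.character(lbl[, el]),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(
    melt_idx(x$cf, x$classes$cf, "Cf"),
    melt_idx(x$igeo, x$classes$igeo, "Igeo"),
    if (!is.null(x$ef)) melt_idx(x$ef, x$classes$ef, "EF"),
    data.frame(site_id = x$site_id, element = "(all)", index = "PLI",
               value = x$pli, class = as.character(x$classes$pli),
               row.names = NULL, stringsAsFactors = FALSE),
    data.frame(site_id = x$site_id, element = "(all)", index = "NPI",
               value = x$npi, class = as.character(x$classes$npi),
               row.names = NULL, stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}
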