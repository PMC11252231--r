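# USEPA residential health risk. Non-carcinogenic hazard quotients use
# child/adult receptors with averaging time ED*365 days; carcinogenic
# risks use the age-adjusted lifetime receptor (IFS/DFS for
# ingestion/dermal, ED = EDc + EDa for inhalation) with averaging time
# 70 years. The exposure-frequency symbol is EFr throughout to avoid
# collision with the enrichment factor EF.

.hr_cache <- new.env(parent = emptyenv())

#' Packaged residential exposure scenario
#'
#' USEPA RSL residential defaults: child (IRS 200 mg/day, ED 6 yr, BW 15
#' kg, SA 2373 cm2/day, AF 0.2 mg/cm2) and adult (IRS 100, ED 20, BW 80,
#' SA 6032, AF 0.07) blocks, EFr 350 days/yr, PEF 1.36e9 m3/kg,
#' carcinogenic averaging time 70 years.
#'
#' @param path Optional JSON override with the packaged schema.
#' @return An `exposure_scenario` list with `child` and `adult` blocks
#'   plus `PEF` and `AT_carcinogenic_years`.
#' @export
default_exposure_scenario <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.hr_cache$scenario)) return(.hr_cache$scenario)
    path <- system.file("extdata", "exposure_scenario.json",
                        package = "soiltrace")
    cache <- TRUE
  } else cache <- FALSE
  raw <- jsonlite::fromJSON(path)
  sc <- structure(list(child = as.list(raw$child), adult = as.list(raw$adult),
                       PEF = raw$PEF,
                       AT_carcinogenic_years = raw$AT_carcinogenic_years),
                  class = "exposure_scenario")
  for (blk in c("child", "adult")) {
    vals <- unlist(sc[[blk]])
    if (any(vals <= 0)) stop_soiltrace("non-positive exposure parameter")
  }
  if (cache) .hr_cache$scenario <- sc
  sc
}

#' Packaged toxicity table
#'
#' Per-element toxicity constants (USEPA RSL residential): oral reference
#' dose RfDo (mg/kg-day), inhalation reference concentration RfC (mg/m3),
#' dermal absorption fraction ABSd, gastrointestinal absorption fraction
#' GIABS, relative bioavailability RBA, oral slope factor CSFo
#' ((mg/kg-day)^-1) and inhalation unit risk IUR ((ug/m3)^-1). CSFo/IUR
#' are defined only for the assessed carcinogens (Cr as Cr(VI), Cd, Ni,
#' Co); absent values are `NA`.
#'
#' @param path Optional JSON override with the packaged schema.
#' @return Data frame, one row per element (row names = element symbols).
#' @export
default_toxicity_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.hr_cache$tox)) return(.hr_cache$tox)
    path <- system.file("extdata", "toxicity_table.json",
                        package = "soiltrace")
    cache <- TRUE
  } else cache <- FALSE
  raw <- jsonlite::fromJSON(path)
  fields <- c("RfDo", "RfC", "ABSd", "GIABS", "RBA", "CSFo", "IUR")
  rows <- lapply(raw$elements, function(e) {
    vapply(fields, function(f) {
      v <- e[[f]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  })
  tox <- as.data.frame(do.call(rbind, rows))
  rownames(tox) <- names(raw$elements)
  ok <- function(v, lo = 0, hi = Inf) all(is.na(v) | (v > lo & v <= hi))
  if (!ok(tox$RfDo) || !ok(tox$RfC)) stop_soiltrace("RfD/RfC must be > 0")
  if (!ok(tox$ABSd, 0, 1) || !ok(tox$GIABS, 0, 1) || !ok(tox$RBA, 0, 1)) {
    stop_soiltrace("ABSd, GIABS, RBA must lie in (0, 1]")
  }
  if (cache) .hr_cache$tox <- tox
  tox
}

#' Age-adjusted soil ingestion factor
#'
#' `IFS = EFr*EDa*IRSa/BWa + EFr*EDc*IRSc/BWc` (mg), combining the child
#' and adult blocks of a lifetime receptor.
#'
#' @param scenario An `exposure_scenario` with both age blocks.
#' @return IFS in mg.
#' @export
#' @examples
#' ifs(default_exposure_scenario())  # 36750 under the packaged defaults
ifs <- function(scenario) {
  a <- scenario$adult; c_ <- scenario$child
  if (is.null(a) || is.null(c_)) stop_soiltrace("both age blocks required")
  a$EFr * a$ED * a$IRS / a$BW + c_$EFr * c_$ED * c_$IRS / c_$BW
}

#' Age-adjusted dermal contact factor
#'
#' `DFS = EFr*EDa*SAa*AFa/BWa + EFr*EDc*SAc*AFc/BWc` (mg).
#'
#' @inheritParams ifs
#' @return DFS in mg.
#' @export
dfs <- function(scenario) {
  a <- scenario$adult; c_ <- scenario$child
  if (is.null(a) || is.null(c_)) stop_soiltrace("both age blocks required")
  a$EFr * a$ED * a$SA * a$AF / a$BW + c_$EFr * c_$ED * c_$SA * c_$AF / c_$BW
}

tox_entry <- function(tox, element) {
  if (!element %in% rownames(tox)) {
    stop_soiltrace("no toxicity entry for %s", element)
  }
  as.list(tox[element, ])
}

#' Route-wise hazard quotient
#'
#' Non-carcinogenic hazard quotient for one element, route and receptor.
#' Averaging time is `ED * 365` days. Dermal divides additionally by
#' GIABS; inhalation uses `Cs*EFr*ED / (AT*RfC*PEF)` with EFr*ED in days.
#'
#' @param cs Soil concentration, mg/kg.
#' @param route `"ingestion"`, `"dermal"` or `"inhalation"`.
#' @param receptor `"child"` or `"adult"`.
#' @param scenario An `exposure_scenario`.
#' @param tox Toxicity table (see [default_toxicity_table()]).
#' @param element Element symbol (row of `tox`).
#' @return HQ (dimensionless), or `NA` with a warning when the route's
#'   toxicity value is undefined for the element.
#' @export
hq_route <- function(cs, route = c("ingestion", "dermal", "inhalation"),
                     receptor = c("child", "adult"),
                     scenario = default_exposure_scenario(),
                     tox = default_toxicity_table(), element) {
  route <- match.arg(route)
  receptor <- match.arg(receptor)
  tx <- tox_entry(tox, element)
  b <- scenario[[receptor]]
  at <- b$ED * 365
  if (route == "inhalation") {
    if (is.na(tx$RfC)) {
      warning("no RfC for ", element, "; inhalation HQ skipped")
      return(NA_real_)
    }
    return(cs * b$EFr * b$ED / (at * tx$RfC * scenario$PEF))
  }
  if (is.na(tx$RfDo)) {
    warning("no RfDo for ", element, "; ", route, " HQ skipped")
    return(NA_real_)
  }
  if (route == "ingestion") {
    cs * b$IRS * tx$RBA * b$EFr * b$ED / (b$BW * at * tx$RfDo * 1e6)
  } else {
    cs * b$SA * b$AF * tx$ABSd * b$EFr * b$ED /
      (b$BW * at * tx$RfDo * tx$GIABS * 1e6)
  }
}

#' Route-wise carcinogenic risk
#'
#' Lifetime (age-adjusted) carcinogenic risk for one element and route.
#' Ingestion and dermal use the IFS/DFS age-adjusted factors; inhalation
#' uses `ED = EDc + EDa`. Averaging time is 70 years.
#'
#' @inheritParams hq_route
#' @return CR (dimensionless), or `NA` with a warning when the element
#'   lacks the route's slope factor / unit risk.
#' @export
cr_route <- function(cs, route = c("ingestion", "dermal", "inhalation"),
                     scenario = default_exposure_scenario(),
                     tox = default_toxicity_table(), element) {
  route <- match.arg(route)
  tx <- tox_entry(tox, element)
  at <- scenario$AT_carcinogenic_years * 365
  if (route == "inhalation") {
    if (is.na(tx$IUR)) {
      warning("no IUR for ", element, "; inhalation CR skipped")
      return(NA_real_)
    }
    ed <- scenario$child$ED + scenario$adult$ED
    efr <- scenario$adult$EFr
    return(cs * efr * ed * tx$IUR * 1000 / (at * scenario$PEF))
  }
  if (is.na(tx$CSFo)) {
    warning("no CSFo for ", element, "; ", route, " CR skipped")
    return(NA_real_)
  }
  if (route == "ingestion") {
    cs * ifs(scenario) * tx$RBA * tx$CSFo / (at * 1e6)
  } else {
    cs * dfs(scenario) * tx$ABSd * tx$CSFo / (at * tx$GIABS * 1e6)
  }
}

#' Aggregate route-wise risks
#'
#' Sums hazard quotients into HI (per element, over routes), CHQ (per
#' route, over elements) and THI (both groupings, identical by
#' construction), and carcinogenic risks into TCR, CCR and CTCR. `NA`
#' entries (routes skipped for missing toxicity values) are dropped from
#' the sums.
#'
#' @param hq 3-d array `element x route x receptor` of hazard quotients
#'   (may be `NULL`).
#' @param cr Matrix `element x route` of carcinogenic risks (may be
#'   `NULL`).
#' @return A `risk_result` list with `hq`, `hi`, `chq`, `thi`, `cr`,
#'   `tcr`, `ccr`, `ctcr`.
#' @export
aggregate_risks <- function(hq = NULL, cr = NULL) {
  out <- list(hq = hq, cr = cr)
  if (!is.null(hq)) {
    out$hi <- apply(hq, c(1, 3), sum, na.rm = TRUE)
    out$chq <- apply(hq, c(2, 3), sum, na.rm = TRUE)
    out$thi <- apply(hq, 3, sum, na.rm = TRUE)
    stopifnot(max(abs(colSums(out$hi) - out$thi)) < 1e-12 * max(1, out$thi),
              max(abs(colSums(out$chq) - out$thi)) < 1e-12 * max(1, out$thi))
  }
  if (!is.null(cr)) {
    out$tcr <- apply(cr, 1, sum, na.rm = TRUE)
    out$ccr <- apply(cr, 2, sum, na.rm = TRUE)
    out$ctcr <- sum(cr, na.rm = TRUE)
    stopifnot(abs(sum(out$tcr) - out$ctcr) <= 1e-12 * max(1, out$ctcr),
              abs(sum(out$ccr) - out$ctcr) <= 1e-12 * max(1, out$ctcr))
  }
  structure(out, class = "risk_result")
}

#' Full health risk assessment
#'
#' Computes route-wise hazard quotients for child and adult receptors and
#' lifetime carcinogenic risks for the assessed carcinogens, from mean
#' soil concentrations, and aggregates them.
#'
#' @param conc A `sample_table` (means are taken per element) or a named
#'   vector of mean concentrations, mg/kg.
#' @param scenario An `exposure_scenario`.
#' @param tox Toxicity table.
#' @return A `risk_result`, see [aggregate_risks()].
#' @export
#' @examples
#' hr <- health_risk_assessment(c(Cr = 44.9, Ni = 37.9, Cd = 0.176, Co = 7.58))
#' hr$tcr
health_risk_assessment <- function(conc,
                                   scenario = default_exposure_scenario(),
                                   tox = default_toxicity_table()) {
  if (inherits(conc, "sample_table")) conc <- colMeans(te_matrix(conc))
  if (is.null(names(conc))) stop_soiltrace("conc must be named by element")
  els <- names(conc)
  unknown <- setdiff(els, rownames(tox))
  if (length(unknown)) {
    warning("no toxicity entry for: ", paste(unknown, collapse = ", "),
            "; element skipped")
    els <- setdiff(els, unknown)
  }
  routes <- c("ingestion", "dermal", "inhalation")
  receptors <- c("child", "adult")
  hq <- array(NA_real_, c(length(els), 3, 2),
              dimnames = list(els, routes, receptors))
  for (el in els) for (ro in routes) for (re in receptors) {
    hq[el, ro, re] <- suppressWarnings(
      hq_route(conc[[el]], ro, re, scenario, tox, el))
  }
  carc <- els[!is.na(tox[els, "CSFo"]) | !is.na(tox[els, "IUR"])]
  cr <- NULL
  if (length(carc)) {
    cr <- matrix(NA_real_, length(carc), 3, dimnames = list(carc, routes))
    for (el in carc) for (ro in routes) {
      cr[el, ro] <- suppressWarnings(
        cr_route(conc[[el]], ro, scenario, tox, el))
    }
  }
  aggregate_risks(hq, cr)
}

#' @export
print.risk_result <- function(x, ...) {
  if (!is.null(x$thi)) {
    cat("Non-carcinogenic: THI child =", signif(x$thi[["child"]], 3),
        ", adult =", signif(x$thi[["adult"]], 3), "\n")
  }
  if (!is.null(x$ctcr)) {
    cat("Carcinogenic: CTCR =", signif(x$ctcr, 3), "\nTCR per element:\n")
    print(signif(x$tcr, 3))
  }
  invisible(x)
}
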