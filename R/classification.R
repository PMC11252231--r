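# Classification schemes for index values.
#
# Each scheme is a set of strictly increasing breakpoints with one label
# per interval and a per-breakpoint closure flag: `lower_in[i]` TRUE means
# a value exactly equal to breakpoint i takes the lower class (the table's
# "<=" reading), FALSE means it takes the upper class (left-closed
# resolution of strict "<"/">" gaps).

#' Construct a classification scheme
#'
#' @param name Scheme name.
#' @param breakpoints Strictly increasing numeric thresholds.
#' @param labels Class labels, one more than there are breakpoints.
#' @param lower_in Logical, one per breakpoint: does a value equal to the
#'   breakpoint belong to the class below it? Scalar is recycled.
#' @return A `classification_scheme` object.
#' @export
classification_scheme <- function(name, breakpoints, labels, lower_in = FALSE) {
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    stop_soiltrace("breakpoints must be strictly increasing")
  }
  if (length(labels) != length(breakpoints) + 1L) {
    stop_soiltrace("need one label more than breakpoints")
  }
  if (anyDuplicated(labels)) stop_soiltrace("labels must be unique")
  lower_in <- rep_len(as.logical(lower_in), length(breakpoints))
  structure(list(name = name, breakpoints = breakpoints, labels = labels,
                 lower_in = lower_in),
            class = "classification_scheme")
}

#' Classify index values
#'
#' Total on finite values: every value receives exactly one label.
#'
#' @param value Numeric vector of index values.
#' @param scheme A `classification_scheme`.
#' @return Factor of class labels with the scheme's level order.
#' @export
#' @examples
#' sch <- default_schemes()
#' classify(c(-0.2, 0.5, 1.96), sch$cf)
#' classify(1.96, sch$cf)
classify <- function(value, scheme) {
  stopifnot(inherits(scheme, "classification_scheme"))
  idx <- vapply(value, function(v) {
    if (!is.finite(v)) return(NA_integer_)
    k <- 1L
    for (i in seq_along(scheme$breakpoints)) {
      b <- scheme$breakpoints[i]
      if (v > b || (v == b && !scheme$lower_in[i])) k <- i + 1L
    }
    k
  }, integer(1))
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Packaged classification schemes
#'
#' The degree schemes for the five pollution indices and three ecological
#' risk indices: `igeo`, `cf`, `ef`, `pli`, `npi`, `er`, `ri`, `nri`.
#' Boundary conventions follow each scheme's printed inequalities; strict
#' gaps at exact breakpoints resolve to the higher class.
#'
#' @return Named list of `classification_scheme` objects.
#' @export
default_schemes <- function() {
  list(
    igeo = classification_scheme(
      "Igeo", 0:5,
      c("Unpolluted", "Unpolluted to moderately polluted",
        "Moderately polluted", "Moderately to heavily polluted",
        "Heavily polluted", "Heavily to extremely polluted",
        "Extremely polluted"),
      lower_in = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    cf = classification_scheme(
      "Cf", c(1, 3, 6),
      c("Low contamination", "Moderate contamination",
        "Considerable contamination", "Very high contamination")),
    ef = classification_scheme(
      "EF", c(2, 5, 20, 40),
      c("Minimal enrichment", "Moderate enrichment",
        "Significant enrichment", "Very high enrichment",
        "Extremely high enrichment")),
    pli = classification_scheme(
      "PLI", c(0, 1),
      c("No contamination", "Baseline contamination", "High contamination"),
      lower_in = c(TRUE, FALSE)),
    npi = classification_scheme(
      "NPI", c(0.7, 1, 2, 3),
      c("Unpolluted", "Warning line of pollution", "Low polluted",
        "Moderately polluted", "Strongly polluted"),
      lower_in = TRUE),
    er = classification_scheme(
      "Er", c(40, 80, 160, 320),
      c("Low potential ecological risk", "Moderate potential ecological risk",
        "Considerable potential ecological risk",
        "High potential ecological risk",
        "Very high potential ecological risk")),
    ri = classification_scheme(
      "RI", c(150, 300, 600),
      c("Low ecological risk", "Moderate ecological risk",
        "Considerable ecological risk", "Very high ecological risk")),
    nri = classification_scheme(
      "NRI", c(40, 80, 160, 320),
      c("Low risk", "Moderate risk", "Considerable risk", "High risk",
        "Very high risk"),
      lower_in = TRUE)
  )
}

#' Class distribution of labels
#'
#' Percentage of sites per class, zero-count classes included. Percentages
#' sum to 100 up to rounding.
#'
#' @param labels Factor (or character) of class labels per site.
#' @param scheme Optional `classification_scheme` supplying the complete
#'   level set; required when `labels` is character.
#' @return Data frame with `class`, `count`, `pct`.
#' @export
class_distribution <- function(labels, scheme = NULL) {
  if (!is.null(scheme)) labels <- factor(labels, levels = scheme$labels)
  if (!is.factor(labels)) labels <- factor(labels)
  if (!length(labels)) stop_soiltrace("need at least one label")
  counts <- table(labels)
  data.frame(
    class = names(counts),
    count = as.integer(counts),
    pct = 100 * as.integer(counts) / length(labels),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
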