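# Packaged reference constants and the sample-table reader/writer.
#
# Backgrounds are upper-continental-crust (UCC) values; guideline sets are
# the world/European soil averages (WSA/ESA), maximum allowable
# concentrations (MAC) and Canadian soil quality guidelines (CSQG).
# Toxicity response coefficients Tr are defined for Zn, Cu, Cd, Ni, Cr, Pb
# only. All constants ship as a versioned JSON file under extdata and can
# be overridden by a user file with the same schema.

.ref_cache <- new.env(parent = emptyenv())

#' Packaged reference constants
#'
#' Returns the packaged per-element constants used throughout the indices:
#' geochemical background (upper continental crust), the WSA/ESA/MAC/CSQG
#' guideline sets and the Hakanson toxicity response coefficients `tr`.
#' Elements without a defined guideline carry `NA`; `tr` is defined only
#' for Zn, Cu, Cd, Ni, Cr and Pb.
#'
#' @param path Optional path to a JSON file with the same schema as the
#'   packaged `reference_values.json`, to override the defaults.
#' @return An object of class `te_reference`: a list with `elements`,
#'   numeric vectors `background`, `wsa`, `esa`, `mac`, `csqg` (named by
#'   element, `NA` where undefined), `tr` (named, six elements) and
#'   `version`.
#' @export
#' @examples
#' ref <- default_reference_set()
#' ref$background[["Cd"]]
#' ref$tr[["Cd"]]
default_reference_set <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ref_cache$default)) return(.ref_cache$default)
    path <- system.file("extdata", "reference_values.json", package = "soiltrace")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  if (!file.exists(path)) stop_soiltrace("reference file not found: %s", path)
  raw <- jsonlite::fromJSON(path)
  elements <- as.character(raw$elements)
  pick <- function(field) {
    v <- setNames(rep(NA_real_, length(elements)), elements)
    got <- unlist(raw[[field]])
    v[names(got)] <- as.numeric(got)
    v
  }
  ref <- structure(
    list(
      elements = elements,
      background = pick("background"),
      wsa = pick("wsa"),
      esa = pick("esa"),
      mac = pick("mac"),
      csqg = pick("csqg"),
      tr = setNames(as.numeric(unlist(raw$tr)), names(raw$tr)),
      version = raw$version
    ),
    class = "te_reference"
  )
  check_positive(ref$background, "background")
  if (cache) .ref_cache$default <- ref
  ref
}

#' @export
print.te_reference <- function(x, ...) {
  cat("Trace-element reference set (version ", x$version, ")\n", sep = "")
  tab <- rbind(background = x$background, wsa = x$wsa, esa = x$esa,
               mac = x$mac, csqg = x$csqg,
               tr = x$tr[match(x$elements, names(x$tr))])
  colnames(tab) <- x$elements
  print(tab, ...)
  invisible(x)
}

# sample tables -------------------------------------------------------------

#' Build a sample table from a data frame or matrix
#'
#' A sample table is a data frame with a `site_id` character column
#' followed by one numeric column per element (concentrations in mg/kg dry
#' soil). All concentrations must be finite and strictly positive and site
#' ids unique. Element columns are case-normalized to the canonical symbol
#' spelling and reordered to the canonical order where applicable.
#'
#' @param x A data frame with a `site_id` column (or a numeric matrix with
#'   row names used as site ids) and element columns.
#' @param elements Optional character vector restricting (and ordering) the
#'   element columns.
#' @return A `sample_table` data frame.
#' @export
as_sample_table <- function(x, elements = NULL) {
  if (is.matrix(x)) {
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("S", seq_len(nrow(x)))
    x <- data.frame(site_id = ids, x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x)) stop_soiltrace("expected a data frame or matrix")
  names(x)[1] <- "site_id"
  x$site_id <- as.character(x$site_id)
  # case-normalize element symbols ("CD", "cd" -> "Cd")
  el_names <- names(x)[-1]
  canon <- te_elements()
  hit <- match(tolower(el_names), tolower(canon))
  el_names[!is.na(hit)] <- canon[hit[!is.na(hit)]]
  names(x)[-1] <- el_names
  if (!is.null(elements)) {
    missing_el <- setdiff(elements, el_names)
    if (length(missing_el)) {
      stop_soiltrace("element missing: %s", paste(missing_el, collapse = ", "))
    }
    x <- x[, c("site_id", elements), drop = FALSE]
  } else {
    # canonicalize column order where columns are known elements
    known <- intersect(canon, el_names)
    other <- setdiff(el_names, canon)
    x <- x[, c("site_id", known, other), drop = FALSE]
  }
  validate_sample_table(x)
}

validate_sample_table <- function(x) {
  if (anyDuplicated(x$site_id)) stop_soiltrace("duplicate site_ids")
  for (el in names(x)[-1]) {
    v <- x[[el]]
    if (!is.numeric(v)) {
      stop_soiltrace("invalid concentration: non-numeric column %s", el)
    }
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) {
      stop_soiltrace("invalid concentration at site %s, element %s",
                     x$site_id[bad[1]], el)
    }
  }
  class(x) <- c("sample_table", "data.frame")
  x
}

#' Read a sample table from CSV
#'
#' Expects UTF-8 CSV with one header row; the first column holds site ids
#' and the remaining columns element concentrations in mg/kg dry soil.
#'
#' @param path CSV file path.
#' @param elements Optional element subset to keep (error if absent).
#' @return A `sample_table` data frame (file row order preserved).
#' @export
read_sample_table <- function(path, elements = NULL) {
  if (!file.exists(path)) stop_soiltrace("file not found: %s", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop_soiltrace("no element columns in %s", path)
  as_sample_table(df, elements = elements)
}

#' Write a sample table to CSV
#'
#' Full-precision round-trip companion of [read_sample_table()].
#'
#' @param x A `sample_table`.
#' @param path Output CSV path.
#' @export
write_sample_table <- function(x, path) {
  out <- as.data.frame(x)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Concentration matrix of a sample table
#'
#' @param x A `sample_table`.
#' @return Numeric matrix (sites x elements) with site ids as row names.
#' @export
te_matrix <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$site_id
  storage.mode(m) <- "double"
  m
}

# guideline comparison -------------------------------------------------------

#' Flag guideline exceedances
#'
#' Compares a per-element statistic (e.g. the mean or maximum
#' concentration) against one packaged guideline set. Elements for which
#' the guideline is undefined are reported as not assessed (`NA`).
#'
#' @param values Named numeric vector of per-element statistics (mg/kg).
#' @param guideline One of `"wsa"`, `"esa"`, `"mac"`, `"csqg"`,
#'   `"background"`.
#' @param ref A `te_reference`; defaults to the packaged constants.
#' @return Data frame with columns `element`, `value`, `guideline`,
#'   `guideline_value` and `exceeds` (logical; `NA` = not assessed).
#' @export
#' @examples
#' flag_guideline_exceedance(c(Ni = 37.9, Cd = 0.176), "esa")
flag_guideline_exceedance <- function(values,
                                      guideline = c("wsa", "esa", "mac",
                                                    "csqg", "background"),
                                      ref = default_reference_set()) {
  guideline <- match.arg(guideline)
  if (is.null(names(values))) stop_soiltrace("values must be named by element")
  g <- ref[[guideline]]
  gv <- g[names(values)]
  data.frame(
    element = names(values),
    value = as.numeric(values),
    guideline = guideline,
    guideline_value = as.numeric(gv),
    exceeds = ifelse(is.na(gv), NA, as.numeric(values) > gv),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
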