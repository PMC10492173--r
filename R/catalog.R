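#' Load a laboratory test catalog
#'
#' The catalog drives every stage that has to reason about laboratory tests:
#' synonym matching during mention extraction, unit conversion, plausibility
#' screening for unit inference and mistranscription checks, and rendering in
#' the synthetic-forum generator. Each entry carries the test's canonical
#' reporting unit, multiplicative conversion factors for accepted alternate
#' units, a healthy reference range and a wider condition-plausible range in
#' canonical units, a distribution family used by the generator, and the
#' decimal precision laboratories typically report for the analyte.
#'
#' The condition-plausible range expands the healthy range to admit the
#' dysregulation typical of the condition being profiled (upper bound tripled
#' for androgen-axis tests, doubled otherwise; lower bound halved), with
#' per-test clinical overrides recorded directly in the data file.
#'
#' @param path Path to a catalog JSON file. Defaults to the catalog shipped
#'   with the package (a PCOS laboratory panel).
#' @return An object of class `lab_catalog`: a named list of test entries.
#' @export
lab_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "test_catalog.json", package = "forumlabs")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("catalog file not found: ", path)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  tests <- lapply(raw$tests, function(t) {
    t$synonyms <- unique(c(vapply(t$synonyms, as.character, character(1)),
                           tolower(t$name)))
    t$alt_units <- if (length(t$alt_units)) {
      vapply(t$alt_units, as.numeric, numeric(1))
    } else {
      stats::setNames(numeric(0), character(0))
    }
    t$healthy <- as.numeric(unlist(t$healthy))
    t$plausible <- as.numeric(unlist(t$plausible))
    t$digits <- as.integer(t$digits)
    t
  })
  validate_catalog(tests)
  structure(tests, class = "lab_catalog", version = raw$version)
}

validate_catalog <- function(tests) {
  for (id in names(tests)) {
    t <- tests[[id]]
    if (!length(t$synonyms)) stop("catalog test '", id, "' has no synonyms")
    if (any(!is.finite(t$alt_units)) || any(t$alt_units <= 0)) {
      stop("catalog test '", id, "' has a non-positive unit factor")
    }
    if (t$healthy[1] >= t$healthy[2]) {
      stop("catalog test '", id, "' reference range is not increasing")
    }
    if (t$plausible[1] > t$healthy[1] || t$plausible[2] < t$healthy[2]) {
      stop("catalog test '", id, "' healthy range not within plausible range")
    }
  }
  invisible(TRUE)
}

#' @export
print.lab_catalog <- function(x, ...) {
  cat("<lab_catalog> ", length(x), " tests: ",
      paste(utils::head(names(x), 8), collapse = ", "),
      if (length(x) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Canonicalize a unit string: lowercase, mu -> u, strip spaces and trailing
# periods, and fold IU spellings onto U (mIU/mL == mIU/ml == miu/ml).
normalize_unit <- function(unit) {
  u <- tolower(trimws(as.character(unit)))
  u <- gsub("µ|μ", "u", u)
  u <- gsub("[[:space:].]", "", u)
  u <- sub("\\^?2$", "2", u)
  u <- sub("^iu/", "u/", u)
  u <- sub("^mcg", "ug", u)
  u
}

# All unit names accepted for a test, canonical first.
catalog_units <- function(catalog, test) {
  t <- catalog[[test]]
  if (is.null(t)) stop("unknown test id: ", test)
  c(t$unit, names(t$alt_units))
}

# Multiplicative factor taking a value in `unit` to the canonical unit,
# or NA when the unit is not listed for the test.
unit_factor <- function(catalog, test, unit) {
  t <- catalog[[test]]
  if (is.null(t)) stop("unknown test id: ", test)
  nu <- normalize_unit(unit)
  if (identical(nu, normalize_unit(t$unit))) return(1)
  alts <- names(t$alt_units)
  hit <- which(vapply(alts, function(a) identical(normalize_unit(a), nu), logical(1)))
  if (length(hit) == 1) unname(t$alt_units[[hit]]) else NA_real_
}

# Every unit string known to the catalog (for recognizing unit-like tokens).
all_known_units <- function(catalog) {
  out <- unlist(lapply(catalog, function(t) c(t$unit, names(t$alt_units))))
  unique(normalize_unit(out[nzchar(out)]))
}
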