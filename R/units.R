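#' Recognised concentration units
#'
#' Molar units convert to nanomolar by pure scale factors; mass-per-volume
#' units additionally require the molecular weight (g/mol).
#' @return Character vector of canonical unit strings.
#' @export
recognized_units <- function() {
  c("nM", "uM", "mM", "M", "ng/mL", "ug/mL", "mg/L", "g/L")
}

# canonicalise a unit token: micro sign and "u" prefix are interchangeable
canonical_unit <- function(unit) {
  u <- stringr::str_squish(unit)
  u <- stringr::str_replace_all(u, "µ|μ", "u")
  key <- tolower(gsub("\\s", "", u))
  map <- c(
    "nm" = "nM", "um" = "uM", "mm" = "mM", "m" = "M",
    "ng/ml" = "ng/mL", "ug/ml" = "ug/mL", "mg/l" = "mg/L", "g/l" = "g/L",
    "mg/ml" = "g/L", "ug/l" = "ng/mL"
  )
  unname(map[key])
}

#' Parse a quantity string
#'
#' Splits a string such as `"129 µM"` or `"0.5 ug/mL"` into a numeric value
#' and a canonical unit. The micro sign and an ASCII `u` prefix are both
#' accepted; unrecognised units raise an error naming the offending token.
#'
#' @param text a single non-empty quantity string.
#' @return A list with elements `value` (positive numeric) and `unit`
#'   (one of [recognized_units()]).
#' @export
#' @examples
#' parse_quantity("129 uM")
#' parse_quantity("1 nM")
parse_quantity <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(stringr::str_squish(text))) {
    stop("quantity string must be a single non-empty string", call. = FALSE)
  }
  m <- stringr::str_match(
    stringr::str_squish(text),
    "^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\s*(.+)$"
  )
  if (is.na(m[1, 1])) {
    stop("cannot parse quantity: '", text, "'", call. = FALSE)
  }
  value <- as.numeric(m[1, 2])
  unit <- canonical_unit(m[1, 3])
  if (is.na(unit)) {
    stop("unrecognised unit: '", m[1, 3], "'", call. = FALSE)
  }
  if (!is.finite(value) || value <= 0) {
    stop("quantity value must be positive: '", text, "'", call. = FALSE)
  }
  list(value = value, unit = unit)
}

#' Convert a quantity to nanomolar
#'
#' Molar units are rescaled by exact decimal factors. Mass-per-volume units
#' are converted via the molecular weight:
#' `nM = value(mg/L) / MW(g/mol) * 1e6`.
#'
#' @param value numeric value, or a list from [parse_quantity()] (in which
#'   case `unit` is taken from it).
#' @param unit unit string (any spelling accepted by [parse_quantity()]).
#' @param molecular_weight g/mol; required for mass-per-volume units,
#'   ignored for molar units.
#' @return Concentration in nM.
#' @export
#' @examples
#' to_nanomolar(129, "uM")              # 129000
#' to_nanomolar(500, "ng/mL", 500)      # 1000
to_nanomolar <- function(value, unit = NULL, molecular_weight = NA) {
  if (is.list(value)) {
    unit <- value$unit
    value <- value$value
  }
  u <- canonical_unit(unit)
  if (is.na(u)) {
    stop("unrecognised unit: '", unit, "'", call. = FALSE)
  }
  molar <- c(nM = 1, uM = 1e3, mM = 1e6, M = 1e9)
  if (u %in% names(molar)) {
    return(value * unname(molar[u]))
  }
  # mass per volume, expressed in mg/L: ng/mL = 1e-3 mg/L; ug/mL = 1 mg/L
  mass_mgL <- c("ng/mL" = 1e-3, "ug/mL" = 1, "mg/L" = 1, "g/L" = 1e3)
  if (is.na(molecular_weight)) {
    stop("MW required: unit '", u, "' needs a molecular weight", call. = FALSE)
  }
  value * unname(mass_mgL[u]) / molecular_weight * 1e6
}

#' Aggregate multiple reported values
#'
#' Combines several harmonised (nM) values for the same quantity into one,
#' using the median; an even count takes the midpoint of the two central
#' values. An empty input yields `NA` (a missing-data marker), not an error.
#'
#' @param values numeric vector of positive nM concentrations; `NA`s are
#'   dropped first.
#' @return A single nM value, or `NA_real_` when nothing remains.
#' @export
aggregate_values <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    return(NA_real_)
  }
  stats::median(values)
}

# Parse a (possibly ';'-separated) affinity/exposure string to a single
# aggregated nM value; NA when the field is empty/missing.
harmonize_quantity_field <- function(text, molecular_weight = NA) {
  if (is.null(text) || length(text) == 0L || is.na(text) ||
      !nzchar(stringr::str_squish(text))) {
    return(NA_real_)
  }
  parts <- stringr::str_squish(stringr::str_split_1(text, ";"))
  parts <- parts[nzchar(parts)]
  nm <- vapply(parts, function(p) {
    to_nanomolar(parse_quantity(p), molecular_weight = molecular_weight)
  }, numeric(1), USE.NAMES = FALSE)
  aggregate_values(nm)
}
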