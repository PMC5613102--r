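#' Parse lipid shorthand fatty-acid names
#'
#' Parses names in the GC shorthand dialect `"C:Dn-S"` (e.g. `"22:5n-3"`) or
#' `"C:0"` for saturates (e.g. `"24:0"`). Tolerated spelling variants are a
#' space before the series (`"22:5 n-3"`) and a parenthesized series
#' (`"22:5(n-3)"`, `"22:5 (n-3)"`); the canonical rendering is always
#' `"22:5n-3"` / `"24:0"`.
#'
#' Accepted fatty acids have an even carbon number between 12 and 40, at most
#' 6 double bonds, and a series in n-3 / n-6 / n-9. A series suffix on a
#' saturate (zero double bonds) is rejected, as is a polyunsaturated name
#' without a series.
#'
#' @param x Character vector of shorthand names.
#' @return A tibble with one row per input: `fatty_acid` (canonical name),
#'   `carbons`, `double_bonds`, and `series` (one of `"n-3"`, `"n-6"`,
#'   `"n-9"`, `"saturated"`).
#' @examples
#' parse_fa(c("22:5n-3", "24:0", "22:5 (n-3)"))
#' @export
parse_fa <- function(x) {
  if (!is.character(x)) {
    abort("`x` must be a character vector of shorthand fatty-acid names.")
  }
  m <- stringr::str_match(
    x,
    "^\\s*(\\d+)\\s*:\\s*(\\d+)\\s*(?:\\(\\s*n\\s*-\\s*(\\d+)\\s*\\)|n\\s*-\\s*(\\d+))?\\s*$"
  )
  bad <- is.na(x) | is.na(m[, 1])
  if (any(bad)) {
    abort(paste0(
      "Malformed fatty-acid name(s): ",
      paste0("\"", unique(x[bad]), "\"", collapse = ", "),
      ". Expected shorthand like \"22:5n-3\" or \"24:0\"."
    ))
  }
  carbons <- as.integer(m[, 2])
  double_bonds <- as.integer(m[, 3])
  omega <- ifelse(is.na(m[, 4]), m[, 5], m[, 4])
  series <- ifelse(is.na(omega), "saturated", paste0("n-", omega))

  fail <- function(cond, msg) {
    if (any(cond)) {
      abort(paste0(
        msg, ": ", paste0("\"", unique(x[cond]), "\"", collapse = ", "), "."
      ))
    }
  }
  fail(carbons %% 2L != 0L, "Odd carbon count")
  fail(carbons < 12L | carbons > 40L, "Carbon count outside the supported 12-40 range")
  fail(double_bonds > 6L, "More than 6 double bonds")
  fail(double_bonds == 0L & series != "saturated",
       "Series given for a saturated (zero double bond) fatty acid")
  fail(double_bonds > 0L & series == "saturated",
       "Polyunsaturated name lacks an n-series")
  fail(!series %in% c("saturated", "n-3", "n-6", "n-9"),
       "Unsupported n-series (expected n-3, n-6 or n-9)")

  tibble(
    fatty_acid = fa_name(carbons, double_bonds, series),
    carbons = carbons,
    double_bonds = double_bonds,
    series = series
  )
}

fa_name <- function(carbons, double_bonds, series) {
  n <- max(length(carbons), length(double_bonds), length(series))
  carbons <- rep_len(carbons, n)
  double_bonds <- rep_len(double_bonds, n)
  series <- rep_len(series, n)
  ifelse(
    double_bonds == 0L,
    paste0(carbons, ":0"),
    paste0(carbons, ":", double_bonds, series)
  )
}

#' Canonical shorthand for parsed fatty acids
#'
#' The inverse of [parse_fa()]: renders carbons / double bonds / series back
#' into canonical shorthand. Saturates print as `"C:0"` with no series suffix.
#'
#' @param fa A data frame with columns `carbons`, `double_bonds`, `series`
#'   (such as the output of [parse_fa()] or [build_cascade()]).
#' @return Character vector of canonical names.
#' @examples
#' format_fa(parse_fa("22:5 (n-3)"))  # "22:5n-3"
#' @export
format_fa <- function(fa) {
  fa <- check_fa_frame(fa)
  fa_name(fa$carbons, fa$double_bonds, fa$series)
}

check_fa_frame <- function(fa) {
  if (!is.data.frame(fa) ||
      !all(c("carbons", "double_bonds", "series") %in% names(fa))) {
    abort("`fa` must be a data frame with columns carbons, double_bonds, series.")
  }
  # re-validate through the parser so invariants hold everywhere
  parse_fa(fa_name(fa$carbons, fa$double_bonds, fa$series))
}

#' Elongate fatty acids by one +2C step
#'
#' Condensation-cycle elongation adds two carbons and leaves the double-bond
#' count and n-series untouched (the carboxyl end grows, so the methyl-end
#' numbering is preserved).
#'
#' @param x Character vector of shorthand names (any accepted dialect).
#' @return Character vector of canonical names of the +2C products.
#' @examples
#' elongate_fa("22:5n-3")  # "24:5n-3"
#' elongate_fa("26:0")     # "28:0"
#' @export
elongate_fa <- function(x) {
  fa <- parse_fa(x)
  over <- fa$carbons + 2L > 40L
  if (any(over)) {
    abort(paste0(
      "Cannot elongate beyond the supported C40 ceiling: ",
      paste0("\"", unique(x[over]), "\"", collapse = ", "), "."
    ))
  }
  fa_name(fa$carbons + 2L, fa$double_bonds, fa$series)
}

#' Build a +2C elongation cascade
#'
#' An elongation cascade is the ordered chain substrate, substrate + 2C,
#' substrate + 4C, ... produced by iterative elongation; the double-bond count
#' and series are constant along the chain. Position 0 is the supplemented
#' substrate; the chain runs up to `max_carbons`.
#'
#' The default ceiling of 36 carbons matches the longest elongation products
#' typically observed for PUFA substrates in yeast expression assays; pass a
#' lower ceiling when the observed product range stops earlier (e.g. C32 for a
#' 22:6n-3 substrate).
#'
#' @param substrate Shorthand name of the supplemented substrate (scalar).
#' @param max_carbons Even integer ceiling for the longest member
#'   (default 36); must be at least the substrate's carbon number.
#' @return A tibble with columns `position` (0 = substrate), `fatty_acid`,
#'   `carbons`, `double_bonds`, `series`.
#' @examples
#' build_cascade("18:4n-3")               # 18:4n-3 ... 36:4n-3
#' build_cascade("22:6n-3", max_carbons = 32)
#' @export
build_cascade <- function(substrate, max_carbons = 36) {
  if (length(substrate) != 1L) {
    abort("`substrate` must be a single fatty-acid name.")
  }
  fa <- parse_fa(substrate)
  if (length(max_carbons) != 1L || is.na(max_carbons) ||
      max_carbons %% 2 != 0 || max_carbons > 40) {
    abort("`max_carbons` must be a single even integer <= 40.")
  }
  if (max_carbons < fa$carbons) {
    abort(sprintf(
      "`max_carbons` (%d) is below the substrate chain length (%d).",
      as.integer(max_carbons), fa$carbons
    ))
  }
  carbons <- seq.int(fa$carbons, as.integer(max_carbons), by = 2L)
  tibble(
    position = seq_along(carbons) - 1L,
    fatty_acid = fa_name(carbons, fa$double_bonds, fa$series),
    carbons = carbons,
    double_bonds = fa$double_bonds,
    series = fa$series
  )
}
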