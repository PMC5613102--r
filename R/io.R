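peak_cols <- c("sample_id", "treatment", "fatty_acid", "area")

#' Read a FAME peak-area table
#'
#' Reads the UTF-8 CSV dialect `sample_id, treatment, fatty_acid, area`
#' (header required, decimal point). Fatty-acid names are validated through
#' [parse_fa()] and canonicalized; offending rows are reported by file row
#' number. Negative areas and duplicate (sample, fatty acid) entries are
#' rejected.
#'
#' @param path CSV file path.
#' @return A peak-area tibble.
#' @export
read_peak_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(peak_cols %in% names(df))) {
    abort(paste0("`", path, "` must have header columns ",
                 paste(peak_cols, collapse = ", "), "."))
  }
  df$sample_id <- as.character(df$sample_id)
  df$treatment <- as.character(df$treatment)
  df$fatty_acid <- as.character(df$fatty_acid)
  df$area <- suppressWarnings(as.numeric(df$area))
  ok <- purrr::map_lgl(df$fatty_acid, ~ !inherits(try(parse_fa(.x),
                                                      silent = TRUE), "try-error"))
  if (!all(ok)) {
    rows <- which(!ok) + 1L  # +1 for the header line
    abort(paste0(
      "Unrecognized fatty-acid name(s) in ", path, ": ",
      paste(sprintf("\"%s\" (row %d)", df$fatty_acid[!ok], rows),
            collapse = ", "), "."
    ))
  }
  neg <- which(is.na(df$area) | df$area < 0)
  if (length(neg) > 0) {
    abort(paste0("Negative or missing area(s) in ", path, " at row(s) ",
                 paste(neg + 1L, collapse = ", "), "."))
  }
  df$fatty_acid <- parse_fa(df$fatty_acid)$fatty_acid
  check_peak_frame(df[peak_cols])
}

#' Write a peak-area table
#'
#' @param peaks Peak-area tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  peaks <- check_peak_frame(peaks)
  readr::write_csv(peaks, path)
  invisible(path)
}

#' Read qPCR measurement and dilution-series tables
#'
#' `read_qpcr_table()` reads the per-reaction CSV
#' `tissue, sex, fish_id, gene, cq_rep1, cq_rep2` (empty Cq cells are
#' allowed and mark failed/no-template reactions). `read_dilution_series()`
#' reads the standard-curve CSV `gene, copies, cq`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_qpcr_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("tissue", "sex", "fish_id", "gene", "cq_rep1", "cq_rep2")
  if (!all(needed %in% names(df))) {
    abort(paste0("`", path, "` must have header columns ",
                 paste(needed, collapse = ", "), "."))
  }
  df$fish_id <- as.character(df$fish_id)
  df$cq_rep1 <- suppressWarnings(as.numeric(df$cq_rep1))
  df$cq_rep2 <- suppressWarnings(as.numeric(df$cq_rep2))
  df
}

#' @rdname read_qpcr_table
#' @export
read_dilution_series <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("gene", "copies", "cq") %in% names(df))) {
    abort(paste0("`", path, "` must have header columns gene, copies, cq."))
  }
  df
}

#' Write a conversion table as TSV
#'
#' Writes the output of [conversion_table()] (or per-sample
#' [stepwise_conversions()]) as a tab-separated table with conversions
#' printed to one decimal place and not-detected steps printed as `N.D.`,
#' mirroring the usual publication layout. Optional metadata (seed, config)
#' is embedded as `#`-prefixed header lines.
#'
#' @param conversions Conversion tibble.
#' @param path Output TSV path.
#' @param meta Optional named list written as `# name: value` header lines.
#' @return `path`, invisibly.
#' @export
write_conversion_table <- function(conversions, path, meta = NULL) {
  out <- dplyr::mutate(
    conversions,
    conversion = ifelse(.data$not_detected, "N.D.",
                        sprintf("%.1f", .data$conversion))
  ) |>
    dplyr::select(-"not_detected")
  lines <- character()
  if (!is.null(meta)) {
    lines <- sprintf("# %s: %s", names(meta),
                     vapply(meta, function(v) paste(format(v), collapse = " "),
                            character(1)))
  }
  body <- c(
    paste(names(out), collapse = "\t"),
    do.call(paste, c(lapply(out, as.character), sep = "\t"))
  )
  writeLines(c(lines, body), path, useBytes = TRUE)
  invisible(path)
}

#' Write an analysis result as JSON
#'
#' @param x A list or tibble of results.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Read and write FASTA sequences
#'
#' Thin wrappers around Biostrings FASTA IO that work with plain named
#' character vectors. `read_fasta()` accepts nucleotide or protein records.
#'
#' @param path FASTA file path.
#' @param x Named character vector of sequences.
#' @return `read_fasta()`: a named character vector; `write_fasta()`:
#'   `path`, invisibly.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(set)), names(set))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  if (!is.character(x) || is.null(names(x))) {
    abort("`x` must be a named character vector of sequences.")
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path)
  invisible(path)
}
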