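#' Step-wise elongation conversions from FAME peak areas
#'
#' Computes, per sample, the step-wise conversion for every +2C elongation
#' step of a cascade: at step k (substrate = cascade member k − 1),
#'
#' \deqn{conversion_k = 100 \times \frac{\sum_{i \ge k} A_i}{A_{k-1} + \sum_{i \ge k} A_i}}
#'
#' i.e. the areas of the first product and all longer-chain products divided
#' by those same areas plus the step's substrate area. The substrate is
#' redefined at each step, so a conversion is the fraction of the pool
#' reaching a given chain length that is elongated at least one step further.
#'
#' Steps where the substrate and every downstream product are below the
#' detection limit are flagged `not_detected` (the denominator is zero); a
#' step whose substrate is absent while downstream products are present
#' reports 100. Cascade members missing from the table are treated as area 0
#' with a warning. Areas below `lod` are zeroed before the statistic.
#'
#' @param peaks Peak-area tibble with columns `sample_id`, `fatty_acid`,
#'   `area` and optionally `treatment` (see [read_peak_table()]).
#' @param substrate Shorthand name of the supplemented substrate.
#' @param max_carbons Cascade ceiling passed to [build_cascade()].
#' @param lod Detection-limit area threshold; areas strictly below it are
#'   treated as undetected (default 0, i.e. no censoring).
#' @param control Optional treatment label of control samples; when given, a
#'   warning is raised if any cascade *product* is detected in a control
#'   sample (endogenous background the statistic does not subtract).
#' @return A tibble with one row per sample and step: `sample_id`,
#'   `treatment` (if present), `step` (1-based), `substrate`, `product`,
#'   `elongation` (label like `"C18 → 36"`), `conversion` (percent in
#'   \[0, 100\], `NA` when not detected) and `not_detected`.
#' @examples
#' peaks <- tibble::tibble(
#'   sample_id = "s1",
#'   fatty_acid = c("18:4n-3", "20:4n-3", "22:4n-3"),
#'   area = c(60, 30, 10)
#' )
#' stepwise_conversions(peaks, "18:4n-3", max_carbons = 22)
#' @export
stepwise_conversions <- function(peaks, substrate, max_carbons = 36,
                                 lod = 0, control = NULL) {
  peaks <- check_peak_frame(peaks)
  if (length(lod) != 1L || is.na(lod) || lod < 0) {
    abort("`lod` must be a single non-negative area threshold.")
  }
  cascade <- build_cascade(substrate, max_carbons)
  if (nrow(cascade) < 2L) {
    abort("The cascade must have at least 2 members (one elongation step).")
  }

  # canonicalize names so dialect variants match cascade members
  peaks$fatty_acid <- parse_fa(peaks$fatty_acid)$fatty_acid

  if (!is.null(control) && "treatment" %in% names(peaks)) {
    bg <- peaks$treatment %in% control &
      peaks$fatty_acid %in% cascade$fatty_acid[-1] &
      peaks$area >= max(lod, .Machine$double.eps)
    if (any(bg)) {
      warn(paste0(
        "Cascade product(s) detected in control sample(s): ",
        paste(unique(paste0(peaks$sample_id[bg], "/", peaks$fatty_acid[bg])),
              collapse = ", "),
        ". Conversions are not background-subtracted."
      ))
    }
  }

  has_treatment <- "treatment" %in% names(peaks)
  samples <- dplyr::distinct(
    peaks, dplyr::across(dplyr::any_of(c("sample_id", "treatment")))
  )

  missing_any <- FALSE
  out <- purrr::pmap(samples, function(sample_id, treatment = NULL) {
    rows <- peaks[peaks$sample_id == sample_id, ]
    idx <- match(cascade$fatty_acid, rows$fatty_acid)
    if (anyNA(idx)) missing_any <<- TRUE
    areas <- ifelse(is.na(idx), 0, rows$area[idx])
    areas[areas < lod] <- 0
    res <- conversion_steps(areas)
    base <- tibble(
      sample_id = sample_id,
      step = seq_len(nrow(cascade) - 1L),
      substrate = cascade$fatty_acid[-nrow(cascade)],
      product = cascade$fatty_acid[-1L],
      elongation = paste0("C", cascade$carbons[-nrow(cascade)], " → ",
                          max(cascade$carbons)),
      conversion = res$conversion,
      not_detected = res$not_detected
    )
    if (has_treatment) dplyr::mutate(base, treatment = treatment,
                                     .after = "sample_id") else base
  })
  if (missing_any) {
    warn("Some cascade members are absent from the peak table; their areas were taken as 0.")
  }
  dplyr::bind_rows(out)
}

# areas: numeric vector along the cascade (position 0 first), already censored
conversion_steps <- function(areas) {
  n <- length(areas)
  downstream <- rev(cumsum(rev(areas)))  # sum_{i >= k} area_i at index k + 1
  num <- downstream[-1L]
  den <- areas[-n] + num
  nd <- den == 0
  conversion <- ifelse(nd, NA_real_, 100 * num / den)
  list(conversion = conversion, not_detected = nd)
}

check_peak_frame <- function(peaks) {
  if (!is.data.frame(peaks) ||
      !all(c("sample_id", "fatty_acid", "area") %in% names(peaks))) {
    abort("`peaks` must have columns sample_id, fatty_acid, area (and optionally treatment).")
  }
  if (any(is.na(peaks$area)) || any(peaks$area < 0)) {
    abort("Peak areas must be non-negative and non-missing.")
  }
  dup <- duplicated(peaks[c("sample_id", "fatty_acid")])
  if (any(dup)) {
    abort(paste0(
      "Duplicate (sample, fatty acid) entries: ",
      paste(unique(paste0(peaks$sample_id[dup], "/", peaks$fatty_acid[dup])),
            collapse = ", "), "."
    ))
  }
  as_tibble(peaks)
}

#' Summarize per-sample conversions into a publication-style table
#'
#' Averages the per-sample step-wise conversions of [stepwise_conversions()]
#' within treatments, mirroring the usual substrate / product / % conversion /
#' elongation layout. A step is reported as not detected only when it is not
#' detected in every replicate.
#'
#' @param conversions Output of [stepwise_conversions()] (with a `treatment`
#'   column).
#' @return A tibble with `substrate`, `product`, `elongation`, one row per
#'   step, plus `treatment`, `conversion` (mean across replicates, `NA` when
#'   not detected), `n` (replicates averaged) and `not_detected`.
#' @export
conversion_table <- function(conversions) {
  needed <- c("treatment", "step", "substrate", "product", "elongation",
              "conversion", "not_detected")
  if (!is.data.frame(conversions) || !all(needed %in% names(conversions))) {
    abort("`conversions` must be the output of stepwise_conversions() with a treatment column.")
  }
  conversions |>
    dplyr::group_by(.data$treatment, .data$step, .data$substrate,
                    .data$product, .data$elongation) |>
    dplyr::summarise(
      n = sum(!.data$not_detected),
      not_detected = all(.data$not_detected),
      conversion = ifelse(all(.data$not_detected), NA_real_,
                          mean(.data$conversion[!.data$not_detected])),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$treatment, .data$step)
}

#' Bar chart of step-wise conversions
#'
#' @param conversions Output of [stepwise_conversions()] or
#'   [conversion_table()].
#' @return A ggplot object: conversion (%) per elongation step, coloured by
#'   treatment when available; not-detected steps are omitted.
#' @export
plot_conversions <- function(conversions) {
  df <- dplyr::filter(conversions, !.data$not_detected)
  df$product <- factor(df$product, levels = unique(conversions$product))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$product, y = .data$conversion))
  if ("treatment" %in% names(df)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$treatment),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col()
  }
  p +
    ggplot2::labs(x = "Elongation product", y = "Conversion (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
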