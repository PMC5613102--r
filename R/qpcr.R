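AVOGADRO <- 6.02214076e23

# summary.lm warns on exactly collinear points (a legitimate case for
# noiseless dilution series); muffle only that warning
lm_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Plasmid copy number from mass and construct length
#'
#' Converts a measured DNA mass into molecule counts using the double-stranded
#' DNA convention of 660 g/mol per base pair: copies = mass / (660 × length)
#' × Avogadro. Used to turn a quantified, linearized plasmid stock into the
#' known copy numbers of a qPCR dilution series.
#'
#' @param mass_g DNA mass in grams (vectorized).
#' @param length_bp Construct length in base pairs.
#' @return Number of molecules (copies).
#' @examples
#' plasmid_copy_number(1e-9, 4900)  # ~1.86e8 copies from 1 ng
#' @export
plasmid_copy_number <- function(mass_g, length_bp) {
  if (any(is.na(length_bp)) || any(length_bp <= 0)) {
    abort("`length_bp` must be positive.")
  }
  if (any(is.na(mass_g)) || any(mass_g < 0)) {
    abort("`mass_g` must be non-negative.")
  }
  mass_g / (660 * length_bp) * AVOGADRO
}

#' Fit a qPCR standard curve
#'
#' Least-squares regression of Cq on log10(copies) over a serial dilution of
#' known copy numbers. The fitted slope and intercept define absolute
#' quantification ([quantify_copies()]); amplification efficiency is reported
#' as `10^(-1/slope) - 1` (1 = perfect doubling per cycle).
#'
#' @param dilutions Tibble with columns `copies` (known copy numbers, > 0)
#'   and `cq`; an optional `gene` column must contain a single gene (fit one
#'   curve per gene).
#' @return An object of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `gene`, `n_points` and the underlying `lm`
#'   fit. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' d <- tibble::tibble(copies = 10^(2:7), cq = 38 - 3.5 * log10(copies))
#' fit_standard_curve(d)
#' @export
fit_standard_curve <- function(dilutions) {
  if (!is.data.frame(dilutions) ||
      !all(c("copies", "cq") %in% names(dilutions))) {
    abort("`dilutions` must have columns copies and cq (optionally gene).")
  }
  gene <- NA_character_
  if ("gene" %in% names(dilutions)) {
    genes <- unique(dilutions$gene)
    if (length(genes) > 1L) {
      abort(paste0(
        "Standard curves are fit per gene; got ",
        paste(genes, collapse = ", "),
        ". Split the dilution series by gene first."
      ))
    }
    gene <- genes
  }
  if (any(is.na(dilutions$copies)) || any(dilutions$copies <= 0)) {
    abort("Known copy numbers must be positive (zero-copy points cannot be log-transformed).")
  }
  if (length(unique(dilutions$copies)) < 3L) {
    abort("At least 3 distinct dilution points are required.")
  }
  df <- tibble(log10_copies = log10(dilutions$copies), cq = dilutions$cq)
  fit <- lm(cq ~ log10_copies, data = df)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    warn("Fitted slope is non-negative; the assay is not a valid dilution series.")
  }
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[1]),
      r_squared = lm_summary(fit)$r.squared,
      efficiency = 10^(-1 / slope) - 1,
      gene = gene,
      n_points = nrow(df),
      model = fit
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve",
      if (!is.na(x$gene)) paste0("(", x$gene, ")"), "\n")
  cat(sprintf("  Cq = %.4f %+.4f x log10(copies)\n", x$intercept, x$slope))
  cat(sprintf("  r^2 = %.4f, efficiency = %.1f%%, n = %d points\n",
              x$r_squared, 100 * x$efficiency, x$n_points))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x,object A `standard_curve`.
#' @param ... Unused.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  s <- lm_summary(x$model)$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = unname(s[, "Estimate"]),
    std_error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p_value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname fit_standard_curve
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(
    gene = x$gene, slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, efficiency = x$efficiency,
    n_points = x$n_points
  )
}

#' @rdname fit_standard_curve
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  df <- object$model$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_copies, y = .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10(copies)", y = "Cq",
      title = if (!is.na(object$gene)) object$gene else NULL,
      subtitle = sprintf("slope %.3f, r² %.4f, efficiency %.1f%%",
                         object$slope, object$r_squared,
                         100 * object$efficiency)
    ) +
    ggplot2::theme_minimal()
}

#' Absolute copy number from a Cq value
#'
#' Inverts a standard curve: copies = 10^((cq − intercept) / slope).
#'
#' @param cq Cq values (vectorized; `NA` propagates).
#' @param curve A [fit_standard_curve()] object with negative slope.
#' @return Absolute copy numbers.
#' @export
quantify_copies <- function(cq, curve) {
  if (!inherits(curve, "standard_curve")) {
    abort("`curve` must be a standard_curve object.")
  }
  if (curve$slope >= 0) {
    abort("Quantification requires a negative standard-curve slope.")
  }
  10^((cq - curve$intercept) / curve$slope)
}

#' Reference-gene normalized expression
#'
#' Normalized ratio = absolute target copies / absolute reference copies in
#' the same sample. Samples with zero reference copies get `NA` with a
#' warning (the ratio is undefined).
#'
#' @param target_copies,reference_copies Absolute copy numbers (vectorized).
#' @return Dimensionless ratios.
#' @export
normalize_expression <- function(target_copies, reference_copies) {
  if (any(target_copies < 0, na.rm = TRUE) ||
      any(reference_copies < 0, na.rm = TRUE)) {
    abort("Copy numbers must be non-negative.")
  }
  zero <- !is.na(reference_copies) & reference_copies == 0
  if (any(zero)) {
    warn(sprintf(
      "%d sample(s) have zero reference copies; their ratios are undefined (NA).",
      sum(zero)
    ))
  }
  ifelse(zero, NA_real_, target_copies / reference_copies)
}

#' Absolute quantification pipeline for a qPCR experiment
#'
#' Runs the full absolute-quantification workflow: fits a standard curve per
#' gene from the dilution series, averages duplicate Cq values on the Cq
#' scale, converts Cq to absolute copies, and normalizes each target gene by
#' the reference gene within the same (tissue, sex, fish) sample. Samples in
#' which neither duplicate amplified (both Cq missing) are treated as
#' no-template flags and dropped with a warning.
#'
#' @param measurements Tibble with columns `tissue`, `sex`, `fish_id`,
#'   `gene`, `cq_rep1`, `cq_rep2` (see [read_qpcr_table()]).
#' @param dilutions Tibble with columns `gene`, `copies`, `cq`
#'   (see [read_dilution_series()]).
#' @param reference Name of the reference gene (default `"28S"`).
#' @return A tibble with one row per sample and target gene: `tissue`, `sex`,
#'   `fish_id`, `gene`, `cq` (duplicate mean), `copies`,
#'   `reference_copies` and `ratio`.
#' @export
qpcr_quantify <- function(measurements, dilutions, reference = "28S") {
  needed <- c("tissue", "sex", "fish_id", "gene", "cq_rep1", "cq_rep2")
  if (!is.data.frame(measurements) || !all(needed %in% names(measurements))) {
    abort(paste0("`measurements` must have columns ",
                 paste(needed, collapse = ", "), "."))
  }
  if (!reference %in% measurements$gene) {
    abort(sprintf("Reference gene \"%s\" is absent from the measurements.", reference))
  }
  genes <- unique(measurements$gene)
  missing_curve <- setdiff(genes, unique(dilutions$gene))
  if (length(missing_curve) > 0) {
    abort(paste0("No dilution series for gene(s): ",
                 paste(missing_curve, collapse = ", "), "."))
  }
  curves <- dilutions |>
    dplyr::filter(.data$gene %in% genes) |>
    (\(d) split(d, d$gene))() |>
    purrr::map(fit_standard_curve)

  meas <- as_tibble(measurements)
  ntc <- is.na(meas$cq_rep1) & is.na(meas$cq_rep2)
  if (any(ntc)) {
    warn(sprintf("%d reaction(s) with no amplification in either duplicate were flagged and dropped.",
                 sum(ntc)))
    meas <- meas[!ntc, ]
  }
  meas <- meas |>
    dplyr::mutate(
      cq = rowMeans(cbind(.data$cq_rep1, .data$cq_rep2), na.rm = TRUE),
      copies = purrr::map2_dbl(.data$cq, .data$gene,
                               ~ quantify_copies(.x, curves[[.y]]))
    )

  ref <- meas |>
    dplyr::filter(.data$gene == reference) |>
    dplyr::select("tissue", "sex", "fish_id", reference_copies = "copies")
  meas |>
    dplyr::filter(.data$gene != reference) |>
    dplyr::inner_join(ref, by = c("tissue", "sex", "fish_id")) |>
    dplyr::mutate(ratio = normalize_expression(.data$copies,
                                               .data$reference_copies)) |>
    dplyr::select("tissue", "sex", "fish_id", "gene", "cq", "copies",
                  "reference_copies", "ratio")
}

#' Per-tissue expression summary with Tukey letters
#'
#' Summarizes normalized expression ratios per tissue (mean ± SE over fish)
#' and tests for differences among tissues with one-way ANOVA followed by
#' Tukey HSD, reporting compact letters per tissue. When several target
#' genes are present each gene is analyzed independently.
#'
#' @param ratios Output of [qpcr_quantify()] (columns `tissue`, `gene`,
#'   `ratio`; one row per fish).
#' @param alpha Significance level (default 0.05).
#' @return A `group_comparison` (see [compare_groups()]).
#' @export
tissue_summary <- function(ratios, alpha = 0.05) {
  if (!is.data.frame(ratios) ||
      !all(c("tissue", "gene", "ratio") %in% names(ratios))) {
    abort("`ratios` must have columns tissue, gene and ratio.")
  }
  compare_groups(ratios, "ratio", "tissue", by = "gene", alpha = alpha)
}
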