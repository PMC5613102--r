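#' Very long-chain saturated fatty-acid area percentages
#'
#' Expresses each qualifying saturate (zero double bonds, `carbons >=
#' min_carbons`) as a percentage of the total qualifying saturated area in
#' the same sample — the normalization used to compare VLC-SFA profiles of
#' control and transgenic yeast.
#'
#' @param peaks Peak-area tibble (`sample_id`, `fatty_acid`, `area`,
#'   optionally `treatment`).
#' @param min_carbons Minimum chain length to qualify (default 24).
#' @return A tibble with `sample_id`, `treatment` (if present), `fatty_acid`,
#'   `carbons` and `percent`; percentages sum to 100 within each sample.
#'   Samples whose qualifying areas are all zero are dropped with a warning.
#' @examples
#' peaks <- tibble::tibble(
#'   sample_id = "y1",
#'   fatty_acid = c("24:0", "26:0", "28:0"),
#'   area = c(2, 46, 2)
#' )
#' sfa_percentages(peaks)
#' @export
sfa_percentages <- function(peaks, min_carbons = 24) {
  peaks <- check_peak_frame(peaks)
  fa <- parse_fa(peaks$fatty_acid)
  peaks$fatty_acid <- fa$fatty_acid
  keep <- fa$double_bonds == 0L & fa$carbons >= min_carbons
  if (!any(keep)) {
    abort(sprintf(
      "No saturated fatty acids with >= %d carbons in the peak table.",
      as.integer(min_carbons)
    ))
  }
  qual <- dplyr::mutate(peaks[keep, ], carbons = fa$carbons[keep])

  totals <- qual |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$area), .groups = "drop")
  empty <- totals$sample_id[totals$total == 0]
  if (length(empty) > 0) {
    warn(paste0(
      "Sample(s) with all qualifying areas zero dropped from the profile: ",
      paste(empty, collapse = ", "), "."
    ))
  }

  qual |>
    dplyr::inner_join(totals[totals$total > 0, ], by = "sample_id") |>
    dplyr::mutate(percent = 100 * .data$area / .data$total) |>
    dplyr::select(dplyr::any_of(c("sample_id", "treatment")),
                  "fatty_acid", "carbons", "percent") |>
    dplyr::arrange(.data$sample_id, .data$carbons)
}

#' Compare groups with one-way ANOVA, Tukey HSD and compact letters
#'
#' For each level of `by` (e.g. each fatty acid, or a single level when `by`
#' is omitted), computes per-group mean and standard error, a one-way ANOVA,
#' all Tukey HSD pairwise comparisons at level `alpha`, and a compact letter
#' display (insert-and-absorb): groups sharing a letter do not differ
#' (Tukey p > alpha); groups sharing no letter differ (p <= alpha). Letters
#' are assigned in order of descending group mean.
#'
#' @param data A tibble of replicate-level values.
#' @param value Unquoted column holding the response (e.g. `percent`,
#'   `ratio`).
#' @param group Unquoted grouping column (e.g. `treatment`, `tissue`).
#' @param by Optional unquoted column splitting the data into independent
#'   comparisons (e.g. `fatty_acid`, `gene`).
#' @param alpha Significance level for Tukey HSD (default 0.05).
#' @return An object of class `group_comparison` with components `summary`
#'   (per by-level and group: `mean`, `se`, `n`, `letters`), `anova`
#'   (per by-level F and p), `tukey` (pairwise Tukey-adjusted p-values) and
#'   `alpha`. Use [tidy()] / [glance()] / [autoplot()] on it.
#' @examples
#' set.seed(1)
#' d <- tidyr::expand_grid(treatment = c("control", "elovl4a"), rep = 1:4)
#' d$percent <- ifelse(d$treatment == "control", 1, 4) + rnorm(8, sd = 0.3)
#' compare_groups(d, percent, treatment)
#' @export
compare_groups <- function(data, value, group, by = NULL, alpha = 0.05) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1.")
  }
  value <- enquo(value); group <- enquo(group); by <- enquo(by)
  has_by <- !rlang::quo_is_null(by)
  df <- tibble(
    value = dplyr::pull(data, !!value),
    group = as.character(dplyr::pull(data, !!group)),
    by = if (has_by) as.character(dplyr::pull(data, !!by)) else "all"
  )
  if (any(is.na(df$value))) abort("Response values must not be missing.")

  pieces <- split(df, df$by)
  fitted <- purrr::map(pieces, tukey_cld_one, alpha = alpha)
  by_name <- if (has_by) as_name(by) else NULL

  relabel <- function(field) {
    tab <- dplyr::bind_rows(purrr::map(fitted, field), .id = "by_level")
    if (has_by) dplyr::rename(tab, !!by_name := "by_level")
    else dplyr::select(tab, -"by_level")
  }
  structure(
    list(
      summary = relabel("summary"), anova = relabel("anova"),
      tukey = relabel("tukey"), alpha = alpha,
      value_name = as_name(value), group_name = as_name(group),
      by_name = by_name
    ),
    class = "group_comparison"
  )
}

tukey_cld_one <- function(df, alpha) {
  counts <- table(df$group)
  if (length(counts) < 2L) {
    abort("At least 2 groups are required for a comparison.")
  }
  if (any(counts < 2L)) {
    abort(paste0(
      "Group(s) with a single replicate cannot be compared: ",
      paste(names(counts)[counts < 2L], collapse = ", "), "."
    ))
  }
  df$group <- factor(df$group)
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
  # TukeyHSD rows follow combn(levels, 2) with names "second-first"; rebuild
  # the pairs instead of splitting row names (labels may contain "-")
  cmb <- utils::combn(levels(df$group), 2)
  stopifnot(identical(rownames(tk), paste(cmb[2, ], cmb[1, ], sep = "-")))
  pairs <- cbind(cmb[2, ], cmb[1, ])

  summary_tab <- df |>
    dplyr::group_by(group = as.character(.data$group)) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      se = sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean))

  p_adj <- setNames(tk[, "p adj"], rownames(tk))
  distinct_pairs <- cbind(pairs[p_adj <= alpha, 1], pairs[p_adj <= alpha, 2])
  letters_tab <- compact_letters(summary_tab$group, distinct_pairs)

  list(
    summary = dplyr::mutate(
      summary_tab, letters = letters_tab[.data$group]
    ),
    anova = tibble(
      statistic = an[["F value"]][1],
      df = an[["Df"]][1], df_residual = an[["Df"]][2],
      p_value = an[["Pr(>F)"]][1]
    ),
    tukey = tibble(
      group1 = pairs[, 1], group2 = pairs[, 2],
      diff = tk[, "diff"], p_adj = unname(p_adj)
    )
  )
}

# Insert-and-absorb compact letter display.
# groups: ordered by descending mean; distinct_pairs: 2-column matrix of
# group pairs declared different. Returns named character vector of letters.
compact_letters <- function(groups, distinct_pairs) {
  cols <- list(groups)  # start with one letter covering every group
  if (!is.null(distinct_pairs) && nrow(distinct_pairs) > 0) {
    for (i in seq_len(nrow(distinct_pairs))) {
      g1 <- distinct_pairs[i, 1]; g2 <- distinct_pairs[i, 2]
      hit <- which(purrr::map_lgl(cols, ~ g1 %in% .x && g2 %in% .x))
      for (j in hit) {
        both <- cols[[j]]
        cols[[j]] <- setdiff(both, g1)       # duplicate, dropping one member
        cols <- c(cols, list(setdiff(both, g2)))
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && keep[a] &&
              all(cols[[a]] %in% cols[[b]]) &&
              (length(cols[[a]]) < length(cols[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- cols[keep]
    }
  }
  # order columns by the best-ranked member so 'a' goes to the top group
  ranks <- purrr::map_int(cols, ~ min(match(.x, groups)))
  cols <- cols[order(ranks)]
  out <- setNames(rep("", length(groups)), groups)
  for (j in seq_along(cols)) {
    members <- cols[[j]]
    out[members] <- paste0(out[members], letters[j])
  }
  vapply(out, function(s) paste(sort(strsplit(s, "")[[1]]), collapse = ""),
         character(1))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (one-way ANOVA + Tukey HSD, alpha =", x$alpha, ")\n")
  cat("Response:", x$value_name, " Groups:", x$group_name,
      if (!is.null(x$by_name)) paste(" By:", x$by_name) else "", "\n\n")
  print(x$summary, ...)
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [compare_groups()] or
#'   [tissue_summary()].
#' @param ... Unused.
#' @return The per-group summary tibble (`mean`, `se`, `n`, `letters`).
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$summary

#' One-row-per-comparison ANOVA summary of a group comparison
#'
#' @inheritParams tidy.group_comparison
#' @return The ANOVA tibble (F statistic, degrees of freedom, p-value) with
#'   the Tukey significance level attached as an `alpha` column.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  dplyr::mutate(x$anova, alpha = x$alpha)
}

#' Plot a group comparison as mean ± SE bars with compact letters
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- object$summary
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey65") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.25
    ) +
    ggplot2::geom_text(
      ggplot2::aes(y = .data$mean + .data$se, label = .data$letters),
      vjust = -0.6
    ) +
    ggplot2::labs(x = object$group_name,
                  y = paste0(object$value_name, " (mean ± SE)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(object$by_name)) {
    p <- p + ggplot2::facet_wrap(object$by_name, scales = "free_y")
  }
  p
}
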