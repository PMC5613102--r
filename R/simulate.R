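#' Simulate FAME peak areas for an elongation cascade
#'
#' Generates per-sample peak areas under a sequential irreversible
#' elongation model with known per-step conversion fractions: of the
#' material reaching cascade node k − 1, a fraction `step_fractions[k]` is
#' elongated to node k. At steady state the amount at node k is
#' `a0 * prod(e[1:k]) * (1 - e[k + 1])` (with `e` beyond the last step 0),
#' so amounts sum to `a0` and [stepwise_conversions()] applied to the
#' noiseless table returns exactly `100 * step_fractions`.
#'
#' Multiplicative lognormal noise (sdlog = `noise_sigma`, median 1) models
#' chromatographic area variation; areas below `lod` are reported as 0,
#' emulating peaks lost under the detection limit.
#'
#' @param substrate Shorthand name of the supplemented substrate.
#' @param step_fractions Per-step conversion fractions in `[0, 1)`; the
#'   cascade ceiling is `substrate carbons + 2 * length(step_fractions)`.
#' @param a0 Total substrate amount entering the cascade (arbitrary area
#'   units, default 100).
#' @param noise_sigma Lognormal sdlog of multiplicative area noise
#'   (default 0 = noiseless).
#' @param lod Detection limit: simulated areas below it become 0.
#' @param seed Integer seed (required; identical seeds give identical
#'   tables).
#' @param n_samples Number of replicate samples (default 1).
#' @param treatment Treatment label for the generated samples.
#' @return A peak-area tibble (`sample_id`, `treatment`, `fatty_acid`,
#'   `area`) consumable by [stepwise_conversions()].
#' @examples
#' simulate_cascade_areas("18:4n-3", c(0.5, 0.25), seed = 1)
#' @export
simulate_cascade_areas <- function(substrate, step_fractions, a0 = 100,
                                   noise_sigma = 0, lod = 0, seed,
                                   n_samples = 1, treatment = "transgenic") {
  if (missing(seed)) abort("`seed` is required for reproducible simulation.")
  if (length(step_fractions) < 1L || any(is.na(step_fractions)) ||
      any(step_fractions < 0) || any(step_fractions >= 1)) {
    abort("`step_fractions` must lie in [0, 1).")
  }
  if (a0 <= 0) abort("`a0` must be positive.")
  if (noise_sigma < 0 || lod < 0) {
    abort("`noise_sigma` and `lod` must be non-negative.")
  }
  fa <- parse_fa(substrate)
  cascade <- build_cascade(substrate,
                           fa$carbons + 2L * length(step_fractions))
  amounts <- cascade_amounts(a0, step_fractions)

  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_samples), function(i) {
      area <- amounts *
        stats::rlnorm(length(amounts), meanlog = 0, sdlog = noise_sigma)
      area[area < lod] <- 0
      tibble(
        sample_id = sprintf("%s_%d", treatment, i),
        treatment = treatment,
        fatty_acid = cascade$fatty_acid,
        area = area
      )
    })
  })
}

# noiseless node amounts of the sequential irreversible model
cascade_amounts <- function(a0, e) {
  reach <- a0 * cumprod(c(1, e))   # material reaching node 0..n
  stay <- 1 - c(e, 0)              # fraction not elongated further
  reach * stay
}

#' Simulate control vs transgenic VLC-SFA profiles
#'
#' Emulates the saturated fatty-acid comparison of an elongase expression
#' assay: control replicates scatter around a baseline VLC-SFA area profile,
#' and each transgenic treatment multiplies selected (typically longer)
#' saturates by boost factors, shifting mass toward longer chain lengths.
#' Replicate variation is multiplicative lognormal with coefficient of
#' variation `cv`.
#'
#' @param baseline Named numeric vector of baseline areas for saturates
#'   (names like `"24:0"`, carbons >= 24).
#' @param boosts Named list: one element per transgenic treatment, each a
#'   named numeric vector of multiplicative boost factors for a subset of
#'   the baseline fatty acids (unlisted fatty acids keep factor 1). Use
#'   factor 1 everywhere for a null treatment.
#' @param n_replicates Cultures per group (default 4).
#' @param cv Coefficient of variation of replicate noise (default 0.05).
#' @param seed Integer seed (required).
#' @return A peak-area tibble covering the control group and every
#'   treatment, consumable by [sfa_percentages()] and [compare_groups()].
#' @examples
#' simulate_sfa_profiles(
#'   baseline = c("24:0" = 1.2, "26:0" = 23.5, "28:0" = 1.0),
#'   boosts = list(elovl4a = c("28:0" = 4)),
#'   seed = 1
#' )
#' @export
simulate_sfa_profiles <- function(baseline, boosts = list(),
                                  n_replicates = 4, cv = 0.05, seed) {
  if (missing(seed)) abort("`seed` is required for reproducible simulation.")
  if (is.null(names(baseline)) || any(baseline < 0)) {
    abort("`baseline` must be a named vector of non-negative areas.")
  }
  if (cv < 0) abort("`cv` must be non-negative.")
  bad_boost <- purrr::map_lgl(boosts, ~ any(.x < 0))
  if (any(bad_boost)) abort("Boost factors must be non-negative.")
  unknown <- purrr::map(boosts, ~ setdiff(names(.x), names(baseline)))
  if (any(lengths(unknown) > 0)) {
    abort(paste0("Boost factors for fatty acids absent from the baseline: ",
                 paste(unique(unlist(unknown)), collapse = ", "), "."))
  }
  parse_fa(names(baseline))  # validate names early
  sdlog <- sqrt(log(1 + cv^2))

  groups <- c(list(control = setNames(rep(1, length(baseline)),
                                      names(baseline))),
              boosts)
  withr::with_seed(seed, {
    purrr::imap_dfr(groups, function(boost, treatment) {
      mult <- setNames(rep(1, length(baseline)), names(baseline))
      mult[names(boost)] <- boost
      purrr::map_dfr(seq_len(n_replicates), function(i) {
        tibble(
          sample_id = sprintf("%s_%d", treatment, i),
          treatment = treatment,
          fatty_acid = names(baseline),
          area = unname(baseline * mult *
                          stats::rlnorm(length(baseline), 0, sdlog))
        )
      })
    })
  })
}

#' Simulate a qPCR experiment with known ground truth
#'
#' Generates the two tables an absolute-quantification run consumes: a
#' dilution series computed exactly from each gene's true standard curve,
#' and per-fish duplicate Cq measurements with Gaussian Cq noise around the
#' curve value at each tissue's true copy number. With `cq_sd = 0` the full
#' pipeline ([qpcr_quantify()]) recovers the true ratios exactly.
#'
#' @param curves Tibble with columns `gene`, `slope` (< 0), `intercept`.
#' @param tissue_truth Tibble with columns `tissue`, `gene`, `copies` (true
#'   per-reaction copy numbers); every gene in `curves` must appear for
#'   every tissue.
#' @param cq_sd Gaussian noise sd on each Cq replicate (default 0.2).
#' @param n_fish Fish per tissue (default 4; sexes alternate F/M).
#' @param dilution_log10 log10 copy numbers of the dilution series
#'   (default `2:8`).
#' @param seed Integer seed (required).
#' @return A list with `dilutions` (`gene`, `copies`, `cq`) and
#'   `measurements` (`tissue`, `sex`, `fish_id`, `gene`, `cq_rep1`,
#'   `cq_rep2`).
#' @export
simulate_qpcr <- function(curves, tissue_truth, cq_sd = 0.2, n_fish = 4,
                          dilution_log10 = 2:8, seed) {
  if (missing(seed)) abort("`seed` is required for reproducible simulation.")
  if (!is.data.frame(curves) ||
      !all(c("gene", "slope", "intercept") %in% names(curves))) {
    abort("`curves` must have columns gene, slope, intercept.")
  }
  if (any(curves$slope >= 0)) {
    abort("Standard-curve slopes must be negative.")
  }
  if (!is.data.frame(tissue_truth) ||
      !all(c("tissue", "gene", "copies") %in% names(tissue_truth))) {
    abort("`tissue_truth` must have columns tissue, gene, copies.")
  }
  if (any(tissue_truth$copies <= 0)) {
    abort("True copy numbers must be positive.")
  }
  if (cq_sd < 0) abort("`cq_sd` must be non-negative.")
  if (n_fish < 1) abort("`n_fish` must be at least 1.")
  full <- tidyr::expand_grid(tissue = unique(tissue_truth$tissue),
                             gene = curves$gene)
  if (nrow(dplyr::anti_join(full, tissue_truth,
                            by = c("tissue", "gene"))) > 0) {
    abort("`tissue_truth` must give copies for every gene in every tissue.")
  }

  dilutions <- tidyr::expand_grid(gene = curves$gene,
                                  log10_copies = dilution_log10) |>
    dplyr::inner_join(curves, by = "gene") |>
    dplyr::mutate(
      copies = 10^.data$log10_copies,
      cq = .data$intercept + .data$slope * .data$log10_copies
    ) |>
    dplyr::select("gene", "copies", "cq")

  design <- tidyr::expand_grid(
    dplyr::inner_join(tissue_truth, curves, by = "gene"),
    fish = seq_len(n_fish)
  ) |>
    dplyr::mutate(
      true_cq = .data$intercept + .data$slope * log10(.data$copies),
      sex = c("F", "M")[(.data$fish - 1) %% 2 + 1],
      fish_id = sprintf("fish_%d", .data$fish)
    )
  measurements <- withr::with_seed(seed, {
    dplyr::mutate(
      design,
      cq_rep1 = .data$true_cq + rnorm(dplyr::n(), 0, cq_sd),
      cq_rep2 = .data$true_cq + rnorm(dplyr::n(), 0, cq_sd)
    )
  }) |>
    dplyr::select("tissue", "sex", "fish_id", "gene", "cq_rep1", "cq_rep2")

  list(dilutions = dilutions, measurements = measurements)
}
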