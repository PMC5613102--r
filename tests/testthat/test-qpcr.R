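exact_dilution <- function(slope, intercept, log10_range = 2:7,
                           gene = NULL) {
  d <- tibble::tibble(copies = 10^log10_range,
                      cq = intercept + slope * log10_range)
  if (!is.null(gene)) d$gene <- gene
  d
}

test_that("plasmid copy numbers follow the 660 g/bp convention", {
  # oracle: 1e-9 / (660 * 4900) * 6.02214076e23
  expect_equal(plasmid_copy_number(1e-9, 4900), 186213385.3, tolerance = 1e-7)
  expect_equal(plasmid_copy_number(0, 4900), 0)
  expect_equal(plasmid_copy_number(2e-9, 4900),
               2 * plasmid_copy_number(1e-9, 4900))
  expect_equal(plasmid_copy_number(1e-9, 9800),
               plasmid_copy_number(1e-9, 4900) / 2)
  expect_error(plasmid_copy_number(1e-9, 0), "positive")
  expect_error(plasmid_copy_number(-1e-9, 100), "non-negative")
})

test_that("standard curves recover exact parameters from collinear points", {
  sc <- fit_standard_curve(exact_dilution(-3.5, 38))
  expect_equal(sc$slope, -3.5)
  expect_equal(sc$intercept, 38)
  expect_equal(sc$r_squared, 1)

  # order invariance
  shuffled <- exact_dilution(-3.5, 38)[sample(6), ]
  sc2 <- fit_standard_curve(shuffled)
  expect_equal(sc2$slope, sc$slope)
  expect_equal(sc2$intercept, sc$intercept)

  # slope -log10(2)^-1 corresponds to 100% efficiency
  sc3 <- fit_standard_curve(exact_dilution(-1 / log10(2), 36))
  expect_equal(sc3$efficiency, 1, tolerance = 1e-9)

  expect_error(fit_standard_curve(exact_dilution(-3.5, 38)[1:2, ]),
               "3 distinct")
  expect_error(
    fit_standard_curve(tibble::tibble(copies = c(0, 10, 100), cq = 30:28)),
    "positive"
  )
  expect_error(
    fit_standard_curve(dplyr::bind_rows(exact_dilution(-3.5, 38, gene = "a"),
                                        exact_dilution(-3.3, 35, gene = "b"))),
    "per gene"
  )
})

test_that("tidy/glance expose the curve fit in broom style", {
  sc <- fit_standard_curve(exact_dilution(-3.5, 38))
  td <- tidy(sc)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate, c(38, -3.5))
  gl <- glance(sc)
  expect_equal(gl$r_squared, 1)
  expect_s3_class(autoplot(sc), "ggplot")
})

test_that("quantification inverts the curve", {
  sc <- fit_standard_curve(exact_dilution(-3.5, 38))
  expect_equal(quantify_copies(38, sc), 1)
  # training points are recovered exactly
  expect_equal(quantify_copies(exact_dilution(-3.5, 38)$cq, sc),
               exact_dilution(-3.5, 38)$copies)
  # 3.5 fewer cycles = 10x more template
  expect_equal(quantify_copies(24.5 - 3.5, sc),
               10 * quantify_copies(24.5, sc))
  bad <- fit_standard_curve(exact_dilution(-3.5, 38))
  bad$slope <- 1
  expect_error(quantify_copies(30, bad), "negative")
})

test_that("normalization is the target/reference copy ratio", {
  expect_equal(normalize_expression(5, 5), 1)
  expect_equal(normalize_expression(2e5, 4e7), 5e-3)
  expect_equal(normalize_expression(3 * 2e5, 3 * 4e7), 5e-3)  # scale invariance
  expect_warning(r <- normalize_expression(c(1, 2), c(4, 0)), "zero reference")
  expect_equal(r, c(0.25, NA))
})

test_that("the noiseless pipeline returns true ratios exactly", {
  curves <- tibble::tibble(gene = c("elovl4a", "28S"),
                           slope = c(-3.4, -3.2), intercept = c(37, 30))
  truth <- tidyr::expand_grid(tissue = c("brain", "liver", "pituitary"),
                              gene = c("elovl4a", "28S")) |>
    dplyr::mutate(copies = c(2e4, 4e7, 50, 4e7, 1e5, 4e7))
  sim <- simulate_qpcr(curves, truth, cq_sd = 0, seed = 42)
  got <- qpcr_quantify(sim$measurements, sim$dilutions, reference = "28S")
  want <- truth |>
    tidyr::pivot_wider(names_from = gene, values_from = copies) |>
    dplyr::mutate(true_ratio = elovl4a / `28S`)
  merged <- dplyr::inner_join(got, want, by = "tissue")
  expect_equal(merged$ratio, merged$true_ratio, tolerance = 1e-6)
  # equal target and reference copies give ratio 1
  eq <- tidyr::expand_grid(tissue = "t", gene = c("elovl4a", "28S")) |>
    dplyr::mutate(copies = 1e6)
  sim2 <- simulate_qpcr(curves, eq, cq_sd = 0, seed = 1)
  expect_equal(
    unique(qpcr_quantify(sim2$measurements, sim2$dilutions)$ratio), 1,
    tolerance = 1e-9
  )
})

test_that("duplicates are averaged on the Cq scale and NTC-like rows are dropped", {
  curves <- tibble::tibble(gene = c("tg", "28S"), slope = c(-3.5, -3.5),
                           intercept = c(38, 38))
  sim <- simulate_qpcr(curves,
                       tidyr::expand_grid(tissue = "t", gene = c("tg", "28S")) |>
                         dplyr::mutate(copies = c(1e4, 1e6)),
                       cq_sd = 0, n_fish = 2, seed = 3)
  m <- sim$measurements
  m$cq_rep1[1] <- m$cq_rep1[1] - 1
  m$cq_rep2[1] <- m$cq_rep2[1] + 1  # mean unchanged
  got <- qpcr_quantify(m, sim$dilutions)
  expect_equal(got$ratio, rep(1e4 / 1e6, 2), tolerance = 1e-9)

  m2 <- sim$measurements
  m2$cq_rep1[1] <- NA
  m2$cq_rep2[1] <- NA
  expect_warning(got2 <- qpcr_quantify(m2, sim$dilutions), "flagged")
  expect_equal(nrow(got2), 1L)
})

test_that("tissue summaries separate a strongly expressed tissue and reuse Tukey letters", {
  curves <- tibble::tibble(gene = c("elovl4b", "28S"),
                           slope = c(-3.3, -3.3), intercept = c(36, 29))
  truth <- tidyr::expand_grid(
    tissue = c("gonad", "liver", "muscle"), gene = c("elovl4b", "28S")
  ) |>
    dplyr::mutate(copies = dplyr::case_when(
      gene == "28S" ~ 2e7,
      tissue == "gonad" ~ 5e5,
      .default = 1e4
    ))
  sim <- simulate_qpcr(curves, truth, cq_sd = 0.05, n_fish = 4, seed = 12)
  ratios <- qpcr_quantify(sim$measurements, sim$dilutions)
  summ <- tissue_summary(ratios)
  tt <- tidy(summ)
  gonad_letter <- tt$letters[tt$group == "gonad"]
  expect_false(gonad_letter %in% tt$letters[tt$group != "gonad"])

  # identical tissues share a single letter
  truth_eq <- tidyr::expand_grid(tissue = c("a", "b", "c"),
                                 gene = c("elovl4b", "28S")) |>
    dplyr::mutate(copies = ifelse(gene == "28S", 2e7, 1e5))
  sim_eq <- simulate_qpcr(curves, truth_eq, cq_sd = 0.05, n_fish = 4, seed = 5)
  tt_eq <- tidy(tissue_summary(qpcr_quantify(sim_eq$measurements,
                                             sim_eq$dilutions)))
  expect_equal(unique(tt_eq$letters), "a")
})

test_that("the reported SE is sd/sqrt(n): quadrupling replicates halves it", {
  vals <- c(1.0, 1.2, 0.9, 1.1)
  dat <- tibble::tibble(tissue = "t", gene = "g",
                        ratio = vals)
  dat2 <- tibble::tibble(tissue = "t", gene = "g",
                         ratio = rep(vals, 4))
  other <- tibble::tibble(tissue = "u", gene = "g", ratio = c(2, 2.1, 1.9, 2))
  se1 <- tidy(tissue_summary(dplyr::bind_rows(dat, other)))
  se2 <- tidy(tissue_summary(dplyr::bind_rows(dat2, other)))
  expect_equal(se1$se[se1$group == "t"], sd(vals) / sqrt(4))
  # sample sd shifts slightly under duplication; SE halves up to that factor:
  # var(rep(x, 4)) = 4 * 3 * var(x) / 15
  expect_equal(se2$se[se2$group == "t"],
               se1$se[se1$group == "t"] / 2 * sqrt(12 / 15))

  lonely <- tibble::tibble(tissue = c("t", "t", "u"), gene = "g",
                           ratio = c(1, 2, 3))
  expect_error(tissue_summary(lonely), "u")
})
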