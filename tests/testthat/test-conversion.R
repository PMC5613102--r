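peaks3 <- function(areas) {
  tibble::tibble(
    sample_id = "s1", treatment = "t",
    fatty_acid = c("18:4n-3", "20:4n-3", "22:4n-3"),
    area = areas
  )
}

test_that("the step-wise conversion matches hand evaluation of the formula", {
  got <- stepwise_conversions(peaks3(c(60, 30, 10)), "18:4n-3", max_carbons = 22)
  expect_equal(got$conversion, c(100 * 40 / 100, 100 * 10 / 40))  # 40%, 25%
  expect_false(any(got$not_detected))
  expect_equal(got$substrate, c("18:4n-3", "20:4n-3"))
  expect_equal(got$product, c("20:4n-3", "22:4n-3"))
  expect_equal(got$elongation, c("C18 → 22", "C20 → 22"))
})

test_that("edge semantics: no products, consumed substrate, undetected tail", {
  # substrate only: step 1 = 0, downstream steps have empty pools -> N.D.
  got <- stepwise_conversions(peaks3(c(100, 0, 0)), "18:4n-3", max_carbons = 22)
  expect_equal(got$conversion[1], 0)
  expect_true(got$not_detected[2])
  expect_true(is.na(got$conversion[2]))

  # substrate fully consumed: step 1 = 100, step 2 = 0
  got <- stepwise_conversions(peaks3(c(0, 50, 0)), "18:4n-3", max_carbons = 22)
  expect_equal(got$conversion, c(100, 0))
  expect_equal(got$not_detected, c(FALSE, FALSE))
})

test_that("missing cascade members are zero-filled with a warning", {
  peaks <- tibble::tibble(sample_id = "s1", treatment = "t",
                          fatty_acid = "18:4n-3", area = 100)
  expect_warning(
    got <- stepwise_conversions(peaks, "18:4n-3", max_carbons = 22),
    "absent"
  )
  expect_equal(got$conversion[1], 0)
})

test_that("negative areas and duplicate entries are rejected", {
  expect_error(stepwise_conversions(peaks3(c(-1, 0, 0)), "18:4n-3", 22),
               "non-negative")
  dup <- dplyr::bind_rows(peaks3(c(1, 2, 3)), peaks3(c(1, 2, 3))[1, ])
  expect_error(stepwise_conversions(dup, "18:4n-3", 22), "Duplicate")
})

test_that("conversions lie in [0, 100] and are invariant to uniform rescaling", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(2:10, 1)
    e <- runif(n - 1, 0, 0.95)
    tab <- simulate_cascade_areas("18:0", e, noise_sigma = 0.3, seed = i)
    maxc <- 18 + 2 * (n - 1)
    got <- stepwise_conversions(tab, "18:0", max_carbons = maxc)
    conv <- got$conversion[!got$not_detected]
    expect_true(all(conv >= 0 & conv <= 100))
    scaled <- dplyr::mutate(tab, area = area * 1000)
    expect_equal(stepwise_conversions(scaled, "18:0", max_carbons = maxc)$conversion,
                 got$conversion)
  }
})

test_that("noiseless simulated cascades return exactly 100 * e_k (recovery identity)", {
  set.seed(7)
  for (i in 1:50) {
    n_steps <- sample(1:9, 1)
    e <- runif(n_steps, 0, 0.95)
    tab <- simulate_cascade_areas("20:5n-3", e, a0 = runif(1, 10, 1000), seed = i)
    got <- stepwise_conversions(tab, "20:5n-3",
                                max_carbons = 20 + 2 * n_steps)
    expect_equal(got$conversion, 100 * e, tolerance = 1e-12)
  }
})

test_that("downstream cumulative flux is non-increasing for simulated tables", {
  set.seed(11)
  e <- runif(8, 0, 0.9)
  tab <- simulate_cascade_areas("18:3n-6", e, seed = 3)
  areas <- tab$area[match(build_cascade("18:3n-6", 34)$fatty_acid,
                          tab$fatty_acid)]
  flux <- rev(cumsum(rev(areas)))
  expect_true(all(diff(flux) <= 1e-12))
})

test_that("LOD censoring moves conversions toward 0/100/N.D., never upward interior", {
  set.seed(13)
  for (i in 1:30) {
    n_steps <- sample(2:8, 1)
    e <- runif(n_steps, 0, 0.9)
    clean <- simulate_cascade_areas("18:0", e, noise_sigma = 0.2, seed = i)
    lod <- stats::quantile(clean$area, runif(1, 0.1, 0.6))
    censored <- dplyr::mutate(clean, area = ifelse(area < lod, 0, area))
    maxc <- 18 + 2 * n_steps
    a <- stepwise_conversions(clean, "18:0", max_carbons = maxc)
    b <- stepwise_conversions(censored, "18:0", max_carbons = maxc)
    for (k in seq_len(n_steps)) {
      if (b$not_detected[k]) next
      expect_true(b$conversion[k] <= a$conversion[k] + 1e-9 ||
                    abs(b$conversion[k] - 100) < 1e-9)
    }
  }
})

test_that("control-sample background triggers a warning but no subtraction", {
  tab <- dplyr::bind_rows(
    peaks3(c(60, 30, 10)),
    dplyr::mutate(peaks3(c(80, 5, 0)), sample_id = "c1", treatment = "control")
  )
  expect_warning(
    got <- stepwise_conversions(tab, "18:4n-3", max_carbons = 22,
                                control = "control"),
    "control"
  )
  expect_equal(got$conversion[got$sample_id == "s1"][1], 40)
})

test_that("conversion_table averages replicates and keeps N.D. only when unanimous", {
  set.seed(5)
  tab <- simulate_cascade_areas("18:4n-3", c(0.5, 0.25), noise_sigma = 0.1,
                                seed = 9, n_samples = 3, treatment = "elovl4a")
  conv <- stepwise_conversions(tab, "18:4n-3", max_carbons = 22)
  summ <- conversion_table(conv)
  expect_equal(nrow(summ), 2L)
  expect_equal(summ$n, c(3L, 3L))
  by_hand <- tapply(conv$conversion, conv$step, mean)
  expect_equal(summ$conversion, as.numeric(by_hand))

  # one replicate with a detected tail keeps the step quantitative
  tab2 <- dplyr::bind_rows(
    peaks3(c(100, 0, 0)),
    dplyr::mutate(peaks3(c(100, 10, 5)), sample_id = "s2")
  )
  conv2 <- stepwise_conversions(tab2, "18:4n-3", max_carbons = 22)
  summ2 <- conversion_table(conv2)
  expect_equal(summ2$not_detected, c(FALSE, FALSE))
  expect_equal(summ2$n[2], 1L)
})
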