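test_that("EF is 1 for a sample identical to background and invariant to rescaling", {
  bg <- c(As = 2, Cr = 15, Cu = 12, Mn = 350, Ni = 6, Pb = 14, Zn = 35)
  ef_id <- enrichment_factor(bg, bg)
  non_ref <- ef_id[ef_id$metal != "Mn", ]
  expect_equal(non_ref$ef, rep(1, nrow(non_ref)))
  expect_true(all(non_ref$category == "minimal"))

  sample <- c(As = 4, Cr = 20, Cu = 30, Mn = 300, Ni = 9, Pb = 120, Zn = 200)
  ef1 <- enrichment_factor(sample, bg)
  ef10 <- enrichment_factor(sample * 10, bg)
  expect_equal(ef10$ef, ef1$ef)
  efbg <- enrichment_factor(sample, bg * 0.5)
  expect_equal(efbg$ef, ef1$ef)
})

test_that("EF matches the double-ratio arithmetic and the reference metal is not applicable", {
  # sample Pb/Mn = 0.4, background Pb/Mn = 0.1 -> EF 4, moderate
  ef <- enrichment_factor(
    c(Pb = 40, Mn = 100), c(Pb = 10, Mn = 100)
  )
  expect_equal(ef$ef[ef$metal == "Pb"], 4)
  expect_equal(as.character(ef$category[ef$metal == "Pb"]), "moderate")
  expect_true(is.na(ef$ef[ef$metal == "Mn"]))
  expect_true(is.na(ef$category[ef$metal == "Mn"]))
})

test_that("EF validates reference and background positivity", {
  expect_error(
    enrichment_factor(c(Pb = 10, Mn = 0), c(Pb = 1, Mn = 100)), "Mn"
  )
  expect_error(
    enrichment_factor(c(Pb = 10, Mn = 50), c(Pb = 0, Mn = 100)), "Pb"
  )
  expect_error(
    enrichment_factor(c(Pb = 10), c(Pb = 1, Mn = 100)), "reference"
  )
})

test_that("classification bands are exercised inclusively/exclusively at 2/5/20/40", {
  x <- c(0, 2, 2.0001, 5, 5.0001, 20, 20.0001, 40, 40.0001, 1000)
  got <- as.character(classify_ef(x))
  expect_identical(got, c(
    "minimal", "minimal", "moderate", "moderate", "significant",
    "significant", "very_high", "very_high", "extremely_high", "extremely_high"
  ))
  expect_error(classify_ef(-0.1), "non-negative")

  # monotone: a larger EF never maps to a lower band
  set.seed(1)
  ef <- sort(runif(200, 0, 60))
  bands <- as.integer(classify_ef(ef))
  expect_true(all(diff(bands) >= 0))
})

test_that("tibble input computes EF per home and medium", {
  homes <- tibble::tibble(
    home_id = rep(c("H1", "H2"), each = 2),
    medium = "garden_soil",
    metal = rep(c("Pb", "Mn"), 2),
    mean_concentration = c(40, 100, 10, 100)
  )
  bg <- c(Pb = 10, Mn = 100)
  ef <- enrichment_factor(homes, bg)
  expect_equal(ef$ef[ef$home_id == "H1" & ef$metal == "Pb"], 4)
  expect_equal(ef$ef[ef$home_id == "H2" & ef$metal == "Pb"], 1)
})

test_that("guideline exceedance counting is strict and monotone in the guideline", {
  homes <- tibble::tibble(
    home_id = paste0("H", 1:4),
    medium = "garden_soil",
    metal = "Pb",
    mean_concentration = c(100, 350, 299, 301)
  )
  cnt <- count_exceedances(homes, hil_a_guideline())
  expect_identical(cnt$n_exceed, 2L)

  # a mean exactly at the guideline is not an exceedance
  tie <- count_exceedances(
    dplyr::mutate(homes, mean_concentration = c(300, 300, 300, 300)),
    hil_a_guideline()
  )
  expect_identical(tie$n_exceed, 0L)

  # raising the guideline can only lower the count
  for (g in c(50, 150, 300, 500)) {
    c_lo <- count_exceedances(homes, c(Pb = g))$n_exceed
    c_hi <- count_exceedances(homes, c(Pb = g + 50))$n_exceed
    expect_true(c_hi <= c_lo)
  }

  # metals without a guideline entry are not assessed, and the total-Cr
  # caveat is carried
  homes2 <- dplyr::mutate(homes, metal = rep(c("Pb", "Cr"), 2))
  cnt2 <- count_exceedances(homes2, c(Pb = 300, Cr = 100))
  expect_match(cnt2$note[cnt2$metal == "Cr"], "Cr\\(VI\\)")
  cnt3 <- count_exceedances(homes2, c(Pb = 300))
  expect_true(is.na(cnt3$n_exceed[cnt3$metal == "Cr"]))
})

test_that("descriptive statistics match hand computations", {
  d <- descriptive_stats(c(1, 2, 3, 4, 5))
  expect_equal(d$mean, 3)
  expect_equal(d$min, 1)
  expect_equal(d$max, 5)
  expect_equal(d$sd, sqrt(2.5), tolerance = 1e-12)

  # degenerate constant vector
  k <- descriptive_stats(c(7, 7, 7))
  expect_equal(k$sd, 0)
  expect_equal(k$ci_lower, 7)
  expect_equal(k$ci_upper, 7)

  # t-based CI: mean 20, half-width t_{0.975, 2} * sd / sqrt(3), with the
  # tabulated t value 4.3027
  ci <- descriptive_stats(c(10, 20, 30))
  expect_equal(ci$mean, 20)
  expect_equal(ci$ci_upper - ci$mean, 4.3027 * 10 / sqrt(3), tolerance = 1e-4)

  expect_error(descriptive_stats(numeric(0)), "at least one")
})

test_that("order statistics are permutation-invariant and bounded by min/max", {
  set.seed(9)
  x <- rlnorm(40, 3, 1)
  a <- descriptive_stats(x, percentiles = c(0.1, 0.5, 0.9))
  b <- descriptive_stats(sample(x), percentiles = c(0.1, 0.5, 0.9))
  expect_equal(a, b)
  expect_true(a$min <= a$p10 && a$p10 <= a$p50 && a$p50 <= a$p90 && a$p90 <= a$max)
  expect_true(a$ci_lower <= a$mean && a$mean <= a$ci_upper)
})

test_that("describe_samples summarises per medium and metal", {
  ds <- generate_dataset(generator_config(n_homes = 8, lod_rate = 0), seed = 2)
  out <- describe_samples(ds$samples)
  expect_setequal(unique(out$metal), metals())
  expect_identical(nrow(out), length(unique(ds$samples$medium)) * 7L)
})
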