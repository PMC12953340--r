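p_child <- list(
  IngR = 50, InhR = 10, ExpF = 365, ED = 6, BW = 15,
  SA = 2800, AF = 0.2, ABS = 0.001, PEF = 1.36e9, CF = 1e-6, AT = 2190
)

test_that("average daily dose equations reproduce hand-computed values", {
  expect_equal(add_ingestion(100, p_child), 3.333e-4, tolerance = 1e-3)
  expect_equal(add_inhalation(100, p_child), 4.902e-8, tolerance = 1e-3)
  expect_equal(add_dermal(100, p_child), 3.733e-6, tolerance = 1e-3)
})

test_that("doses are homogeneous in concentration and vanish appropriately", {
  expect_identical(add_ingestion(0, p_child), 0)
  expect_identical(add_inhalation(0, p_child), 0)
  expect_equal(add_ingestion(200, p_child), 2 * add_ingestion(100, p_child))

  # dermal is linear in each of SA, AF, ABS
  for (par in c("SA", "AF", "ABS")) {
    p2 <- p_child; p2[[par]] <- p_child[[par]] / 2
    expect_equal(add_dermal(100, p2), add_dermal(100, p_child) / 2)
  }
  p0 <- p_child; p0$ABS <- 0
  expect_identical(add_dermal(100, p0), 0)

  # PEF -> infinity drives the inhalation dose to 0
  pinf <- p_child; pinf$PEF <- 1e30
  expect_lt(add_inhalation(100, pinf), 1e-25)
})

test_that("dose equations validate their parameters", {
  bad_bw <- p_child; bad_bw$BW <- 0
  expect_error(add_ingestion(10, bad_bw), "BW")
  bad_pef <- p_child; bad_pef$PEF <- -1
  expect_error(add_inhalation(10, bad_pef), "PEF")
  bad_abs <- p_child; bad_abs$ABS <- 1.2
  expect_error(add_dermal(10, bad_abs), "ABS")
})

test_that("hazard quotient/index and cancer risk follow their definitions", {
  expect_equal(hazard_quotient(3e-4, 3e-4), 1)
  expect_equal(hazard_index(c(0.2, 0.3, 0.5)), 1)
  expect_identical(hazard_index(numeric(0)), 0)
  expect_error(hazard_quotient(1, 0), "positive")

  expect_equal(cancer_risk(1e-3, 1.5), 1.5e-3)
  expect_equal(cancer_risk(1e-3, 3), 2 * cancer_risk(1e-3, 1.5))
  expect_identical(total_cancer_risk(numeric(0)), 0)
  expect_error(cancer_risk(1e-3, NA), "slope factor")
})

test_that("degenerate Monte Carlo equals the deterministic composition exactly", {
  conc <- list(As = dist_point(33), Pb = dist_point(245), Zn = dist_point(1562))
  scen <- point_scenario()
  d <- run_monte_carlo(conc, scen, n_iter = 100, seed = 1)
  oracle <- deterministic_risk(
    c(As = 33, Pb = 245, Zn = 1562),
    lapply(scen$params, `[[`, "value"),
    default_toxicity(),
    at_nc = scen$params$ED$value * 365, at_ca = 70 * 365
  )
  expect_identical(unique(d$hi), oracle$hi)
  expect_identical(unique(d$tcr), oracle$tcr)
})

test_that("identical seeds reproduce the run bit-for-bit", {
  conc <- list(Pb = dist_lognormal(245, 282), Zn = dist_lognormal(1562, 670))
  scen <- default_scenario("child")
  a <- run_monte_carlo(conc, scen, n_iter = 500, seed = 77, keep_inputs = TRUE)
  b <- run_monte_carlo(conc, scen, n_iter = 500, seed = 77, keep_inputs = TRUE)
  expect_identical(a$hi, b$hi)
  expect_identical(a$tcr, b$tcr)
  expect_identical(a$hq, b$hq)
  expect_equal(a$inputs, b$inputs)
})

test_that("per-iteration HI and TCR equal the sums of their components, all non-negative", {
  d <- run_monte_carlo(
    list(As = dist_lognormal(33, 24), Pb = dist_lognormal(245, 282)),
    default_scenario("child"),
    n_iter = 400, seed = 5
  )
  expect_equal(d$hi, rowSums(d$hq), tolerance = 1e-12)
  expect_equal(d$tcr, rowSums(d$cr), tolerance = 1e-12)
  expect_true(all(d$hq >= 0) && all(d$hi >= 0))
  expect_true(all(d$cr >= 0) && all(d$tcr >= 0))
})

test_that("metals without slope factors contribute nothing to TCR", {
  d <- run_monte_carlo(
    list(Zn = dist_lognormal(1562, 670), Mn = dist_lognormal(503, 230)),
    default_scenario("child"),
    n_iter = 50, seed = 2
  )
  expect_null(d$cr)
  expect_identical(d$tcr, numeric(50))
})

test_that("risk is monotone in concentration draws", {
  scen <- point_scenario()
  lo <- run_monte_carlo(list(Pb = dist_point(100)), scen, n_iter = 1, seed = 1)
  hi <- run_monte_carlo(list(Pb = dist_point(400)), scen, n_iter = 1, seed = 1)
  expect_gt(hi$hi, lo$hi)
  expect_gt(hi$tcr, lo$tcr)
})

test_that("exceedance summaries count fractions and percentiles correctly", {
  d <- run_monte_carlo(list(Pb = dist_point(245)), point_scenario(),
    n_iter = 10, seed = 1)
  # construct a known HI vector: 150 of 10000 above 1
  d$hi <- c(rep(2, 150), rep(0.5, 9850))
  d$n_iter <- 10000L
  s <- exceedance_summary(d, "HI", 1)
  expect_equal(s$fraction, 0.015)
  expect_equal(s$first_percentile, 98.5)
  expect_equal(s$maximum, 2)

  d$hi <- rep(0.2, 10000)
  none <- exceedance_summary(d, "HI", 1)
  expect_equal(none$fraction, 0)
  expect_true(is.na(none$first_percentile))

  d$hi <- rep(3, 10000)
  all_over <- exceedance_summary(d, "HI", 1)
  expect_equal(all_over$fraction, 1)
  expect_equal(all_over$first_percentile, 0)
})

test_that("invalid configuration fails before sampling", {
  scen <- default_scenario("child")
  expect_error(run_monte_carlo(list(), scen), "non-empty")
  expect_error(run_monte_carlo(list(Xx = dist_point(1)), scen), "unknown metal")
  expect_error(
    run_monte_carlo(list(Pb = dist_point(1)), scen,
      toxicity = default_toxicity()[default_toxicity()$metal != "Pb", ]),
    "no entry"
  )
  expect_error(
    exposure_scenario("child_2y", params = list(IngR = dist_point(50))),
    "missing parameter"
  )
  expect_error(
    default_scenario("child", overrides = list(ABS = dist_point(2))),
    "ABS"
  )
})

test_that("tidy and glance summarise a risk distribution", {
  d <- run_monte_carlo(
    list(As = dist_lognormal(33, 24), Pb = dist_lognormal(245, 282)),
    default_scenario("child"),
    n_iter = 300, seed = 8, medium = "indoor_dust"
  )
  td <- tidy(d)
  expect_setequal(unique(td$metric), c("HQ", "CR"))
  expect_true(all(td$route %in% c("ingestion", "dermal", "inhalation")))
  gl <- glance(d)
  expect_identical(gl$n_iter, 300L)
  expect_equal(gl$mean_hi, mean(d$hi))

  cf <- cumulative_frequency(d, "HI")
  expect_equal(nrow(cf), 300L)
  expect_true(!is.unsorted(cf$value))
})

test_that("risk outputs are written as delimited text plus JSON summary", {
  d <- run_monte_carlo(list(Pb = dist_lognormal(245, 282)),
    default_scenario("child"), n_iter = 200, seed = 3)
  dir <- tempfile()
  paths <- write_risk_outputs(d, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[2])
  expect_equal(js$n_iter, 200L)
  expect_true(all(c("p50", "p86", "p94", "p95", "p98", "p99") %in%
    names(js$HI$percentiles)))
})

test_that("scenario files round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    age_group = "adult",
    params = list(
      IngR = list(kind = "triangular", low = 5, mode = 25, high = 50),
      InhR = 15, ExpF = 350, ED = list(kind = "uniform", low = 10, high = 30),
      BW = list(kind = "normal_truncated", mean = 70, sd = 10, low = 40, high = 120),
      SA = 5700, AF = 0.07, ABS = 0.001, PEF = 1.36e9, CF = 1.0e-6
    ),
    rba = 0.8
  ), path)
  scen <- read_scenario(path)
  expect_identical(scen$age_group, "adult")
  expect_identical(scen$params$IngR$kind, "triangular")
  expect_equal(scen$rba, 0.8)
})

test_that("toxicity tables validate and accept overrides", {
  tox <- default_toxicity(overrides = tibble::tibble(metal = "Pb", rfd_ingestion = 1e-3))
  expect_equal(tox$rfd_ingestion[tox$metal == "Pb"], 1e-3)
  expect_error(
    default_toxicity(overrides = tibble::tibble(metal = "Xx", rfd_ingestion = 1)),
    "unknown metal"
  )
  bad <- default_toxicity()
  bad$rfd_dermal[1] <- -1
  expect_error(run_monte_carlo(list(Pb = dist_point(1)),
    default_scenario("child"), toxicity = bad), "positive")
})
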