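test_that("delimited tables parse with below-LOD tokens and half-LOD substitution", {
  path <- write_sample_csv(c(
    "home_id,medium,location_type,As,Pb,Ni",
    "H1,garden_soil,front_garden,<LOD,12.5,8",
    "H1,garden_soil,back_garden,3,ND,<LOD",
    "H2,indoor_dust,vacuum_dust,5,<2.5,30"
  ))
  s <- read_samples(path, lod = lod_vanta_vmw())

  pb_h1 <- s$concentration[s$home_id == "H1" & s$metal == "Pb" &
    s$location_type == "front_garden"]
  expect_identical(pb_h1, 12.5)

  # VMW As LOD is 1 mg/kg -> substituted value is exactly 0.5
  as_h1 <- s[s$home_id == "H1" & s$metal == "As" &
    s$location_type == "front_garden", ]
  expect_true(as_h1$below_lod)
  expect_identical(as_h1$concentration, 0.5)

  # VMW Ni LOD is 4 -> "ND"/"<LOD" both substitute to 2
  ni_h1 <- s$concentration[s$home_id == "H1" & s$metal == "Ni" &
    s$location_type == "back_garden"]
  expect_identical(ni_h1, 2)

  # "<x" cell-level limit overrides the instrument LOD
  pb_h2 <- s$concentration[s$home_id == "H2" & s$metal == "Pb"]
  expect_identical(pb_h2, 1.25)
})

test_that("substitution is idempotent, never touches unflagged values, and stays below the LOD", {
  path <- write_sample_csv(c(
    "home_id,medium,location_type,As,Pb",
    "H1,garden_soil,front_garden,<LOD,40",
    "H2,garden_soil,back_garden,7,<LOD"
  ))
  s1 <- read_samples(path, lod = lod_vanta_vmw())
  s2 <- substitute_half_lod(s1, lod_vanta_vmw())
  expect_identical(s1, s2)
  expect_identical(s1$concentration[s1$metal == "Pb" & s1$home_id == "H1"], 40)
  flagged <- s1[s1$below_lod, ]
  expect_true(all(flagged$concentration < flagged$lod))
})

test_that("schema and value errors are specific", {
  no_medium <- write_sample_csv(c(
    "home_id,location_type,Pb", "H1,front_garden,5"
  ))
  expect_error(read_samples(no_medium), "medium")

  neg <- write_sample_csv(c(
    "home_id,medium,location_type,Pb",
    "H1,garden_soil,front_garden,-3"
  ))
  expect_error(read_samples(neg), "negative")

  bad_medium <- write_sample_csv(c(
    "home_id,medium,location_type,Pb",
    "H1,street_soil,front_garden,3"
  ))
  expect_error(read_samples(bad_medium), "medium")

  # below-LOD flag with no LOD entry anywhere is a configuration error
  s <- read_samples(write_sample_csv(c(
    "home_id,medium,location_type,Pb",
    "H1,garden_soil,front_garden,<LOD"
  )))
  expect_error(
    substitute_half_lod(s, lod_table("partial", c(As = 1))),
    "no LOD"
  )
})

test_that("header-only files yield an empty collection and column names are case-insensitive", {
  empty <- write_sample_csv("home_id,medium,location_type,As,Pb")
  expect_identical(nrow(read_samples(empty)), 0L)

  mixed <- write_sample_csv(c(
    "HOME_ID,Medium,Location_Type,as,PB",
    "H1,garden_soil,front_garden,2,9"
  ))
  s <- read_samples(mixed)
  expect_setequal(unique(s$metal), c("As", "Pb"))
})

test_that("home aggregation averages per (home, medium), skips background, and is order-invariant", {
  path <- write_sample_csv(c(
    "home_id,medium,location_type,Pb",
    "H1,garden_soil,front_garden,10",
    "H1,garden_soil,back_garden,20",
    "H1,garden_soil,drip_line,30",
    "H1,garden_soil,vegetable_garden,40",
    "H1,garden_soil,unspecified,50",
    "H1,indoor_dust,vacuum_dust,77",
    "BG,background_soil,background,5"
  ))
  s <- read_samples(path)
  h <- aggregate_homes(s)
  soil <- h[h$medium == "garden_soil", ]
  expect_equal(soil$mean_concentration, 30)
  expect_identical(soil$n_samples, 5L)
  dust <- h[h$medium == "indoor_dust", ]
  expect_equal(dust$mean_concentration, 77)
  expect_identical(dust$n_samples, 1L)
  expect_false("background_soil" %in% h$medium)

  set.seed(42)
  perm <- s[sample.int(nrow(s)), ]
  h2 <- aggregate_homes(perm)
  expect_equal(dplyr::arrange(h2, home_id, medium, metal),
    dplyr::arrange(h, home_id, medium, metal))
})

test_that("SRM recovery reports percent recoveries, their mean, and scale equivariance", {
  r <- compute_recovery(c(Pb = 96), c(Pb = 100))
  expect_equal(r$recovery, 96)

  measured <- c(As = 10, Cr = 20, Cu = 30, Mn = 40, Ni = 50, Pb = 60, Zn = 70)
  r_id <- compute_recovery(measured, measured)
  expect_equal(r_id$recovery, rep(100, 7))
  expect_equal(attr(r_id, "mean_recovery"), 100)

  # seven recoveries spanning 88-113%: the reported mean is their
  # arithmetic mean (hand-computed)
  cert <- c(As = 100, Cr = 100, Cu = 100, Mn = 100, Ni = 100, Pb = 100, Zn = 100)
  meas <- c(As = 88, Cr = 92, Cu = 96, Mn = 99, Ni = 104, Pb = 108, Zn = 113)
  r7 <- compute_recovery(meas, cert)
  expect_equal(attr(r7, "mean_recovery"), mean(c(88, 92, 96, 99, 104, 108, 113)))

  r_scaled <- compute_recovery(meas * 3.7, cert * 3.7)
  expect_equal(r_scaled$recovery, r7$recovery)

  expect_error(compute_recovery(c(Pb = 5), c(Pb = 0)), "positive")
  expect_error(compute_recovery(c(Pb = 5), c(As = 5)), "overlap")
})

test_that("replicate SRM measurements yield per-metal RSDs", {
  reps <- rbind(c(Pb = 95, Zn = 100), c(Pb = 97, Zn = 110), c(Pb = 96, Zn = 105))
  r <- compute_recovery(reps, c(Pb = 100, Zn = 100))
  expect_equal(r$recovery[r$metal == "Pb"], 96)
  expect_equal(r$rsd[r$metal == "Pb"], 100 * sd(c(95, 97, 96)) / 96)
})

test_that("sample tables round-trip through write_samples / read_samples", {
  ds <- generate_dataset(generator_config(n_homes = 6, lod_rate = 0.1), seed = 11)
  path <- tempfile(fileext = ".csv")
  write_samples(ds$samples, path)
  back <- read_samples(path, lod = lod_vanta_vmw())
  orig <- dplyr::arrange(ds$samples, sample_id, metal)
  back <- dplyr::arrange(back, sample_id, metal)
  expect_equal(back$below_lod, orig$below_lod)
  # dust rows were generated under the VMR LODs; compare unflagged cells
  keep <- !orig$below_lod
  expect_equal(back$concentration[keep], orig$concentration[keep],
    tolerance = 1e-9)
})
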