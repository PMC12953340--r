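## Synthetic home-structured dataset generator.
##
## Emulates the structure of a residential soil/dust survey: each home
## contributes five garden-soil samples (front, back, drip line, vegetable
## garden, plus one unspecified) drawn around a home-level lognormal mean,
## and a fraction of homes contribute one matched indoor-dust sample. Home
## age is linked to dust As/Pb/Zn through a Gaussian copula so target rank
## correlations are hit in expectation; six unenriched background-soil
## records support enrichment-factor normalisation.

SOIL_LOCATIONS <- c("front_garden", "back_garden", "drip_line",
  "vegetable_garden", "unspecified")

default_soil_summary <- function() {
  tibble::tibble(
    metal = METALS,
    mean = c(11, 51, 137, 477, 13, 143, 442),
    sd = c(10, 24, 278, 289, 25, 216, 1115)
  )
}

default_dust_summary <- function() {
  tibble::tibble(
    metal = METALS,
    mean = c(33, 189, 283, 503, 55, 245, 1562),
    sd = c(24, 159, 214, 230, 27, 282, 670)
  )
}

## synthetic low, crustal-style background concentrations (mg/kg)
default_background <- function() {
  c(As = 2, Cr = 15, Cu = 12, Mn = 350, Ni = 6, Pb = 14, Zn = 35)
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate a legacy-industrial regional survey: 75 homes with five
#' garden-soil samples each, roughly 30% of homes contributing a matched
#' indoor-dust sample, per-metal lognormal concentrations calibrated to
#' regional summary statistics, and moderate rank correlations between home
#' age and indoor-dust As/Pb/Zn (0.573/0.471/0.533).
#'
#' @param n_homes Number of homes.
#' @param soil_samples_per_home Garden-soil samples per home (default 5).
#' @param dust_fraction Fraction of homes with a matched dust sample.
#' @param soil_summary,dust_summary Tibbles (`metal`, `mean`, `sd`, mg/kg)
#'   giving the target sample-level arithmetic moments per metal.
#' @param background Named vector of background-soil concentrations
#'   (mg/kg); synthetic crustal-style defaults.
#' @param age_cor Named vector of target Spearman correlations between home
#'   age and dust concentrations, each in (-1, 1).
#' @param age_mean,age_sd,age_range Home-age distribution (truncated
#'   normal, years).
#' @param within_home_cv Coefficient of variation of the five soil samples
#'   around their home mean.
#' @param lod_rate Fraction of measurements flagged below the detection
#'   limit.
#' @param lod_soil,lod_dust [lod_table()]s used for flagged values.
#' @param materials Construction-material labels, assigned with no
#'   concentration effect unless `material_effect > 0`.
#' @param material_effect Optional multiplicative concentration effect
#'   (on homes of the first material label) for power studies; default 0.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_homes = 75,
                             soil_samples_per_home = 5,
                             dust_fraction = 23 / 75,
                             soil_summary = default_soil_summary(),
                             dust_summary = default_dust_summary(),
                             background = default_background(),
                             age_cor = c(As = 0.573, Pb = 0.471, Zn = 0.533),
                             age_mean = 50, age_sd = 25,
                             age_range = c(1, 120),
                             within_home_cv = 0.3,
                             lod_rate = 0.02,
                             lod_soil = lod_vanta_vmw(),
                             lod_dust = lod_vanta_vmr(),
                             materials = c("brick", "timber", "fibro", "weatherboard"),
                             material_effect = 0) {
  stopifnot(n_homes >= 1, soil_samples_per_home >= 1)
  if (dust_fraction < 0 || dust_fraction > 1) {
    abort("dust_fraction must lie in [0, 1].")
  }
  if (lod_rate < 0 || lod_rate > 1) abort("lod_rate must lie in [0, 1].")
  for (tbl in list(soil_summary, dust_summary)) {
    if (!all(c("metal", "mean", "sd") %in% names(tbl))) {
      abort("concentration summaries need columns metal, mean, sd.")
    }
    if (any(tbl$mean <= 0) || any(tbl$sd < 0)) {
      abort("summary means must be positive and sds non-negative.")
    }
  }
  if (any(background <= 0)) abort("background concentrations must be positive.")
  if (any(abs(age_cor) >= 1)) abort("target rank correlations must lie in (-1, 1).")
  bad <- setdiff(names(age_cor), dust_summary$metal)
  if (length(bad)) abort(paste0("age_cor names unknown in dust summary: ", toString(bad)))
  ## feasibility of the Gaussian copula: the (age, metals) correlation
  ## matrix must be positive definite
  r <- copula_corr(age_cor, dust_summary$metal)
  ok <- tryCatch({ chol(r); TRUE }, error = function(e) FALSE)
  if (!ok) abort("target rank correlations are jointly infeasible (copula correlation matrix is not positive definite).")

  structure(
    list(
      n_homes = as.integer(n_homes),
      soil_samples_per_home = as.integer(soil_samples_per_home),
      dust_fraction = dust_fraction,
      soil_summary = soil_summary, dust_summary = dust_summary,
      background = background, age_cor = age_cor,
      age_mean = age_mean, age_sd = age_sd, age_range = age_range,
      within_home_cv = within_home_cv, lod_rate = lod_rate,
      lod_soil = lod_soil, lod_dust = lod_dust,
      materials = materials, material_effect = material_effect
    ),
    class = "generator_config"
  )
}

## Pearson correlation of normal scores reproducing a target Spearman rho:
## r = 2 sin(pi * rho / 6).
copula_corr <- function(age_cor, dust_metals) {
  k <- length(dust_metals)
  r <- diag(k + 1)
  rownames(r) <- colnames(r) <- c("age", dust_metals)
  for (m in names(age_cor)) {
    r["age", m] <- r[m, "age"] <- 2 * sin(pi * age_cor[[m]] / 6)
  }
  r
}

qtrunc_norm <- function(p, mean, sd, low, high) {
  plo <- pnorm(low, mean, sd)
  phi <- pnorm(high, mean, sd)
  qnorm(plo + p * (phi - plo), mean, sd)
}

#' Generate a synthetic home survey dataset
#'
#' Draws a fully reproducible synthetic dataset per the [generator_config()]
#' conditions: per-home garden-soil samples with within-home dispersion,
#' matched indoor-dust samples whose concentrations are rank-linked to home
#' age via a Gaussian copula, home metadata (age, construction material),
#' below-LOD flags at the configured rate, and six background-soil records.
#' The emitted sample table uses the same long schema [read_samples()]
#' produces, with flagged values already substituted at half the detection
#' limit; [write_dataset()] round-trips it through the delimited-text
#' schema.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; identical (config, seed) pairs reproduce the
#'   dataset exactly.
#' @return A list with tibbles `samples` (garden soil + indoor dust, long
#'   schema), `homes` (`home_id`, `home_age_years`,
#'   `construction_material`, `has_dust`), and `background`
#'   (background-soil records, long schema).
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(n_homes = 10), seed = 1)
#' dplyr::count(ds$samples, medium)
generate_dataset <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_homes
  home_ids <- sprintf("H%04d", seq_len(n))
  dust_metals <- config$dust_summary$metal

  ## Gaussian copula draws for (age, dust metals)
  r <- copula_corr(config$age_cor, dust_metals)
  z <- matrix(rnorm(n * ncol(r)), nrow = n) %*% chol(r)
  colnames(z) <- colnames(r)
  u <- pnorm(z)

  ages <- qtrunc_norm(u[, "age"], config$age_mean, config$age_sd,
    config$age_range[1], config$age_range[2])
  material <- sample(config$materials, n, replace = TRUE)
  n_dust <- round(config$dust_fraction * n)
  dust_homes <- if (n_dust > 0) sort(sample.int(n, n_dust)) else integer(0)

  homes <- tibble::tibble(
    home_id = home_ids,
    home_age_years = ages,
    construction_material = material,
    has_dust = seq_len(n) %in% dust_homes
  )

  ## indoor dust: lognormal quantile transform of the copula scores keeps
  ## both the marginal moments and the target rank correlations
  dust <- NULL
  if (n_dust > 0) {
    dust_conc <- purrr::map2(dust_metals, seq_along(dust_metals), function(m, j) {
      spec <- fit_lognormal_from_summary(
        config$dust_summary$mean[j], config$dust_summary$sd[j])
      if (spec$kind == "point") rep(spec$value, n_dust)
      else stats::qlnorm(u[dust_homes, m], spec$meanlog, spec$sdlog)
    })
    dust <- tibble::tibble(
      home_id = rep(home_ids[dust_homes], each = length(dust_metals)),
      medium = "indoor_dust",
      location_type = "vacuum_dust",
      sample_id = rep(paste0(home_ids[dust_homes], "_dust"),
        each = length(dust_metals)),
      metal = rep(dust_metals, times = n_dust),
      ## metal-major list -> sample-major value vector
      concentration = as.numeric(do.call(rbind, dust_conc))
    )
  }

  ## garden soil: two-level lognormal. Total log-variance matches the
  ## target sample-level moments; within-home log-variance comes from the
  ## configured CV (capped at the total).
  k <- config$soil_samples_per_home
  locs <- rep_len(SOIL_LOCATIONS, k)
  soil_metals <- config$soil_summary$metal
  soil_cols <- purrr::pmap(config$soil_summary, function(metal, mean, sd) {
    sigma2_tot <- log(1 + sd^2 / mean^2)
    sigma2_w <- min(log(1 + config$within_home_cv^2), sigma2_tot)
    sigma2_b <- sigma2_tot - sigma2_w
    mu <- log(mean) - sigma2_tot / 2
    b <- rep(rnorm(n, 0, sqrt(sigma2_b)), each = k)
    exp(mu + b + rnorm(n * k, 0, sqrt(sigma2_w)))
  })
  names(soil_cols) <- soil_metals
  soil_wide <- tibble::tibble(
    home_id = rep(home_ids, each = k),
    medium = "garden_soil",
    location_type = rep(locs, times = n),
    sample_id = paste0(rep(home_ids, each = k), "_s", rep(seq_len(k), times = n)),
    !!!soil_cols
  )
  soil <- tidyr::pivot_longer(soil_wide, dplyr::all_of(soil_metals),
    names_to = "metal", values_to = "concentration")

  if (config$material_effect > 0) {
    bump <- homes$home_id[homes$construction_material == config$materials[1]]
    soil$concentration[soil$home_id %in% bump] <-
      soil$concentration[soil$home_id %in% bump] * (1 + config$material_effect)
    if (!is.null(dust)) {
      dust$concentration[dust$home_id %in% bump] <-
        dust$concentration[dust$home_id %in% bump] * (1 + config$material_effect)
    }
  }

  samples <- dplyr::bind_rows(soil, dust)
  samples$below_lod <- FALSE
  samples$lod <- NA_real_

  ## below-LOD injection: flagged cells take LOD/2 of their instrument
  if (config$lod_rate > 0) {
    flag <- runif(nrow(samples)) < config$lod_rate
    inst <- ifelse(samples$medium == "indoor_dust",
      config$lod_dust$lods[samples$metal], config$lod_soil$lods[samples$metal])
    samples$below_lod <- flag
    samples$lod[flag] <- inst[flag]
    samples$concentration[flag] <- inst[flag] / 2
  }

  ## six undisturbed background-soil records with mild dispersion
  bg_metals <- names(config$background)
  bg_wide <- tibble::tibble(
    home_id = NA_character_,
    medium = "background_soil",
    location_type = "background",
    sample_id = paste0("BG", seq_len(6)),
    !!!setNames(lapply(bg_metals, function(m) {
      spec <- fit_lognormal_from_summary(config$background[[m]],
        0.1 * config$background[[m]])
      draw(spec, 6)
    }), bg_metals)
  )
  background <- tidyr::pivot_longer(bg_wide, dplyr::all_of(bg_metals),
    names_to = "metal", values_to = "concentration")
  background$below_lod <- FALSE
  background$lod <- NA_real_

  list(samples = samples, homes = homes, background = background)
}

#' Write a synthetic dataset to delimited-text files
#'
#' Emits `samples.csv` and `background.csv` in the schema [read_samples()]
#' reads (below-LOD cells as `"<LOD"` tokens) and `homes.csv` with the home
#' metadata.
#'
#' @param dataset List returned by [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    samples = file.path(dir, "samples.csv"),
    homes = file.path(dir, "homes.csv"),
    background = file.path(dir, "background.csv")
  )
  write_samples(dataset$samples, paths[["samples"]])
  readr::write_csv(dataset$homes, paths[["homes"]], progress = FALSE)
  bg <- dataset$background
  bg$home_id <- "background"
  write_samples(bg, paths[["background"]])
  invisible(paths)
}
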