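## Exposure scenarios and toxicity tables for the risk engine.

SCENARIO_PARAMS <- c(
  "IngR", "InhR", "ExpF", "ED", "BW", "SA", "AF", "ABS", "PEF", "CF"
)

#' Build an exposure scenario
#'
#' An exposure scenario collects, for one age group, the distribution spec
#' of every exposure parameter used by the dose equations:
#'
#' * `IngR` — soil/dust ingestion rate (mg/day)
#' * `InhR` — inhalation rate (m^3/day)
#' * `ExpF` — exposure frequency (days/year)
#' * `ED`   — exposure duration (years)
#' * `BW`   — body weight (kg)
#' * `SA`   — exposed dermal surface area (cm^2)
#' * `AF`   — soil-to-skin adherence factor (mg/cm^2/day)
#' * `ABS`  — dermal absorption fraction (unitless, in `[0, 1]`)
#' * `PEF`  — particle emission factor (m^3/kg)
#' * `CF`   — mass conversion factor (kg/mg, point 1e-6)
#'
#' The non-carcinogenic averaging time `AT_nc` (days) defaults to
#' `"linked"`, i.e. computed per iteration as `ED x 365`; it may instead be
#' any [dist_spec]. The carcinogenic averaging time `AT_ca` is a lifetime
#' (default a point at 70 x 365 days). `rba` is a relative bioavailability
#' multiplier applied to all concentrations (default 1, i.e. the
#' conservative 100%-bioavailability assumption).
#'
#' @param age_group `"child_2y"` or `"adult"`.
#' @param params Named list of [dist_spec] objects (bare numbers are
#'   promoted to point specs) covering all parameters above.
#' @param at_nc `"linked"` or a [dist_spec] (days).
#' @param at_ca A [dist_spec] (days).
#' @param rba Relative bioavailability in `(0, 1]`.
#' @return An object of class `exposure_scenario`.
#' @seealso [default_scenario()]
#' @export
exposure_scenario <- function(age_group = c("child_2y", "adult"), params,
                              at_nc = "linked",
                              at_ca = dist_point(70 * 365), rba = 1) {
  age_group <- match.arg(age_group)
  params <- lapply(params, as_dist_spec)
  missing_p <- setdiff(SCENARIO_PARAMS, names(params))
  if (length(missing_p)) {
    abort(paste0("scenario missing parameter(s): ", toString(missing_p)))
  }
  abs_spec <- params$ABS
  abs_hi <- switch(abs_spec$kind,
    point = abs_spec$value,
    uniform = , triangular = abs_spec$high,
    normal_truncated = abs_spec$high,
    lognormal = Inf
  )
  if (abs_hi > 1) abort("ABS (dermal absorption fraction) must lie in [0, 1].")
  if (!identical(at_nc, "linked")) at_nc <- as_dist_spec(at_nc)
  if (!is.numeric(rba) || rba <= 0 || rba > 1) {
    abort("rba must lie in (0, 1].")
  }
  structure(
    list(age_group = age_group, params = params, at_nc = at_nc,
      at_ca = as_dist_spec(at_ca), rba = rba),
    class = "exposure_scenario"
  )
}

#' Default Australian residential exposure scenarios
#'
#' Conventional residential exposure-parameter distributions for a young
#' child (2 years) and an adult, drawing central values from Australian
#' (enHealth/NEPC) and USEPA residential guidance. Intake-rate and
#' behavioural parameters that dominate variability (IngR, InhR, ExpF, ED,
#' BW, SA) are sampled; physical constants (AF, ABS, PEF, CF) are points.
#' All values are config-driven defaults, not fixed truths: replace any of
#' them via `overrides` or build a scenario from your own file with
#' [read_scenario()].
#'
#' @param age `"child"` or `"adult"`.
#' @param overrides Named list of [dist_spec] objects replacing individual
#'   defaults.
#' @return An `exposure_scenario`.
#' @export
#' @examples
#' default_scenario("child")
default_scenario <- function(age = c("child", "adult"), overrides = list()) {
  age <- match.arg(age)
  params <- if (age == "child") {
    list(
      IngR = dist_triangular(10, 50, 100),     # mg/day
      InhR = dist_triangular(5, 9, 13),        # m^3/day
      ExpF = dist_triangular(180, 345, 365),   # days/year
      ED   = dist_uniform(2, 6),               # years
      BW   = dist_truncnorm(15, 2, 8, 30),     # kg
      SA   = dist_truncnorm(2800, 300, 1200, 5000), # cm^2
      AF   = dist_point(0.2),                  # mg/cm^2/day
      ABS  = dist_point(0.001),
      PEF  = dist_point(1.36e9),               # m^3/kg
      CF   = dist_point(1e-6)                  # kg/mg
    )
  } else {
    list(
      IngR = dist_triangular(5, 25, 50),
      InhR = dist_triangular(10, 15, 20),
      ExpF = dist_triangular(180, 345, 365),
      ED   = dist_uniform(10, 30),
      BW   = dist_truncnorm(70, 10, 40, 120),
      SA   = dist_truncnorm(5700, 600, 3000, 9000),
      AF   = dist_point(0.07),
      ABS  = dist_point(0.001),
      PEF  = dist_point(1.36e9),
      CF   = dist_point(1e-6)
    )
  }
  params[names(overrides)] <- overrides
  exposure_scenario(
    age_group = if (age == "child") "child_2y" else "adult",
    params = params
  )
}

#' Read an exposure scenario from a YAML/JSON config file
#'
#' The file must contain `age_group` and a `params` mapping of parameter
#' name to a distribution spec (`kind` plus its parameters, or a bare
#' number for a point value); optional `at_nc`, `at_ca`, `rba`.
#'
#' @param path Path to the config file.
#' @return An `exposure_scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- read_config_file(path)
  exposure_scenario(
    age_group = cfg$age_group,
    params = cfg$params,
    at_nc = cfg$at_nc %||% "linked",
    at_ca = if (is.null(cfg$at_ca)) dist_point(70 * 365) else as_dist_spec(cfg$at_ca),
    rba = cfg$rba %||% 1
  )
}

#' Route-specific toxicity table
#'
#' Reference doses (RfD, mg/kg/day) per exposure route, and slope factors
#' (SF, per mg/kg/day) for the configured carcinogens. `default_toxicity()`
#' ships conventional screening values compiled from public toxicological
#' databases (IRIS/OEHHA-style), with slope factors for As and Pb only —
#' the metals in this suite with established slope factors. They are
#' defaults for screening, not authoritative values: override any entry or
#' load your own table with [read_toxicity()] (delimited text or
#' YAML/JSON with the same columns).
#'
#' @param overrides Optional tibble with a `metal` column and any of the
#'   toxicity columns; matching cells replace the defaults.
#' @param path Path to a config file (`read_toxicity`).
#' @return A tibble with columns `metal`, `rfd_ingestion`, `rfd_dermal`,
#'   `rfd_inhalation`, `sf_ingestion`, `sf_dermal`, `sf_inhalation`.
#' @export
#' @examples
#' default_toxicity()
default_toxicity <- function(overrides = NULL) {
  tox <- tibble::tribble(
    ~metal, ~rfd_ingestion, ~rfd_dermal, ~rfd_inhalation, ~sf_ingestion, ~sf_dermal, ~sf_inhalation,
    "As", 3.0e-4, 1.23e-4, 3.01e-4, 1.5,    3.66, 15.1,
    "Cr", 3.0e-3, 6.0e-5,  2.86e-5, NA,     NA,   NA,
    "Cu", 4.0e-2, 1.2e-2,  4.02e-2, NA,     NA,   NA,
    "Mn", 4.6e-2, 1.84e-3, 1.43e-5, NA,     NA,   NA,
    "Ni", 2.0e-2, 5.4e-3,  2.06e-2, NA,     NA,   NA,
    "Pb", 3.5e-3, 5.25e-4, 3.52e-3, 8.5e-3, NA,   4.2e-2,
    "Zn", 3.0e-1, 6.0e-2,  3.0e-1,  NA,     NA,   NA
  )
  if (!is.null(overrides)) {
    if (!"metal" %in% names(overrides)) abort("overrides require a `metal` column.")
    for (i in seq_len(nrow(overrides))) {
      j <- match(overrides$metal[i], tox$metal)
      if (is.na(j)) abort(paste0("unknown metal in overrides: ", overrides$metal[i]))
      for (col in intersect(names(overrides), names(tox))) {
        if (col != "metal") tox[j, col] <- overrides[i, col]
      }
    }
  }
  validate_toxicity(tox)
}

#' @rdname default_toxicity
#' @export
read_toxicity <- function(path) {
  if (grepl("\\.(ya?ml|json)$", path, ignore.case = TRUE)) {
    cfg <- read_config_file(path)
    tox <- tibble::as_tibble(cfg)
  } else {
    tox <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_toxicity(tox)
}

validate_toxicity <- function(tox) {
  rfd_cols <- paste0("rfd_", EXPOSURE_ROUTES)
  need <- c("metal", rfd_cols)
  missing_cols <- setdiff(need, names(tox))
  if (length(missing_cols)) {
    abort(paste0("toxicity table missing column(s): ", toString(missing_cols)))
  }
  for (col in paste0("sf_", EXPOSURE_ROUTES)) {
    if (!col %in% names(tox)) tox[[col]] <- NA_real_
  }
  vals <- unlist(tox[, c(rfd_cols, paste0("sf_", EXPOSURE_ROUTES))])
  if (any(vals <= 0, na.rm = TRUE)) {
    abort("RfD and slope-factor values must be strictly positive where present.")
  }
  tox
}
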