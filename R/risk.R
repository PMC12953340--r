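## Dose and risk equations plus the Monte Carlo wrapper.
##
## The deterministic core follows the standard residential exposure
## formulation (USEPA RAGS / enHealth): route-specific average daily doses
## from soil or dust concentrations, hazard quotients against reference
## doses, and lifetime-averaged cancer risks against slope factors.

#' Average daily dose equations
#'
#' The three route-specific average daily doses (mg/kg/day) from a soil or
#' dust concentration `C` (mg/kg) and a parameter set `p`:
#'
#' \deqn{ADD_{ing} = \frac{C \cdot IngR \cdot CF \cdot ExpF \cdot ED}{BW \cdot AT}}
#' \deqn{ADD_{inh} = \frac{C \cdot InhR \cdot ExpF \cdot ED}{PEF \cdot BW \cdot AT}}
#' \deqn{ADD_{derm} = \frac{C \cdot SA \cdot AF \cdot ABS \cdot CF \cdot ExpF \cdot ED}{BW \cdot AT}}
#'
#' With the non-carcinogenic averaging time (`AT = ED x 365`) these are
#' chronic daily doses; with a lifetime averaging time they are the
#' lifetime average daily doses used for cancer risk.
#'
#' @param C Concentration in mg/kg (vectorised).
#' @param p Named list (or one-row data frame) of exposure parameters; see
#'   [exposure_scenario()] for names and units. `AT` (days) must be
#'   supplied in `p`.
#' @return Numeric vector of doses in mg/kg/day.
#' @name average_daily_dose
#' @examples
#' p <- list(IngR = 50, CF = 1e-6, ExpF = 365, ED = 6, BW = 15, AT = 2190)
#' add_ingestion(100, p)  # 3.333e-4
NULL

get_par <- function(p, name) {
  v <- p[[name]]
  if (is.null(v)) abort(paste0("exposure parameter `", name, "` is missing."))
  v
}

#' @rdname average_daily_dose
#' @export
add_ingestion <- function(C, p) {
  bw <- get_par(p, "BW"); at <- get_par(p, "AT")
  if (any(bw <= 0) || any(at <= 0)) abort("BW and AT must be strictly positive.")
  C * get_par(p, "IngR") * get_par(p, "CF") * get_par(p, "ExpF") *
    get_par(p, "ED") / (bw * at)
}

#' @rdname average_daily_dose
#' @export
add_inhalation <- function(C, p) {
  pef <- get_par(p, "PEF")
  if (any(pef <= 0)) abort("PEF must be strictly positive.")
  bw <- get_par(p, "BW"); at <- get_par(p, "AT")
  if (any(bw <= 0) || any(at <= 0)) abort("BW and AT must be strictly positive.")
  C * get_par(p, "InhR") * get_par(p, "ExpF") * get_par(p, "ED") /
    (pef * bw * at)
}

#' @rdname average_daily_dose
#' @export
add_dermal <- function(C, p) {
  abs_f <- get_par(p, "ABS")
  if (any(abs_f < 0) || any(abs_f > 1)) abort("ABS must lie in [0, 1].")
  bw <- get_par(p, "BW"); at <- get_par(p, "AT")
  if (any(bw <= 0) || any(at <= 0)) abort("BW and AT must be strictly positive.")
  C * get_par(p, "SA") * get_par(p, "AF") * abs_f * get_par(p, "CF") *
    get_par(p, "ExpF") * get_par(p, "ED") / (bw * at)
}

#' Hazard quotient and hazard index
#'
#' `hazard_quotient()` divides an average daily dose by the route-specific
#' reference dose; `hazard_index()` sums hazard quotients across metals and
#' routes (an empty set sums to 0).
#'
#' @param add Average daily dose (mg/kg/day), vectorised.
#' @param rfd Reference dose (mg/kg/day), strictly positive.
#' @param hq Numeric vector of hazard quotients.
#' @return Dimensionless HQ (vector) or HI (scalar).
#' @export
#' @examples
#' hazard_index(c(0.2, 0.3, 0.5))  # 1
hazard_quotient <- function(add, rfd) {
  if (any(!is.finite(rfd)) || any(rfd <= 0)) {
    abort("reference dose must be finite and strictly positive.")
  }
  add / rfd
}

#' @rdname hazard_quotient
#' @export
hazard_index <- function(hq) {
  if (!length(hq)) return(0)
  sum(hq)
}

#' Cancer risk and total cancer risk
#'
#' `cancer_risk()` multiplies a lifetime average daily dose by the slope
#' factor; `total_cancer_risk()` sums risks across carcinogens and routes.
#'
#' @param ladd Lifetime average daily dose (mg/kg/day), computed with the
#'   lifetime averaging time.
#' @param sf Slope factor (per mg/kg/day), strictly positive.
#' @param cr Numeric vector of cancer risks.
#' @return Dimensionless CR (vector) or TCR (scalar).
#' @export
#' @examples
#' cancer_risk(1e-3, 1.5)  # 1.5e-3
cancer_risk <- function(ladd, sf) {
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    abort("slope factor must be finite and strictly positive; metals without an established slope factor cannot be assessed for cancer risk.")
  }
  ladd * sf
}

#' @rdname cancer_risk
#' @export
total_cancer_risk <- function(cr) {
  if (!length(cr)) return(0)
  sum(cr)
}

#' Concentration specs from per-metal summary statistics
#'
#' Converts a summary tibble (columns `metal`, `mean`, `sd`) into the named
#' list of lognormal concentration specs the Monte Carlo engine samples,
#' by moment matching ([fit_lognormal_from_summary()]).
#'
#' @param summary_tbl Tibble with columns `metal`, `mean`, `sd` (mg/kg).
#' @return Named list of [dist_spec] objects.
#' @export
conc_specs_from_summary <- function(summary_tbl) {
  need <- c("metal", "mean", "sd")
  if (!all(need %in% names(summary_tbl))) {
    abort("summary table requires columns metal, mean, sd.")
  }
  specs <- purrr::map2(summary_tbl$mean, summary_tbl$sd, fit_lognormal_from_summary)
  setNames(specs, summary_tbl$metal)
}

#' Monte Carlo probabilistic risk simulation
#'
#' Draws `n_iter` independent realisations of every concentration and
#' exposure parameter, evaluates the three exposure routes for every metal,
#' and records per-iteration hazard quotients (HQ), the hazard index
#' (HI, summed over metals and routes), cancer risks (CR, for metals with
#' slope factors) and the total cancer risk (TCR). Runs are reproducible
#' given `seed`.
#'
#' @param conc Named list of [dist_spec] concentration distributions
#'   (mg/kg) per metal, or a tibble with columns `metal`, `mean`, `sd`
#'   (converted via [conc_specs_from_summary()]).
#' @param scenario An [exposure_scenario()].
#' @param toxicity Toxicity table, see [default_toxicity()].
#' @param n_iter Number of iterations (default 10000).
#' @param seed Optional integer seed.
#' @param keep_inputs Retain the per-iteration input draws (needed by
#'   [sensitivity_tornado()]).
#' @param medium Optional medium label carried through to outputs.
#' @return An object of class `risk_distribution`: per-iteration matrices
#'   `hq` and `cr` (columns `metal_route`), vectors `hi` and `tcr`, and the
#'   run metadata. Use [generics::tidy()], [generics::glance()],
#'   [exceedance_summary()], [ggplot2::autoplot()].
#' @export
#' @examples
#' dist <- run_monte_carlo(
#'   conc = list(Pb = dist_lognormal(245, 282)),
#'   scenario = default_scenario("child"),
#'   n_iter = 500, seed = 42
#' )
#' glance(dist)
run_monte_carlo <- function(conc, scenario, toxicity = default_toxicity(),
                            n_iter = 10000, seed = NULL,
                            keep_inputs = FALSE, medium = NA_character_) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (is.data.frame(conc)) conc <- conc_specs_from_summary(conc)
  if (!length(conc) || is.null(names(conc))) {
    abort("concentration specs must be a non-empty named list.")
  }
  conc <- lapply(conc, as_dist_spec)
  bad <- setdiff(names(conc), METALS)
  if (length(bad)) abort(paste0("unknown metal(s) in concentration specs: ", toString(bad)))
  toxicity <- validate_toxicity(toxicity)
  missing_tox <- setdiff(names(conc), toxicity$metal)
  if (length(missing_tox)) {
    abort(paste0("toxicity table has no entry for: ", toString(missing_tox)))
  }
  n_iter <- as.integer(n_iter)
  if (n_iter < 1) abort("n_iter must be at least 1.")
  if (!is.null(seed)) set.seed(seed)

  mets <- names(conc)
  ## sample exposure parameters, then concentrations (fixed draw order for
  ## reproducibility)
  par_draws <- lapply(scenario$params, draw, n = n_iter)
  at_nc <- if (identical(scenario$at_nc, "linked")) {
    par_draws$ED * 365
  } else {
    draw(scenario$at_nc, n_iter)
  }
  at_ca <- draw(scenario$at_ca, n_iter)
  conc_draws <- lapply(conc, draw, n = n_iter)
  conc_mat <- do.call(cbind, conc_draws) * scenario$rba
  colnames(conc_mat) <- mets

  p_nc <- c(par_draws, list(AT = at_nc))
  p_ca <- c(par_draws, list(AT = at_ca))
  dose_fun <- list(
    ingestion = add_ingestion, dermal = add_dermal, inhalation = add_inhalation
  )

  ## hazard quotients: routes outer, metals inner
  hq_cols <- list()
  for (route in EXPOSURE_ROUTES) {
    rfd <- setNames(toxicity[[paste0("rfd_", route)]], toxicity$metal)
    for (m in mets) {
      if (is.na(rfd[[m]])) next
      hq_cols[[paste0(m, "_", route)]] <-
        hazard_quotient(dose_fun[[route]](conc_mat[, m], p_nc), rfd[[m]])
    }
  }
  hq <- do.call(cbind, hq_cols)
  hi <- if (is.null(hq)) numeric(n_iter) else rowSums(hq)

  ## cancer risks for metals with slope factors
  cr_cols <- list()
  for (route in EXPOSURE_ROUTES) {
    sf <- setNames(toxicity[[paste0("sf_", route)]], toxicity$metal)
    for (m in mets) {
      if (is.na(sf[[m]])) next
      cr_cols[[paste0(m, "_", route)]] <-
        cancer_risk(dose_fun[[route]](conc_mat[, m], p_ca), sf[[m]])
    }
  }
  cr <- do.call(cbind, cr_cols)
  tcr <- if (is.null(cr)) numeric(n_iter) else rowSums(cr)

  inputs <- NULL
  if (keep_inputs) {
    input_cols <- c(
      setNames(as.list(as.data.frame(conc_mat)), paste0("C_", mets)),
      par_draws, list(AT_nc = at_nc, AT_ca = at_ca)
    )
    varying <- c(
      setNames(vapply(conc, is_varying, logical(1)), paste0("C_", mets)),
      vapply(scenario$params, is_varying, logical(1)),
      AT_nc = identical(scenario$at_nc, "linked") && is_varying(scenario$params$ED) ||
        (!identical(scenario$at_nc, "linked") && is_varying(scenario$at_nc)),
      AT_ca = is_varying(scenario$at_ca)
    )
    inputs <- tibble::as_tibble(input_cols)
    attr(inputs, "varying") <- varying
  }

  structure(
    list(
      n_iter = n_iter, seed = seed, medium = medium,
      age_group = scenario$age_group,
      hq = hq, hi = hi, cr = cr, tcr = tcr,
      inputs = inputs, conc = conc, scenario = scenario, toxicity = toxicity
    ),
    class = "risk_distribution"
  )
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat("<risk_distribution> ", x$n_iter, " iterations, ",
    x$age_group, if (!is.na(x$medium)) paste0(", ", x$medium), "\n",
    sep = ""
  )
  cat(sprintf("  HI : mean %.3g, median %.3g, p95 %.3g, max %.3g\n",
    mean(x$hi), median(x$hi), quantile(x$hi, 0.95, names = FALSE), max(x$hi)))
  if (length(x$tcr) && any(x$tcr > 0)) {
    cat(sprintf("  TCR: mean %.3g, median %.3g, p95 %.3g, max %.3g\n",
      mean(x$tcr), median(x$tcr), quantile(x$tcr, 0.95, names = FALSE), max(x$tcr)))
  }
  invisible(x)
}

#' Threshold exceedance summary of a risk distribution
#'
#' Fraction of iterations whose HI (or TCR) exceeds the cautionary
#' threshold, the first percentile of the empirical cumulative distribution
#' at which exceedance occurs (`100 x (1 - fraction)`, `NA` when the
#' threshold is never reached), and the distribution maximum.
#'
#' @param dist A `risk_distribution`.
#' @param metric `"HI"` or `"TCR"`.
#' @param threshold Cautionary threshold; defaults to 1 for HI and 1e-4 for
#'   TCR.
#' @return A one-row tibble: `metric`, `threshold`, `fraction`,
#'   `first_percentile`, `maximum`, `n_iter`.
#' @export
exceedance_summary <- function(dist, metric = c("HI", "TCR"), threshold = NULL) {
  stopifnot(inherits(dist, "risk_distribution"))
  metric <- match.arg(metric)
  x <- switch(metric, HI = dist$hi, TCR = dist$tcr)
  if (!length(x)) abort("risk distribution is empty.")
  threshold <- threshold %||% switch(metric, HI = 1, TCR = 1e-4)
  frac <- mean(x > threshold)
  tibble::tibble(
    metric = metric,
    threshold = threshold,
    fraction = frac,
    first_percentile = if (frac > 0) 100 * (1 - frac) else NA_real_,
    maximum = max(x),
    n_iter = length(x)
  )
}

#' Cumulative-frequency coordinates of a risk metric
#'
#' Returns (value, cumulative probability) pairs of the empirical
#' distribution of HI or TCR, suitable for cumulative-frequency plotting or
#' export.
#'
#' @inheritParams exceedance_summary
#' @return A tibble with columns `value` and `cumulative_probability`.
#' @export
cumulative_frequency <- function(dist, metric = c("HI", "TCR")) {
  stopifnot(inherits(dist, "risk_distribution"))
  metric <- match.arg(metric)
  x <- sort(switch(metric, HI = dist$hi, TCR = dist$tcr))
  tibble::tibble(
    value = x,
    cumulative_probability = seq_along(x) / length(x)
  )
}

#' Write per-iteration risk results and a JSON summary
#'
#' Emits the per-iteration HQ/HI/CR/TCR table as delimited text and a JSON
#' summary holding means, the 50/86/94/95/98/99 percentiles, maxima and
#' threshold exceedance fractions for HI and TCR.
#'
#' @param dist A `risk_distribution`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_risk_outputs <- function(dist, dir, prefix = "risk") {
  stopifnot(inherits(dist, "risk_distribution"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hq_tbl <- as.data.frame(dist$hq)
  names(hq_tbl) <- paste0("HQ_", names(hq_tbl))
  cr_tbl <- if (!is.null(dist$cr)) {
    d <- as.data.frame(dist$cr)
    names(d) <- paste0("CR_", names(d))
    d
  }
  iter_tbl <- tibble::as_tibble(cbind(
    iteration = seq_len(dist$n_iter),
    hq_tbl, HI = dist$hi, cr_tbl, TCR = dist$tcr
  ))
  iter_path <- file.path(dir, paste0(prefix, "_iterations.csv"))
  readr::write_csv(iter_tbl, iter_path, progress = FALSE)

  pct <- c(0.50, 0.86, 0.94, 0.95, 0.98, 0.99)
  summarise_metric <- function(x, thr) list(
    mean = mean(x),
    percentiles = setNames(as.list(quantile(x, pct, names = FALSE)),
      paste0("p", 100 * pct)),
    max = max(x),
    exceedance_fraction = mean(x > thr),
    threshold = thr
  )
  summary <- list(
    n_iter = dist$n_iter, age_group = dist$age_group, medium = dist$medium,
    HI = summarise_metric(dist$hi, 1),
    TCR = summarise_metric(dist$tcr, 1e-4)
  )
  json_path <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(c(iter_path, json_path))
}
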