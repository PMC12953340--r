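## Mn-normalised enrichment factors, guideline benchmarking, and
## descriptive summaries.

EF_CATEGORIES <- c("minimal", "moderate", "significant", "very_high", "extremely_high")

#' Classify an enrichment factor into the five standard bands
#'
#' Bands: EF <= 2 minimal; 2 < EF <= 5 moderate; 5 < EF <= 20 significant;
#' 20 < EF <= 40 very high; EF > 40 extremely high.
#'
#' @param ef Numeric vector of enrichment factors, all >= 0.
#' @return An ordered factor with levels minimal < moderate < significant <
#'   very_high < extremely_high (`NA` for `NA` input).
#' @export
#' @examples
#' classify_ef(c(0, 2, 4.9, 20, 20.0001, 41))
classify_ef <- function(ef) {
  if (any(ef < 0, na.rm = TRUE)) abort("enrichment factors must be non-negative.")
  cut(ef,
    breaks = c(-Inf, 2, 5, 20, 40, Inf),
    labels = EF_CATEGORIES, ordered_result = TRUE
  )
}

#' Enrichment factors against background soil
#'
#' Computes the geochemical enrichment factor
#' \deqn{EF = \frac{(TE/RE)_{sample}}{(TE/RE)_{background}}}
#' for every metal except the reference element (Mn by default), i.e. the
#' double ratio of target element TE to reference element RE in the sample
#' versus the background. The reference metal itself is reported with
#' `ef = NA` (not applicable — an element cannot be enriched against
#' itself), never 1.
#'
#' @param sample Named numeric vector of concentrations (mg/kg), or a long
#'   tibble of home means (columns `metal` and `mean_concentration`, with
#'   optional grouping columns such as `home_id`, `medium`).
#' @param background Named numeric vector of background concentrations
#'   (mg/kg), typically the mean of the background-soil samples; all
#'   evaluated entries must be strictly positive.
#' @param reference_metal Reference element for normalisation (default
#'   `"Mn"`).
#' @return A tibble with columns `metal`, `ef`, `category` (plus any
#'   grouping columns of a tibble input).
#' @export
#' @examples
#' bg <- c(As = 2, Mn = 350, Pb = 14, Zn = 35)
#' enrichment_factor(c(As = 4, Mn = 350, Pb = 140, Zn = 120), bg)
enrichment_factor <- function(sample, background, reference_metal = "Mn") {
  if (is.data.frame(sample)) {
    return(enrichment_factor_df(sample, background, reference_metal))
  }
  if (is.null(names(sample)) || is.null(names(background))) {
    abort("concentration maps must be named by metal.")
  }
  if (!reference_metal %in% names(sample) || !reference_metal %in% names(background)) {
    abort(paste0("reference metal ", reference_metal,
      " must be present in both sample and background."))
  }
  if (!is.finite(sample[[reference_metal]]) || sample[[reference_metal]] <= 0) {
    abort(paste0("reference metal ", reference_metal,
      " must be strictly positive in the sample."))
  }
  metals_eval <- intersect(names(sample), names(background))
  metals_eval <- metals_eval[order(match(metals_eval, METALS))]
  bg <- background[metals_eval]
  if (any(!is.finite(bg)) || any(bg <= 0)) {
    bad <- metals_eval[!is.finite(bg) | bg <= 0][1L]
    abort(paste0("background concentration for ", bad,
      " must be strictly positive."))
  }
  ratio_s <- sample[metals_eval] / sample[[reference_metal]]
  ratio_b <- bg / background[[reference_metal]]
  ef <- unname(ratio_s / ratio_b)
  ef[metals_eval == reference_metal] <- NA_real_
  tibble::tibble(
    metal = metals_eval,
    ef = ef,
    category = classify_ef(ef)
  )
}

enrichment_factor_df <- function(sample, background, reference_metal) {
  need <- c("metal", "mean_concentration")
  if (!all(need %in% names(sample))) {
    abort("tibble input requires columns `metal` and `mean_concentration`.")
  }
  keys <- intersect(c("home_id", "medium"), names(sample))
  sample |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, ...) {
      conc <- setNames(d$mean_concentration, d$metal)
      enrichment_factor(conc, background, reference_metal)
    }) |>
    dplyr::ungroup()
}

#' NEPM Health Investigation Level A residential soil guideline
#'
#' Default HIL-A values (mg/kg) for accessible residential soil:
#' As 100, Cr 100, Cu 7000, Mn 3000, Ni 400, Pb 300, Zn 8000. The Cr entry
#' applies to Cr(VI); benchmarking total Cr against it is conservative and
#' the exceedance report carries a caveat to that effect. Override any
#' value via `...`.
#'
#' @param ... Named overrides, e.g. `Pb = 270`.
#' @return A named numeric vector of guideline concentrations.
#' @export
#' @examples
#' hil_a_guideline()
hil_a_guideline <- function(...) {
  g <- c(As = 100, Cr = 100, Cu = 7000, Mn = 3000, Ni = 400, Pb = 300, Zn = 8000)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), METALS)
    if (length(bad)) abort(paste0("unknown metal(s): ", toString(bad)))
    g[names(over)] <- over
  }
  if (any(g <= 0)) abort("guideline values must be strictly positive.")
  g
}

#' Count homes exceeding a guideline
#'
#' Counts, per medium and metal, the homes whose representative mean
#' concentration strictly exceeds the guideline value. Ties count as
#' non-exceedances; metals without a guideline entry are reported with
#' `NA` counts (not assessed).
#'
#' @param homes Home-summary tibble from [aggregate_homes()].
#' @param guideline Named numeric vector of guideline concentrations
#'   (mg/kg), e.g. [hil_a_guideline()].
#' @param guideline_name Label recorded in the output.
#' @return A tibble with columns `medium`, `metal`, `n_homes`, `n_exceed`,
#'   `guideline`, `guideline_name`, `note` (the total-Cr caveat where
#'   relevant).
#' @export
count_exceedances <- function(homes, guideline, guideline_name = "NEPM HIL-A") {
  if (any(guideline <= 0, na.rm = TRUE)) {
    abort("guideline values must be strictly positive.")
  }
  homes |>
    dplyr::group_by(.data$medium, .data$metal) |>
    dplyr::summarise(
      n_homes = dplyr::n(),
      n_exceed = if (dplyr::first(.data$metal) %in% names(guideline)) {
        sum(.data$mean_concentration > guideline[[dplyr::first(.data$metal)]])
      } else NA_integer_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      guideline = unname(guideline[.data$metal]),
      guideline_name = guideline_name,
      note = dplyr::if_else(.data$metal == "Cr",
        "total Cr benchmarked against a Cr(VI) guideline; exceedances are conservative",
        NA_character_
      )
    )
}

#' Descriptive statistics of a concentration vector
#'
#' Mean, sample SD, min, max, requested percentiles (linear interpolation
#' between closest ranks), and a two-sided confidence interval on the mean
#' from the t distribution with n - 1 degrees of freedom.
#'
#' @param x Numeric vector (n >= 1; CI requires n >= 2).
#' @param percentiles Probabilities of the percentiles to report.
#' @param conf_level Confidence level for the interval on the mean.
#' @return A one-row tibble: `n`, `mean`, `ci_lower`, `ci_upper`, `sd`,
#'   `min`, one column per percentile (`p50` etc.), `max`.
#' @export
#' @examples
#' descriptive_stats(c(1, 2, 3, 4, 5))
descriptive_stats <- function(x, percentiles = c(0.25, 0.5, 0.75),
                              conf_level = 0.95) {
  x <- x[!is.na(x)]
  if (!length(x)) abort("descriptive statistics require at least one value.")
  n <- length(x)
  m <- mean(x)
  s <- if (n >= 2) sd(x) else NA_real_
  half <- if (n >= 2) qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n) else NA_real_
  q <- quantile(x, probs = percentiles, names = FALSE, type = 7)
  out <- tibble::tibble(
    n = n, mean = m,
    ci_lower = m - half, ci_upper = m + half,
    sd = s, min = min(x)
  )
  qcols <- setNames(as.list(q), paste0("p", formatC(100 * percentiles,
    format = "fg")))
  dplyr::bind_cols(out, tibble::as_tibble(qcols), tibble::tibble(max = max(x)))
}

#' Descriptive statistics per medium and metal
#'
#' Applies [descriptive_stats()] across a long sample (or home-summary)
#' tibble, grouped by medium and metal.
#'
#' @param samples Long tibble with `medium`, `metal` and a value column.
#' @param value Name of the value column (default `"concentration"`).
#' @inheritParams descriptive_stats
#' @return A tibble with one row per (medium, metal).
#' @export
describe_samples <- function(samples, value = "concentration",
                             percentiles = c(0.25, 0.5, 0.75),
                             conf_level = 0.95) {
  samples |>
    dplyr::group_by(.data$medium, .data$metal) |>
    dplyr::group_modify(~ descriptive_stats(.x[[value]], percentiles, conf_level)) |>
    dplyr::ungroup()
}
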