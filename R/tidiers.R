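## broom-style tidiers for fitted/simulated result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Monte Carlo risk distribution
#'
#' One row per (metal, route, metric) with the mean, median, 95th
#' percentile and maximum of the per-iteration hazard quotients (`HQ`) and
#' cancer risks (`CR`).
#'
#' @param x A `risk_distribution`.
#' @param ... Unused.
#' @return A tibble: `metric`, `metal`, `route`, `mean`, `median`, `p95`,
#'   `max`.
#' @export
tidy.risk_distribution <- function(x, ...) {
  one <- function(mat, metric) {
    if (is.null(mat)) return(NULL)
    parts <- strsplit(colnames(mat), "_", fixed = TRUE)
    tibble::tibble(
      metric = metric,
      metal = vapply(parts, `[`, "", 1L),
      route = vapply(parts, `[`, "", 2L),
      mean = colMeans(mat),
      median = apply(mat, 2, median),
      p95 = apply(mat, 2, quantile, probs = 0.95, names = FALSE),
      max = apply(mat, 2, max)
    )
  }
  dplyr::bind_rows(one(x$hq, "HQ"), one(x$cr, "CR"))
}

#' Glance at a Monte Carlo risk distribution
#'
#' @param x A `risk_distribution`.
#' @param ... Unused.
#' @return A one-row tibble with iteration count, scenario labels, HI and
#'   TCR means, 95th percentiles, maxima, and the fractions of iterations
#'   above the cautionary thresholds (HI > 1, TCR > 1e-4).
#' @export
glance.risk_distribution <- function(x, ...) {
  tibble::tibble(
    n_iter = x$n_iter,
    age_group = x$age_group,
    medium = x$medium,
    mean_hi = mean(x$hi),
    p95_hi = quantile(x$hi, 0.95, names = FALSE),
    max_hi = max(x$hi),
    frac_hi_gt_1 = mean(x$hi > 1),
    mean_tcr = mean(x$tcr),
    p95_tcr = quantile(x$tcr, 0.95, names = FALSE),
    max_tcr = max(x$tcr),
    frac_tcr_gt_1e4 = mean(x$tcr > 1e-4)
  )
}

#' @export
tidy.kruskal_dunn <- function(x, ...) x$pairwise

#' @export
glance.kruskal_dunn <- function(x, ...) x$omnibus
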