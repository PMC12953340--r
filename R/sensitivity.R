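## Tornado sensitivity analysis: Spearman rank correlation of every sampled
## Monte Carlo input against the per-iteration hazard index.

#' Spearman tornado sensitivity analysis
#'
#' Correlates each varying Monte Carlo input (per-metal concentration draws
#' `C_<metal>` and every sampled exposure parameter) with the
#' per-iteration hazard index, using Spearman rank correlation. Inputs
#' held at a point value are excluded — not reported as zero — and results
#' are ordered by absolute correlation (ties broken alphabetically), the
#' order used by a tornado plot.
#'
#' The Monte Carlo run must have retained its input draws
#' (`run_monte_carlo(..., keep_inputs = TRUE)`).
#'
#' @param dist A `risk_distribution` with retained inputs, n_iter >= 10.
#' @param metric Response to correlate against: `"HI"` (default) or
#'   `"TCR"`.
#' @return A tibble of class `sensitivity_result`: `input`, `rho`, `rank`.
#' @export
#' @examples
#' dist <- run_monte_carlo(
#'   conc = list(Pb = dist_lognormal(245, 282)),
#'   scenario = default_scenario("child"),
#'   n_iter = 1000, seed = 7, keep_inputs = TRUE
#' )
#' sensitivity_tornado(dist)
sensitivity_tornado <- function(dist, metric = c("HI", "TCR")) {
  stopifnot(inherits(dist, "risk_distribution"))
  metric <- match.arg(metric)
  if (is.null(dist$inputs)) {
    abort("input draws were not retained; rerun with keep_inputs = TRUE.")
  }
  if (dist$n_iter < 10) abort("sensitivity analysis requires n_iter >= 10.")
  y <- switch(metric, HI = dist$hi, TCR = dist$tcr)

  varying <- attr(dist$inputs, "varying")
  keep <- names(varying)[varying]
  ## derived averaging times are internal, not scenario inputs
  keep <- setdiff(keep, c("AT_nc", "AT_ca"))
  keep <- keep[vapply(keep, function(nm) sd(dist$inputs[[nm]]) > 0, logical(1))]
  if (!length(keep)) {
    abort("no varying inputs: every spec in this run is point-valued.")
  }
  rho <- vapply(keep, function(nm) {
    cor(dist$inputs[[nm]], y, method = "spearman")
  }, numeric(1))
  out <- tibble::tibble(input = keep, rho = unname(rho)) |>
    dplyr::arrange(dplyr::desc(abs(.data$rho)), .data$input) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("sensitivity_result", class(out))
  attr(out, "metric") <- metric
  out
}

#' Write a sensitivity table as delimited text and JSON
#'
#' @param sens A `sensitivity_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_sensitivity <- function(sens, dir, prefix = "sensitivity") {
  stopifnot(inherits(sens, "sensitivity_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, ".csv"))
  readr::write_csv(as.data.frame(sens), csv, progress = FALSE)
  js <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(as.data.frame(sens), js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
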