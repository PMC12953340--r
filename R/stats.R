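## Nonparametric comparisons: Mann-Whitney (optionally paired Wilcoxon),
## Kruskal-Wallis with Dunn's post hoc z tests, and Spearman rank
## correlation. Thin, tidy wrappers over base R's rank tests; Dunn's test
## is implemented here.

#' Mann-Whitney U test (with a paired Wilcoxon option)
#'
#' Compares two groups by ranks. The exact null distribution is used when
#' both groups have at most 8 observations and there are no ties; otherwise
#' the normal approximation with tie correction applies. `paired = TRUE`
#' switches to the Wilcoxon signed-rank test for home-matched designs.
#'
#' @param x,y Numeric vectors (each n >= 1).
#' @param alternative One of `"two_sided"`, `"less"`, `"greater"`.
#' @param paired Use the signed-rank test on matched pairs.
#' @return A one-row tibble: `test`, `statistic` (the U statistic, or V for
#'   the paired test), `p_value`, `n_x`, `n_y`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(10, 20, 30))
mann_whitney <- function(x, y, alternative = c("two_sided", "less", "greater"),
                         paired = FALSE) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) abort("both groups must be non-empty.")
  alt <- sub("two_sided", "two.sided", alternative)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !paired && !ties && length(x) <= 8 && length(y) <= 8
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = alt, paired = paired, exact = exact)
  )
  tibble::tibble(
    test = if (paired) "wilcoxon_signed_rank" else "mann_whitney",
    statistic = unname(res$statistic),
    p_value = res$p.value,
    n_x = length(x), n_y = length(y),
    method = if (exact) "exact" else "normal_approx"
  )
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Omnibus Kruskal-Wallis H (tie-corrected, chi-square reference with
#' k - 1 df) followed by Dunn's pairwise z statistics on the pooled mean
#' ranks. Pairwise comparisons are always computed; interpreting them in
#' light of the omnibus p-value is left to the caller. Adjusted p-values
#' are capped at 1.
#'
#' @param x Numeric vector of values.
#' @param g Group labels, same length as `x`; k >= 2 non-empty groups.
#' @param adjust Multiplicity adjustment for the pairwise p-values:
#'   `"bonferroni"` (default) or `"none"`.
#' @return A list of class `kruskal_dunn` with elements `omnibus` (one-row
#'   tibble: `statistic`, `df`, `p_value`, `n`) and `pairwise` (tibble:
#'   `group1`, `group2`, `z`, `p_value`, `p_adjusted`). [generics::tidy()]
#'   returns the pairwise table, [generics::glance()] the omnibus row.
#' @export
#' @examples
#' kruskal_dunn(c(1, 2, 3, 4, 5, 6, 7, 8, 9), rep(c("a", "b", "c"), each = 3))
kruskal_dunn <- function(x, g, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- as.character(g[keep])
  counts <- table(g)
  if (length(counts) < 2) abort("Kruskal-Wallis requires at least two groups.")
  if (any(counts == 0)) abort("all groups must be non-empty.")

  if (length(unique(x)) == 1L) {
    ## completely constant data: no separation by construction
    omnibus <- tibble::tibble(statistic = 0, df = length(counts) - 1L,
      p_value = 1, n = length(x))
  } else {
    kw <- kruskal.test(x, factor(g))
    omnibus <- tibble::tibble(
      statistic = unname(kw$statistic), df = unname(kw$parameter),
      p_value = kw$p.value, n = length(x)
    )
  }

  ## Dunn's z tests on pooled mean ranks, with tie correction
  r <- rank(x)
  n_tot <- length(x)
  tie_sizes <- table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n_tot - 1))
  mean_ranks <- tapply(r, g, mean)
  groups <- sort(names(counts))
  pairs <- utils::combn(groups, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) *
      (1 / counts[[p[1]]] + 1 / counts[[p[2]]]))
    (mean_ranks[[p[1]]] - mean_ranks[[p[2]]]) / se
  })
  p_raw <- 2 * pnorm(-abs(z))
  pairwise <- tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = unname(z), p_value = unname(p_raw),
    p_adjusted = p.adjust(unname(p_raw), method = adjust)
  )
  structure(list(omnibus = omnibus, pairwise = pairwise, adjust = adjust),
    class = "kruskal_dunn"
  )
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
    x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  cat("Dunn's post hoc (", x$adjust, " adjustment):\n", sep = "")
  print(x$pairwise)
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t approximation on \eqn{r_s \sqrt{(n-2)/(1-r_s^2)}}.
#'
#' @param x,y Numeric vectors of equal length, n >= 3; neither may be
#'   constant (the correlation is undefined for a constant vector).
#' @return A one-row tibble: `test`, `estimate` (rs), `p_value`, `n`.
#' @export
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("Spearman correlation requires n >= 3.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Spearman correlation is undefined for a constant vector.")
  }
  res <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(
    test = "spearman",
    estimate = unname(res$estimate),
    p_value = res$p.value,
    n = length(x)
  )
}

#' Correlate home metadata with per-metal home concentrations
#'
#' Convenience wrapper running [spearman_cor()] of a home metadata column
#' (home age by default) against each metal's home-mean concentration,
#' per medium.
#'
#' @param homes Home-summary tibble from [aggregate_homes()] including the
#'   metadata column.
#' @param var Metadata column name (default `"home_age_years"`).
#' @return A tibble with one row per (medium, metal): `estimate`,
#'   `p_value`, `n`.
#' @export
correlate_homes <- function(homes, var = "home_age_years") {
  if (!var %in% names(homes)) {
    abort(paste0("column `", var, "` not found in home summary."))
  }
  homes |>
    dplyr::group_by(.data$medium, .data$metal) |>
    dplyr::group_modify(function(d, ...) {
      out <- spearman_cor(d[[var]], d$mean_concentration)
      dplyr::select(out, -"test")
    }) |>
    dplyr::ungroup()
}
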