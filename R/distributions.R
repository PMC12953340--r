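## Distribution specifications for Monte Carlo inputs.
##
## Every sampled quantity in the risk engine (concentrations and exposure
## parameters) is described by a small spec object rather than a bare number,
## so that scenario files can swap a point value for a distribution without
## touching any code.

new_dist_spec <- function(kind, ...) {
  spec <- c(list(kind = kind), list(...))
  class(spec) <- "dist_spec"
  spec
}

#' Distribution specifications for Monte Carlo inputs
#'
#' Constructors for the distribution families the risk engine can sample:
#' a degenerate point value, uniform, triangular, truncated normal, and
#' lognormal parameterised by its natural-scale (arithmetic) mean and
#' standard deviation.
#'
#' `dist_lognormal()` moment-matches: given natural-scale mean \eqn{m} and
#' standard deviation \eqn{s}, the log-scale parameters are
#' \eqn{\sigma^2 = \log(1 + s^2/m^2)} and \eqn{\mu = \log(m) - \sigma^2/2},
#' so that draws reproduce the requested moments. A zero `sd` degenerates to
#' a point spec.
#'
#' @param value Point value (must be finite).
#' @param low,high Support bounds; `low < high` for uniform/triangular.
#' @param mode Mode of the triangular distribution, in `[low, high]`.
#' @param mean,sd Natural-scale mean and standard deviation.
#' @return An object of class `dist_spec`.
#' @seealso [draw()], [fit_lognormal_from_summary()]
#' @examples
#' dist_lognormal(245, 282)   # indoor-dust Pb, mg/kg
#' dist_triangular(10, 50, 100)
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
dist_point <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  new_dist_spec("point", value = as.numeric(value))
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(low, high) {
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    abort("`dist_uniform()` requires finite bounds with low < high.")
  }
  new_dist_spec("uniform", low = low, high = high)
}

#' @rdname dist_spec
#' @export
dist_triangular <- function(low, mode, high) {
  if (!all(is.finite(c(low, mode, high))) || low > mode || mode > high || low >= high) {
    abort("`dist_triangular()` requires low <= mode <= high with low < high.")
  }
  new_dist_spec("triangular", low = low, mode = mode, high = high)
}

#' @rdname dist_spec
#' @export
dist_truncnorm <- function(mean, sd, low = 0, high = Inf) {
  if (!is.finite(mean) || !is.finite(sd) || sd < 0) {
    abort("`dist_truncnorm()` requires finite mean and sd >= 0.")
  }
  if (low >= high) abort("`dist_truncnorm()` requires low < high.")
  if (sd == 0) return(dist_point(mean))
  ## rejection sampling is used for draws; refuse supports the normal
  ## essentially never visits
  p_in <- pnorm(high, mean, sd) - pnorm(low, mean, sd)
  if (p_in < 1e-6) {
    abort("`dist_truncnorm()` truncation bounds exclude virtually all mass.")
  }
  new_dist_spec("normal_truncated", mean = mean, sd = sd, low = low, high = high)
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(mean, sd) {
  fit_lognormal_from_summary(mean, sd)
}

#' Fit a lognormal spec from an arithmetic mean and SD
#'
#' Bridges published summary statistics (e.g. per-metal mean and SD of a
#' concentration table) to a sampleable concentration distribution by moment
#' matching: \eqn{\sigma^2 = \log(1 + sd^2/mean^2)},
#' \eqn{\mu = \log(mean) - \sigma^2/2}. With `sd = 0` the result degenerates
#' to a point spec at `mean`.
#'
#' @param mean Arithmetic (natural-scale) mean, must be > 0.
#' @param sd Arithmetic standard deviation, must be >= 0.
#' @return A `dist_spec` of kind `lognormal` (or `point` when `sd = 0`),
#'   carrying both the natural-scale moments and the log-scale `meanlog`,
#'   `sdlog`.
#' @export
#' @examples
#' spec <- fit_lognormal_from_summary(245, 282)
#' spec$meanlog  # ~5.08
#' spec$sdlog    # ~0.92
fit_lognormal_from_summary <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0) {
    abort("lognormal fitting requires a strictly positive natural-scale mean.")
  }
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0) {
    abort("lognormal fitting requires a non-negative natural-scale sd.")
  }
  if (sd == 0) return(dist_point(mean))
  sigma2 <- log(1 + sd^2 / mean^2)
  new_dist_spec("lognormal",
    mean = mean, sd = sd,
    meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2)
  )
}

#' Draw random variates from a distribution spec
#'
#' @param spec A [dist_spec] object.
#' @param n Number of draws.
#' @return A numeric vector of length `n`.
#' @export
#' @examples
#' set.seed(1)
#' draw(dist_lognormal(245, 282), 5)
draw <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"), is.numeric(n), n >= 0)
  n <- as.integer(n)
  switch(spec$kind,
    point = rep.int(spec$value, n),
    uniform = runif(n, spec$low, spec$high),
    triangular = draw_triangular(n, spec$low, spec$mode, spec$high),
    normal_truncated = draw_truncnorm(n, spec$mean, spec$sd, spec$low, spec$high),
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    abort(paste0("unknown distribution kind: ", spec$kind))
  )
}

## Inverse-CDF sampler for the triangular distribution.
draw_triangular <- function(n, low, mode, high) {
  u <- runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
    low + sqrt(u * (high - low) * (mode - low)),
    high - sqrt((1 - u) * (high - low) * (high - mode))
  )
}

## Truncated normal by rejection; acceptance probability was validated at
## construction so the loop terminates quickly in practice.
draw_truncnorm <- function(n, mean, sd, low, high) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    ## inflate proposals by the inverse acceptance rate to keep passes few
    p_in <- pnorm(high, mean, sd) - pnorm(low, mean, sd)
    x <- rnorm(ceiling(m / max(p_in, 1e-6)) + 8L, mean, sd)
    out <- c(out, x[x >= low & x <= high])
  }
  out[seq_len(n)]
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat("<dist_spec> ", x$kind, ": ",
    paste(names(pars), signif(unlist(pars), 5), sep = "=", collapse = ", "),
    "\n",
    sep = ""
  )
  invisible(x)
}

## TRUE when a spec actually varies between draws.
is_varying <- function(spec) {
  inherits(spec, "dist_spec") && spec$kind != "point"
}

## Parse a plain list (e.g. from YAML/JSON config) into a dist_spec.
as_dist_spec <- function(x) {
  if (inherits(x, "dist_spec")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(dist_point(x))
  if (!is.list(x) || is.null(x$kind)) {
    abort("cannot interpret value as a distribution spec; supply kind + parameters.")
  }
  switch(x$kind,
    point = dist_point(x$value),
    uniform = dist_uniform(x$low, x$high),
    triangular = dist_triangular(x$low, x$mode, x$high),
    normal_truncated = dist_truncnorm(x$mean, x$sd, x$low %||% 0, x$high %||% Inf),
    lognormal = fit_lognormal_from_summary(x$mean, x$sd),
    abort(paste0("unknown distribution kind: ", x$kind))
  )
}
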