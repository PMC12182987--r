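#' Zero-inflated gamma parameters
#'
#' A `zig_params` object describes the mixture used to model one brain
#' connection within one site (and stratum): a point mass of weight `lam`
#' at exactly zero, plus a gamma density with shape `gamma_shape` and scale
#' `beta` on the positive values. With `lam = 1` the gamma component is
#' undefined and must not be evaluated.
#'
#' @param lam zero-inflation weight in \[0, 1\].
#' @param beta gamma scale parameter (> 0), or `NA` when `lam = 1`.
#' @param gamma_shape gamma shape parameter (> 0), or `NA` when `lam = 1`.
#' @param n_obs,n_nonzero observation counts behind the fit (informational).
#' @param reliable logical; `FALSE` flags a fit based on fewer positive
#'   values than the configured minimum (see [fit_zig()]).
#' @return An object of class `zig_params`.
#' @export
zig_params <- function(lam, beta = NA_real_, gamma_shape = NA_real_,
                       n_obs = NA_integer_, n_nonzero = NA_integer_,
                       reliable = TRUE) {
  if (is.na(lam) || lam < 0 || lam > 1) stop("lam must be in [0, 1]")
  if (lam < 1) {
    if (is.na(beta) || beta <= 0) stop("beta must be positive when lam < 1")
    if (is.na(gamma_shape) || gamma_shape <= 0)
      stop("gamma_shape must be positive when lam < 1")
  }
  structure(list(lam = lam, beta = beta, gamma_shape = gamma_shape,
                 n_obs = as.integer(n_obs), n_nonzero = as.integer(n_nonzero),
                 reliable = isTRUE(reliable)),
            class = "zig_params")
}

#' @export
print.zig_params <- function(x, ...) {
  cat(sprintf("zig_params: lam = %.4g, shape = %.4g, scale = %.4g%s\n",
              x$lam, x$gamma_shape, x$beta,
              if (x$reliable) "" else "  [unreliable]"))
  invisible(x)
}

#' Fit a zero-inflated gamma distribution to one connection's sample
#'
#' The zero-inflation weight is estimated as the empirical fraction of exact
#' zeros (no epsilon thresholding: a tract count of zero is an exact zero).
#' The gamma shape and scale are the maximum-likelihood estimates on the
#' strictly positive values, obtained with [fitdistrplus::fitdist()]. The
#' shape is not constrained to be >= 1; a warning is emitted when the
#' estimate falls below 1.
#'
#' @param values non-negative numeric sample (one connection across the
#'   subjects of one site/stratum).
#' @param min_nonzero minimum number of positive values for a trusted gamma
#'   fit; below it the result is flagged unreliable (harmonization then
#'   passes the connection through unchanged).
#' @return A [zig_params()] object.
#' @examples
#' set.seed(1)
#' x <- c(rgamma(500, shape = 2, scale = 1.5), numeric(100))
#' fit_zig(x)
#' @export
fit_zig <- function(values, min_nonzero = 10L) {
  if (length(values) == 0L) stop("empty sample")
  if (anyNA(values)) stop("missing values in sample")
  if (any(values < 0)) stop("negative values in sample")
  n <- length(values)
  pos <- values[values > 0]
  lam <- 1 - length(pos) / n
  if (length(pos) == 0L)
    return(zig_params(1, n_obs = n, n_nonzero = 0L, reliable = TRUE))
  est <- gamma_mle(pos)
  if (is.null(est))
    return(structure(list(lam = lam, beta = NA_real_, gamma_shape = NA_real_,
                          n_obs = as.integer(n),
                          n_nonzero = length(pos), reliable = FALSE),
                     class = "zig_params"))
  if (est[["shape"]] < 1)
    warning("fitted gamma shape ", signif(est[["shape"]], 4), " is below 1")
  zig_params(lam, beta = est[["scale"]], gamma_shape = est[["shape"]],
             n_obs = n, n_nonzero = length(pos),
             reliable = length(pos) >= min_nonzero)
}

# Gamma MLE on strictly positive data; NULL when the fit cannot be trusted
# (degenerate sample or optimizer failure).
gamma_mle <- function(x) {
  if (length(x) < 2L || stats::var(x) == 0) return(NULL)
  fit <- tryCatch(
    suppressWarnings(fitdistrplus::fitdist(x, "gamma", keepdata = FALSE,
                                           control = list(reltol = 1e-14)
                                           )$estimate),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit)) return(NULL)
  c(shape = unname(fit["shape"]), scale = 1 / unname(fit["rate"]))
}

check_params <- function(params) {
  stopifnot(inherits(params, "zig_params"))
  if (params$lam < 1 && (is.na(params$beta) || is.na(params$gamma_shape)))
    stop("gamma component undefined for this fit")
  invisible(params)
}

#' Zero-inflated gamma density
#'
#' Continuous part of the mixture density: `(1 - lam) * g(c; shape, scale)`
#' for `c > 0`. The point mass at zero is a weight, not a density, and is
#' reported separately via the `zero_mass` attribute rather than conflated
#' into the returned values (the density at `c = 0` is returned as the limit
#' of the continuous part).
#'
#' @param c non-negative numeric vector of connectivity values.
#' @param params a [zig_params()] object with `lam < 1` (or all `c = 0`).
#' @return Numeric vector of continuous densities, with attribute
#'   `zero_mass = lam`.
#' @export
zig_pdf <- function(c, params) {
  check_params(params)
  if (any(c < 0)) stop("c must be non-negative")
  if (params$lam == 1) {
    if (any(c > 0)) stop("gamma component undefined when lam = 1")
    return(structure(rep(0, length(c)), zero_mass = 1))
  }
  dens <- (1 - params$lam) *
    stats::dgamma(c, shape = params$gamma_shape, scale = params$beta)
  structure(dens, zero_mass = params$lam)
}

#' Zero-inflated gamma cumulative distribution function
#'
#' `F(c) = lam * u(c) + (1 - lam) * G(c)` where `u(c)` is 0 for `c <= 0` and
#' 1 otherwise and `G` is the gamma CDF. Note `F(0) = 0` under this
#' convention: the zero point mass is accrued only strictly above zero,
#' which is what makes zeros map to zeros under harmonization.
#'
#' @param c numeric vector.
#' @param params a [zig_params()] object.
#' @return Probabilities in \[0, 1\].
#' @export
zig_cdf <- function(c, params) {
  check_params(params)
  u <- as.numeric(c > 0)
  g <- if (params$lam < 1)
    stats::pgamma(pmax(c, 0), shape = params$gamma_shape, scale = params$beta)
  else 0
  params$lam * u + (1 - params$lam) * g
}

#' Zero-inflated gamma quantile function (closed-form inverse CDF)
#'
#' Returns 0 for `p <= lam` and the gamma quantile of `(p - lam)/(1 - lam)`
#' otherwise. Probabilities are clipped to at most `1 - 1e-12` before the
#' gamma-quantile evaluation so outputs are always finite.
#'
#' @param p probabilities in \[0, 1\].
#' @param params a [zig_params()] object.
#' @return Non-negative quantiles.
#' @export
zig_invcdf <- function(p, params) {
  check_params(params)
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  p <- pmin(p, 1 - 1e-12)
  out <- numeric(length(p))
  up <- p > params$lam      # never true when lam = 1, thanks to the clip
  if (any(up)) {
    q <- (p[up] - params$lam) / (1 - params$lam)
    out[up] <- stats::qgamma(q, shape = params$gamma_shape,
                             scale = params$beta)
  }
  out
}

#' Draw from a zero-inflated gamma distribution
#'
#' @param n number of draws.
#' @param params a [zig_params()] object.
#' @return Non-negative numeric vector with exact zeros occurring with
#'   probability `lam`.
#' @export
zig_rand <- function(n, params) {
  check_params(params)
  zero <- stats::runif(n) < params$lam
  out <- numeric(n)
  if (any(!zero))
    out[!zero] <- stats::rgamma(sum(!zero), shape = params$gamma_shape,
                                scale = params$beta)
  out
}
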