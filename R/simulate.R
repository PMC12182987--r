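#' Specify one synthetic acquisition site
#'
#' Describes the statistical structure of one site's cohort for the
#' generator: per-connection zero-inflation weights and gamma parameters
#' (of the log-space distribution of connectivity), the covariate models,
#' and the sex ratio. Per-connection parameters may be a single value
#' (recycled), a vector of length `n_connections`, or a function `f(n)`
#' drawing `n` values (e.g. `function(n) runif(n, 0.05, 0.35)`); functions
#' are resolved once, at spec creation, under the spec's seed, so that
#' paired sites can share or vary parameters explicitly.
#'
#' @param site site label.
#' @param n_subjects cohort size (>= 1).
#' @param n_regions number of brain regions (defines
#'   `n_regions (n_regions - 1) / 2` connections). Default 21 gives 210
#'   connections; an 85-region spec reproduces the full 3570-connection
#'   connectome.
#' @param lam,gamma_shape,beta per-connection zero fraction, log-space gamma
#'   shape and scale: scalar, vector, or generator function (see above).
#' @param covariates named list; each element is a list with `mean`, `sd`
#'   and `effect` (per-connection linear effect of the centered covariate on
#'   log-space connectivity: scalar, vector, or function, resolved like the
#'   distribution parameters). Example:
#'   `list(age = list(mean = 70, sd = 8, effect = 0))`.
#' @param sex_ratio probability that a subject is male ("M" vs "F").
#' @param seed integer seed; drives both parameter resolution and
#'   [generate_site()].
#' @return A list of class `site_spec` with resolved per-connection
#'   parameter vectors.
#' @export
site_spec <- function(site, n_subjects, n_regions = 21L,
                      lam = 0.2, gamma_shape = 2, beta = 1,
                      covariates = list(), sex_ratio = 0.5, seed = 1L) {
  n_regions <- as.integer(n_regions)
  n_conn <- (n_regions * (n_regions - 1L)) %/% 2L
  resolve <- function(par, what) {
    v <- if (is.function(par)) par(n_conn) else rep_len(as.numeric(par), n_conn)
    if (length(v) != n_conn)
      stop(what, " resolved to length ", length(v), ", expected ", n_conn)
    v
  }
  out <- local({
    set.seed(seed)
    lam <- resolve(lam, "lam")
    shape <- resolve(gamma_shape, "gamma_shape")
    scale <- resolve(beta, "beta")
    covs <- lapply(covariates, function(cv) {
      list(mean = cv$mean, sd = cv$sd,
           effect = resolve(if (is.null(cv$effect)) 0 else cv$effect,
                            "covariate effect"))
    })
    list(lam = lam, shape = shape, scale = scale, covs = covs)
  })
  if (any(out$lam < 0 | out$lam > 1)) stop("lam must be in [0, 1]")
  if (any(out$shape <= 0) || any(out$scale <= 0))
    stop("gamma shape and scale must be positive")
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  structure(
    list(site = site, n_subjects = as.integer(n_subjects),
         n_regions = n_regions, n_connections = n_conn,
         lam = out$lam, gamma_shape = out$shape, beta = out$scale,
         covariates = out$covs, sex_ratio = sex_ratio,
         seed = as.integer(seed)),
    class = "site_spec")
}

#' Generate one site's synthetic cohort
#'
#' Draws, for every connection, exact zeros with the connection's
#' probability `lam` and log-space positive values from
#' `gamma(shape, scale)`; covariate effects `alpha (x - xbar)` are added in
#' log space to the positive draws (clamped at 0 so raw values stay
#' non-negative), and values are mapped to raw space with `expm1`. Sex and
#' covariates are drawn per subject from the spec. Fully reproducible from
#' the spec's seed.
#'
#' @param spec a [site_spec()].
#' @return A list with elements `table` (a `connectivity_table`) and `meta`
#'   (metadata data frame with `subject_id`, `site`, `sex` and one column
#'   per covariate).
#' @export
generate_site <- function(spec) {
  stopifnot(inherits(spec, "site_spec"))
  set.seed(spec$seed + 1L)      # spec creation consumed the base seed
  n <- spec$n_subjects
  nc <- spec$n_connections
  ids <- sprintf("%s_%04d", spec$site, seq_len(n))
  sex <- ifelse(stats::runif(n) < spec$sex_ratio, "M", "F")
  covvals <- lapply(spec$covariates, function(cv)
    stats::rnorm(n, cv$mean, cv$sd))
  vals <- matrix(0, n, nc)
  for (j in seq_len(nc)) {
    nonzero <- stats::runif(n) >= spec$lam[j]
    if (!any(nonzero)) next
    lv <- stats::rgamma(sum(nonzero), shape = spec$gamma_shape[j],
                        scale = spec$beta[j])
    for (cv_name in names(spec$covariates)) {
      cv <- spec$covariates[[cv_name]]
      x <- covvals[[cv_name]][nonzero]
      lv <- lv + cv$effect[j] * (x - mean(covvals[[cv_name]]))
    }
    vals[nonzero, j] <- expm1(pmax(lv, 0))
  }
  meta <- data.frame(subject_id = ids, site = spec$site, sex = sex,
                     stringsAsFactors = FALSE)
  for (cv_name in names(covvals)) meta[[cv_name]] <- covvals[[cv_name]]
  list(table = connectivity_table(vals, ids, spec$n_regions), meta = meta)
}

#' Generate a reference/new site pair
#'
#' Generates two cohorts whose site parameters (`lam`, shape, scale) differ
#' — the site effect — while, when `shared_effects = TRUE`, the new site
#' inherits the reference spec's covariate effect sizes, which is exactly
#' the regime in which distribution matching should recover the shared
#' biological signal from the pooled data.
#'
#' @param spec_ref,spec_new [site_spec()]s with equal `n_regions`.
#' @param shared_effects copy covariate effect sizes (and covariate
#'   means/sds) from `spec_ref` into `spec_new` before generating.
#' @return A list with elements `ref` and `new`, each a
#'   `list(table, meta)` as from [generate_site()], plus `meta` combining
#'   both cohorts.
#' @export
generate_paired_sites <- function(spec_ref, spec_new, shared_effects = TRUE) {
  stopifnot(inherits(spec_ref, "site_spec"), inherits(spec_new, "site_spec"))
  if (spec_ref$n_regions != spec_new$n_regions)
    stop("sites must share n_regions")
  if (shared_effects)
    spec_new$covariates <- spec_ref$covariates
  ref <- generate_site(spec_ref)
  new <- generate_site(spec_new)
  list(ref = ref, new = new, meta = rbind(ref$meta, new$meta))
}
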