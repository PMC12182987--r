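#' Fit a distribution-matching harmonization model
#'
#' For every brain connection (and optionally within each sex stratum), fits
#' a zero-inflated gamma distribution to the reference site and to the new
#' site, in `log(1 + c)` space. The fitted pair defines the per-connection
#' transform `T = F_ref^-1 o F_new` that [apply_harmonization()] uses to map
#' new-site values onto the reference site's distribution while preserving
#' percentiles, exact zeros, and within-site rank order.
#'
#' Connections whose fit is unreliable in either site (fewer than
#' `min_nonzero` positive values, or a failed gamma fit) are flagged for
#' passthrough and left unchanged by [apply_harmonization()].
#'
#' @param ref `connectivity_table` for the reference site.
#' @param new `connectivity_table` for the new site to be harmonized.
#' @param meta metadata data frame covering the subjects of both tables
#'   (columns `subject_id`, `site`, `sex`, ...).
#' @param stratify_by_sex fit and apply the transform separately within each
#'   sex group; requires non-missing `sex` for every subject, and every sex
#'   present in the new site must also be present in the reference site.
#' @param min_nonzero minimum positive-value count for a trusted gamma fit
#'   (see [fit_zig()]).
#' @param zero_preserving if `TRUE` (the default, and the primary design),
#'   the step function in the mixture CDF takes the value 0 at zero, so
#'   zeros always map to zeros. `FALSE` selects the non-zero-preserving
#'   variant in which a zero carries its site's full zero mass and may map
#'   to a positive value.
#' @return An object of class `dm_model`.
#' @export
fit_harmonization <- function(ref, new, meta, stratify_by_sex = FALSE,
                              min_nonzero = 10L, zero_preserving = TRUE) {
  stopifnot(inherits(ref, "connectivity_table"),
            inherits(new, "connectivity_table"))
  if (ref$n_regions != new$n_regions)
    stop("reference and new tables have different region counts")
  ref_meta <- align_metadata(ref, meta)
  new_meta <- align_metadata(new, meta)
  ref_site <- unique(ref_meta$site)
  new_site <- unique(new_meta$site)
  if (length(ref_site) != 1L || length(new_site) != 1L)
    stop("each table must hold subjects from a single site")

  if (stratify_by_sex) {
    if (anyNA(ref_meta$sex) || anyNA(new_meta$sex))
      stop("sex must be non-missing for every subject under stratification")
    strata <- sort(unique(new_meta$sex))
    missing_ref <- setdiff(strata, unique(ref_meta$sex))
    if (length(missing_ref))
      stop("sex stratum absent from the reference site: ",
           paste(missing_ref, collapse = ", "))
  } else {
    strata <- "all"
  }

  fit_site <- function(values) {
    # fits run in log space; zeros are invariant under log1p so lam is
    # identical in either space
    lv <- log1p(values)
    fits <- lapply(seq_len(ncol(lv)), function(j)
      fit_zig(lv[, j], min_nonzero = min_nonzero))
    list(lam = vapply(fits, `[[`, numeric(1), "lam"),
         gamma_shape = vapply(fits, `[[`, numeric(1), "gamma_shape"),
         beta = vapply(fits, `[[`, numeric(1), "beta"),
         n_obs = vapply(fits, `[[`, integer(1), "n_obs"),
         n_nonzero = vapply(fits, `[[`, integer(1), "n_nonzero"),
         reliable = vapply(fits, `[[`, logical(1), "reliable"))
  }

  per_stratum <- lapply(strata, function(st) {
    rsel <- if (identical(st, "all")) rep(TRUE, nrow(ref$values)) else
      ref_meta$sex == st
    nsel <- if (identical(st, "all")) rep(TRUE, nrow(new$values)) else
      new_meta$sex == st
    rfit <- fit_site(ref$values[rsel, , drop = FALSE])
    nfit <- fit_site(new$values[nsel, , drop = FALSE])
    list(ref = rfit, new = nfit,
         passthrough = !(rfit$reliable & nfit$reliable))
  })
  names(per_stratum) <- strata

  structure(
    list(reference_site = ref_site, new_site = new_site, strata = strata,
         n_regions = ref$n_regions, pair_index = ref$pair_index,
         per_stratum = per_stratum,
         config = list(stratify_by_sex = stratify_by_sex,
                       min_nonzero = as.integer(min_nonzero),
                       log_space = TRUE,
                       zero_preserving = zero_preserving,
                       quantile_clip = 1 - 1e-12)),
    class = "dm_model")
}

#' @export
print.dm_model <- function(x, ...) {
  cat("dm_model:", x$new_site, "->", x$reference_site, "\n")
  cat("  connections:", nrow(x$pair_index),
      " strata:", paste(x$strata, collapse = ", "), "\n")
  pt <- vapply(x$per_stratum, function(s) sum(s$passthrough), numeric(1))
  cat("  passthrough connections per stratum:",
      paste(pt, collapse = ", "), "\n")
  invisible(x)
}

stratum_params <- function(model, stratum, connection) {
  s <- model$per_stratum[[stratum]]
  make <- function(site) {
    lam <- s[[site]]$lam[connection]
    if (lam == 1)
      structure(list(lam = 1, beta = NA_real_, gamma_shape = NA_real_,
                     n_obs = s[[site]]$n_obs[connection],
                     n_nonzero = 0L, reliable = TRUE), class = "zig_params")
    else
      structure(list(lam = lam, beta = s[[site]]$beta[connection],
                     gamma_shape = s[[site]]$gamma_shape[connection],
                     n_obs = s[[site]]$n_obs[connection],
                     n_nonzero = s[[site]]$n_nonzero[connection],
                     reliable = s[[site]]$reliable[connection]),
                class = "zig_params")
  }
  list(ref = make("ref"), new = make("new"))
}

#' Apply a fitted harmonization model to new-site data
#'
#' Maps every value `c` of the new site through
#' `expm1( F_ref^-1( F_new( log1p(c) ) ) )` using the per-connection (and
#' per-stratum) fits stored in the model. Exact zeros always map to exact
#' zeros (in the default zero-preserving design); nonzero values map to zero
#' when the reference site has a larger zero fraction and the value's
#' percentile falls inside the reference zero mass. Passthrough connections
#' are returned unchanged.
#'
#' @param model a `dm_model` from [fit_harmonization()].
#' @param new `connectivity_table` of new-site subjects (same region count
#'   as the model).
#' @param meta metadata for the subjects of `new`; only needed to resolve
#'   sex strata when the model was fitted with `stratify_by_sex = TRUE`.
#' @return A `connectivity_table` of harmonized values.
#' @export
apply_harmonization <- function(model, new, meta = NULL) {
  stopifnot(inherits(model, "dm_model"), inherits(new, "connectivity_table"))
  if (new$n_regions != model$n_regions)
    stop("table does not match the model's region count")
  clip <- model$config$quantile_clip
  stratified <- !identical(model$strata, "all")
  if (stratified) {
    if (is.null(meta)) stop("metadata required for a sex-stratified model")
    new_meta <- align_metadata(new, meta)
    if (anyNA(new_meta$sex)) stop("subject with unresolvable sex stratum")
    unknown <- setdiff(unique(new_meta$sex), model$strata)
    if (length(unknown))
      stop("sex stratum not present in the model: ",
           paste(unknown, collapse = ", "))
  }

  out <- new$values
  for (st in model$strata) {
    rows <- if (stratified) which(new_meta$sex == st) else
      seq_len(nrow(new$values))
    if (!length(rows)) next
    s <- model$per_stratum[[st]]
    for (j in seq_len(ncol(out))) {
      if (s$passthrough[j]) next
      x <- log1p(new$values[rows, j])
      lam_n <- s$new$lam[j]
      p <- if (lam_n == 1) numeric(length(x)) else
        lam_n * (x > 0) + (1 - lam_n) *
          stats::pgamma(x, shape = s$new$gamma_shape[j], scale = s$new$beta[j])
      if (!model$config$zero_preserving)
        p[x == 0] <- lam_n
      p <- pmin(p, clip)
      lam_r <- s$ref$lam[j]
      y <- numeric(length(p))
      up <- p > lam_r
      if (any(up))
        y[up] <- stats::qgamma((p[up] - lam_r) / (1 - lam_r),
                               shape = s$ref$gamma_shape[j],
                               scale = s$ref$beta[j])
      out[rows, j] <- expm1(y)
    }
  }
  out[out < 0] <- 0   # guard against expm1 rounding at tiny quantiles
  with_values(new, out)
}

#' Remove a linear covariate effect before harmonization
#'
#' Within each site, fits the per-connection least-squares slope of
#' connectivity on the centered covariate, `c = cbar + alpha (x - xbar) + e`,
#' and returns the residualized values `c - alpha (x - xbar)`. Slopes are
#' recorded per site and connection so the caller can restore the effect
#' after harmonization if desired. Residualized values may be slightly
#' negative; the returned table deliberately skips the non-negativity check.
#'
#' @param table a `connectivity_table`.
#' @param meta metadata covering the table's subjects; must contain `site`
#'   and the covariate column.
#' @param covariate name of a numeric metadata column, non-missing for all
#'   subjects of the table.
#' @return A list with elements `table` (residualized values) and `slopes`
#'   (data frame with columns `site`, `connection`, `alpha`).
#' @export
residualize_covariate <- function(table, meta, covariate) {
  stopifnot(inherits(table, "connectivity_table"))
  m <- align_metadata(table, meta)
  if (!covariate %in% names(m)) stop("covariate not found: ", covariate)
  x <- as.numeric(m[[covariate]])
  if (anyNA(x)) stop("covariate has missing values; drop those subjects first")
  vals <- table$values
  slopes <- list()
  for (site in unique(m$site)) {
    rows <- which(m$site == site)
    xc <- x[rows] - mean(x[rows])
    ssx <- sum(xc^2)
    if (ssx == 0) stop("covariate is constant within site ", site)
    alpha <- as.numeric(crossprod(vals[rows, , drop = FALSE], xc)) / ssx
    vals[rows, ] <- vals[rows, , drop = FALSE] - outer(xc, alpha)
    slopes[[site]] <- data.frame(site = site,
                                 connection = seq_along(alpha),
                                 alpha = alpha)
  }
  out <- table
  out$values <- vals          # bypasses the >= 0 invariant on purpose
  list(table = out, slopes = do.call(rbind, c(slopes, make.row.names = FALSE)))
}

#' Persist and reload a harmonization model
#'
#' The model is written as a single JSON document (per stratum and site:
#' `lam`, `beta`, `gamma_shape`, observation counts and reliability flags,
#' plus the configuration used), so fitting and application can run in
#' separate sessions.
#'
#' @param model a `dm_model`.
#' @param path JSON file path.
#' @return `write_harmonization_model()` invisibly returns `path`;
#'   `read_harmonization_model()` returns the `dm_model`.
#' @export
write_harmonization_model <- function(model, path) {
  stopifnot(inherits(model, "dm_model"))
  obj <- unclass(model)
  obj$pair_index <- unname(as.data.frame(obj$pair_index))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_harmonization_model
#' @export
read_harmonization_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$pair_index <- cbind(i = obj$pair_index[[1]], j = obj$pair_index[[2]])
  obj$per_stratum <- lapply(obj$per_stratum, function(s) {
    for (site in c("ref", "new")) {
      s[[site]]$lam[is.na(s[[site]]$lam)] <- NA_real_
      s[[site]]$n_obs <- as.integer(s[[site]]$n_obs)
      s[[site]]$n_nonzero <- as.integer(s[[site]]$n_nonzero)
    }
    s
  })
  obj$config$min_nonzero <- as.integer(obj$config$min_nonzero)
  structure(obj, class = "dm_model")
}
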