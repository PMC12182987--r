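#' Bounded connectivity transform
#'
#' Confines connectivity values to `[0, 1)` for robust correlation analysis:
#' each value becomes `1 - exp(-c / cbar)` where `cbar` is the
#' cross-subject mean of its connection. Order within a connection is
#' preserved; all-zero connections stay all-zero.
#'
#' @param table a `connectivity_table`.
#' @return A `connectivity_table` of transformed values.
#' @export
bounded_transform <- function(table) {
  stopifnot(inherits(table, "connectivity_table"))
  cbar <- colMeans(table$values)
  out <- table$values
  nz <- cbar > 0
  out[, nz] <- 1 - exp(-sweep(table$values[, nz, drop = FALSE], 2,
                              cbar[nz], "/"))
  out[, !nz] <- 0
  with_values(table, out)
}

#' Correlate every connection with a covariate
#'
#' Pearson correlation between each connection and a numeric covariate,
#' computed after the bounded transform (the default, as in the evaluation
#' design). Subjects with a missing covariate are dropped. Two-sided
#' p-values come from the standard t transform of r; the Bonferroni factor
#' is the number of connections tested in this run.
#'
#' @param table a `connectivity_table`.
#' @param meta metadata covering the table's subjects.
#' @param covariate name of a numeric metadata column.
#' @param bounded apply [bounded_transform()] first (default `TRUE`).
#' @return A data frame of class `connection_stats` with one row per
#'   connection: region pair `i`, `j`, `r`, two-sided `p`, Bonferroni
#'   `p_bonf`, significance `s = -log(p)` (natural log) and `n_used`.
#'   Zero-variance connections yield `NA` statistics and are excluded from
#'   downstream summaries.
#' @export
correlate_connections <- function(table, meta, covariate, bounded = TRUE) {
  stopifnot(inherits(table, "connectivity_table"))
  m <- align_metadata(table, meta)
  if (!covariate %in% names(m)) stop("covariate not found: ", covariate)
  x <- as.numeric(m[[covariate]])
  keep <- !is.na(x)
  if (sum(keep) < 3L) stop("fewer than 3 subjects with a usable covariate")
  vals <- table$values[keep, , drop = FALSE]
  x <- x[keep]
  if (bounded) {
    sub <- connectivity_table(vals, table$subject_ids[keep], table$n_regions)
    vals <- bounded_transform(sub)$values
  }
  n <- length(x)
  sds <- apply(vals, 2, stats::sd)
  r <- rep(NA_real_, ncol(vals))
  ok <- sds > 0 & stats::sd(x) > 0
  if (any(ok))
    r[ok] <- as.numeric(stats::cor(vals[, ok, drop = FALSE], x))
  if (any(!ok))
    message(sum(!ok), " zero-variance connection(s) recorded as missing")
  # two-sided p via the t transform, as in cor.test
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  n_conn <- ncol(vals)
  out <- data.frame(connection = seq_len(n_conn),
                    i = table$pair_index[, 1], j = table$pair_index[, 2],
                    r = r, p = p,
                    p_bonf = pmin(1, p * n_conn),
                    s = -log(p), n_used = n)
  class(out) <- c("connection_stats", "data.frame")
  out
}

#' Summarize a harmonization's effect on correlation strength
#'
#' Pairs post- and pre-harmonization per-connection correlations and
#' computes the four headline measures of the evaluation battery: mean and
#' SD of |r| (post), the p-value of the one-sided Wilcoxon signed-rank test
#' of `|r_post| > |r_pre|`, the number of connections whose Bonferroni
#' p-value stays below 0.05 (post), and the smallest Bonferroni p-value
#' (post), together with the per-connection change in significance
#' `delta_s = s_post - s_pre`. Zero differences in |r| are discarded before
#' ranking (the test's usual convention); when every difference is zero the
#' p-value is degenerate and reported as 1 with a warning. Connections with
#' missing r in either collection are excluded from pairing.
#'
#' @param post,pre `connection_stats` data frames over the same connection
#'   set (from [correlate_connections()]), after and before harmonization.
#' @return A list of class `dm_evaluation`: `mean_abs_r`, `std_abs_r`,
#'   `wilcoxon_p`, `n_significant`, `min_p_bonf`, and a data frame
#'   `delta_s` with columns `connection`, `i`, `j`, `delta_s`.
#' @export
compare_to_baseline <- function(post, pre) {
  if (nrow(post) != nrow(pre) ||
      any(post$i != pre$i) || any(post$j != pre$j))
    stop("post and pre statistics cover different connection sets")
  ok <- !is.na(post$r) & !is.na(pre$r)
  a <- abs(post$r[ok]); b <- abs(pre$r[ok])
  d <- a - b
  if (all(d == 0)) {
    warning("all paired |r| differences are zero; Wilcoxon p degenerate")
    wp <- 1
  } else {
    # exact null for small tie-free samples, normal approximation otherwise
    # (wilcox.test's own switching rule)
    wp <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE,
                         alternative = "greater")$p.value)
  }
  structure(
    list(mean_abs_r = mean(a), std_abs_r = stats::sd(a),
         wilcoxon_p = wp,
         n_significant = sum(post$p_bonf[ok] < 0.05),
         min_p_bonf = min(post$p_bonf[ok]),
         delta_s = data.frame(connection = post$connection[ok],
                              i = post$i[ok], j = post$j[ok],
                              delta_s = post$s[ok] - pre$s[ok])),
    class = "dm_evaluation")
}

#' @export
print.dm_evaluation <- function(x, ...) {
  cat(sprintf("mean |r| = %.4f +/- %.4f\n", x$mean_abs_r, x$std_abs_r))
  cat(sprintf("one-sided Wilcoxon signed-rank p = %.3g\n", x$wilcoxon_p))
  cat(sprintf("connections with Bonferroni p < 0.05: %d\n", x$n_significant))
  cat(sprintf("minimum Bonferroni p = %.3g\n", x$min_p_bonf))
  invisible(x)
}

#' Pick connections at quantiles of the significance change
#'
#' Sorts connections by `delta_s` and returns those at the requested
#' quantiles under the nearest-rank rule (quantile q maps to order statistic
#' `max(1, ceiling(q * n))`). The defaults select the smallest, 25th
#' percentile, median, 75th percentile and largest `delta_s`. Ties are
#' broken by connection index.
#'
#' @param summary a `dm_evaluation` from [compare_to_baseline()] (or any
#'   data frame with columns `connection` and `delta_s`).
#' @param quantiles numeric vector of quantiles in \[0, 1\].
#' @return The selected rows of the `delta_s` table, ordered as requested,
#'   with a `quantile` column.
#' @export
rank_by_delta_s <- function(summary,
                            quantiles = c(0, 0.25, 0.5, 0.75, 1)) {
  ds <- if (inherits(summary, "dm_evaluation")) summary$delta_s else summary
  if (is.null(ds) || nrow(ds) == 0L) stop("no delta_s values available")
  ord <- order(ds$delta_s, ds$connection)
  n <- nrow(ds)
  ranks <- pmax(1L, ceiling(quantiles * n))
  out <- ds[ord[ranks], , drop = FALSE]
  out$quantile <- quantiles
  rownames(out) <- NULL
  out
}

#' Stability of a connection's fit under subject subsampling
#'
#' Repeatedly draws uniform random subsets (without replacement) of one
#' connection's sample, refits the zero-inflated gamma each time, and
#' returns all refits next to the full-sample fit — a permutation picture of
#' how much a reduced cohort can distort the estimated distribution. Fully
#' reproducible from the seed.
#'
#' @param values one connection's non-negative sample across subjects.
#' @param subset_size subset size, strictly less than `length(values)`.
#' @param n_perm number of random subsets.
#' @param seed integer seed.
#' @param grid optional grid of values at which to evaluate each refit's
#'   continuous density; defaults to 200 points spanning the positive data.
#' @return A list of class `dm_stability`: `full` (the full-sample
#'   [zig_params()]), `fits` (list of per-permutation fits), `params`
#'   (data frame of per-permutation `lam`, `gamma_shape`, `beta`), `grid`,
#'   and `densities` (`n_perm` x `length(grid)` matrix of continuous mixture
#'   densities, `NA` rows for unreliable refits).
#' @export
subsample_stability <- function(values, subset_size, n_perm = 1000L,
                                seed = 1L, grid = NULL) {
  n <- length(values)
  if (subset_size >= n) stop("subset_size must be smaller than the sample")
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (is.null(grid)) {
    pos <- values[values > 0]
    grid <- seq(0, if (length(pos)) max(pos) * 1.2 else 1, length.out = 200)
  }
  full <- fit_zig(values)
  rng <- local({ set.seed(seed); lapply(seq_len(n_perm), function(k)
    sample.int(n, subset_size)) })
  fits <- lapply(rng, function(idx) fit_zig(values[idx]))
  dens <- t(vapply(fits, function(f) {
    if (f$lam < 1 && !is.na(f$beta))
      as.numeric(zig_pdf(grid, f))
    else rep(NA_real_, length(grid))
  }, numeric(length(grid))))
  structure(
    list(full = full, fits = fits,
         params = data.frame(
           lam = vapply(fits, `[[`, numeric(1), "lam"),
           gamma_shape = vapply(fits, `[[`, numeric(1), "gamma_shape"),
           beta = vapply(fits, `[[`, numeric(1), "beta")),
         grid = grid, densities = dens),
    class = "dm_stability")
}
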