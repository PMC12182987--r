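# Shared fixtures, built in code. Oracles that cross-check package routines
# deliberately use base stats only.

# Draw raw-space connectivity whose log1p follows a zero-inflated gamma:
# zeros with probability lam, otherwise expm1(gamma(shape, scale)).
rzig_raw <- function(n, lam, shape, scale) {
  zero <- runif(n) < lam
  out <- numeric(n)
  out[!zero] <- expm1(rgamma(sum(!zero), shape = shape, scale = scale))
  out
}

# Table with given value matrix and minimal metadata for one or two sites.
make_table <- function(values, n_regions, site = "A", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("%s_%03d", site, seq_len(nrow(values)))
  connectivity_table(values, ids, n_regions)
}

meta_for <- function(table, site, sex = NULL, ...) {
  n <- nrow(table$values)
  df <- data.frame(subject_id = table$subject_ids, site = site,
                   sex = if (is.null(sex)) NA_character_ else sex,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# Exact gamma MLE via the profile score equation; precision limited only by
# uniroot's tolerance. Independent of fitdistrplus.
gamma_mle_oracle <- function(x) {
  s <- log(mean(x)) - mean(log(x))
  shape <- uniroot(function(k) log(k) - digamma(k) - s,
                   c(1e-8, 1e8), tol = 1e-14)$root
  c(shape = shape, scale = mean(x) / shape)
}

# Random paired-site fixture in raw space (log-space ZIG per connection).
random_paired_fixture <- function(n_conn = 15, n_subj = 120, seed = 1) {
  set.seed(seed)
  r <- dmconn:::n_regions_for(n_conn)
  par <- function() list(lam = runif(n_conn, 0, 0.4),
                         shape = runif(n_conn, 1.5, 4),
                         scale = runif(n_conn, 0.5, 2))
  gen <- function(par, site) {
    vals <- sapply(seq_len(n_conn), function(j)
      rzig_raw(n_subj, par$lam[j], par$shape[j], par$scale[j]))
    make_table(vals, r, site = site)
  }
  pr <- par(); pn <- par()
  ref <- gen(pr, "R"); new <- gen(pn, "N")
  list(ref = ref, new = new,
       meta = rbind(meta_for(ref, "R"), meta_for(new, "N")))
}
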