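test_that("self-harmonization is the identity within 1e-8 on nonzeros", {
  fx <- random_paired_fixture(n_conn = 15, n_subj = 150, seed = 42)
  meta <- meta_for(fx$ref, "R")
  mod <- fit_harmonization(fx$ref, fx$ref, meta)
  out <- apply_harmonization(mod, fx$ref)
  nz <- fx$ref$values > 0
  expect_lt(max(abs(out$values[nz] - fx$ref$values[nz]) /
                fx$ref$values[nz]), 1e-8)
  expect_identical(out$values[!nz], fx$ref$values[!nz])
})

test_that("harmonization maps zeros to zeros and preserves nonzero ranks", {
  for (seed in 1:3) {
    fx <- random_paired_fixture(n_conn = 15, n_subj = 120, seed = seed)
    mod <- fit_harmonization(fx$ref, fx$new, fx$meta)
    out <- apply_harmonization(mod, fx$new)
    expect_true(all(out$values[fx$new$values == 0] == 0))
    expect_true(all(out$values >= 0))
    # monotone per connection: order of inputs preserved
    for (j in seq_len(ncol(out$values))) {
      ord <- order(fx$new$values[, j])
      expect_true(all(diff(out$values[ord, j]) >= 0))
    }
  }
})

test_that("a connection all-zero in the new site stays all-zero", {
  fx <- random_paired_fixture(n_conn = 15, n_subj = 80, seed = 9)
  vals <- fx$new$values
  vals[, 4] <- 0
  new <- make_table(vals, fx$new$n_regions, ids = fx$new$subject_ids)
  mod <- fit_harmonization(fx$ref, new, fx$meta)
  expect_equal(mod$per_stratum$all$new$lam[4], 1)
  out <- apply_harmonization(mod, new)
  expect_true(all(out$values[, 4] == 0))
})

test_that("nonzero values map to zero when the reference has the larger zero mass", {
  set.seed(77)
  # ref lam 0.5 >> new lam 0: low new-site percentiles fall inside the
  # reference zero mass
  ref_vals <- cbind(rzig_raw(400, 0.5, 2, 1), rzig_raw(400, 0.1, 2, 1),
                    rzig_raw(400, 0.1, 2, 1))
  new_vals <- cbind(rzig_raw(400, 0.0, 2, 1), rzig_raw(400, 0.1, 2, 1),
                    rzig_raw(400, 0.1, 2, 1))
  ref <- make_table(ref_vals, 3, site = "R")
  new <- make_table(new_vals, 3, site = "N")
  meta <- rbind(meta_for(ref, "R"), meta_for(new, "N"))
  mod <- fit_harmonization(ref, new, meta)
  out <- apply_harmonization(mod, new)
  frac0 <- mean(out$values[, 1] == 0)
  expect_gt(frac0, 0.4)       # roughly the reference zero fraction
  expect_lt(frac0, 0.6)
})

test_that("sex stratification fits strata independently and validates labels", {
  set.seed(13)
  n <- 200
  # males and females differ in scale in the new site only
  mk <- function(scales, site) {
    sex <- rep(c("M", "F"), each = n / 2)
    vals <- sapply(1:3, function(j)
      c(expm1(rgamma(n / 2, 2, scale = scales[1])),
        expm1(rgamma(n / 2, 2, scale = scales[2]))))
    tab <- make_table(vals, 3, site = site)
    list(tab = tab, meta = meta_for(tab, site, sex = sex))
  }
  ref <- mk(c(1, 1), "R"); new <- mk(c(2, 0.5), "N")
  meta <- rbind(ref$meta, new$meta)
  mod <- fit_harmonization(ref$tab, new$tab, meta, stratify_by_sex = TRUE)
  expect_setequal(mod$strata, c("M", "F"))
  expect_false(isTRUE(all.equal(mod$per_stratum$M$new$beta,
                                mod$per_stratum$F$new$beta)))
  out <- apply_harmonization(mod, new$tab, meta)
  # both strata pulled toward the common reference: pooled means align
  expect_lt(abs(mean(log1p(out$values)) - mean(log1p(ref$tab$values))), 0.1)

  bad <- meta; bad$sex[3] <- NA
  expect_error(fit_harmonization(ref$tab, new$tab, bad,
                                 stratify_by_sex = TRUE), "non-missing")
  bad2 <- meta; bad2$sex[bad2$site == "R"] <- "M"
  expect_error(fit_harmonization(ref$tab, new$tab, bad2,
                                 stratify_by_sex = TRUE), "absent")
})

test_that("unreliable fits pass the connection through unchanged", {
  fx <- random_paired_fixture(n_conn = 15, n_subj = 100, seed = 3)
  vals <- fx$new$values
  vals[, 7] <- 0
  vals[1:4, 7] <- rexp(4) + 0.5          # only 4 nonzeros: below min_nonzero
  new <- make_table(vals, fx$new$n_regions, ids = fx$new$subject_ids)
  mod <- fit_harmonization(fx$ref, new, fx$meta)
  expect_true(mod$per_stratum$all$passthrough[7])
  out <- apply_harmonization(mod, new)
  expect_identical(out$values[, 7], new$values[, 7])
  expect_false(any(mod$per_stratum$all$passthrough[-7]))
})

test_that("harmonized new-site distribution aligns with the reference", {
  set.seed(123)
  n <- 1500
  ref <- make_table(cbind(rzig_raw(n, 0.4, 3, 2)), 2, site = "R")
  new <- make_table(cbind(rzig_raw(n, 0.2, 2, 1)), 2, site = "N")
  meta <- rbind(meta_for(ref, "R"), meta_for(new, "N"))
  mod <- fit_harmonization(ref, new, meta)
  out <- apply_harmonization(mod, new)
  expect_lt(abs(mean(out$values == 0) - 0.4), 0.03)
  ks <- suppressWarnings(
    ks.test(out$values[out$values > 0], ref$values[ref$values > 0]))
  n1 <- sum(out$values > 0); n2 <- sum(ref$values > 0)
  expect_lt(ks$statistic, 1.358 * sqrt((n1 + n2) / (n1 * n2)))
})

test_that("re-harmonizing an already harmonized table changes little", {
  fx <- random_paired_fixture(n_conn = 15, n_subj = 400, seed = 21)
  mod <- fit_harmonization(fx$ref, fx$new, fx$meta)
  once <- apply_harmonization(mod, fx$new)
  meta2 <- fx$meta
  mod2 <- fit_harmonization(fx$ref, once, meta2)
  twice <- apply_harmonization(mod2, once)
  nz <- once$values > 0 & twice$values > 0
  # second pass moves values by less than typical one-pass sampling noise
  shift1 <- median(abs(log1p(once$values[nz]) - log1p(fx$new$values[nz])))
  shift2 <- median(abs(log1p(twice$values[nz]) - log1p(once$values[nz])))
  expect_lt(shift2, shift1)
})

test_that("model JSON round-trips and reproduces the transform exactly", {
  fx <- random_paired_fixture(n_conn = 15, n_subj = 90, seed = 6)
  mod <- fit_harmonization(fx$ref, fx$new, fx$meta)
  path <- withr::local_tempfile(fileext = ".json")
  write_harmonization_model(mod, path)
  back <- read_harmonization_model(path)
  expect_equal(back$reference_site, mod$reference_site)
  expect_equal(back$per_stratum$all$ref$lam, mod$per_stratum$all$ref$lam)
  out1 <- apply_harmonization(mod, fx$new)
  out2 <- apply_harmonization(back, fx$new)
  expect_equal(out1$values, out2$values, tolerance = 1e-12)
})

test_that("the non-zero-preserving variant can move zeros off zero", {
  set.seed(55)
  ref <- make_table(cbind(rzig_raw(300, 0.05, 3, 1.5)), 2, site = "R")
  new <- make_table(cbind(rzig_raw(300, 0.5, 2, 1)), 2, site = "N")
  meta <- rbind(meta_for(ref, "R"), meta_for(new, "N"))
  mod <- fit_harmonization(ref, new, meta, zero_preserving = FALSE)
  out <- apply_harmonization(mod, new)
  zeros <- new$values[, 1] == 0
  expect_true(any(out$values[zeros, 1] > 0))
})

test_that("residualization removes a linear covariate effect", {
  set.seed(17)
  n <- 300
  x <- rnorm(n, 70, 8)
  noise <- matrix(rnorm(n * 3, sd = 0.5), n, 3)
  vals <- 20 + 0.3 * (x - mean(x)) + noise   # intercept far from 0: stays positive
  tab <- make_table(vals, 3, site = "A")
  meta <- meta_for(tab, "A", age = x)
  res <- residualize_covariate(tab, meta, "age")
  se <- 0.5 / sqrt(sum((x - mean(x))^2))   # slope SE at known noise sd
  expect_true(all(abs(res$slopes$alpha - 0.3) < 3 * se + 0.02))
  for (j in 1:3)
    expect_lt(abs(cor(res$table$values[, j], x)), 1e-10)

  # uncorrelated covariate: slopes near zero, values nearly unchanged
  meta$junk <- rnorm(n)
  res2 <- residualize_covariate(tab, meta, "junk")
  expect_true(all(abs(res2$slopes$alpha) < 0.5))
  expect_lt(max(abs(res2$table$values - tab$values)), 2)

  meta$flat <- 1
  expect_error(residualize_covariate(tab, meta, "flat"), "constant")
  meta$age[1] <- NA
  expect_error(residualize_covariate(tab, meta, "age"), "missing")
})
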