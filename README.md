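# dmconn

Distribution-matching harmonization of structural brain connectivity.

## The problem

Pooling diffusion-MRI structural connectomes from several sites or scanners
adds statistical power, but scanner hardware and acquisition protocols shift
each connection's distribution in ways that have nothing to do with biology.
Generic batch-correction tools built on Gaussian location/scale models (such
as ComBat-style adjustments) are a poor fit for structural connectivity,
which is non-negative, strongly right-skewed, and sparse — a large fraction
of region pairs have exactly zero streamlines — and they can turn exact
zeros into spurious (even negative) connections.

`dmconn` is for researchers who already have per-subject connectivity
matrices (any parcellation; 85 regions and 3570 unique connections in a
typical FreeSurfer-based pipeline) plus a table of subject metadata, and who
want to map one site's cohort onto a reference site's distribution before
pooled analysis.

## The model

For each brain connection, within each site, connectivity `c >= 0` (after
`c <- log(1 + c)`) is modeled as a zero-inflated gamma mixture:

    f(c) = lambda * delta+(c) + (1 - lambda) * g(c; gamma, beta)

where `lambda` is the fraction of exact zeros, `delta+` a one-sided point
mass at the origin, and `g` the gamma density with shape `gamma` and scale
`beta`. The mixture CDF is

    F(c) = lambda * u(c) + (1 - lambda) * G(c; gamma, beta),   u(0) = 0,

and its inverse has the closed form

    F^-1(p) = 0                                   for p <= lambda
            = G^-1((p - lambda) / (1 - lambda))   for p >  lambda.

Harmonization of a new site N onto a reference site R is quantile mapping
with these parametric CDFs, independently per connection:

    T_{N->R} = F_R^-1 o F_N,

followed by `c <- exp(c) - 1` to return to the raw scale. Because `u(0) = 0`,
zeros always map to zeros; the map is monotone, so within-site rank order is
preserved; and outputs are non-negative by construction. `lambda` is
estimated as the empirical zero fraction and (`gamma`, `beta`) by maximum
likelihood on the positive values. An optional sex-stratified mode fits and
applies the transform separately for male and female subjects, and a linear
residualization helper removes the effect of a continuous covariate
(`c - alpha (x - xbar)`) before harmonization.

The package also provides effective-conductance augmentation (indirect,
multi-synaptic connectivity via the graph-Laplacian pseudoinverse), the
evaluation battery used to judge harmonization (bounded transform
`1 - exp(-c / cbar)`, per-connection Pearson correlation with a covariate,
one-sided Wilcoxon signed-rank comparison of |r| against baseline,
Bonferroni accounting, ranking by the change in significance
`delta_s = -log p_post + log p_pre`, subsampling stability of a fit), and a
seed-reproducible synthetic multi-site generator so everything is testable
without imaging data.

## Worked example

Two synthetic 21-region sites (210 connections, 300 subjects each) share an
age effect on 20 connections, but the new site's connectivity scale is
shifted — the situation harmonization exists for:

```r
library(dmconn)

spec_ref <- site_spec("siteA", n_subjects = 300, n_regions = 21,
                      lam = function(n) runif(n, 0.05, 0.35),
                      gamma_shape = function(n) runif(n, 1.5, 4),
                      beta = function(n) runif(n, 0.5, 2),
                      covariates = list(age = list(mean = 70, sd = 8,
                        effect = function(n) ifelse(seq_len(n) <= 20, 0.3, 0))),
                      seed = 11)
spec_new <- site_spec("siteB", n_subjects = 300, n_regions = 21,
                      lam = function(n) runif(n, 0.05, 0.35),
                      gamma_shape = function(n) runif(n, 1.5, 4),
                      beta = function(n) runif(n, 1.5, 4),   # site shift
                      seed = 22)
sites <- generate_paired_sites(spec_ref, spec_new, shared_effects = TRUE)

model <- fit_harmonization(sites$ref$table, sites$new$table, sites$meta)
print(model)
#> dm_model: siteB -> siteA
#>   connections: 210  strata: all
#>   passthrough connections per stratum: 0

harmonized <- apply_harmonization(model, sites$new$table)

pooled_pre  <- connectivity_table(
  rbind(sites$ref$table$values, sites$new$table$values),
  c(sites$ref$table$subject_ids, sites$new$table$subject_ids), 21)
pooled_post <- connectivity_table(
  rbind(sites$ref$table$values, harmonized$values),
  pooled_pre$subject_ids, 21)

st_pre  <- correlate_connections(pooled_pre,  sites$meta, "age")
st_post <- correlate_connections(pooled_post, sites$meta, "age")
ev <- compare_to_baseline(st_post, st_pre)
print(ev)
#> mean |r| = 0.0550 +/- 0.0918
#> one-sided Wilcoxon signed-rank p = 0.387
#> connections with Bonferroni p < 0.05: 15
#> minimum Bonferroni p = 1.75e-42

rank_by_delta_s(ev)
#>   connection  i  j      delta_s quantile
#> 1        205 17 18 -5.237024241     0.00
#> 2        126  7 14 -0.606767283     0.25
#> 3        155  9 20 -0.003251883     0.50
#> 4         25  1  6  0.638594562     0.75
#> 5         17  0 17 93.428828714     1.00
```

Before harmonization the pooled analysis found `mean |r| = 0.0441` and 7
connections surviving Bonferroni correction; after distribution matching it
finds 15, and the connections that gain the most significance (largest
`delta_s`, here connection 17 between regions 0 and 17) are among those
carrying the simulated age effect. The whole-brain Wilcoxon p is
unremarkable here because 190 of the 210 connections are null, where
harmonization neither helps nor hurts |r| — the gain is concentrated in the
20 true connections.

Matrix-file I/O (`read_connectivity_matrices()` /
`write_connectivity_matrices()`), a stacked table format with a JSON
sidecar, model persistence as JSON, and a command-line wrapper
(`system.file("scripts", "dmconn", package = "dmconn")` with subcommands
`simulate`, `fit`, `apply`, `augment`, `evaluate`, `compare`) round out the
tool. See `vignettes/distribution-matching.Rmd` for the methods account.

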