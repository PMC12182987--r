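---
title: "Distribution matching for multi-site structural connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution matching for multi-site structural connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(dmconn)
```

## Why a zero-inflated gamma, and why quantile mapping

Structural connectivity from tractography is non-negative, right-skewed and
sparse: many region pairs have no reconstructed streamline at all, so their
value is exactly zero, and the positive values peak away from zero with a
long upper tail. A per-connection, per-site model that respects all of this
is the mixture of a point mass at zero with weight $\lambda$ and a gamma
density with shape $\gamma$ and scale $\beta$ on the positive part:

$$ f(c) = \lambda\,\delta^+(c) + (1-\lambda)\,g_{\beta,\gamma}(c). $$

Its CDF is $F(c) = \lambda u(c) + (1-\lambda) G_{\beta,\gamma}(c)$ with the
convention $u(0) = 0$, and its inverse is available in closed form:
$F^{-1}(p) = 0$ for $p \le \lambda$, otherwise the gamma quantile of
$(p-\lambda)/(1-\lambda)$. Harmonizing a new site $N$ onto a reference $R$
is then parametric quantile mapping, $T_{N\to R} = F_R^{-1}\circ F_N$,
applied independently to every connection: a value keeps its percentile, so
the map is monotone, preserves within-cohort rank order, and is
non-negative by construction. The $u(0)=0$ convention is what makes zeros
invariant: a zero has $F_N(0)=0 \le \lambda_R$, hence maps to zero. When the
reference is sparser than the new site ($\lambda_R > \lambda_N$), the
smallest nonzero new-site values have percentiles inside the reference zero
mass and are mapped to zero — the intended behavior, since those percentiles
correspond to absent connections in the reference population. A
non-zero-preserving variant ($u(0)=1$, so a zero carries its site's full
zero mass and can map to a positive value) exists behind
`zero_preserving = FALSE` in `fit_harmonization()`; it is off by default and
excluded from the package's own acceptance checks, since it trades the
physical interpretation of sparsity for potentially higher correlation
scores.

## The fitting pipeline and its conventions

`fit_harmonization()` transforms values as $c \leftarrow \log(1+c)$, fits
the mixture per connection per site, and `apply_harmonization()` undoes the
transform with $c \leftarrow e^c - 1$ after mapping. Both fitting and
mapping happen in log space: the log transform damps the extreme upper tail
so the gamma MLE is not dominated by a few outliers, and since
$\log(1+0)=0$, the zero pattern — hence $\lambda$ — is identical in either
space. $\lambda$ is the empirical fraction of *exact* zeros (no epsilon
threshold: a zero streamline count is a true zero, and thresholding would
silently redefine sparsity). The gamma parameters are maximum-likelihood
estimates on the strictly positive values via `fitdistrplus::fitdist()`,
with a tightened optimizer tolerance (`reltol = 1e-14`) so the estimates sit
at the score-equation root to ~1e-7. The shape is estimated unconstrained;
notationally the model expects $\gamma \ge 1$ (a mode away from zero), so a
fitted $\hat\gamma < 1$ triggers a warning rather than a constraint — this
mirrors how such fits are done in practice and keeps the likelihood machinery
standard.

Tunable parameters that matter:

* `min_nonzero` (default 10): the fewest positive values considered enough
  for a trusted gamma fit. Below it — or when the optimizer fails, e.g. on
  constant positives — the connection is flagged and *passed through
  unchanged* rather than aborting a whole-connectome run; the flags are in
  the model object (`per_stratum[[s]]$passthrough`).
* quantile clip $1 - 10^{-12}$: probabilities are capped before the gamma
  quantile, so a new-site value at its distribution's extreme maps to a
  large finite value instead of infinity.
* `stratify_by_sex`: fits and applies the transform separately per sex. A
  sex present in the new site but absent from the reference is an error —
  there is no reference distribution to map onto, and silently pooling would
  contaminate the strata.

Degenerate inputs are given defined behavior: a connection that is all-zero
in the new site has $\lambda_N = 1$ and maps to all zeros; an all-zero
reference connection absorbs everything into the reference zero mass (the
clip guarantees $p \le \lambda_R$); and self-harmonization ($R = N$) is the
identity on nonzeros to within floating-point round trip (~1e-12 relative,
tested at 1e-8).

## Covariate residualization

If a continuous variable $x$ (say age) differs in distribution between
sites, its effect can leak into the site transform.
`residualize_covariate()` fits, per site and connection, the least-squares
slope $\alpha$ of $c = \bar c + \alpha(x - \bar x) + \varepsilon$ and
returns $\tilde c = c - \alpha(x - \bar x)$, recording the slopes. Two
deliberate choices: the function operates on the values as given (the caller
decides whether that is the raw or the log scale; the synthetic generator
injects effects additively in log space, where the removal is exactly
specified), and the effect is *not* automatically added back after
harmonization — whether restoration is appropriate depends on the downstream
analysis, and adding it back is a one-line operation with the returned
slopes. Residualized values can dip slightly below zero; the returned table
is exempted from the non-negativity invariant and is intended for immediate
harmonization, not as a connectome. Residualization should not be used when
$x$ (or a variable correlated with it) is itself the outcome of the pooled
analysis, because it leaks the outcome into the harmonization.

## Conductance augmentation

Direct connectivity ignores multi-synaptic routes. `augment_conductance()`
treats each subject's matrix as a resistor network with edge conductance
equal to connectivity and returns pairwise effective conductance
$1/R_{\mathrm{eff}}$, with
$R_{\mathrm{eff}}(i,j) = L^+_{ii} + L^+_{jj} - 2L^+_{ij}$ computed from the
Moore–Penrose pseudoinverse of the graph Laplacian, per connected component;
disconnected pairs get 0 (no current path means zero conductance). This is
the standard effective-conductance definition, isolated behind a single
function so an alternative augmentation rule can be swapped in. Because
harmonization must preserve zeros, the intended order of operations is:
harmonize the *original* matrices, then re-augment the harmonized values.
Whether effective conductances should be normalized or capped before
downstream use is left to the caller; the package applies none.

## The evaluation battery

Correlation analyses first pass values through the bounded transform
$c \leftarrow 1 - e^{-c/\bar c}$ (per-connection cross-subject mean
$\bar c$), which confines values to $[0,1)$ monotonically and tames
leverage from the heavy tail. Per connection, Pearson's $r$ against a
covariate with two-sided $p$ from the usual $t$ transform; Bonferroni
correction multiplies by the number of connections *in the run* (3570 for 85
regions, but never hard-coded); significance is $s = -\log p$ in natural
log — any fixed base would only rescale $\Delta s$, leaving rankings
unchanged. `compare_to_baseline()` reports the four summary measures — mean
and SD of $|r|$, the one-sided Wilcoxon signed-rank $p$ for
$|r_{\text{post}}| > |r_{\text{pre}}|$, the Bonferroni-surviving count, and
the minimum corrected $p$ — plus per-connection $\Delta s$. Zero paired
differences are discarded before ranking (the test's common convention); the
signed-rank test assumes symmetry of the paired differences, which paired
$|r|$ values do not guarantee, so its $p$-values should be read as
indicative. Zero-variance connections are recorded as missing and excluded
from summaries rather than imputed. $\Delta s$ quantile selection
(`rank_by_delta_s()`) uses the nearest-rank rule with ties broken by
connection index. `subsample_stability()` refits the mixture on repeated
random subject subsets (e.g. 106 of 209, 1000 times) to show how much a
smaller cohort can distort the estimated distribution — the practical
caution for using small new sites.

## The synthetic generator

`generate_site()` draws, per connection, zeros with probability $\lambda$
and log-space positives from gamma$(\gamma,\beta)$, adds covariate effects
$\alpha(x-\bar x)$ in log space to the positive draws, then maps to raw
space with $e^c - 1$. Effects are injected in log space because that is
where the harmonization model lives, which keeps the generator's assumptions
and the method's assumptions aligned and makes `residualize_covariate()`
exactly correct on the log scale. A covariate effect can push a log-space
draw below zero; such draws are clamped at 0, a rare event at realistic
effect sizes that slightly inflates the zero fraction rather than producing
invalid negative connectivity. What the generator deliberately does *not*
emulate: spatial structure, inter-connection covariance, and tractography
artifacts. Tests passing on this generator therefore demonstrate the
method's statistical correctness under its own model class, not robustness
to model misspecification on real connectomes.

Default study conditions used in the package's own checks: two sites of
150–300 subjects, 21 regions (210 connections) with per-connection
$\lambda \sim U(0.05, 0.35)$, shape $\sim U(1.5, 4)$ and log-space scale
$\sim U(0.5, 2)$ (reference) vs. a scale-shifted new site; end-to-end checks
put a shared covariate effect of 0.3 (log-space units per unit of a
covariate with SD 8) on 20 of 210 connections. These sizes keep the gamma
MLE stable while the full suite runs in well under a minute.

## Numerical choices and check sizes

* CDF/inverse-CDF round trips are exact to ~1e-15 on a $p$-grid; checks
  assert 1e-9.
* Distribution alignment is checked at $n = 2000$ per site with the fixture
  (new: $\lambda=0.2$, shape 2, scale 1; reference: $\lambda=0.4$, shape 3,
  scale 2, all in log space): harmonized zero fraction within $0.4 \pm
  0.03$ and a two-sample KS statistic of harmonized vs. reference nonzeros
  under the 5% critical value.
* Agreement with a brute-force empirical-quantile-mapping oracle is checked
  at $n = 10^6$ per site, where estimation error is negligible, so the
  comparison isolates the correctness of the closed-form parametric map
  itself: deciles of the continuous part agree within 2% on the log scale.
  At $n = 2000$ the same statistic is dominated by gamma-MLE sampling noise
  (decile deviations of ~5–15% are typical and reflect the sample, not the
  transform), which is why the small-sample check is the KS/zero-fraction
  pair and the decile check is a large-sample one.
* Type-I calibration of the correlation screen is checked on a null
  covariate at 500 subjects x 1035 connections (46 regions), where the
  binomial noise on the 5% rejection rate is ~0.7 percentage points.
* The signed-rank implementation is compared against full $2^n$ sign
  enumeration for $n \le 12$.

## Known limitations

Each new site is harmonized to the reference pairwise and independently;
there is no joint multi-site model. The gamma family is a commitment —
alternative positive families (log-normal, Weibull) are out of scope. The
method matches marginal distributions per connection; it does not address
site effects in the covariance between connections. Reference-site choice
matters (the larger, more representative cohort is the sensible reference,
since its data remain untouched), and small new sites yield noisier
transforms — quantified by `subsample_stability()`. Finally, passthrough of
unreliably fitted connections means extremely sparse connections are left
unharmonized by design; the model object records which.
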