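---
title: "Phylogenetic GLS and multimodel selection for reproductive allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic GLS and multimodel selection for reproductive allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scorpallo)
```

## The question and the data

Sperm-competition theory predicts that males of polyandrous species
invest relatively more in sperm production: larger testes, possibly
larger ejaculates, and — depending on the selective regime — longer or
shorter sperm.  `scorpallo` asks these questions across eight
Neotropical bothriurid scorpion species, for which the bundled dataset
(`vrech2014_traits()`) records species means of body mass (g), testes
mass (mg), spermatophore trunk volume (mm³, trunk area × trunk width,
a proxy for ejaculate volume), sperm-package length (µm, a reliable
proxy for sperm length, measured as 10 packages per male and averaged
male → species), and the polyandry level — the mean number of males a
female accepts per reproductive season in laboratory trials, used as
the measure of sperm-competition risk.  Relative allocation is
summarized by the gonadosomatic index, GSI = gonad mass / body mass ×
100.

Species are not independent data points: close relatives resemble each
other because of shared ancestry.  All regressions therefore run as
**phylogenetic generalized least squares** (pGLS) on a working
cladogram (`default_cladogram()`) in which congeners form clades and
every branch has length 1 — a punctuated-evolution convention in which
expected divergence is proportional to the number of cladogenesis
events, adopted because no calibrated branch lengths exist for this
group.  The arrangement of the four genus-level clades above the genus
level, `((Bothriurus, Brachistosternus), (Timogenes, Urophonius))`, is
a documented assumption; any user-supplied Newick tree
(`read_newick()`) overrides it.  Note the equal-branch-length tree is
deliberately *not* ultrametric (the lone *Urophonius* tip sits closer
to the root), and tip variances are used as-is.

## The model

Traits are log10-transformed (`log10_traits()`; testes mass converted
to grams first, so intercepts are on the gram scale), which the
Shapiro–Wilk check (`shapiro_wilk()`) confirms is adequate for all
four analysis columns.  For a response $y$ and design $X$ the model is

$$ y = X\beta + \varepsilon, \qquad
   \varepsilon \sim \mathcal{N}\!\big(0,\; \sigma^2 V(\lambda)\big), $$

where $V$ is the phylogenetic variance–covariance matrix — entry
$(i,j)$ is the shared root-to-MRCA path length of tips $i$ and $j$
(`phylo_vcv()`) — and Pagel's $\lambda \in [0,1]$ rescales its
off-diagonal entries (`lambda_transform()`): $\lambda = 0$ means the
trait evolved independently of phylogeny, $\lambda = 1$ full
Brownian-motion covariance.  For fixed $\lambda$, $\beta$ and
$\sigma^2$ have closed-form ML solutions, computed by Cholesky
whitening and QR (`gls_profile_fit()`); $\sigma^2$ uses the ML divisor
$n$ so that likelihoods are comparable across fixed-effect structures
in information-criterion work.  $\lambda$ itself is profiled by a
coarse grid scan (the profile can be multimodal on an 8-tip tree)
followed by bounded Brent refinement (`optimize_lambda()`).

Search bounds default to $[10^{-4}, 0.9999]$, so boundary estimates
print as exactly 0.0001 or 0.9999 — the values a boundary solution
should be read as.  Each fitted model carries likelihood-ratio tests
of $\hat\lambda$ against $\lambda$ fixed at exactly 0 and exactly 1
(`lambda_lrt()`), using the plain $\chi^2_1$ upper tail without a
boundary mixture correction, matching the methodology this analysis
line descends from; statistics are floored at zero since a boundary
$\hat\lambda$ can sit numerically a hair below the fixed-value
likelihood.

Predictors are assessed by **sequential (Type I) ANOVA** in formula
order — body mass always first, so polyandry, testes mass or sperm
length are tested after controlling for body mass.  The decomposition
is computed on data whitened by the *full* model's fitted
$V(\hat\lambda)$; $\lambda$ is not re-estimated inside the nested
submodels, which keeps the sums of squares an exact decomposition
(set `anova_refit_lambda = TRUE` in `pgls_fit()` for the re-profiled
variant).

## Model selection

Eighteen a-priori candidate models (`candidate_models()`) are split
across the three responses — 4 for testes mass, 6 for sperm length, 8
for spermatophore volume; each set contains the intercept-only null
model and no interactions (interaction models were screened out a
priori as uncompetitive).  Each model gets its own ML $\hat\lambda$,
never shared, because different traits can carry different degrees of
phylogenetic signal.  Models are ranked by small-sample AICc
(`aicc()`), $-2\ell + 2k + 2k(k+1)/(n-k-1)$, summarized by Akaike
weights (`akaike_weights()`, computed after subtracting the minimum
for numerical stability), and the selection rule keeps the minimum-
AICc model plus everything with $\Delta\mathrm{AICc} < 2$ (strict).

**What counts as a parameter.**  `k_counting` controls what $k$
charges: regression coefficients only (default), coefficients plus
the residual variance, or coefficients plus variance plus the
estimated $\lambda$.  The default follows the accounting under which
the study's published AICc values are recovered to within rounding of
its table (and under which a two-predictor interaction model is a
"four-parameter" model): with only eight species the harsher
accountings push $n - k - 1$ toward zero and mechanically hand the
null model the win regardless of signal, which is statistically
defensible but is not the computation the study performed.  All three
modes are exercised in the test suite; likelihoods are identical
across modes, only the penalty differs.

With the bundled data, `reproduce_study()` selects **testes mass ~
polyandry** (positive slope), **sperm length ~ body mass** (negative
slope), and **spermatophore volume ~ body mass + testes mass** (both
positive, weight ≈ 1).  Published slopes, F statistics and AICc values
are *not* reproduced digit-for-digit: they derive from unrounded
per-individual data that were never deposited, and the printed table
is internally inconsistent in places (its ΔAICc column does not equal
differences of its AICc column).  The package's acceptance surface is
therefore the arithmetic-forced quantities (GSI, summaries, W
statistics from printed means) plus best-model identity and slope
signs — which are stable — rather than the unrecoverable decimals.
The same gap explains per-model $\hat\lambda$ differences (e.g. the
testes-mass null model).

## GSI and the averaging chain

`gsi()` computes GSI from species means.  The published per-species
GSI column was evidently computed per individual and then averaged,
which differs from the ratio of means whenever individuals vary —
Jensen's inequality, not an error.  The individual-level simulator
(`simulate_study()`) reproduces this mechanically: with the published
SDs the two GSI versions split by up to a few tenths of a percentage
point, and with all SDs at zero they coincide exactly.  The three
species whose printed GSI matches mean-ratio arithmetic at 2 d.p.
(*T. dorbignyi* 0.37 %, *T. elegans* 0.48 %, *Br. pentheri* 2.30 %)
are the ones used as exact reproduction targets.

## The simulators

`simulate_traits()` draws replicate species-level responses
$y = X\beta + \varepsilon$, $\varepsilon \sim \mathcal{N}(0, \sigma^2
V(\lambda))$, via the Cholesky factor of the transformed covariance —
exactly the generative model the regression assumes, so parameter
recovery is a meaningful check.  `simulate_study()` rebuilds the
sampling design bottom-up: 6–19 males per species (the study's
per-species N where recorded), per-male body and testes mass drawn
lognormally around the species means with the species SDs (lognormal
because traits are positive and several SDs approach their means;
parameterized by moment matching of the arithmetic mean and SD — a
package choice, since within-species distributions were never
reported), 10 sperm packages per male with a small within-male
coefficient of variation (default 0.05), and 1–3 spermatophores per
species realized as (area, width) pairs whose product is the sampled
volume.  Species-level tables are then derived by the same averaging
chain as the real study.  Each species draws from its own RNG stream,
keyed by a stable hash of its name folded into the root seed, so
adding or dropping a species never perturbs the others — and a fixed
seed reproduces a study bit-for-bit.

What the simulators do *not* emulate: real mass–length correlations
within males, measurement error of the microbalance or the image
analysis, and any behavioural dynamics behind polyandry (it stays an
exogenous covariate).  Passing recovery tests therefore validate the
estimator under its own assumptions, not those aspects of real data.

## Numerical choices and limitations

* Covariances are factored by plain Cholesky; a failure is reported
  with the matrix's condition number rather than silently jittered.
* An exact (to rounding) fit flags its log-likelihood as $+\infty$
  instead of returning a rounding-noise value.
* $\lambda$ profiling uses a 21-point bracketing grid + Brent with
  tolerance $10^{-8}$; the estimate agrees with a 1000-point grid
  argmax to 0.01 in tests.
* Species matching between table and tree is exact after whitespace/
  underscore normalization — no fuzzy matching, mismatches are listed
  by name.
* Validation problem sizes: λ-recovery uses 200 replicates per regime
  (8-tip and balanced 64-tip trees), coefficient recovery 500
  replicates, simulator convergence 10⁴ males per species — sizes at
  which Monte-Carlo error is comfortably below the tested margins.
* With $n = 8$ species, power is modest and $\hat\lambda$ is noisy;
  on simulated data mimicking the study's conditions the
  polyandry-containing models carry a summed Akaike weight of ~0.45
  on average — detectably above the no-effect baseline (the
  directional power the tests assert) but far from certainty.
  Inference at this scale leans on the a-priori candidate set, not on
  per-model hypothesis tests.
* No independent contrasts, no Ornstein–Uhlenbeck or κ/δ transforms,
  no measurement-error ("lambda-with-SE") models, and no model
  averaging of coefficients: out of scope by design.
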