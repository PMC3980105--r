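---
title: "QTL mapping in recombinant congenic strains: model, bootstrap and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL mapping in recombinant congenic strains: model, bootstrap and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcsqtl)
```

## The mapping problem

A recombinant congenic strain (RCS) panel is a set of inbred mouse strains
derived from two parental strains: after two backcrosses to the recipient
parent and many generations of inbreeding, each strain carries random donor
segments covering about 12.5% of its genome in an otherwise recipient
background. All animals of one strain are genetically identical, so the
panel is genotyped once and phenotyped many times — typically several
animals per strain.

Mapping a quantitative trait locus (QTL) in such a panel means regressing
the phenotype on the strain distribution pattern at each of $M$ markers.
The catch is that strains are *related*: strains sharing a background share
the bulk of their genome, and polygenic trait variation therefore induces a
strain-level random effect with a covariance structure given by the kinship
matrix. Ignoring that term does not bias the per-marker effect estimates,
but it invalidates their standard errors and, much worse, the resampling
schemes used to calibrate genome-wide significance: individual phenotypes
are no longer exchangeable under the null once strain effects exist.

## Models

At marker $m$ with BB-genotype indicator $q_{im}$, the naive model is the
per-marker simple regression

$$y_i = \mu + q_{im}\,\xi_m + e_i, \qquad e_i \sim N(0, \sigma^2),$$

while the mixed model adds a strain-level polygenic term,

$$y = X\beta + Z\gamma + q_m\,\xi_m + e, \qquad
\gamma \sim N(0, \sigma_\gamma^2 \Delta_1), \quad e \sim N(0, \sigma^2 I),$$

with $Z$ the individuals-to-strains incidence matrix and $\Delta_1$ the
$S \times S$ strain kinship matrix. Writing
$\lambda = \sigma^2_\gamma / \sigma^2$ (the signal-to-noise ratio, monotone
in heritability under a purely polygenic model),
$\mathrm{Var}(y) = \sigma^2(\lambda Z \Delta_1 Z' + I) = \sigma^2\Sigma$.

Two kinship matrices are provided:

* **design expectation**: $\delta_{1ij} = 1$, $15/16$ or $1/16$ according
  as $i = j$, same background, or reciprocal backgrounds — exact rational
  values implied by the two-backcross construction;
* **genomic estimate**: the proportion of jointly observed markers at which
  the two strains carry the identical parental-origin genotype — a direct
  IBD-sharing estimator for fully inbred strains.

The two do not coincide (the design expectation accounts for allele
identity states, the genomic estimate for marker concordance); the package
deliberately does not reconcile them. All model fitting and the simulation
study use the genomic estimate, which is what one would compute from a real
panel; the design matrix is available for sensitivity analyses.
Because the genomic estimate divides each entry by a pair-specific
joint-observation count, missing genotypes can leave it indefinite; when
its smallest eigenvalue is not safely positive a diagonal ridge of
$10^{-6}$ plus the eigenvalue deficit is added and recorded, so downstream
code always receives a usable covariance. (A fixed ridge cannot guarantee
positive definiteness, so the repair is adaptive by necessity.)

## Estimation

With $\lambda$ fixed, whitening by the symmetric inverse square root
$\Sigma^{-1/2}$ gives $W = \Sigma^{-1/2}X$, $v = \Sigma^{-1/2}y$, and

$$\tilde\beta = (W'W)^- W'v, \qquad
\hat\gamma = \lambda \Delta_1 Z' \Sigma^{-1}(y - X\tilde\beta), \qquad
\hat\sigma^2 = \frac{\|v - W\tilde\beta\|^2}{n - \mathrm{rank}(W)},$$

the BLUE of $\beta$ and the BLUP of $\gamma$. The polygenic variance is
updated by the Henderson/EM moment formula

$$\hat\sigma^2_\gamma = \frac{1}{S}\left(
  \hat\gamma' \Delta_1^{-1} \hat\gamma
  + \hat\sigma^2\,\mathrm{tr}(\Delta_1^{-1} C)\right), \qquad
C = \left(Z'MZ + (\lambda\Delta_1)^{-1}\right)^{-1},\;
M = I - X(X'X)^{-}X',$$

where $\sigma^2 C$ is the conditional covariance of $\gamma - \hat\gamma$.
The quadratic form and the trace correction must involve $\Delta_1^{-1}$
(the correlation structure), not $(\lambda\Delta_1)^{-1}$: since
$E[\gamma'(\lambda\Delta_1)^{-1}\gamma] = \sigma^2 S$, a
$(\lambda\Delta_1)^{-1}$ version would estimate the error variance and
drive every fit to $\lambda = 1$ regardless of the data. With
$\Delta_1^{-1}$ the iteration
$\lambda \leftarrow \hat\sigma^2_\gamma/\hat\sigma^2$ has the REML
stationary point: on a random-intercept design ($\Delta_1 = I$) the
converged estimates agree with `lme4::lmer` REML to six significant
digits, and on general kinships with a direct restricted-likelihood
search (both checks are in the test suite).

Numerical choices:

* $\Sigma(\lambda)^{-1/2}$ is applied through one thin SVD of
  $Z L$ ($L$ a Cholesky factor of $\Delta_1$), valid for every $\lambda$
  at once; the dense $n \times n$ eigendecomposition is the reference
  implementation and the two agree to $10^{-8}$ (tested).
* Generalized inverses are Moore–Penrose with singular values below
  $10^{-10}$ of the maximum treated as zero.
* $\lambda = 0$ is an admissible boundary: negative updates are clamped to
  zero, where the fit is exactly ordinary least squares and
  $\hat\sigma^2_\gamma = 0$ by convention.
* The iteration starts at $\lambda = 1$ and stops when the relative change
  falls below $10^{-6}$ (cap 200 iterations). Near the $\lambda = 0$
  boundary the EM-type iteration converges slowly and may hit the cap with
  a step still above tolerance; the fit is then flagged, returned with a
  warning, and in practice lies within $10^{-3}$ of the boundary. A
  constant response makes $\hat\sigma^2 = 0$ and is rejected as degenerate.

## Genome scan and the z transform

Both scans reduce to OLS in a whitened coordinate system: the naive scan
uses the identity whitening, the mixed scan augments $W$ with
$\Sigma^{-1/2}q_m$ at the *null-model* $\tilde\lambda$ (the ratio is not
re-estimated per marker — the scan model is the QTL mixed model with
$\lambda$ replaced by its null estimate). The absolute $t$-statistic with
$\nu_m = n_m - \mathrm{rank}(W) - 1$ degrees of freedom is mapped to

$$z_m = t_m\left(1 - \frac{1}{4\nu_m}\right)
        \left(1 + \frac{t_m^2}{2\nu_m}\right)^{-1/2},$$

which puts markers with different $\nu_m$ (missing genotypes) on a common
genome-wide baseline. The transform is evaluated as
$(1 - 1/(4\nu)) / \sqrt{1/t^2 + 1/(2\nu)}$, which handles $t = 0$ and
$t = \infty$ (a perfectly separating marker) without special cases. A
`tprime` variant substitutes the null-model residual variance for the
per-marker one; with no missing data the two order markers identically.

Markers that are monomorphic among the retained individuals (whitened
genotype collinear with the design, tolerance $10^{-8} n$) or retain fewer
than three individuals are flagged `skipped` and excluded from the
max-statistic. For the mixed scan, rows with a missing genotype are dropped
from the *already whitened* system, with the whitening of $q_m$ restricted
to the retained rows; this is approximate (the whitening was computed on
all $n$ rows) but the z transform keeps the baseline comparable, and at
$\tilde\lambda = 0$ the scan collapses exactly to the naive OLS scan,
missing data included.

## Genome-wide p-values by the max-statistic bootstrap

Significance is calibrated by the union–intersection principle: the global
null is rejected when $\max_m z_m$ is extreme, and the genome-wide
corrected p-value of marker $m$ is

$$\hat p_m = \frac{\#\{r : z_m \le z^{*}_{\max,r}\}}{R},$$

reported as the exact count ratio (ties accepted; an optional
$(c+1)/(R+1)$ smoothing is off by default).

* **Naive path**: resample the raw phenotype vector with replacement
  (valid only when phenotypes are exchangeable under the null).
* **Mixed path**: under the null fit, the whitened residuals
  $v - W\tilde\beta$ are approximately exchangeable with variance
  $\sigma^2 I$. They are rescaled by $(1 - h_{ii})^{-1/2}$ ($h_{ii}$ the
  whitened hat-matrix leverages), mean-centered, resampled with
  replacement, and reassembled as $v^* = W\tilde\beta + \epsilon^*$; each
  pseudo-response is rescanned with the whitening and $\tilde\lambda$ held
  fixed.

The exponent $-1/2$ is the variance-restoring choice of the regression
bootstrap literature ($E[r_i^2] = \sigma^2(1 - h_{ii})$ under
homoscedasticity); the full $(1 - h_{ii})^{-1}$ factor is also offered
(`exponent = "one"`) for comparison. With an intercept-only design and
balanced strains the leverages are all $1/n$, so the choice is immaterial
in the simulation study below.

Resamples are drawn in fixed-size batches from a single seeded stream, so
results are independent of batching and bit-reproducible from the seed.
The naive and mixed procedures consume the resampling stream identically
(one $n$-vector of indices per resample); combined with the affine
invariance of the $t$-statistic this makes the two procedures *exactly*
coincide when $\tilde\lambda = 0$ and the kinship is the identity — a
useful end-to-end consistency check that the test suite asserts.

A *significant peak* at level $\alpha$ is the minimum-p marker of a maximal
run of consecutive markers on one chromosome with $\hat p_m \le \alpha$.

## The simulation study

`run_type1_study()` rebuilds the study design: one simulated panel of 36
strains in two reciprocal groups of 18, with 619 markers on 19 autosomes at
3 cM spacing (the real panel the design mirrors is not publicly deposited,
so the package simulates one; naive-row magnitudes are panel-dependent and
are compared as orders of magnitude, not cell values). For each
$\lambda \in \{0, 1/8, 1/4, 1/2, 1, 2\}$ it draws null phenotype sets
(7 individuals per strain, $\sigma^2 = 1.175$, $\mu = 7$, no major gene),
runs both bootstraps, and reports the fraction of datasets with at least
one marker at $\hat p \le 0.01$ — the empirical genome-wide type I error —
with its binomial standard error.

Three Monte Carlo scales are preset: `paper` (1000 datasets × 10000
resamples), `desk` (200 × 1000) and `smoke` (20 × 100). The package's own
acceptance checks run at desk scale, where a rate compared against a
reference $p$ carries a standard error of $\sqrt{p(1-p)/200}$; all
comparisons are made within three such standard errors. One desk-scale arm
(200 datasets, one method) completes in under a minute on a single core
because the per-marker statistics for all markers and all resamples in a
batch are computed as a handful of matrix products.

Two deliberate design choices sharpen the study without biasing it:

* **Common random numbers.** The phenotype generator draws the strain
  effects and errors in a fixed order regardless of $\lambda$, and
  dataset-level seeds depend only on the dataset index. Arms at different
  $\lambda$ (and the two methods within an arm) therefore share noise
  realizations; each arm remains a valid marginal estimate while cross-arm
  contrasts — the naive-vs-mixed gap and the monotone growth of the naive
  inflation in $\lambda$ — are estimated with far less noise.
* **Generator defaults are the study conditions.** Donor fraction 1/8,
  two reciprocal groups, and a map-distance decay with an expansion factor
  of 4 (the accumulated-meioses scale of a two-backcross plus inbreeding
  scheme, giving inter-marker state correlation $e^{-2d \cdot 4}$ at map
  distance $d$ Morgans) were fixed from the breeding design, not from any
  test outcome.

### What the simulator does and does not emulate

The panel simulator is a stationary two-state Markov chain along each
chromosome: it reproduces the expected donor fraction, the linkage decay of
the strain distribution patterns, and the within/between-group kinship
separation — the first-order structure that drives the type-I-error
phenomenon. It does not model explicit pedigrees, selection during strain
construction, segment-length distributions beyond the Markov approximation,
heterozygous residues, or genotyping error. Passing the study at desk scale
therefore shows that the *methods* behave as claimed under the stated
generating model; it does not certify calibration on any particular real
panel, where kinship estimation error and non-normal phenotypes add further
slack. On this synthetic panel the mixed-model bootstrap in fact errs on
the conservative side (empirical rates at or below nominal), while the
naive bootstrap inflates the genome-wide rate by one to two orders of
magnitude as $\lambda$ grows.

## Known limitations

* The mixed scan holds $\tilde\lambda$ fixed from the null fit; per-marker
  re-estimation is out of scope.
* No interval mapping between markers, no multi-QTL conditional scans, no
  dominance or epistasis in the phenotype generator.
* Permutation-based calibration is intentionally absent: with $\lambda$
  estimated, residuals cannot be made even weakly exchangeable for
  permutation, which is precisely the regime where the bootstrap is the
  workable tool.
* Standard errors for the BLUP $\hat\gamma$ are not reported; the random
  effects are nuisance parameters here.

## A worked example

```{r example, eval = FALSE}
panel <- simulate_rcs_panel(36, make_map(19, 619, 3), seed = 1)
K <- genomic_kinship(panel)
ph <- simulate_phenotypes(panel, K, lambda = 1, xi = 1.5,
                          qtl_marker = "c5m10", seed = 2)
Z <- sapply(panel$strain_id, function(s) as.numeric(ph$strain_id == s))
fit <- fit_null_mixed(ph$y, NULL, Z, K)
boot <- mixed_bootstrap(panel, ph, K, R = 1000, seed = 3, null_fit = fit)
count_significant_peaks(boot, threshold = 0.01)
```
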