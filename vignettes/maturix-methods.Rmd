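---
title: "Statistical methods in maturix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in maturix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maturix)
```

# The design and the model

maturix analyzes a two-age by four-genotype reciprocal-cross fetal design.
Sows of two breeds — Large White (LW, high perinatal mortality) and Meishan
(MS, low mortality) — are inseminated with mixed semen, so every litter
contains purebred and crossbred fetuses: a LW sow carries LW and MSLW
fetuses, a MS sow carries MS and LWMS fetuses. Each sow is sampled by
caesarean at exactly one gestational age (day 90 or day 110 of a 114-day
gestation), giving a cross-sectional factorial with eight age-by-genotype
cells and the litter (sow) as a natural random block: fetuses sharing a
uterus share maternal environment.

Per probe, expression follows the linear mixed model

$$y_{ijk} = \mu + a_i + g_j + (ag)_{ij} + u_k + \varepsilon_{ijk},$$

with fixed gestational-age effect $a$, fetal-genotype effect $g$ (treatment
contrasts, level order LW < MSLW < LWMS < MS with LW as reference),
their interaction, a random sow intercept
$u_k \sim N(0, \sigma^2_{sow})$ and residual
$\varepsilon \sim N(0, \sigma^2_{res})$, all on the log2 intensity scale.

## Fitting

With a single random factor, the covariance is
$V = \sigma^2_{res}(I + \lambda ZZ^\top)$, $\lambda =
\sigma^2_{sow}/\sigma^2_{res}$. We eigendecompose $ZZ^\top = QDQ^\top$ once
per design; on the rotated scale ($\tilde y = Q^\top y$) the profiled ML or
REML criterion is a one-dimensional function of $\lambda$, minimized by
golden-section search on $\log\lambda$ (convergence tolerance $10^{-10}$ on
the criterion) with an explicit boundary evaluation at $\lambda = 0$, so
$\hat\sigma^2_{sow} \ge 0$ with boundary estimates allowed. The search runs
in compiled code; on a 64-sample design a probe fits in well under a
millisecond, which is what makes genome-wide scans and the simulation-based
test suite cheap. Fits are validated in the test suite against `lme4::lmer`
(coefficients, variance components, and both log-likelihoods agree to
$10^{-6}$ or better). One numerical convention: our REML criterion includes
$\log|X^\top V^{-1} X|$ but not the constant $-\log|X^\top X|$; the constant
does not depend on the variance parameters, so estimates and tests are
unaffected.

Degenerate inputs are defined rather than left to chance: a probe whose
response is fitted perfectly (e.g. a constant row) is assigned
$\lambda = 0$ and a common variance floor, so the ML likelihoods of
different fixed-effect structures stay comparable and a constant probe
falls to the smallest candidate model by the tie-break rule. Constant rows
are excluded from testing with p recorded as 1, since an F statistic is
undefined there.

## The F-type test

Differential probes are found by comparing the full model against the
reduced model containing only the intercept and the random sow term, i.e.
jointly testing all seven fixed-effect contrasts ("any age and/or genotype
signal"). The test is a Wald-type joint F at the REML variance estimates.
Denominator degrees of freedom use the Satterthwaite approximation: for
each eigen-contrast of the Wald matrix we compute
$\nu_i = 2 f_i^2 / (\nabla f_i^\top W \nabla f_i)$ with $W$ the inverse
REML Hessian of the two variance components (numeric derivatives), and the
per-contrast $\nu_i$ are pooled as in the standard mixed-model practice.
The suite checks our F, denominator df and p against `lmerTest::contest`
(agreement to about $10^{-5}$). A ML likelihood-ratio chi-square is
available behind `ftypeTest(type = "lrt")` for sensitivity analysis. This
joint-Wald-plus-Satterthwaite construction reduces to the classical ANOVA
F when the sow variance is estimated at zero on a balanced design.

Across probes, p-values are adjusted by Benjamini–Hochberg step-up
(`stats::p.adjust`); the DEP threshold defaults to FDR < 0.01. Measured on
the synthetic generator (5,000 probes, 80% null, 10 replicates), the
realized false discovery proportion stays near the nominal level — the
acceptance script recomputes this number on every run. The per-test type-I
rate at $\alpha = 0.05$ sits slightly above nominal (typically 0.05–0.06 on
2,000 null probes), which is the known small-sample behavior of
Satterthwaite-based joint tests with 16 blocks, not an implementation
artifact — the lmerTest cross-check pins the implementation.

## Sub-model classification by BIC

Each DEP is refitted under four fixed-effect structures — complete
(age + genotype + interaction), additive, age-only, genotype-only — all
retaining the random sow intercept, and assigned to the minimum-BIC
structure with $\mathrm{BIC} = -2\ell_{ML} + k\log n$. ML (not REML)
likelihoods are used because REML likelihoods are not comparable across
fixed-effect structures; $k$ counts the fixed coefficients plus both
variance components, so penalty differences reflect fixed effects only.
Exact ties break toward fewer parameters (age < genotype < additive <
complete). The random sow term is retained in all four candidates; the
alternative (dropping it for some candidates) would confound the
fixed-effect comparison with a variance-structure comparison.

## The parental-genome model

To separate parental contributions, the factorial is reparameterized as
maternal genotype + paternal genotype + gestational age with all pairwise
interactions (the maternal-by-paternal product spans the fourth
fetal-genotype contrast, so the fixed-effect space is the 7-dimensional
subspace of the full factorial without the three-way term). Separate
F-type tests cover the paternal term set (paternal main effect and its two
interactions) and the maternal set, each BH-adjusted at FDR < 0.05 — a more
permissive threshold than the main scan, matching the screening character
of this contrast.

# Phenotype ANOVA

Phenotypic variables (morphometry, enzyme activities, blood parameters) are
analyzed per variable by fixed-effects two-way ANOVA (age, genotype,
interaction). Normality of residuals is checked by Shapiro–Wilk and
variance homogeneity by Bartlett across the eight cells; in the automatic
mode a variable is Box-Cox transformed when the Shapiro p-value falls below
0.05, and the decision and fitted $\lambda$ are recorded per variable. The
Box-Cox exponent maximizes the profile log-likelihood on a grid over
$[-2, 2]$ (step 0.05) refined by golden-section search; $\lambda$ is weakly
identified when data sit far from zero relative to their spread — expected,
and visible in the wide recovery tolerance of the tests. Because cell
counts are unbalanced (6–9 fetuses per cell after quality filtering in a
real study), Type-II sums of squares are used (`car::Anova`); with
balanced data they coincide with the classical decomposition, which the
suite verifies. Post-hoc letter groupings come from pairwise Tukey HSD at
$\alpha = 0.05$ with an insertion-order compact letter display. The
phenotype ANOVA deliberately omits a random litter term: it operates at
fetus level, mirroring the conventional analysis of such phenotype panels;
litter-level inference is the mixed model's job.

# Multivariate integration

## Sparse PLS

To relate expression to the phenotype panel, probes serve as predictors of
phenotypic variables in a sparse partial least squares regression. Both
blocks are centered and unit-scaled. Per component, the dominant singular
pair of $X_h^\top Y_h$ is computed by alternating iteration, with the
X-weight soft-thresholded so exactly `keepX[h]` probes survive, then
renormalized; scores are $t_h = X_h w_h$, and both blocks are deflated by
regression on $t_h$ (regression mode). With `keepX = p` this reproduces
classical PLS2 — the suite checks the first component against a
power-iteration oracle at $10^{-8}$ and the sparse fit against
`mixOmics::spls` (identical selections, variates correlating to machine
precision). Successive variates are exactly uncorrelated under this
deflation. Missing phenotype entries are mean-imputed (zero after
standardization) for the fit only; cross-validation and correlations
exclude them pairwise, preserving n for complete variables.

## Q2, MSEP, and the keepX ladder

Predictive value per component is measured by
$Q^2_h = 1 - \mathrm{PRESS}_h / \mathrm{RSS}_{h-1}$: PRESS pools the
held-out squared prediction error of an h-component model over 5
cross-validation folds stratified by age-by-genotype cell (seeded), and
RSS is the full-data residual sum of squares after $h-1$ components.
Components are retained while $Q^2 > 0.09$, the conventional significance
threshold for this diagnostic. `keepX` is tuned over a documented ladder
(10, 25, 50, 100, 250 probes, clipped to p) by first-component Q2;
`tuneKeepX` applies the ladder per component rather than jointly — a
pragmatic choice that keeps the tuning cost linear in the ladder length.
MSEP and $R^2$ are computed per phenotype on the standardized scale from
the same fold scheme; ranking phenotypes by MSEP identifies the variables
best predicted by expression co-variation.

## Relevance network

The probe–phenotype network scores each pair by
$\sum_h \mathrm{cor}(X_j, t_h)\,\mathrm{cor}(Y_k, t_h)$ over the retained
components — the standard relevance-network construction from sPLS latent
variates; with one component the score is a product of two correlations and
lies in $[-1, 1]$. Edges with absolute score above 0.75 are kept. A flag
substitutes raw Pearson probe–phenotype correlation for sensitivity
analysis. By default only probes selected by the sPLS are scored. Writers
emit SIF and GraphML, the latter carrying the signed score as an edge
attribute and each probe's sub-model label as a node attribute.

# qPCR validation

Quantification cycles convert to calibrator-relative quantities
$Q = (1+E)^{Cq_{\min} - Cq}$ using each primer pair's measured
amplification efficiency (typically 0.99–1.04), so the highest-expressed
sample has $Q = 1$. Reference genes are ranked by the geNorm stability
measure — the mean, over partners, of the standard deviation of pairwise
log2 ratios — with iterative exclusion of the least stable candidate down
to the algorithm's minimum of two; the measure is invariant to rescaling
any gene, and the implementation is tested against a brute-force oracle at
$10^{-10}$. Targets are normalized by the per-sample geometric mean of the
selected references, and validation is the Pearson correlation between
log2 qPCR expression and the log2 microarray row, matched by sample. Both
platforms are correlated on the log2 scale — array data is already log2 and
qPCR quantities are exponential in Cq, so the log scale is the one on which
noise is approximately additive. The pairwise-variation criterion for the
optimal reference count is out of scope.

# Enrichment

Gene lists (DEPs of a sub-model, gated at |log2FC| ≥ 0.5 in a chosen
genotype) are tested for over-representation against user-supplied GMT
annotation sets by the upper-tail hypergeometric probability
$P[X \ge k]$, BH-adjusted at FDR < 0.01. The universe is user-supplied
(defaulting, in the pipeline, to all probes on the array): a knowledge
base's internal universe is not reproducible, so making it explicit is the
only defensible contract.

# The synthetic generator and what the tests do (and do not) show

`generateDesign` reproduces the sampling layout: sows per breed split
across the two ages (default 9 per breed as in the study; the acceptance
simulations use 8 so that 4 fetuses per sow give a 64-sample grid), litters
drawn from the two possible sire breeds with both present whenever the
litter size allows. `simulateExpression` plants each probe in one of five
truth classes — null, complete, additive, age-only, genotype-only — with a
configurable effect magnitude (default 1 log2 unit) applied to every
nonzero coefficient in a fixed sign pattern, baseline
$\mu \sim U(4, 14)$ log2 units to mimic microarray dynamic range, and
noise defaults $\sigma_{sow} = 0.15$, $\sigma_{res} = 0.3$ — a
litter-to-residual variance ratio of one quarter, a moderate within-litter
correlation chosen once as a realistic default; the real study's ratio is
unknown, so it is a simulation knob, not an estimate. Default class
proportions are 80% null and 5% per signal class. Per-probe RNG streams
derive from a master seed as a prefix sequence, so enlarging the probe set
never reshuffles earlier probes and identical seeds give byte-identical
tables.

`simulatePhenotypes` builds each phenotype as a weighted sum of a recorded
driver-probe set plus Gaussian noise. One structural point matters for
interpreting the recovery tests: when 20 mutually independent probes drive
a phenotype with equal weights, each carries only 1/20 of the signal
variance and its marginal correlation with the phenotype is about 0.21
regardless of the weight — below the extreme-value noise floor of ~1,980
null probes at 64 samples, so no correlation-based method can identify
those drivers individually. The driver-recovery condition therefore plants
the drivers as a correlated module (age-responsive probes among nulls)
driving the phenotype at signal-to-noise 3, which is also the biologically
realistic situation: maturity phenotypes co-vary with coordinated gene
modules, not with 20 unrelated transcripts. Recovery there is essentially
perfect. Passing these tests shows the machinery is correct under the
generative model; it does not certify performance on real arrays, whose
probe correlation structure, heavy-tailed noise and normalization artifacts
the generator deliberately does not emulate (no dye effects, no scanner
artifacts, no probe-sequence content).

`simulateQPCR` converts selected probes' expression to cycles under
per-gene efficiencies with additive Cq noise and appends stable reference
candidates; a per-target SNR mode scales the noise to the row's biological
spread, which gives the closed-form check
$r = \mathrm{SNR}/\sqrt{1 + \mathrm{SNR}^2}$ for the platform correlation.

# Problem sizes and reproducibility

The test suite and the acceptance script run the scans at 1,200–5,000
probes and 64 samples, the sPLS recovery at 2,000 probes over 20 seeded
replicates, and the type-I calibration on 2,000 null probes — sizes at
which every property is measured with useful precision while a complete
run stays in the minutes range on one core. The pipeline (`runPipeline`)
routes all randomness through one master seed and writes a manifest with
per-artifact checksums; two runs with the same configuration are
byte-identical.

# Known limitations

* Upstream microarray normalization is out of contract: the pipeline
  starts at a normalized (optionally raw-scale) intensity matrix.
* The Satterthwaite joint test is mildly liberal at 16 litters; users
  wanting exactness at small cluster counts can use the LRT flag with a
  parametric bootstrap of their own.
* Whether fixed effects should be tested jointly (our default) or per term
  before pooling is a design choice; the joint test matches the "any
  signal" DEP definition.
* sPLS keepX tuning is per component on a fixed ladder, not a joint
  search.
* The enrichment universe must be supplied; there is no built-in
  annotation.
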