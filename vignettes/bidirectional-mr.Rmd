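---
title: "Bidirectional two-sample Mendelian randomization with bimr: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional two-sample MR: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimr)
```

# The problem

`bimr` infers causal relationships between quantitative traits (its motivating
use is brain imaging-derived phenotypes, IDPs) and binary disease outcomes
from GWAS *summary statistics only*, in both directions: trait as exposure,
disease as outcome ("forward"), and disease as exposure, trait as outcome
("reverse"). The identifying idea of Mendelian randomization is that alleles
are randomized at conception, so genetic variants robustly associated with an
exposure act as instrumental variables: their downstream association with the
outcome is shielded from the confounding and reverse causation that plague
observational imaging–disease correlations — provided the instruments (i)
are strongly associated with the exposure, (ii) are independent of
confounders, and (iii) affect the outcome only through the exposure.

Two-sample MR estimates the SNP–exposure effects $\hat\gamma_j$ (SE
$\sigma_{x_j}$) and SNP–outcome effects $\hat\Gamma_j$ (SE $\sigma_{y_j}$)
in different cohorts, which is what public GWAS repositories provide.

# Summary-statistic preparation

**Standardization.** To compare effects across studies with different trait
units, every table can be rescaled to the per-SD scale using only the z-score
$z = \beta/se$, the minor allele frequency $f = \min(\mathrm{eaf},
1-\mathrm{eaf})$ and the sample size $n$:
$$\beta^\ast = \frac{z}{\sqrt{2f(1-f)(n+z^2)}}, \qquad
  se^\ast = \frac{1}{\sqrt{2f(1-f)(n+z^2)}}.$$
The transformation preserves $z$, and hence every p-value, exactly
(`standardize_effects()`); records with $f \in \{0,1\}$ are rejected because
the scale factor degenerates. For a binary GWAS whose SE carries the
case-ratio factor $r(1-r)$, standardization changes the effect *units* by
$\sqrt{r(1-r)}$; significance and z-statistics are unaffected. Whether to
standardize before selection is a config switch (`standardize`), on by
default; the workflow scripts disable it when inputs are already emitted on
their analysis scale so that binary-outcome estimates exponentiate to an
odds ratio per SD directly.

**Harmonization.** SNPs shared by the exposure and outcome tables are aligned
to the exposure's allele orientation (`harmonize()`): swapped alleles flip
the sign of the outcome effect and reflect the frequency. Palindromic SNPs
(A/T, C/G) are strand-ambiguous; those with MAF within
`palindrome_maf_window` of 0.5 (default 0.08, i.e. MAF > 0.42) are removed,
and the ones kept are oriented by frequency concordance, the convention of
the established harmonization tools. Allele pairs that cannot be reconciled
by a swap are dropped — no frequency-based strand inference is attempted for
them, because at the frequencies where it would be needed it is exactly
where it is unreliable. The default window is a design choice: the
convention in the field is "MAF close to 0.5", and 0.08 removes the region
where orientation by frequency flips sign with appreciable probability.

# Instrument selection

Candidate instruments pass, in order: genome-wide significance ($p < 5\times
10^{-8}$), greedy LD clumping ($r^2 < 0.001$ within 10,000 kb: repeatedly
promote the smallest-p SNP and discard linked neighbours; ties broken by
position then id so output is deterministic), removal of SNPs associated at
$p < 5\times10^{-8}$ with catalogued confounders (education, socioeconomic
status, smoking, drinking — supplied as a file, the offline stand-in for
trait-association database queries) and with the outcome itself, optional
exclusion of the extended MHC (chr6:28,477,797–33,448,354, GRCh37 — the
region's pervasive disease associations make exclusion a standard
sensitivity analysis), and a weak-instrument filter. Instrument strength
uses
$$R^2_j = \frac{\beta_j^2}{\beta_j^2 + se_j^2\, n}, \qquad
  F = \frac{R^2 (n-k-1)}{(1-R^2)k},$$
with the set-level $R^2$ the sum of the per-SNP values. The per-SNP filter
(F ≥ 10, i.e. the formula at $k=1$) is the default, matching the convention
that *SNPs* with F ≥ 10 are retained; the set-level F is also reported. If
fewer than `min_k = 4` instruments survive, selection reruns once at the
relaxed threshold $5\times10^{-6}$, still requiring per-SNP F ≥ 10; a
stricter $5\times10^{-9}$ threshold is available for sensitivity reruns.

# Estimators

Let $w_j = 1/\sigma_{y_j}^2$. All confidence intervals are
$\hat\theta \pm 1.96\,se$ (normal quantiles; t-quantiles optional for
Egger), and for binary outcomes every estimate is also reported as
$OR = e^{\hat\theta}$ with exponentiated CI bounds.

* **Wald ratio** (k = 1): $\hat\theta = \hat\Gamma/\hat\gamma$, first-order
  delta SE $\sigma_y/|\hat\gamma|$. (A second-order correction is not
  applied by default; with F ≥ 10 instruments the first-order term
  dominates.)
* **IVW with multiplicative random effects** (primary, k ≥ 2): weighted
  regression of $\hat\Gamma$ on $\hat\gamma$ through the origin, equal to the
  $(\hat\gamma_j/\sigma_{y_j})^2$-weighted mean of the per-SNP ratios. The
  SE is scaled by the residual SD but floored at the fixed-effect value —
  heterogeneity can only widen, never narrow, the interval.
* **MR-Egger** (k ≥ 3): the same regression with an intercept, after
  orienting all instruments to $\hat\gamma_j \ge 0$ (required for the
  intercept to estimate the average directional pleiotropic effect). Valid
  under the weaker InSIDE assumption at the cost of much lower precision.
* **Weighted median** (k ≥ 3): per-SNP ratios are ordered and interpolated
  at normalized cumulative weight 1/2 (cumulative weight of the $j$-th
  ratio taken as $\sum_{i\le j} w'_i - w'_j/2$); consistent when valid
  instruments carry ≥ 50% of the weight. Its SE comes from a parametric
  bootstrap (default 1000 replicates, seed recorded in the output).
* **Maximum likelihood** (k ≥ 2): joint normal likelihood with per-SNP
  nuisance means $\xi_j$, profiled in closed form to the one-dimensional
  objective $\sum_j (\hat\Gamma_j - \theta\hat\gamma_j)^2 / (\sigma_{y_j}^2 +
  \theta^2\sigma_{x_j}^2)$, minimized from the IVW starting value (Brent);
  the SE is the observed information of the profile.
* **RAPS** (robust adjusted profile score, k ≥ 3): standardized residuals
  $t_j = (\hat\Gamma_j - \theta\hat\gamma_j)/\sqrt{\sigma_{y_j}^2 +
  \theta^2\sigma_{x_j}^2 + \tau^2}$ with systematic-pleiotropy
  overdispersion $\tau^2 \ge 0$ estimated from
  $\sum_j \psi(t_j)t_j = k\,\delta$ and a Huber-robustified loss (tuning
  constant 1.345, $\delta = 2\Phi(c)-1$); quadratic loss and
  no-overdispersion variants are options. Solved by alternating a Brent
  step in $\theta$ with a root-find in $\tau^2$; $\hat\tau^2$ pinned at 0 is
  legal and reported. The SE is the M-estimation sandwich with $\tau^2$
  plugged in.

`mr_run_all()` picks the battery by instrument count (k = 1: Wald; k = 2:
IVW + ML; k ≥ 3: all five) and a failing method is recorded without
aborting the rest. IVW (or the Wald ratio) is the primary estimator; the
others are concordance checks.

# Sensitivity battery

Run for every result below the nominal threshold:

* **Cochran's Q**: $Q = \sum_j w'_j(\hat\beta_j - \hat\beta_{IVW})^2$ over
  per-SNP ratios with first-order weights $(\hat\gamma_j/\sigma_{y_j})^2$,
  $\chi^2_{k-1}$ p-value. Q equals the weighted residual sum of squares of
  the origin regression (an algebraic identity the tests verify). The
  modified second-order weights are available but off by default.
* **Egger intercept test**: two-sided test of the Egger intercept, the
  average directional pleiotropic effect.
* **MR-PRESSO**: the observed leave-one-out weighted RSS is compared with
  its parametric-bootstrap null (draws centred on the leave-one-out IVW
  predictions); per-SNP residuals give the outlier test
  (Bonferroni-adjusted over k at `outlier_alpha` = 0.05), and when outliers
  are found a distortion test compares the outlier-removed estimate against
  removals of random inlier subsets of the same size. Defaults: 1000
  simulations, explicit seed; empirical p-values carry the +1 correction so
  they are never 0. The test needs k ≥ 4 to be stable.
* **Leave-one-out**: k IVW refits each dropping one SNP; a flag is raised
  when any single removal changes the significance status at the nominal
  level.

# Multiple testing and power

With hundreds of correlated phenotypes, Bonferroni over the raw count is
too blunt. The effective number of tests comes from the spectral
decomposition of the phenotype correlation matrix (`matspd_meff()`):
Nyholt's $M_{eff} = 1 + (M-1)(1 - \mathrm{Var}(\lambda)/M)$ (default — it
is the variant that yields non-integer values like the 135.48 used for the
341-IDP panel) and the Li–Ji integer-part variant as an alternative. The
study-wide threshold is then $\alpha / (M_{eff} \cdot
\text{diseases} \cdot \text{directions})$ — e.g. $0.05/135.48/7/2 =
2.64\times10^{-5}$ — with a nominal (suggestive) level of $10^{-4}$.

Power uses the normal approximation for the IVW estimate: for a binary
outcome
$\Phi\!\big(\sqrt{n\,R^2\,r(1-r)}\,|\log OR| - z_{1-\alpha/2}\big)$ with
$n$ the outcome GWAS size and $r$ the case ratio; for continuous outcomes
the $r(1-r)$ factor is dropped. At zero effect it returns $\alpha/2$ (the
wrong-sign rejection tail is ignored, which is negligible at any usable
power).

# The synthetic-data generator

`simulate_pair()` emulates the statistical structure of real two-sample
inputs so the whole pipeline can be built and validated offline. The genome
is a sequence of LD blocks (default 5 SNPs, within-block $r^2 = 0.8$); a
random subset of blocks carries true instrument effects $\gamma_j$
(magnitudes U(0.12, 0.18) on the standardized scale, oriented positive on
the effect allele — estimators are invariant to joint sign flips, so this
is without loss of generality, and it makes "directional" pleiotropy
directional in ratio space). Tag SNPs carry $r\gamma$ and within-block
sampling noise is exchangeable-correlated at $r = \sqrt{r^2}$. Observed
effects follow the two-sample model
$$\hat\gamma_j \sim N(\gamma_j, \sigma_{x_j}^2),\qquad
  \hat\Gamma_j \sim N(\theta\gamma_j + \alpha_j, \sigma_{y_j}^2 + \tau^2),$$
with SEs set by the standardization relation $1/\sqrt{2f(1-f)n}$ (times the
case-ratio factor for binary outcomes) and MAF drawn from U(0.05, 0.5).
Direct effects $\alpha_j$ implement the pleiotropy regimes: `balanced`
(mean zero), `directional` (nonzero mean), `inside_violating` ($\alpha$
regressed on $\gamma$, violating InSIDE), over a configurable fraction of
instruments. A fraction of instruments is planted in the confounder
catalog, a fraction of outcome rows is stored on the swapped allele
orientation, and a small fraction of SNPs is palindromic, so selection,
harmonization and exclusion are all exercised. A shared `panel_seed` lets
several traits sit on one genotyping panel while drawing independent
effects. Defaults mirror a UK-Biobank-scale imaging GWAS against an
AD-scale case-control GWAS ($n_{exp}$ = 33,224; $n_{out}$ = 63,926 with
21,982 cases).

What the generator does **not** emulate: realistic MAF-dependent LD decay,
allele-frequency mismatch between cohorts, population stratification,
sample overlap, winner's-curse beyond index-SNP selection within a block,
or genuine liability-scale link functions for binary traits. Passing tests
therefore demonstrate correctness of the estimators and the pipeline
contract on well-specified two-sample data, not robustness to every
pathology of real GWAS inputs.

# Validation design and problem sizes

The test suite validates each operation against an independent oracle
(closed-form weighted means, hand arithmetic, analytic eigenvalues of
block-exchangeable matrices, a Monte-Carlo power oracle) and each estimator
against parameter-recovery simulations. Scales were chosen so the whole
suite runs in well under a minute on one core: coverage at 500 replicates
(k = 50), Egger intercept level at 1000 replicates (k = 30), MR-PRESSO
detection at 200 seeded runs (k = 10, 1000 simulations each).

The robustness contrast (weighted median vs IVW under 40% directional
pleiotropy) is run in a deliberately precise-instrument regime
($n_{exp} = 5\times10^5$, $n_{out} = 10^6$, continuous outcome, $\gamma
\sim U(0.10, 0.20)$, $\alpha \sim N(0.03, 0.005^2)$ on 40% of
instruments): the contamination shift in ratio space (~0.2) then dwarfs
per-SNP sampling noise (~0.011), which is the regime where the weighted
median's 50%-breakdown property bites (predicted biases: IVW
$0.4\,E[\gamma\alpha]/E[\gamma^2] \approx 0.077$; weighted median
$z_{0.833}\times$ ratio-noise $\approx 0.011$). At GWAS-realistic noise the
contamination bleeds into the median and the contrast is smaller.

# Numerical choices and degenerate inputs

* Residual-scale floor at 1 for IVW/Egger (multiplicative random effects
  never report less than fixed-effect uncertainty); under exact
  proportional data the floor binds and the SE equals the fixed-effect SE.
* Empirical p-values (MR-PRESSO) use the +1 correction; their minimum is
  $1/(n_{sim}+1)$.
* RAPS alternates Brent minimization and a bracketed root-find;
  convergence floors are absolute + relative because `optimize()` cannot
  localize below $\sqrt{\epsilon}$. Non-convergence is an explicit error
  carrying the last iterate.
* Clumping ties on p-value break by position then id; output is
  deterministic and every randomized procedure (weighted-median bootstrap,
  MR-PRESSO, the generator) takes an explicit seed, so pipeline runs are
  byte-for-byte reproducible.
* Zero exposure effect makes the Wald ratio an explicit error; all-equal
  exposure effects make the Egger slope unidentified (collinearity error);
  `eaf` of exactly 0/1 rejects the record; an empty exposure/outcome SNP
  overlap is an error distinguishable from an empty post-filter result.

# Known limitations

Single LD reference for all traits; no multivariable MR, Steiger filtering,
or contamination-mixture estimators; no genotype-level computation (the LD
matrix is an input); power is the IVW normal approximation, not simulation;
and the confounder catalog is only as complete as the file supplied — the
same caveat that applies to database lookups in real analyses.
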