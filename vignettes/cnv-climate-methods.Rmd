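---
title: "Methods: CNV-climate association analysis with cnvclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV-climate association analysis with cnvclim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvclim)
```

## The problem

Copy number variants (CNVs) — deletions and duplications of genomic
segments — segregate in structured populations sampled across contrasting
climates. If the carrier frequency of a CNV follows a climatic gradient
more strongly than neutral population structure predicts, the locus is a
candidate for climate-mediated selection. `cnvclim` provides the full
chain from raw CNV call tables to such candidates: quality control and
region construction, a physical model turning sunshine records into solar
radiation, two complementary genotype–environment association scans, a
kinship-corrected probe-level association with permutation-based
family-wise error control, and interval annotation.

Throughout the package, genomic coordinates are 1-based inclusive (the
PennCNV convention); BED output is converted to 0-based half-open at the
boundary. Copy-number classes are CN0 (homozygous deletion), CN1
(hemizygous deletion), CN3 (duplication) and CN4 (triplication); CN0/CN1
are "deletion-polarity", CN3/CN4 "duplication-polarity".

## Quality control and CNVR construction

A sample passes QC iff its log-R-ratio standard deviation is below 0.3,
B-allele-frequency drift below 0.01 and waviness factor below 0.05 (all
strict inequalities), and its call count does not exceed 100 (counts
above 100 indicate poor DNA quality). A call is retained iff it is
supported by **more than** 3 consecutive SNP probes and spans at least
1 kb. The probe-count bound is exposed as `min_snps_exclusive` because a
common alternative convention is "at least 3"; the strict reading is the
default.

`merge_to_cnvrs()` unions overlapping **or book-ended** intervals per
chromosome (distance-0 merge, the default semantics of interval-merging
tools), classifying each region *loss*, *gain*, or — when both deletion-
and duplication-polarity calls support it — *mixed*. Because it is not
obvious whether a CNVR's carrier frequency should count calls or samples,
both `n_calls` and `n_carriers` are reported. Percentages in
`summarize_cnvs()` are rounded half-up to two decimals, matching how such
tables are usually printed; note base R's `round()` rounds half-even,
which would differ at exact halves.

Call-set concordance (for comparing against an external call set) is the
percentage of query calls with ≥ 1 bp overlap with a same-direction call
in the same sample; the direction-aware, per-sample rule is a package
decision (the quantity is rarely given a precise published definition)
and each piece is configurable through the call/table inputs.

## Solar radiation from sunshine fraction

Daily extraterrestrial radiation on a horizontal surface is

$$H_o = \frac{86400\,G_{sc}}{\pi}\Big(1 + 0.033\cos\tfrac{2\pi n}{365}\Big)
 \big(\cos\Phi\cos\Delta\sin\omega_s + \omega_s\sin\Phi\sin\Delta\big),$$

with solar constant $G_{sc} = 1361$ W/m², day-of-year $n$, latitude
$\Phi$, declination
$\Delta = 23.45\frac{\pi}{180}\sin\big(2\pi\frac{284+n}{365}\big)$ and
sunset hour angle $\omega_s = \arccos(-\tan\Phi\tan\Delta)$. Numerical
choices:

* the $\arccos$ argument is clamped to $[-1, 1]$, so polar night yields
  $\omega_s = 0$ (and $H_o = 0$) and polar day $\omega_s = \pi$;
* the annual mean uses Klein's twelve representative days
  (17, 47, 75, 105, 135, 162, 198, 228, 258, 288, 318, 344), one per
  month; the tests confirm this approximates the 365-day daily mean
  within 2 % for $|\Phi| \le 66°$;
* the year length is fixed at 365 days (no leap handling), matching the
  formulas above;
* computation is in J/m²/day and reported in MJ/m²/day.

The annual clearness index relates surface to extraterrestrial radiation
through the annual sunshine fraction $S \in [0,1]$. The relationship is
implemented in the multiplicative form

$$\bar K = \bar K_{clear}\,\big(\beta + (1-\beta)\,S^{\gamma}\big),$$

with $\bar K_{clear} = 0.7191$, $\beta = 0.1930$, $\gamma = 0.7283$. The
typography of this equation in secondary sources is ambiguous between the
multiplicative form and an exponent form
$\bar K_{clear}^{\,\beta+(1-\beta)S^\gamma}$; both coincide at $S = 1$
(returning 0.7191 exactly), but at $S = 0$ the multiplicative form gives a
physically sensible overcast value of ≈ 0.139 whereas the exponent form
gives ≈ 0.94, so the multiplicative form is the default and the exponent
variant is available via `solar_constants(clearness_form = "exponent")`.
Site radiation is $\bar H = \bar K \times \bar H_o$. The annual sunshine
fraction is used directly (rather than averaging monthly clearness
indices), because the relationship is stated for annual averages.

## Genotype–environment association

CNV genotypes are coded as binary presence/absence per sample
(`build_genotype_matrix()`), with per-sample climate obtained by joining
each sample to its site's value (`sample_climate()`); assigning the site
value to every individual is the package default, the only option the
sampling design supports when climate is recorded per site.

**Univariate logistic scan.** `sambada_scan()` fits one logistic
regression per (locus, variable) pair by IRLS, with optional structure
covariates (e.g. climate principal components from `env_pca()`). The Wald
statistic is $(\hat\beta/\mathrm{se})^2$ with a two-sided $\chi^2_1$
p-value. Bonferroni adjustment uses the **full model grid**
(loci × variables) as denominator, including skipped models, so the
correction never becomes anti-conservative when loci are dropped.
Selection requires adjusted $p < 0.01$ and Wald score $> 34$; the score
cutoff is a reported operating point in this literature, not a derived
quantity, and is therefore a plain configurable argument. Loci with fewer
than 5 carriers (or non-carriers) are skipped — logistic fits on such
margins are unstable. (Quasi-)separation and non-convergence are detected
from the IRLS warnings and flagged with `NA` p-values rather than
reported as finite estimates.

**Latent factor mixed model.** `lfmm_scan()` implements the least-squares
LFMM: center the genotype matrix $G$; estimate $K$ latent factors as the
top-$K$ left singular vectors of the residual of $G$ after regressing out
the (standardized) environment $X$; refit every locus on $[X, U]$;
form $z = \hat\beta/\mathrm{se}$; calibrate by the genomic inflation
factor $\lambda = \mathrm{median}(z^2)/0.456$ per variable; BH-adjust the
calibrated p-values. Two design points deserve comment:

* *Why residual-based factors?* Estimating factors from $G$ itself (a
  PCA-covariate approach) absorbs genuine locus-level environmental
  effects into the factors: in planted-effect simulations it drops
  top-rank recovery of planted loci from 10/10 to 2/10. Residual-based
  factors preserve that signal; the price is that structure collinear
  with the environment is not removed locus-by-locus, which is exactly
  what the global GIF calibration then corrects. This mirrors the
  published least-squares LFMM pipeline (ridge factor estimation plus
  GIF-calibrated tests).
* Selection applies both thresholds literally — calibrated $|z| \ge 10$
  and BH-adjusted $p < 10^{-6}$ — although they are partially redundant
  at large sample sizes.

With $K = 0$ the scan reduces *exactly* to ordinary per-locus regression
(a tested invariant). If the refit design is ill-conditioned, a ridge
penalty of $10^{-5}$ is added (with a message).

`env_pca()` standardizes variables before decomposition, drops constant
columns with a warning, and fixes component signs deterministically (the
largest-magnitude loading is made positive). The dimensionality question
— one axis or two — is left to the caller via `n_components`
(default 2); the components are intended as structure covariates.

## Probe-based association with solar radiation

`build_probe_matrix()` marks, separately per polarity, every probe whose
position lies within a call's span (boundaries inclusive). Kinship is
Balding–Nichols standardized:

$$K_{ij} = \frac{1}{M^*}\sum_{m}
  \frac{(x_{im}-\hat p_m)(x_{jm}-\hat p_m)}{\hat p_m(1-\hat p_m)},$$

over the $M^*$ polymorphic probes; monomorphic probes carry no
information and are excluded. The Gram construction is PSD by design;
should floating-point error leave an eigenvalue below $-10^{-8}$, the
minimal diagonal ridge restoring PSD is added and reported.

`emma_reml_fit()` fits $y = X\beta + u + e$,
$\mathrm{var}(u) = \sigma_g^2 K$, $\mathrm{var}(e) = \sigma_e^2 I$, by
profiling the restricted likelihood over the single ratio
$\delta = \sigma_e^2/\sigma_g^2$ on $\log\delta \in [-10, 10]$, after one
spectral decomposition of $K$. The whitening rotation at the fitted
$\delta$ is cached and reused by every probe test and every permutation —
the standard single-fit approximation that makes genome-wide mixed-model
scans tractable. `mlm_scan()` then tests each probe by generalized least
squares in the whitened coordinates (via residualization against the
fixed covariates, so each probe costs one inner product), flagging probes
at the suggestive level $p < 5\times10^{-4}$. The logistic counterpart
(`logistic_scan()`, occurrence regressed on radiation plus PC covariates,
top threshold $5\times10^{-5}$) inverts the role of response and
predictor, matching the two tool conventions this mirrors; consensus
probes are those significant under both.

**Region merging.** Runs of probes with $p$ below a threshold, allowing
gaps up to 1 Mb between consecutive significant probes, become candidate
regions; runs with fewer than 3 probes are discarded (3 is the smallest
supporting-probe count one sees reported for such regions). The region's
raw p is its **peak probe p** — peak-probe significance rather than a
Fisher combination, because the downstream permutation adjustment is
defined on the maximum statistic. The merging rule itself is a package
decision (the upstream tool's rule is unpublished) and every piece is an
argument.

**max(T) permutation.** The phenotype is permuted $B$ times (seeded); per
permutation the per-probe GLS $|t|$ is recomputed at the *fixed* REML
$\delta$ and the genome-wide maximum recorded. A region's adjusted p is
$(1 + \#\{\max_b \ge \text{peak}_r\})/(B+1) \ge 1/(B+1)$. Maxima are
taken genome-wide (not within regions), the more conservative and more
common choice. Not re-estimating $\delta$ per permutation is the standard
max(T) shortcut; re-estimation would be $B$ times costlier for a
second-order change in the null distribution. Because candidate-region
formation is only a screening step, its threshold must be lenient
relative to the permutation rejection boundary — with few effective
independent probe blocks the boundary can sit at raw $p \approx 0.02$ —
otherwise screening, not max(T), becomes the binding error control and
the realized family-wise error falls well below nominal. The package's
FWER simulation therefore screens at $p < 0.10$ and lets the permutation
adjustment do the control; the measured family-wise error is then within
the binomial confidence band of the nominal 0.05.

## Annotation

Gene pairs are reported when the overlap covers at least 10 % of the
**region** length (the entity being annotated; the fraction-of-gene
alternative is available by swapping the inputs). QTL annotation first
excludes QTLs with confidence intervals of 5 Mb or wider (strict `<`
retention) and then requires 50 % coverage of the region; a `reciprocal`
flag additionally requires 50 % of the QTL. Overlap is computed with
GenomicRanges; the tests verify it against an all-pairs oracle.

## The synthetic world

`generate_world()` emulates the sampling design this pipeline targets:
47 sites in 4 geographic clusters (latitude centers 55, 42, 35, 10 °N —
a Europe / Central-East Asia / West Asia / Africa layout), 15 individuals
per site (≈ 700 samples), 9 climate parameters × 12 monthly columns whose
mean plus small noise gives the yearly column (117 climate variables),
plus elevation. Sunshine fraction is clamped to (0, 1] so the solar
module's domain is always valid. CNV copy-number classes are drawn with
weights 4726 : 23298 : 11018 : 103 (the class balance of a large
published sheep call set). Population structure enters as per-locus,
per-cluster Gaussian logit offsets (SD 0.5 by default; 1.5 in the
"strong structure" calibration simulations) — precisely the confounding
the LFMM and kinship models must correct, because climate is itself
cluster-patterned through latitude. Planted loci add a logistic slope
(default 1.5) on the standardized target variable (annual sunshine by
default). A configurable fraction of samples (5 %) is drawn to violate a
QC threshold. Loci are probe-aligned and span at least 3 probes, so
probe-level machinery always has blocks to work with.

What the generator does **not** emulate: linkage disequilibrium between
loci, uneven probe spacing, raw LRR/BAF intensities and the HMM calling
step, admixture clines (clusters are discrete), measurement error in
climate records, and site-level sample-size imbalance. Passing tests
therefore demonstrate the statistical machinery's correctness and
calibration under the stated generative model, not robustness to every
artifact of real array data.

## Problem sizes used by the test suite

The simulation-based tests run at reduced but adequate sizes chosen for
desk-scale reproducibility: LFMM calibration uses 50 null worlds of 400
samples × 500 loci; family-wise error uses 200 exchangeable null worlds
of 64 samples with ~15 probe blocks at B = 1000 permutations (scaled down
from the 10,000 one would use on a real call set); planted-locus recovery
uses one world of 600 samples × 200 loci with 10 planted effects; oracle
equivalence checks use 100 random instances per primitive. The full
pipeline at realistic scale (tens of thousands of probes, B = 10,000) is
a matter of minutes, not hours, because the scans are matrix-formulated.

## Known limitations

* The logistic scans rely on asymptotic Wald inference; with very few
  carriers the skip rule (< 5) is a blunt guard, and exact tests are not
  provided.
* GIF calibration rescales all z-scores by one factor per variable; it
  corrects global inflation but cannot undo locus-specific confounding.
* The mixed model treats radiation as Gaussian; heavy-tailed phenotypes
  would need transformation.
* `maxt_adjust()` holds $\delta$ and the kinship eigendecomposition fixed
  across permutations (the standard shortcut), which is slightly
  anti-conservative in principle; the FWER simulation shows the effect is
  negligible at these sizes.
* GO/KEGG-style enrichment of annotated genes is out of scope (it
  requires external annotation services).
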