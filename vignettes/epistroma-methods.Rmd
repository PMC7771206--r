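---
title: "Methods: linking chromatin accessibility to epithelial tissue proportion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking chromatin accessibility to epithelial tissue proportion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`epistroma` implements an integrative screen for tumor cohorts with matched
ATAC-seq and H&E histopathology. The phenotype is a single image-derived
number per sample, the epithelial tissue proportion

$$\mathrm{Proportion}_{epi} = \frac{\mathrm{Area}_{epi}}
{\mathrm{Area}_{epi} + \mathrm{Area}_{stro}},$$

computed from a segmentation label mask in which each pixel is background,
epithelial, or stromal. Background pixels appear in neither numerator nor
denominator, so the proportion is invariant to padding or to how much empty
slide the mask covers. Samples with proportion $\ge 0.5$ are called
epithelial-high, the rest epithelial-low; the boundary is inclusive for
"high". ER-positive breast tumors are strongly skewed toward low
proportions, and the synthetic cohort generator reproduces that skew by
default.

The pipeline then proceeds in four stages.

**1. Peak-phenotype screen.** For every accessibility peak, the Spearman
correlation $\rho$ between the peak's normalized accessibility and the
proportion is computed across samples (mid-ranks on ties). Two-tailed
p-values come from one of three methods: exhaustive enumeration of all $n!$
rank pairings (refused above $n = 8$, where enumeration stops being
feasible), the $t$ approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ with
$n-2$ degrees of freedom, or a seeded Monte-Carlo permutation test
($\ge 10^5$ draws) for sensitivity analysis. At realistic cohort sizes
($n \approx 54$) an exact permutation distribution cannot be enumerated, so
the $t$ approximation is the default; the Monte-Carlo option lets a user
check that method choice does not move any call that matters.
Benjamini-Hochberg q-values are computed over **all testable peaks** (never
over a pre-selected subset), and peaks are called significant at $q <
\alpha$ with $\alpha = 0.05$. Peaks with constant accessibility have no
defined correlation; they are reported with `NA` statistics and excluded
from the multiple-testing universe, with a warning — silently treating them
as $p = 1$ would distort the BH universe.

**2. Peak-to-gene linking.** Two routes, mirroring how regulatory regions
act:

* *Promoter links.* The promoter is defined as 1000 to 100 bp upstream of
  the TSS, strand-aware: $[\mathrm{tss}-1000, \mathrm{tss}-100]$ on `+`
  genes, $[\mathrm{tss}+100, \mathrm{tss}+1000]$ on `-` genes, 1-based
  inclusive, truncated at the chromosome start with a warning. A significant
  peak whose summit falls in a gene's window is linked to it; a summit in
  several windows goes to the gene with the nearest TSS, ties broken by
  lexicographic gene id so results are deterministic.
* *Distal links.* Every (significant peak, gene) pair on the same
  chromosome with summit-to-TSS distance strictly below 500 kbp is a
  candidate. For each candidate the Spearman correlation between peak
  accessibility and gene expression is computed over the shared samples; BH
  is applied over **all candidate pairs**, and links with $q \le 0.01$
  survive. Two filters then remove likely artifacts: a link is
  *copy-number driven* when adjusting for the peak's copy-number signal
  destroys most of the association — operationalized as
  $|\rho_{\text{partial}}| < c \cdot |\rho|$ with attenuation threshold
  $c = 0.5$ (the partial Spearman correlation is the Pearson partial
  correlation of the three pairwise rank correlations) — and a link is
  dropped when its peak summit overlaps *any* gene's promoter window, since
  such peaks are promoter elements, not enhancers. The 0.5 attenuation
  threshold is a package choice: the source procedure states the filter's
  intent but no formula, and a relative rule is scale-free and directly
  testable with planted constructions.

Links of both kinds collapse to one row per distinct target gene. Each gene
is signed by the Spearman correlation between its expression and the
proportion: positive genes track epithelial content, negative genes track
stroma. A correlation of exactly zero is labeled positive by convention
(and logged); genes absent from the expression matrix keep sign `unknown`
with a warning rather than being silently dropped.

**3. Over-representation analysis.** Target genes (separately for the
positive and negative groups) are tested against a GMT gene-set collection
with the one-sided hypergeometric test
$p = P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, BH across sets.
The background universe defaults to all genes in the expression matrix.
This is a deliberate generic stand-in for proprietary pathway tools; no
attempt is made to reproduce any vendor knowledge base.

**4. Survival analysis.** Univariately, each target gene (and the
proportion itself) is median-split — values strictly above the median are
"high", ties at the median go low, a convention fixed for determinism —
and the two groups are compared with the standard two-group log-rank test
$(\sum(O-E))^2/V$ with hypergeometric variance at each distinct event time
and a $\chi^2_1$ reference (no continuity correction; exact small-sample
p-values are out of scope). Multivariately, the significant features are
z-scored per feature and samples are clustered with k-means ($k = 2$,
seeded initialization, 10 restarts, best inertia kept). Cluster indices are
arbitrary, so the high-risk label goes to the cluster with the higher
Nelson-Aalen cumulative hazard at the median follow-up time (falling back
to the raw event rate, then to the first cluster, on exact ties). The
log-rank p between the two clusters is the headline number. z-scoring
before k-means, and including the image feature as one more z-scored row,
are package choices where the source procedure is silent; both are plain
function arguments, not hidden behavior.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| screen FDR `alpha` | 0.05 | q-value | standard discovery threshold for the peak screen |
| distal FDR `fdr_cut` | 0.01 | q-value | conservative, guards the much larger pair universe |
| `max_dist` | 500,000 | bp | strict upper bound on summit-TSS distance for enhancer candidates |
| promoter window | 1000 / 100 | bp upstream of TSS | regulatory-region convention; the 100 bp proximal gap excludes core-promoter machinery |
| epithelial cutoff | 0.5 | proportion | high/low boundary, inclusive for high |
| CNV attenuation | 0.5 | relative | fraction of the marginal correlation that must survive CN adjustment |
| p-value method | auto | — | exhaustive for $n \le 8$, $t$ approximation otherwise |

The 500 kbp bound is implemented as a strict inequality and is
configurable; whether the original bound was inclusive is not stated
anywhere, and at 1 bp resolution the choice is immaterial in practice. An
optional $|\rho|$ cutoff for the screen exists (`rho_cut`, default off)
because a stringent-correlation remark appears only in discussion-level
text and was never part of the stated procedure; it is not applied to any
default result.

# The synthetic cohort generator

Every input the pipeline reads can be generated: peak atlases, cohorts,
accessibility/expression/copy-number matrices, label masks, survival
tables. The generators are pure functions of their arguments plus an
explicit seed (bit-identical outputs per seed) and write the same TSV/JSON
formats the pipeline consumes.

* *Cohort.* Proportions are Beta$(2, b)$ with $b$ solved so
  $P(X < 0.5)$ equals the requested low fraction (default 0.87, the
  observed skew of ER-positive cohorts). The degenerate fractions 0 and 1
  fall back to a truncated Beta$(2,2)$, since no Beta distribution puts
  zero mass below its median support point.
* *Accessibility.* A planted peak of strength $s$ and direction $\pm 1$
  draws its latent value from a Gaussian copula with latent Pearson
  correlation $r = 2\sin(\pi s/6)$ to the proportion's normal scores — the
  exact bivariate-normal relation between Pearson and Spearman — then maps
  through the strictly increasing transform $2^{\mu + \text{latent}}$, so
  values are positive and the rank structure (hence Spearman) is exactly
  the latent one. At `noise_sd` $\to 0$ a planted row is a noiseless
  monotone transform and the sample correlation equals the direction
  exactly; at intermediate strengths the *population* Spearman equals $s$
  while the sample value carries ordinary sampling error (the sample
  Spearman at $n$ untied observations lives on a lattice of spacing
  $12/(n(n^2-1))$, so no generator can pin it to arbitrary targets
  exactly).
* *Expression.* Linked genes couple to their peak's realized accessibility
  through the same copula (coupling 0.9 by default); all other genes are
  independent noise.
* *Copy number.* Neutral rows sit at 2 with small noise; designated rows
  carry a strong sample-level CN signal, and both the accessibility and the
  expression of a CN-driven link track that signal with *independent*
  noise, so the marginal association is strong while the partial
  correlation given CN vanishes — exactly the situation the CNV filter
  must catch.
* *Survival.* Event times are exponential with per-sample hazard
  $h_0\exp(\sum_g \beta_g z_g + \beta_p z_{prop})$ (proportional hazards by
  construction, $h_0 = \log 2/1500$ per day, i.e. 1500-day baseline median
  survival); censoring is an independent exponential whose rate is solved
  so the expected censored fraction matches `censor_rate` (default 0.7,
  typical of breast-cancer cohorts with long follow-up).
* *Masks.* Tissue occupies a centered ellipse; a smoothed Gaussian field is
  thresholded at the exact pixel count giving the requested epithelial
  fraction, so the measured proportion matches the target up to pixel
  rounding.

What the generator does **not** emulate: read-level ATAC noise,
fragment-size or Tn5 bias, library-size normalization (values are emitted
already normalized, matching how public peak matrices ship), gene-gene
co-expression beyond planted links, informative censoring, or realistic
H&E texture. A green test on synthetic data therefore establishes that the
statistics and plumbing behave as specified under the stated statistical
structure — not that the pipeline is robust to every artifact of real
assay data.

# Numerical choices and degenerate inputs

* Mid-ranks everywhere for ties; Spearman is the Pearson correlation of
  those ranks.
* $p$-values are floored at the smallest positive double so downstream
  $\log$ transforms never see 0; $\rho = \pm 1$ under the $t$ method hits
  this floor.
* BH is the standard step-up computed as a reverse cumulative minimum;
  q-values are order-invariant and clipped at 1.
* Constant features: undefined correlation (screen) and impossible median
  split (survival) are reported as `NA`/errors, never silently imputed.
* The log-rank variance term is skipped when a risk set has a single
  subject; a zero total variance yields $\chi^2 = 0$, $p = 1$.
* k-means runs on z-scored features; a feature with zero variance
  contributes a zero row rather than `NaN`s. Empty clusters raise a
  degenerate-clustering error instead of relabeling.
* Coordinates: peaks are BED-style 0-based half-open with an absolute
  0-based summit; TSS and promoter windows are 1-based inclusive. All
  conversions happen in the readers and in `summit + 1`, nowhere else.
* Masks are serialized as integer label TSV grids (0/1/2). A PNG codec is
  deliberately not a dependency; the in-memory contract is an integer
  matrix either way, and unknown label values are an error, not background.

# Known limitations

* The screen's default p-value is the $t$ approximation. Its worst-case
  deviation from the exact permutation p is material at very small $n$
  (about 0.024 at $n = 8$, worse below); for tiny cohorts use
  `method = "exhaustive"`.
* Distal links are recomputed from the user's matrices; cohorts or
  normalizations different from those behind any published link set will
  produce different links, by design.
* One proportion per sample is assumed; aggregation over multiple slides
  per patient is out of scope, as are CNN segmentation, ROI detection and
  WSI tiling.
* The multivariate stratification depends on the k-means initialization
  protocol; the seeded protocol here is deterministic but not unique, so
  only ordering-style comparisons between feature sets (not exact
  p-values) are meaningful across implementations.
* Cox modeling, time-dependent covariates and competing risks are not
  implemented; the endpoint is overall survival with death from any cause.
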