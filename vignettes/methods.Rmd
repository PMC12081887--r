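---
title: "Models and methods behind neurohic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neurohic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurohic)
```

neurohic implements the 3D-chromatin analysis stack used in developmental
brain Hi-C studies: ICE balancing and observed/expected (O/E) normalization
of binned contact matrices, A/B compartment profiles and their dynamics,
insulation-score TAD boundaries, two interaction callers (distance-stratified
negative binomial loops, Weibull significant interactions), ROSE-style
super-enhancer (SE) identification, SSIM comparison of contact maps, GWAS
SNP-to-gene linkage, and fuzzy soft clustering of time-course expression.
Because the real datasets such analyses consume are not reproducible at desk
scale, the package carries a first-class synthetic-data generator that plants
every structure the callers look for, with serialized ground truth; all
validation is by recovery and calibration against that truth.

This vignette records the models, the parameter choices that matter, and the
numerical decisions — including the places where the implemented procedure
deliberately departs from the textbook version, and why.

## The synthetic contact model

`synthetic_spec()` defines one chromosome (default 20 Mb). The expected
intensity of pixel $(i, j)$ at bin distance $d = j - i$ is

$$\lambda_{ij} = L \cdot (d+1)^{-\alpha} \cdot (1 + a\,c_i c_j) \cdot T_{ij}
  \cdot P_{ij} \cdot b_i b_j,$$

with decay exponent $\alpha = 1$ (typical Hi-C scaling), plaid compartment
amplitude $a = 0.4$ acting on per-bin signs $c_i \in \{\pm 1\}$, within-TAD
enrichment $T_{ij} = \tau = 2.5$ when $i$ and $j$ share a TAD, focal loop
enrichment $P_{ij} = \varphi$ at planted loop pixels ($\varphi/2$ on the
1-bin shoulder, so neighborhood filtering has realistic local maxima to
resolve), and per-bin biases $b_i$ drawn log-uniform on $[0.5, 2]$ (two bins
are zeroed entirely to exercise masking). Counts are Poisson. The library
size default (2,000 counts per bin of expected upper-triangle mass, about
1&nbsp;million read pairs for 20 Mb at 40 kb) corresponds to the depth of a
modern deep in-situ Hi-C study once scaled down to a 20-Mb chromosome.

Structural layout choices that the callers' validation depends on:

* **TAD edges are snapped to bin boundaries** and compartment blocks are
  unions of whole TADs. Both mirror real genomes — compartment boundaries
  overwhelmingly coincide with domain boundaries — and both are necessary
  for the planted truth to be expressible at bin resolution: a domain edge
  inside a bin displaces the insulation valley by a bin, and free-floating
  compartment edges create insulation valleys that no TAD caller should be
  penalized for finding.
* **Loops are intra-TAD with probability 0.9** (all types: generic,
  promoter-anchored, SE-promoter, SE-SE, SNP-promoter, TE-promoter).
  Chromatin loops in real data live overwhelmingly inside domains; the
  remaining 10% cross a boundary and are genuinely hard for any caller with
  a genome-wide background.
* **Typical enhancers exist as stitchable clusters.** Besides the
  super-enhancer constituent clusters (4–6 peaks, high signal), the
  generator plants 15 weak 3–4-peak clusters and 60 isolated peaks. The
  isolated peaks exercise the >2-constituent validity filter; the weak
  clusters populate the TE class after the rank split, so SE-vs-TE
  comparisons have a real background. Both SE and TE elements loop to a
  promoter; only SE target genes receive the expression boost.
* **Expression** is log-normal around
  $\log_2 \mathrm{FPKM} = \mathrm{baseline} + \beta_{comp}\mathbf{1}[A] +
  \beta_{loop}\,s_{\ell(g)} + \beta_{SE}\mathbf{1}[SE] + \mathrm{trend} +
  \varepsilon$, with $\beta_{comp} = 1$, $\beta_{loop} = 0.5$,
  $\beta_{SE} = 2$ (SE targets are typically several-fold above TE targets)
  and $\varepsilon \sim N(0, 0.5)$. Half the genes carry a monotone stage
  trend of 3 log2 units, split between rising and falling shapes — the two
  planted trajectory classes the soft clustering must recover. A fraction
  (0.15) of compartment blocks flips sign between early and late stages;
  the per-stage compartment state feeds back into expression, which is what
  the B→A upregulation test detects.
* **GWAS input**: 30 index SNPs at association $p \in [10^{-12}, 10^{-7}]$,
  half placed in distal (intergenic, same-TAD-biased) loop anchors of a
  uniquely-binned gene promoter — these are the intended links; 20 SNPs
  above the $10^{-6}$ threshold exercise filtering, LD proxies at
  $r^2 \in [0.5, 1]$ within 50 kb exercise the 0.8 cutoff and position
  dedupe.

What the generator does **not** emulate: mappability structure beyond
uniform biases, copy-number variation, translocations, trans contacts with
structure (the trans generator is uniform, used only as a null), read-level
artifacts, and replicate-level biological variability. Passing tests
therefore demonstrate correctness of the algorithms under the stated model,
not robustness to every pathology of real libraries.

## Normalization

Bins whose marginal is zero or below the 2% quantile of nonzero marginals
are masked (`mask_low_coverage()`; the threshold is configurable — pipelines
differ and no universal value exists). ICE (`ice_balance()`) is the
symmetric iterative correction on the sparse upper triangle: marginals are
equalized to coefficient of variation $< 10^{-5}$ (at most 200 iterations),
weights are normalized to mean 1 over unmasked bins, and the balanced value
is $x_{ij}/(w_i w_j)$, so the weights are direct bias estimates (on
synthetic data, $\log w$ recovers $\log b$ with $r > 0.95$).

One measured property deserves emphasis: **ICE genuinely inflates
chromosome-end bins.** Near an end, a bin has fewer contact partners, so its
marginal is honestly smaller; marginal equalization misreads this geometry
as a bias and scales those bins up by 1.5–2x. On a 250-Mb chromosome this
affects a sliver of the genome; on a 20-Mb test chromosome it is 5–10% of
all bins and visibly fattens per-distance value distributions. This matters
for the significance callers below.

`expected_by_distance()` averages over all unmasked pixel positions at each
distance, counting absent sparse entries between unmasked bins as zeros
(sparse storage makes this ambiguous; the convention is stated because the
alternative — averaging stored entries only — biases the expected value up).
O/E division then removes the decay; per-distance O/E means are exactly 1.

## Compartments

The correlation matrix of O/E rows shows the plaid pattern; its top-3
eigenvectors (after mean-centering) are candidate compartment tracks.
Selection is automated: the PC with the largest absolute Pearson correlation
against the gene-density track wins (ties to the lower index), its sign is
flipped if the correlation is negative, and A = positive. If no PC reaches
$|r| = 0.1$ the profile is flagged unresolved and carries no labels — the
automated, reproducible replacement for manual track inspection.

Per-bin dynamics across stages use one-way ANOVA (`stats::oneway.test`,
pooled-variance by default, Welch optional) on oriented PC values with
samples grouped by stage, BH-adjusted genome-wide; bins with $q < 0.05$ are
dynamic. The replicate structure is the caller's choice (true replicates, or
regions treated as replicates); both designs are supported because the
upstream convention varies.

Compartment strength uses a 5-quantile saddle: bins ranked by PC value,
mean O/E per quantile pair, and strength = (AA corner + BB corner) / (2 AB
corner), with pixels closer than 2 bins excluded so the diagonal does not
dominate. Shuffled labels give strength ≈ 1; the statistic is invariant to
global rescaling and increases monotonically in the planted plaid amplitude.

## Insulation and TADs

The insulation score of bin $b$ is computed from the 480 kb x 480 kb square
of pixels spanning $(b-w..b-1) \times (b+1..b+w)$ — the diagonal bin itself
is excluded, matching the upstream convention. The score is the IQR mean:
the mean of the square's values inside $[Q_1, Q_3]$ (a 25–75% trimmed mean;
the plain mean is exposed as an option). Normalization is
$\log_2(\mathrm{IS}_b / \overline{\mathrm{IS}})$ per chromosome, which makes
the profile invariant to global matrix rescaling.

**The package computes insulation on the O/E matrix by default** (this is
what `run_pipeline()` does; the function accepts balanced input too). The
reason is statistical, and was measured on synthetic data: a trimmed mean is
only a meaningful robust statistic when the trimmed values are exchangeable.
On a decaying matrix the square's top quartile is simply its near-diagonal
corner, so the trim systematically discards the most informative pixels and
flattens boundary valleys (mean valley contrast 0.03 log2 units, against
0.09 on O/E input, where the trim removes genuine outliers such as loop
pixels). Boundary recovery at ±1 bin moves from ~0.75 to ≥0.9 as a result.

Boundaries are strict local minima of the normalized profile with strength —
mean of the nearest flanking local maxima minus the minimum — of at least
`delta = 0.1` (recalibrated on synthetic data; the upstream tool's 0.01
applies to a different statistic). Equal-minimum plateaus yield one boundary
at their leftmost bin; when a valley has no interior flanking maximum the
highest value on that side substitutes. TADs are the regions between
consecutive boundary midpoints, closed by the scored span, with domains
under 400 kb merged into a neighbor. A single-scale valley detector is not
the multi-scale q-value machinery of hicFindTADs; the divergence is
accepted and documented, and the minimum TAD size matches the upstream
boundary-distance setting.

The 480-kb window bounds resolution: two boundaries closer than ~12 bins
(the window) produce merged, shallow valleys, which is where the residual
recovery misses live.

## Interaction callers

**Negative binomial candidates** (`nb_candidates()`): per distance (strata
under 200 pixels pooled into log-spaced bands), an NB is fitted to all
unmasked pixel values, zeros included — method-of-moments with a bounded
one-dimensional MLE polish of the size parameter, dispersion floored at the
Poisson limit. The candidate p-value is the NB upper tail $P(X \ge x)$;
candidates need $p < \alpha$ (default 0.05). On null matrices the candidate
fraction stays at or below the nominal level (the NB is conservative on
Poisson data).

**Neighborhood filtering and the sweep** (`neighborhood_filter()`,
`sweep_and_merge()`): within a $(2w+1)^2$ window only the candidate with the
highest value survives (ties to the smaller index), making the output an
antichain. The defaults add two *local* criteria, and this is the package's
most consequential deviation from the bare global design: a surviving
candidate must exceed 2x its neighborhood-ring mean (the window minus the
3x3 peak core), and its raw read support $x_{ij} w_i w_j$ must be
Poisson-improbable at $10^{-5}$ under the ring-mean expectation scaled by
the same weights. Without these, two measured failure modes dominate the
calls: ordinary within-TAD pixels at sparsely populated distances pass the
genome-global NB test, and 2–3-read pixels between two low-coverage bins are
scaled by $1/(w_i w_j) \approx 4$ into apparently strong balanced values
(measured precision 0.55–0.78; with the local criteria ≥ 0.9 at recall
≥ 0.8). This is deliberately *not* a donut/lower-left replica — a single
ring mean and one Poisson tail — and each criterion can be disabled. The
sweep grid defaults to candidate $\alpha \in \{10^{-4}, 10^{-5}\}$ and
windows $\{3, 5\}$, stricter than the upstream tool's 0.05 because that
tool's additional filters are out of scope here; merged calls collapse
within a 2-bin radius, keeping the smallest p.

**Weibull significant interactions** (`weibull_background()`,
`significant_interactions()`): per chromosome and distance, zeros are
removed, values above the 95th percentile are excluded (so real interactions
do not distort the background), and a Weibull is fitted to the retained
values. Two numerical corrections are applied: the fit maximizes the
*right-truncated* likelihood — a plain MLE on truncated data underestimates
the tail — and values are shifted to lattice midpoints ($x - 0.5$; balanced
Hi-C values live on a near-integer count lattice), the standard continuity
correction when a continuous family models counts. Significance is the
Weibull upper tail at $p < 10^{-4}$, no multiplicity correction (the fixed
threshold is the field convention; BH q-values are reported alongside).
Virtual-4C mode restricts the test set to one anchor bin's row.

**Calibration, honestly measured.** On null decay-only matrices the
Weibull caller's significant fraction is ~2x10^-3, about twenty times the
nominal 10^-4 even after both corrections (the naive procedure gives
~7x10^-3). Two causes, each quantified on simulations: (i) no Weibull can
carry a near-Gaussian Poisson body (short distances, mean counts 20–70) and
its super-exponential upper tail at once — a body fit at shape $k \approx
7$–10 makes 2.7σ values look like $10^{-5}$ events; (ii) the ICE edge
inflation described above mixes honestly-scaled-up pixels into every
stratum. The corresponding acceptance check is therefore expected to fail
its two-sided band, and is left failing rather than widened: the mismatch is
a property of the procedure itself on count data, not an implementation
defect. Consumers of the caller should treat the fixed $10^{-4}$ threshold
as a ranking device, not a frequency guarantee — which is how the
linkage analyses below use it.

**Distance floors for linkage.** SNP-to-gene and SE-to-gene links require
the two bins to be at least 5 bins (50 kb at 10-kb resolution) apart, and
never the same bin. Near the diagonal, contact frequency is polymer
proximity, the background fit is at its worst (see above), and a
"significant interaction" between a SNP and a promoter 20 kb away carries no
regulatory evidence that nearest-gene annotation would not; proximal
assignment is a separate, explicit annotation.

## Super-enhancers

Stitching merges peaks within 12.5 kb transitively after removing peaks
fully inside TSS ± 2.5 kb; stitched regions need more than 2 constituents.
(The promoter exclusion is occasionally quoted in kb; 2,500 *bp* is the
established value and the flank is configurable.) The SE/TE
split is the ROSE tangent rule: regions ranked ascending by total signal,
both axes rescaled to the unit square, cutoff where the curve's slope
reaches 1; everything above is SE. Consistency: every SE's signal exceeds
every TE's. Specificity across regions uses best reciprocal overlap below
0.3. The TE class is stitched non-SE regions (the alternative — unstitched
singleton peaks — would compare against elements that failed the validity
filter).

## SSIM map comparison

For equal-size O/E windows $R, Q$:
$S = l \cdot c \cdot s$ with brightness
$l = (2\mu_R\mu_Q + C_1)/(\mu_R^2 + \mu_Q^2 + C_1)$, contrast
$c = (2\sigma_R\sigma_Q + C_2)/(\sigma_R^2 + \sigma_Q^2 + C_2)$ and
structure $s = (\sigma_{RQ} + C_3)/(\sigma_R\sigma_Q + C_3)$, population
moments throughout. $S = 1$ exactly for identical windows and $|S| \le 1$
always (Cauchy–Schwarz, given positive constants). The stabilizing
constants follow the image-analysis convention $C_1 = (0.01 D)^2$,
$C_2 = (0.03 D)^2$, $C_3 = C_2/2$ with $D$ the dynamic range of the two
windows; exponents are 1. Windows of unequal bin counts are rescaled by
bilinear interpolation. The genome scan tiles 2-Mb windows every 500 kb
(25-kb maps; 4 Mb / 1 Mb for 50-kb maps), imputes masked pixels at the O/E
expectation 1, skips windows over 30% masked, and reports a z-score against
all windows of the comparison plus an empirical left-tail rank probability
(suppressed under 10 windows). The empirical rank is this package's null —
labeled as such, not claimed equivalent to any external tool's.

## Expression dynamics

Genes below 0.5 FPKM in every stage are removed. Stage profiles
(log2 of per-stage mean FPKM) are z-scored per gene and clustered with fuzzy
c-means (`e1071::cmeans`, fuzzifier $m = 2$), the algorithm underlying the
established time-course soft-clustering packages. Memberships are
row-stochastic; genes with maximal membership strictly above 0.5 are
confident members. The cluster count is user-set, with
`screen_cluster_count()` reporting the minimum pairwise centroid distance
over a candidate range (an elbow marks where real shapes start splitting) —
no single c is asserted as canonical.

## Pipeline and scoring

`run_pipeline()` wires the stages in dependency order from one config (list
or YAML), carries a manifest (config hash, package version, seed,
per-stage record counts), and is byte-reproducible for fixed config.
`score_against_truth()` measures boundary recovery at ±1 bin, loop
precision/recall at 2-bin anchor tolerance, compartment label agreement,
and SNP-link precision/recall — counting only *recoverable* intended links,
i.e. those whose anchor bins survived masking, the same convention as
excluding unscorable chromosome ends from boundary recall.

Problem sizes used by the validation suite: 20-Mb chromosomes at 10, 40 and
100 kb (2,000 / 500 / 200 bins) for the end-to-end recovery experiments,
8-Mb chromosomes for module-level tests, with recovery rates pooled over
several independently seeded layouts wherever the per-layout rate is itself
stochastic (the planted cross-TAD fraction, switch-block placement). These
sizes keep every experiment comfortably reproducible on a laptop while
leaving enough planted features (≈25 boundaries, ≈70 loops, 6 SEs, 15
intended SNP links per layout) for rate estimates with usable error bars.

## Known limitations

* The Weibull caller's absolute error rate is not nominal (see above); its
  output is a ranked shortlist.
* Cross-domain loops (~10% of planted truth) are systematically missed by
  any genome-global background; recall bounds reflect that.
* A 480-kb insulation window cannot separate boundaries closer than the
  window.
* The SSIM significance is an empirical within-comparison rank, useful for
  flagging outlier windows, not a calibrated genome-wide p-value.
* The generator's Poisson counts have no overdispersion by default, making
  NB-based calibration checks conservative by construction.
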