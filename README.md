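# neurohic

Developing brain tissue undergoes sweeping reorganization of its 3D genome:
megabase-scale A/B compartments switch activity state, topologically
associating domains (TADs) sharpen, and focal chromatin loops wire distal
enhancers and disease-associated variants to the promoters they regulate.
Studies that profile this with deep in-situ Hi-C (plus H3K27ac/CTCF
ChIP-seq and RNA-seq) all lean on the same analysis stack, usually spread
across a dozen disconnected tools. **neurohic** implements that stack as
one tested R package, for analysts who want the pipeline's every step —
and its failure modes — inspectable in a single place:

* sparse contact-matrix I/O, bin masking, **ICE balancing**, expected-by-
  distance and **O/E normalization**, correlation matrices;
* **A/B compartments** — eigenvectors of the O/E correlation matrix,
  automated selection/orientation against gene density, switch classes,
  per-bin ANOVA dynamics across developmental stages, saddle-plot
  compartment strength;
* **insulation scores and TADs** — sliding 480-kb square, IQR-trimmed mean,
  log2 normalization, valley detection, differential insulation, CTCF
  meta-profiles;
* **interaction calling** — distance-stratified negative-binomial loop
  candidates with neighborhood filtering and a parameter sweep, and
  Weibull-background significant interactions (with virtual-4C mode);
* **super-enhancers** — ROSE-style stitching, tangent-rule SE/TE split,
  specificity, SE-gene linkage, SE-SE cis/trans interaction enrichment;
* **SSIM** (structural similarity) comparison of contact maps over sliding
  windows, with dissimilar-region calls;
* **GWAS SNP-to-gene linkage** through significant promoter interactions,
  with LD expansion and multi-disorder set operations;
* **time-course expression**: FPKM filtering and fuzzy c-means soft
  clustering of stage trajectories.

Everything is validated against a first-class **synthetic-data generator**
(`synthetic_spec()`, `generate_hic()`, …) that plants compartments, TADs,
loops, super-enhancers, expression drivers and SNP links with serialized
ground truth, so every caller's recall, precision and calibration are
measured, not assumed. The central quantity behind the map-comparison
module is the SSIM score

S = l·c·s,  l = (2 μ_R μ_Q + C1)/(μ_R² + μ_Q² + C1),
            c = (2 σ_R σ_Q + C2)/(σ_R² + σ_Q² + C2),
            s = (σ_RQ + C3)/(σ_R σ_Q + C3),

which is exactly 1 for identical O/E windows and bounded by 1 in magnitude.

## Worked example

Simulate a 20-Mb chromosome at 10-kb resolution, run the full pipeline, and
score the calls against the planted truth:

```r
library(neurohic)
res <- run_pipeline(list(seed = 42, spec = list(resolution = 1e4)))
str(res$scorecard)
#> List of 7
#>  $ boundary_recall      : num 0.955
#>  $ boundary_precision   : num 0.955
#>  $ loop_recall          : num 0.829
#>  $ loop_precision       : num 1
#>  $ compartment_agreement: num 0.999
#>  $ snplink_recall       : num 0.857
#>  $ snplink_precision    : num 0.75
```

21 of 22 planted TAD boundaries are recovered within one bin with one false
call; every called loop is a planted loop and 83% of planted loops are
found (the misses are mostly the ~10% of loops planted across a TAD
boundary, invisible to a genome-global background); compartment labels
match the planted signs on 99.9% of bins; 6 of 7 recoverable SNP→gene links
are found. Individual stages are ordinary functions:

```r
spec <- synthetic_spec(seed = 42)          # 20 Mb at 40 kb
sim  <- generate_hic(spec)
bal  <- ice_balance(mask_low_coverage(sim$matrix))
prof <- detect_boundaries(normalize_insulation(
          insulation_score(observed_over_expected(bal))))
prof
#> <insulation_profile> 500 bins, window 12 bins, 467 scored, 22 boundaries

comp <- call_compartments(bal, generate_tracks(sim$truth)$gene_density)
comp
#> <compartment_profile> PC1 selected (|r|=0.31 with gene density): 281 A / 207 B bins
```

The methods vignette (`vignettes/methods.Rmd`) documents the models, every
default that matters, and the measured limitations — including why the
Weibull significance caller's fixed 1e-4 threshold should be read as a
ranking device rather than a frequency guarantee.

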