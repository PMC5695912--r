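---
title: "Detecting training-induced co-expression rewiring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting training-induced co-expression rewiring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coRewire` analyses paired two-condition expression studies — each subject
measured once before ("pre") and once after ("post") an intervention such
as endurance training — for changes in the *correlation structure* of gene
expression, as opposed to changes in mean expression. This vignette is the
package's account of the statistical machinery: the model behind each
stage, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where more than one defensible option
existed.

## The differential co-expression model

The observation unit is a `PairedExpressionSet`: a genes × samples matrix
of log2 expression with every subject contributing exactly one sample per
condition. All correlations are computed across subjects within one
condition, with columns aligned on subjects, so permutation schemes that
respect the pairing are well defined.

For gene pair (i, j), let `c1_ij` and `c2_ij` be the Pearson correlations
in the pre and post condition. The differential adjacency is

```
a_ij = (|c1_ij - c2_ij| / 2)^beta .
```

Dividing by two maps the largest possible change (+1 to −1) onto adjacency
1; the exponent `beta` soft-thresholds noise-level changes. The adjacency
is *unsigned*: a pair that gains correlation and a pair that loses it are
treated alike, because the target of the analysis is the magnitude of
rewiring, not its direction. A signed variant is deliberately out of
scope.

**Assumptions.** Pearson correlation on log2 expression is an adequate
dependence measure (Spearman is available via `method = "spearman"` for
heavy-tailed data); subjects are exchangeable within condition; the two
conditions have equal sample size by design (pairing).

### Parameters

| parameter | default | role |
|---|---|---|
| `beta` | 6 | soft-threshold exponent on the half correlation change (dimensionless). 6 is the customary middle of the 1–10 range used for unsigned WGCNA-family networks: small enough not to erase genuine intermediate rewiring, large enough that null-level changes (≈ 0.1–0.2 at n = 40) are suppressed by two to three orders of magnitude. |
| `min_module_size` | 10 | smallest reported module, matching the convention of treating only clusters of more than ~10 genes as interpretable units for enrichment. |
| `cut_fraction` | 0.99 | position of the adaptive tree cut within the dendrogram's merge-height range (below). |
| `n_perm` | 999 | gene-pair permutation count; the attainable p floor is `1/(n_perm+1)`. |
| `n_random` | 1000 | random cluster sets for the dispersion null. |
| FDR thresholds | 1% (pairs), 10% (module edges), 5% (SAM), 10% (enrichment), 5% (seed correlations) | the conventional operating points of each stage. |

### Module detection and the adaptive cut

Differential TOM values are numerically small (for `beta = 6` a strong
rewiring of Δc = 1.2 gives `a ≈ 0.05`), so all dissimilarities `1 − T`
crowd into a narrow band just below 1 and no *fixed* cut height separates
anything. Dedicated dynamic tree-cut algorithms solve this by analysing
the dendrogram shape; `coRewire` uses the simplest member of that family:
the tree is cut at

```
h = min(height) + cut_fraction * (max(height) - min(height)),
```

i.e. branches joining in the top `(1 - cut_fraction)` stretch of the
merge-height range are separated, whatever the absolute TOM scale.
Clusters smaller than `min_module_size` are left unassigned (label 0). A
degenerate tree — all merges at one height, as for an all-zero TOM — yields
no modules rather than one all-gene module. A fixed absolute `cut_height`
can be supplied for full control. Lowering `cut_fraction` splits more
aggressively, playing the role of a deeper "split sensitivity" setting.

### The paired permutation null for gene pairs

The null hypothesis for a gene pair is *no change in correlation between
conditions*. It is simulated by independently swapping each subject's
pre/post condition assignment with probability one half — a sign-flip-style
scheme that preserves the paired design and each subject's two samples.
The two correlation matrices are recomputed on the flipped data and the
statistic `|c1 − c2|` collected; `p = (1 + #{null ≥ obs}) / (n_perm + 1)`,
so p is never zero and is exact under exchangeability. BH correction runs
across all tested within-module pairs. With `n_perm` permutations and `P`
tested pairs, no pair can reach FDR `alpha` unless
`P / (n_perm + 1) ≤ alpha`; the implementation warns when `n_perm < 99`,
and analyses at FDR 1% over hundreds of pairs should use `n_perm ≥ 999`.

Genes that lose all their within-module edges are, by default, dropped
from the module (`drop_genes = TRUE`); whether the original procedure
removed genes or only edges is ambiguous, so the edge-only behavior
remains available.

### Module dispersion and its size-matched null

The module-level statistic is the root-mean-square half change over the
gene pairs connecting two modules (unordered within-module pairs for a
module against itself). Its null scale depends strongly on the module
sizes — smaller blocks average fewer pairs and fluctuate more — so the null
is built from 1,000 random partitions *with the same multiset of module
sizes*, genes drawn without replacement from the analysed universe, and
each observed pair is compared only with null values of the same
(unordered) size pair. A pooled null (all sizes together) is available via
`null = "pooled"` but is anti-conservative for small modules.

## Paired SAM-style differential expression

The per-gene statistic is `d = r / (s + s0)` with `r` the mean paired
difference, `s` its standard error and `s0` a fudge factor that prevents
genes with tiny variance from dominating. This is a deliberate
simplification of the original SAM machinery: permutation p-values plus BH
replace the delta-table/median-FDR construction, because an FDR threshold
is all the downstream analysis consumes, and BH is the correction used
everywhere else in the pipeline. The default `s0` rule follows the common
SAM heuristic: among candidate percentiles (5% steps) of the `s`
distribution, pick the one minimising the coefficient of variation of
`mad(d)` across ~10 quantile bins of `s`. A `"median"` rule and a fixed
numeric value are available; `s0 = 0` reduces `d` exactly to the classical
paired t statistic, which is the oracle the tests compare against. The
null flips the sign of each subject's difference vector — the exact
permutation group of a paired design.

## Enrichment

Over-representation uses the upper-tail hypergeometric test with the
**measured genes** as universe (enrichment against the genome would
conflate detection with biology); sets with fewer than `min_set = 5`
in-universe members are skipped; `q ≤ 0.10` is called enriched (boundary
inclusive). The ranked statistic is the weighted Kolmogorov–Smirnov
running sum (hit increments `|score|^w` normalised over hits, miss
decrements `1/(N − |S|)`), `w = 1` by default and `w = 0` for the
classical KS form; the leading edge is the hits at or before a positive
extremum (at or after a negative one); significance is by random sets of
the same size. Gene-set collections are flat: no GO-graph ancestry or
redundancy pruning.

## The integration graph

Candidate regulators acquire two kinds of edges, both FDR 10%:

* **pathway edges** — enrichment of the regulator's significantly rewired
  neighborhood (genes whose pairwise differential co-expression with the
  regulator passes the paired-permutation FDR) in each gene set;
* **phenotype edges** — ordinary least squares of the training-induced
  phenotype change on *baseline* expression of the regulator, two-sided
  slope p, BH across the full (regulator × phenotype) grid.

The response is the raw delta (post − pre) by default; percent change is a
flag. Delta was chosen as the minimal reading of "effect of training on
the physiological variable"; a percent response changes the error model,
not the procedure. The merged graph keeps one edge per node pair (best q)
and node degree — with a deterministic name tie-break — ranks regulators.
For condition-specific seed networks, per-gene correlation significance
uses the exact t transform `t = r sqrt((n−2)/(1−r²))` rather than
Fisher's z: at n = 40 the t form is exact under normality while z is
asymptotic. Note an FDR-threshold subtlety: "fraction of genes significant
at FDR 5%" under a global null is near zero (that is what FDR control
means); the ~5% figure applies to the per-gene p ≤ 0.05 fraction.

Permutation nulls for regulator scores are computed for all permutations
in one set of matrix products by decomposing every moment of a flipped
condition into its pre and post parts — a pure reformulation of the loop,
verified equivalent in tests, that makes 999 permutations on 2,000 genes
take well under a second.

## Capillary morphometry

Domains are computed *exactly*: each capillary's cell is the region
polygon clipped by the perpendicular-bisector half-planes against every
other capillary (Sutherland–Hodgman). Areas therefore sum to the region
area by construction (the tests assert relative error < 1e−6, which is
floating-point noise, and agreement with a 1000×1000 nearest-neighbor
rasterisation oracle). Edge effects are handled by clipping to the
supplied region boundary — boundary cells are truncated, not discarded —
and capillaries exactly on the boundary are included. logSD uses the
natural log (the base is a pure rescaling; it is recorded in the output
metadata), with the sample (n−1) standard deviation. Degenerate
(zero-area) fiber polygons are excluded with a warning; duplicate
capillary points are an error because they make the tessellation
ill-defined.

## The synthetic-data generator

The generator emulates the structure the pipeline is designed to detect,
with exact planted targets:

* **modules** — each module's genes load `sqrt(rho)` on one latent factor
  per subject *per condition* (independent across conditions), plus
  `sqrt(1−rho)` independent noise, so the expected within-condition
  pairwise correlation is exactly `rho`; rewiring is `rho_pre ≠ rho_post`.
  The default design plants 5 rewired modules of 30 genes
  (`0.7 → 0`) among 2,000 genes for 40 subjects. A negative within-module
  target is realised with alternating sign loadings (pairwise |corr| =
  |rho|, mixed signs), since a single factor cannot make all pairs of more
  than two genes negatively correlated.
* **hub regulator** — a hub gene and 30 neighbors correlated `0.6` before
  training and `−0.6` after (sign-flip rewiring, `hub_corr_post =
  -hub_corr`). The sign flip is the canonical strong rewiring: with 2,000
  genes, a neighborhood that merely *loses* correlation (0.6 → 0) is
  selectable by FDR only marginally, because BH over ~2,000 scores needs
  most neighbors at the permutation floor. The planted default should be
  comfortably inside the method's detection region, and the sign flip is.
* **coupled modules** — two modules can share a latent factor whose sign
  flips between conditions, planting an inter-module dispersion edge.
* **phenotypes** — per-subject delta = Σ coeff × baseline expression of
  driver genes + Gaussian noise; `post = pre + delta`.
* **gene sets** — copies of the planted modules and hub neighborhood plus
  decoys drawn uniformly from background genes.

What it does **not** emulate: probe-level artifacts, batch effects,
platform noise models, missing values, correlated background structure,
or mean-expression shifts coupled to rewiring. Passing tests therefore
demonstrate that the statistics are calibrated and the planted structure
recoverable under a clean factor model — not that any particular biological
dataset has detectable rewiring.

In the seed-network contrast experiment (a post-only neighborhood, the
qualitative pre/post degree asymmetry), the planted neighborhood
correlation is 0.7: at n = 40 that puts the per-gene correlation t near 6,
so that within-condition detection operates away from the FDR-5% borderline
and the contrast measures the design rather than detection noise.

## Numerical choices and degenerate inputs

* Permutation p-values use the `+1` correction; p = 0 is impossible.
* Quantile normalization (via limma) resolves ties by the mean of tied
  target quantiles; a single-column matrix is returned unchanged with a
  warning; the transform is idempotent on tie-free data.
* Zero-variance genes are an error in correlation stages (named in the
  message) and in SAM only when `s0 = 0`.
* `r = ±1` in seed-gene correlation gets the minimum representable p with
  a warning instead of an infinite t.
* hclust average-linkage heights are forced monotone (`cummax`) before
  cutting; average linkage is mathematically monotone and any violation is
  rounding noise.
* Missing values are rejected at load time, never imputed.
* All stochastic stages take explicit integer seeds; identical seeds give
  bit-identical output, which the manifest-driven pipeline reruns verify.

## Problem sizes used by the test-suite

Unit tests run on small instances (tens of genes); oracle comparisons use
8×8 TOMs, universes ≤ 12 for exhaustive hypergeometric enumeration, and
1,000 random BH vectors. Calibration and recovery experiments use the
package's default study scale — 1,000–2,000 genes, 40 subjects, 20
replicate seeds — which keeps the full suite and the acceptance script
each within a few minutes on one CPU while leaving the per-seed power of
every planted effect high. These sizes are the package's validation
design, chosen to match the default synthetic study conditions.

## Known limitations

* The adaptive height cut is a deliberately simple stand-in for the full
  dynamic tree-cut family; deeply nested module structure may need manual
  `cut_height` tuning.
* The unsigned adjacency cannot distinguish gained from lost correlation.
* The Voronoi clipper assumes a simple region polygon; strongly
  non-convex regions are handled set-wise (cells may be split across the
  concavity) but have not been exercised beyond rectangles in tests.
* ORA and ranked enrichment share one interface but answer slightly
  different questions; the default (ORA on the FDR-selected list) follows
  the "over-represented pathways" reading of the integration step.
* The pair filter's FDR resolution is bounded by `n_perm`; the module
  count and memory grow with the square of the number of *module* genes,
  so very large modules (> ~10³ genes) need a larger machine.
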