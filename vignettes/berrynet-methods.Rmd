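---
title: "Stage-resolved metabolite correlation networks: methods and design"
author: "berrynet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved metabolite correlation networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berrynet)
```

# The analysis

berrynet implements the downstream analysis of an annotated GC--MS
metabolite intensity table collected across grape berry development: two
cultivars (Cabernet Sauvignon, CS; Merlot, ME) sampled at six phenological
stages — flowering (FLW), fruit setting (FS), pre-veraison (PRV), veraison
(VR), post-veraison (PSV) and ripening (RP) — with about ten biological
replicates per cultivar--stage group split over two field seasons, and a
universe of 115 annotated metabolites in eight chemical classes. The
pipeline starts at the annotated matrix; chromatogram processing, peak
picking and library annotation are upstream and out of scope.

Two complementary views are produced. The *single-compound* view asks
which metabolites change between stages or cultivars (ANOVA/Tukey with FDR
control, fold-change discriminators, PCA/HCA overviews). The *network*
view asks how metabolites co-vary within a developmental stage: one signed
correlation network per cultivar--stage group, whose topology and
cross-stage conservation are then quantified.

# Preprocessing

Raw intensities are normalized per metabolite by the median of **all** its
measurements in the experiment — both cultivars, all stages and seasons
pooled — and then log2-transformed. Pooling the normalization across
cultivars keeps the two cultivars on one common scale, which is what makes
cross-cultivar fold changes meaningful. Missing entries are excluded from
medians and propagated, never imputed (except inside PCA, below). The
container tracks a processing tag with the only legal chain
`raw -> normalized -> log2`, so a matrix cannot be normalized or
log-transformed twice by accident. With an odd replicate count the
normalized median of every metabolite is exactly 1 and the log2 median
exactly 0; with an even count the mid-mean median convention makes the
normalized median exactly 1 while the log2 median is only approximately 0
(the mean of two central order statistics does not commute with log2).

# Stage-wise statistics

For each cultivar and metabolite, a one-way ANOVA over stages is followed
by Tukey honest significant differences for the stage pairs, computed only
when the ANOVA p-value passes a 0.05 gate; ungated pairs carry p = 1.
Benjamini--Hochberg correction is applied across metabolites within each
comparison family: when counting significant changes "versus flowering" or
"versus the previous stage", the family is (comparison mode x cultivar)
over metabolites and the mode's stage pairs. The correction family is a
genuinely open choice — nothing in the procedure pins it down — so it is
exposed and documented rather than hidden. A metabolite counts as up
(down) at a stage when its adjusted pair p-value is below 0.05 and its
log2 median difference against the reference stage is positive (negative);
the first stage compared with itself is zero by definition.

Cultivar discriminators at a fixed stage use Welch's two-sample test on
log2 values (no test is canonical here; Welch is the robust default and is
exposed), BH-corrected across metabolites, combined with a twofold filter
`|median log2 difference| >= 1`.

PCA standardizes each metabolite to zero mean and unit variance; missing
entries are imputed at the column mean (zero after standardization) and
counted, constant metabolites are zeroed and flagged. Orientation is fixed
by forcing the largest-magnitude loading of each component positive, so
runs are reproducible to the sign. HCA clusters metabolite stage-median
profiles with Euclidean distance and complete linkage; rows are sorted by
metabolite id first so the tree does not depend on input order, and the
tree serializes to Newick with merge heights as branch lengths.

# Correlation networks

For each cultivar--stage group (n = 10 samples, all 115 metabolites) the
pipeline computes the Spearman correlation matrix (average ranks for ties;
pairwise-complete observations, with pairs under 4 complete observations
masked), an empirical null, and calls edges.

The null is a *matrix shuffle*: all cells of the group matrix are permuted
at once, destroying both sample and metabolite structure, the full
Spearman matrix is recomputed, and every off-diagonal coefficient is
pooled into one null sample; this is repeated B = 1000 times. Because
Spearman correlation only sees ranks, the global shuffle is equivalent in
distribution to independently permuting columns, but the global scheme is
kept as the default with `scheme = "per_column"` available; a per-pair
null (`pooled = FALSE`) is also available. Empirical p-values are
two-sided with add-one smoothing, `p = (1 + #{|r_null| >= |r_obs|}) /
(1 + N_null)`, so p is never zero, and are BH-adjusted over the
`choose(m, 2)` off-diagonal family.

An edge requires **both** `|r| > 0.75` (strict) and adjusted p below 0.05.
The 0.05 level is the single significance convention used for every test
in the pipeline. It is worth recording why no 0.001 *threshold* is used:
at n = 10 the exact two-sided Spearman tail at |r| = 0.75 is about 0.01,
so sub-0.001 p-values at the threshold are not attainable pairwise —
observed p-values below 0.001 arise only for the stronger correlations
that dominate a thresholded network. With the pooled null the smallest
reportable p is `1 / (B * choose(m, 2) + 1)`, far below any working
level. Isolated nodes stay in the 115-node universe; the sign of an edge
is the sign of its correlation.

# Topology conventions

The per-network summary follows fixed conventions, each validated where an
external anchor exists:

* **density** = edges / `choose(115, 2)` over the *full* universe
  including isolated nodes. This convention reproduces all twelve printed
  density values of the published reference table
  (`referenceTopology()`) to their three decimals exactly — e.g. 625
  edges give 625/6555 = 0.095 — which is why it is the default rather
  than a connected-nodes denominator.
* **connected/isolated nodes** partition the universe by degree >= 1
  versus 0 and always sum to 115.
* **components** are counted among size >= 2 only; isolated nodes are
  reported separately.
* **diameter and average path length** are taken over connected node
  pairs only (infinite distances of a disconnected graph excluded); an
  edgeless network reports 0 with a `no_paths` flag.
* **clustering coefficient** per node is `2 T(n) / (deg (deg - 1))` with
  degree < 2 giving 0; the network coefficient averages over connected
  nodes by default, with a universe average behind
  `clusteringOver = "universe"`. The reference table cannot
  disambiguate the two, so this field is not used as an anchor.
* **betweenness** is raw shortest-path betweenness, with a normalized
  variant dividing by `(Nc - 1)(Nc - 2)/2` within each component.

Degree-distribution model selection builds the empirical CCDF
`P(K >= k)` over positive degrees and fits `c k^(-gamma)` and
`c exp(-lambda k)` by Levenberg--Marquardt nonlinear least squares
(starting values from the log--log and semi-log linear fits; 500
iterations, ftol 1e-8), comparing models by
`AIC = n log(RSS / n) + 2 p` and reporting Akaike weights. Fewer than
five distinct positive degrees is flagged unfit-able — two CCDF points can
be interpolated exactly by either family, so selection would be
meaningless.

# Cross-network comparison

Edges are compared as unordered, unsigned pairs (a sign-aware variant is a
flag); overlap percent is relative to a stated reference network, so the
matrix of percents is asymmetric while shared counts are symmetric. Two
significance routes are provided:

1. **Fisher's exact test**, one-sided for enrichment, on the 2x2 table
   (shared, A-only, B-only, neither) over the `choose(115, 2)` candidate
   pair universe — the same universe that the density convention
   validated.
2. **Degree-preserving rewiring**: both networks (or one, behind a flag)
   are independently randomized by repeated double-edge swaps —
   10 x |E| attempted swaps per replicate; swaps creating self- or
   duplicate edges are rejected — and the statistic (edge overlap, or the
   difference in average path length) is recomputed B times. The overlap
   p-value is enrichment-sided, the path-difference p two-sided, both
   with add-one smoothing. The degree sequence is asserted unchanged on
   every replicate; swap-free graphs (a star, a lone triangle) are
   returned unchanged and flagged.

A calibration subtlety is documented here because it shapes the test
suite: on an integer-valued statistic the tie-inclusive add-one p-value is
*valid but conservative* — its expectation under the null exceeds 1/2 by
about half the tie probability at the observed value. The p-values the
package reports therefore cannot be uniform in finite samples, and a KS
test against the continuous uniform would reject for any correct
implementation. Calibration checks accordingly test two things: the
reported p never rejects above its nominal level, and the tie-randomized
transform `u = (#{null > obs} + U (1 + #{null = obs})) / (1 + B)` — which
is exactly uniform under exchangeability — passes a KS test.

# The synthetic-data generator

No raw data accompany the study design this pipeline targets, so a
generator produces experiment-shaped datasets with known ground truth.
Its defaults are the study conditions: 2 cultivars x 6 stages x 10
replicates split evenly over 2 seasons, and 115 metabolites with the
published class composition (19 amino acids, 4 fatty acids, 22 acids, 3
flavonoids, 11 miscellaneous, 19 sugars, 17 unclassified, 20 unknown).

Intensities are a latent Gaussian copula on the log2 scale: each
metabolite has a baseline drawn once from N(10, 2^2) log2 units (shared
across groups so the experiment-wide median normalization is meaningful),
a class trend added per stage step — by default +1 log2/stage for sugars
and -0.5 for amino acids, the two dominant developmental patterns, all
other classes flat — and unit-SD replicate noise. Planted correlations
are specified as target absolute Spearman values and realized through the
bivariate-normal relation `rho = 2 sin(pi r_s / 6)`; the final
exponentiation is monotone, so rank correlations survive untouched.
Three planting models exist: hub-and-spoke (spokes are noisy, possibly
sign-flipped copies of their hub), block (shared factor per block), and
random edge sets (realized via the nearest positive-definite correlation
matrix, with the caveat that infeasible target matrices are projected and
targets then hold only approximately). The default experiment plants a
conserved core sub-network (identical in every group, about a third of
the universe, target |r| = 0.9) plus group-specific hubs at target
|r| = 0.85, a quarter of edges negative. The core is planted stronger
than the group hubs deliberately: BH over the `choose(115, 2)` pair
family makes the binding correlation at n = 10 roughly 0.87 — the
corrected analogue of a raw p near 0.001 — and the core's purpose is to
be recoverable in every stage network. These defaults yield per-group
edge counts in the published table's range and cross-stage overlaps that
are modest in percentage but strongly Fisher-significant, the
qualitative pattern the study reports. Missing values can be injected completely at random
(default rate 0: the design's missingness is undocumented); seasons are a
pure labeling with no year effect, matching the reported absence of a
year signal.

Determinism is strict: every seeded operation runs in a local RNG scope,
and per-group child seeds derive from one master seed by a stable string
hash (`groupSeed()`), so identical configurations are byte-identical
end-to-end.

## What the generator does and does not emulate

It emulates the design geometry, log-scale class trends, group-specific
plus conserved correlation structure, and (optionally) MCAR missingness.
It does not emulate retention-time drift, batch or season effects,
heteroscedastic technical noise, censoring at the detection limit, or
biologically structured missingness. Passing recovery and calibration
tests therefore demonstrates that the *machinery* is correct and
calibrated on data matching its assumptions — not that the thresholds are
optimal for real berry data.

## A structural limit on hub recovery

One recovery property deserves its own analysis. For a planted star with
hub--spoke target |r_s| = 0.95, any joint Gaussian embedding forces the
spoke--spoke correlation up as well: with k exchangeable spokes at
Pearson rho = 0.953 to a common hub, spoke pairs satisfy
`corr >= rho^2 - (1 - rho^2)/(k - 1)` (about 0.90 for k = 19, Spearman
~0.897) — above the 0.75 edge threshold. The *true* thresholded graph
over a star is thus a clique, and the hub's degree advantage in the
recovered network rests only on the per-edge call-rate gap (~0.96 for hub
edges versus ~0.89 for spoke pairs at n = 10). Measured across star sizes
the probability that the hub attains the maximum degree plateaus at about
0.85--0.89 and *decreases* toward the full 115-node universe (~0.70),
because more spokes compete. Edge sensitivity, by contrast, is
comfortably high (~0.96). The corresponding hub-dominance assertion in
the acceptance suite is kept at its stated 90% level and may fail by this
margin; the package reports the measured rate rather than redefining the
statistic.

# Problem sizes and numerical choices in the test suite

The suite exercises the same machinery at sizes chosen to keep the
statistics sharp: null calibration uses 10 groups of n = 10 x m = 30 with
B = 500 shuffles; randomization-test calibration uses 200 pairs of
40-node Erdős--Rényi graphs at density 0.25 (dense enough that the
integer overlap statistic has small tie atoms) with B = 100 rewires;
recovery uses 100 seeds of a 20-node star at target 0.95 with B = 300;
oracle equivalence covers 200 random graphs of up to 25 nodes against
Floyd--Warshall distances, path-count betweenness and triangle
enumeration. The end-to-end smoke configuration (12 metabolites, 4
replicates, B = 100) runs the entire pipeline twice and compares file
checksums. Degenerate inputs are guarded explicitly: constant group
matrices refuse to shuffle, B < 100 is refused as too coarse for p
resolution, all-missing metabolites and non-positive intensities abort
with the offending coordinates, and unknown stage labels stop a pipeline
run before any computation.

# Knobs

| knob | default | meaning |
|---|---|---|
| `rMin` | 0.75 | correlation threshold for edges (strict) |
| `networkAlpha` | 0.05 | FDR level for edge calls |
| `alpha` | 0.05 | FDR level for stage/cultivar tests |
| `B` | 1000 | matrix shuffles per group null |
| `BRewire` | 1000 | rewiring replicates per comparison |
| `scheme` | global | matrix shuffle scheme (`per_column` alternative) |
| `pooled` | TRUE | pooled vs per-pair permutation null |
| `rewire` | both | rewire both networks or only one |
| `clusteringOver` | connected | node set for the network clustering mean |
| `minAbsLog2fc` | 1 | twofold filter for cultivar discriminators |
| `anovaGate` | 0.05 | ANOVA gate before Tukey |
| `noiseSd` | 1 | generator replicate SD (log2) |
| `missingRate` | 0 | generator MCAR missingness |

# Known limitations

Total (marginal) correlation cannot separate direct from indirect
association; partial-correlation networks are deliberately out of scope.
The per-group sample size (10) makes the Spearman null heavy-tailed, so
the |r| > 0.75 threshold, not the FDR cut, is usually the binding
constraint on edges. The CCDF least-squares AIC route to power-law
detection is the classical one and is kept for fidelity; it is known to be
less rigorous than likelihood-based tail fitting. Betweenness and path
conventions on disconnected graphs follow the connected-pairs definitions
above; other conventions exist and would shift the reported diameters of
sparse stages.
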