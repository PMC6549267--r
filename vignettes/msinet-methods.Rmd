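---
title: "msinet methods: from m/z-images to molecular communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{msinet methods: from m/z-images to molecular communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msinet)
```

## The model

MALDI mass spectrometry imaging produces, per selected m/z-channel, a
lateral intensity image over the measured pixels of a tissue section.
The working assumption of `msinet` is biological colocalization:
molecules participating in the same spatially bound process show
correlated lateral distributions. The package therefore analyzes the
*graph* of image correlations rather than the images in isolation, in
four computational stages plus visualization exports.

**Data model.** An `MSIDataset` stores the `N_P × N_V` intensity matrix
`D` together with 1-based integer pixel coordinates and per-channel m/z
values. Only measured pixels are stored — unmeasured grid cells are
absent rows, never zero-filled sentinels — and every similarity
computation runs on these pixel vectors, not on rendered grids, so
empty background can never inflate a correlation. Channels are assumed
pre-selected (e.g. expert-picked discriminative m/z values); peak
picking, m/z alignment and intensity normalization beyond winsorizing
are out of scope.

**Preprocessing.** Per channel, intensities above the upper quantile
(default 0.99) are clipped to it. We use the classic rank-based
winsorization bound — the inverse-ECDF (order statistic) quantile —
rather than an interpolating estimator, for a structural reason: with
the order-statistic bound the operation is *exactly* idempotent
(clipping cannot change the bound itself), which is an invariant the
test suite relies on; interpolating estimators lose idempotence because
clipping the tail shifts the interpolated quantile downward. For the
data sizes involved (thousands of pixels) the numerical difference
between estimators is far below the effect of the clipping itself.

**Similarity.** `w_ij` is the Pearson correlation of channel pixel
vectors. It is symmetric, scale-free (invariant under positive affine
rescaling of a channel, so detector gain differences are harmless), and
standard in MSI colocalization analysis. A zero-variance channel has no
lateral structure; its off-diagonal similarities are defined as 0 (with
a warning) so it becomes an isolated node instead of propagating NaNs.
Values are clamped to `[−1, 1]` against floating-point overshoot. The
`measure` argument reserves identifiers for alternative symmetric
measures (cosine, mutual information), but only Pearson is implemented.

## Threshold selection

The similarity graph is complete; the scientific content lies in which
edges are *strong*. Instead of manual tuning, the threshold is selected
by an objective built from three quantitative graph properties computed
on each candidate graph `A(t_i)`, `t_i ∈ {−1, −0.9, …, 1}`:

* `N_E` — edge count (a size baseline);
* `ζ` — average local clustering coefficient, a segregation measure;
* `ξ` — global efficiency (mean inverse shortest-path length,
  disconnected pairs contributing 0), an integration measure.

The joint use of segregation and integration mirrors the small-world
property common in biological networks: dense subgraphs, robustly
interconnected.

Two numerical interpretations deserve explicit statement:

* **Normalization before baselining.** All three raw vectors are
  min-max normalized to `[0, 1]` before the baselined vectors
  `η^ζ = ν̂^ζ − ν̂^{N_E}` and `η^ξ = ν̂^ξ − ν̂^{N_E}` are formed. `ζ`
  and `ξ` are already on `[0, 1]` scales, but raw `N_E` is unbounded;
  subtracting it meaningfully requires a common scale. A constant
  vector (e.g. every candidate yields the same graph) normalizes to all
  zeros.
* **Uncentered projection.** `y = X u_0` is computed from the
  *uncentered* `X = [η^ζ, η^ξ]`, with `u_0` the leading eigenvector of
  the covariance of the centered `X`. Centering would shift `y` by a
  constant and cannot change the argmax; the tests assert the projection
  against an independent closed-form 2×2 eigen-decomposition.

Two conventions are load-bearing:

* **Eigenvector sign.** `u_0` is oriented so its `η^ζ` component is
  nonnegative. The clustering coefficient carries more variance and
  hence more weight; with the opposite orientation the argmax would
  become an argmin and select a degenerate threshold. A test asserts
  that flipping the orientation flips the selection.
* **Tie-breaking.** The argmax over `y` frequently sits on a flat
  plateau (on the benchmark, every candidate between the last
  between-group and the first within-group similarity yields the
  identical graph, hence identical `y`). Ties resolve to the smallest
  candidate index — the lowest threshold, retaining the most edges.
  Any fixed rule on a flat plateau yields the same graph; ours is
  simply documented and deterministic.

Thresholding keeps ties: an edge survives iff `w_ij ≥ t` (only strictly
smaller similarities are dropped). Because similarity values essentially
never coincide with 0.1-grid candidates, the completed sweep also
reports the **effective minimum edge weight** — the smallest surviving
similarity, i.e. the tightest threshold producing the same graph. When
comparing against thresholds reported elsewhere at 4-decimal precision,
this is the comparable quantity, not the grid value; the package makes
no claim of reproducing any particular printed threshold for data it
does not have.

## Community detection

The leading-eigenvector modularity method proceeds divisively: a
community `c` is bipartitioned by the sign pattern (`u_i ≥ 0` vs
`u_i < 0`) of the leading eigenvector of its generalized modularity
matrix, accepted while the leading eigenvalue is positive. We use
Newman's generalized form `B^(g)_ij = A_ij − k_i k_j / 2m − δ_ij Σ_k B_ik`
with degrees and `m` from the **full** graph, the standard formulation
for in-place splits; its rows sum to zero, which is exactly what turns
"no division" into the zero-eigenvalue case.

Modifications and numerical choices:

* **Connected-component initialization.** Thresholded MSI graphs are
  routinely disconnected. Instead of starting from one all-node
  community, each connected component starts as its own community; no
  split can merge across components, and singleton components are
  immediately indivisible.
* **Stop tolerance.** The exact "λ = 0" criterion is unattainable in
  floating point; we declare a community indivisible when
  `λ_max ≤ 1e−10`. The scale is defensible because `B` entries are O(1)
  for the graphs at hand and LAPACK's symmetric solver is accurate to
  ~1e−15 relative error.
* **Degenerate splits.** If the leading eigenvector has one sign
  everywhere, the "split" would leave one side empty — the best
  division is no division; the community is marked indivisible.
  Components of `u` that are exactly zero join the `u_i ≥ 0` side.
* **Determinism.** Eigenpairs come from a dense symmetric solver
  (`eigen(symmetric = TRUE)`; `N_V` is ~100 in practice, so no
  iterative methods are warranted), and the eigenvector is
  sign-canonicalized (largest-magnitude component positive) so results
  cannot depend on solver sign conventions. Identical inputs give
  identical partitions.
* **Acceptance rule.** A split is accepted purely on `λ_max > tol`, the
  documented procedure; an optional `verifyGain` flag additionally
  requires a strict modularity increase but defaults off.
* Final community labels are contiguous integers ordered by smallest
  member index.

The summary statistic `nLarge` (communities of at least `minSize`
members) keeps its cutoff as a parameter because the two natural
readings — "multi-member" (size ≥ 2) and "size greater than two"
(size ≥ 3) — both occur in practice; the default is `minSize = 2`,
counting every (n)-community with n > 1.

## Visualization products

* **Community maps** aggregate member images per pixel: maximum
  projection (total covered area) or average (signal quantity). The
  average never exceeds the maximum pixelwise, and both share the
  union of member supports.
* **Single-mass maps** are min-max rescaled to `[0, 1]` for contrast;
  constant images map to 0.
* **PCA RGB map:** pixels are projected onto three selected principal
  components of the channel covariance (default the first three;
  selectable, e.g. components 2–4) and each projection min-max rescaled
  into one of the R, G, B channels. This is plain covariance PCA on the
  winsorized data; squared-data or thresholded-image PCA variants are
  deliberately not implemented.
* **Community graph `G′`:** communities collapse to nodes; a community
  edge exists iff any underlying edge joins members of the two
  communities. Expanding a community materializes its m/z-nodes and
  intra-edges; its cross-edges become *hybrid* edges (m/z-node to
  collapsed community node) or plain m/z-edges when both ends are
  expanded. The JSON export (`msinet-viewer/1`, validated against the
  shipped schema) carries this graph, member m/z lists, and references
  to PNG community maps; colorization is a viewer concern, exports
  carry raw values.

## The synthetic benchmark

`generateBenchmark()` emulates the structural essentials of a
colocalization experiment: nine m/z-images on a fully measured
205 × 190 grid, each a localized rotated anisotropic 2-D Gaussian, in
three groups of three sharing a location, with every pair of group
footprints overlapping. Distortion per channel: center jitter uniform
in ±5 px per axis, x- and y-sigma independently scaled by `1 ± 0.1`,
rotation uniform in `[0, π)`. Defaults chosen once as a realistic
instance of that qualitative description:

| parameter | default | rationale |
|---|---|---|
| `baseSigma` | 22 px | footprint (~3σ ≈ 66 px) localized but non-trivial on a 205 × 190 grid |
| amplitudes | 1.0, 1.1, 1.2 per group | "slightly different amplitude"; irrelevant to Pearson similarity by scale-invariance |
| `positionJitter` | 5 px | small versus `baseSigma`, so group membership stays visually obvious |
| `sigmaJitterFrac` | 0.1 | mild shape distortion of x and y sizes |
| group centers | equilateral triangle, side `2.2 · baseSigma`, grid-centered | all three pairwise overlaps occur |
| `noiseSd` | 0 | the benchmark isolates the geometry; additive noise is available but off |

All draws are consumed in a fixed documented order from a single seeded
generator (the caller's RNG state is restored afterwards), so the cube
is bit-reproducible.

What the benchmark does **not** emulate: mass spectra, isotope
patterns, detector noise, spatial intensity artifacts, partial tissue
coverage, or the hundreds of channels of a real experiment. Passing the
recovery tests therefore demonstrates the pipeline's correctness on
cleanly separated colocalization structure — it does not certify
performance on real tissue, where similarity distributions are broader
and communities overlap.

On this construction, within-group correlations (~0.9 and above, groups
sharing a jittered center) separate cleanly from between-group
correlations (overlapping but offset footprints), so the sweep's argmax
plateau covers the thresholds at which exactly the nine within-group
edges survive, and community detection returns the three planted
groups. The package's acceptance script measures exactly this: across
20 independently seeded cubes, the recovered-partition count and the
modal community/edge counts.

## Problem sizes and runtime choices

The unit tests run the full-size 9 × 205 × 190 benchmark where the
asserted property belongs to the default study conditions (recovery,
plateau flatness, histogram separation) and a scaled-down variant
(60 × 55 grid, `baseSigma` 7 px — same geometry rules) where any
correlated Gaussian cube suffices; brute-force oracles (triangle
enumeration, BFS distances, exhaustive partition search) run on graphs
of 6–30 nodes, where exhaustive search is exact and fast. These sizes
are the package's own testing design: large enough to exercise every
code path at full fidelity where it matters, small enough that the
whole suite stays interactive.

## Known limitations

* Pearson similarity is linear; nonlinearly related distributions
  score low. The measure interface anticipates alternatives but does
  not implement them.
* The 0.1 candidate grid bounds threshold resolution; the effective
  minimum edge weight recovers the exact graph-equivalent threshold,
  but a finer grid changes nothing on a flat plateau and costs sweep
  time elsewhere.
* The leading-eigenvector method is a heuristic: tests document that
  its modularity lands within 0.05 of the exhaustive optimum on small
  random graphs, not that it is optimal.
* imzML ingestion is an interface only (`readMSI(format = "imzml")`
  raises a clear not-implemented error); the native JSON + CSV format is
  authoritative, and external converters (e.g. pyimzML) cover the gap.
* Overlapping communities are out of scope; every m/z-image receives
  exactly one label.
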