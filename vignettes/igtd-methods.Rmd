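---
title: "Distance-rank matching for tabular-to-image transformation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-rank matching for tabular-to-image transformation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igtd)
```

## The model

Given an `M x N` table `X` (samples by features), the goal is to assign
each feature to one pixel of an `Nr x Nc` grid (`Nr * Nc = N`) so that
similar features occupy nearby pixels, and then to render each sample as a
grayscale image whose pixel intensities are the sample's feature values.

Two rank matrices drive the assignment. `R` holds the ascending ranks of
the `N(N-1)/2` pairwise feature distances, arranged symmetrically with a
zero diagonal; `Q` holds the ranks of pairwise pixel distances, computed
from integer pixel coordinates with the grid linearised row by row. Ranks,
rather than raw distances, make the two spaces commensurable: feature
distances and pixel distances live on entirely different scales, but their
orderings can be compared directly. The objective

$$\mathrm{err}(R, Q) = \sum_{i=2}^{N}\sum_{j=1}^{i-1}
  \mathrm{diff}(r_{ij}, q_{ij})$$

sums a per-entry difference (absolute by default, squared as an option
that emphasises large discrepancies) over the strict lower triangle.

The search space is the set of synchronized row/column reorderings of `R`.
Any reordering is a product of transpositions, so the optimiser works in
single feature swaps:

1. **Initialise** the iteration counter, the error `e_0`, the ordering
   `k_0 = (1, ..., N)`, and `h`, a length-`N` vector of `-Inf` recording
   when each feature was last considered.
2. **Select** `n* = argmin h` (the feature untouched the longest; ties to
   the smallest index) and find the partner `l*` maximising the error
   reduction of the swap `(n*, l*)`.
3. **Accept** the swap iff its relative reduction exceeds `t_swap`,
   updating `k`, `e`, `R`, and `h[n*] = h[l*] = s`; otherwise only
   `h[n*] = s`.
4. **Terminate** at `S_max` iterations, or when the relative error
   reduction against the error `S_con` iterations earlier stays below
   `t_con` for the whole window; return the ordering and error of the
   best (earliest, under ties) iteration.

The swap-error update is incremental: swapping features `n` and `l`
changes only rows/columns `n` and `l` of `R`, so the error delta involves
only those entries (the `(n, l)` entry itself is invariant under a
synchronized swap). The package additionally vectorises the partner search
over all `l` at once, making one iteration `O(N^2)` rather than `O(N^3)`.
Incremental deltas are exact, not approximate: a test compares them
against full recomputation on a thousand random instances.

## Assumptions and what the method can represent

The transformation presumes that feature relationships are captured by
pairwise distances — cluster structure, co-expression, descriptor
redundancy. Data with purely independent features gain nothing from any
layout; the rank-matching error then simply cannot be reduced much, which
is visible in the error trace.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `s_max` | 30000 | iteration cap (reference run on 2500-feature tables) |
| `s_con` | 500 | convergence window length (iterations) |
| `t_con` | 1e-6 | relative-reduction threshold declaring convergence |
| `t_swap` | 0 | acceptance threshold on relative error reduction |
| `diff_fn` | absolute | per-entry rank difference |
| feature metric | euclidean | also `1 - correlation`, `1 - Jaccard` (binary data) |
| pixel metric | euclidean | also manhattan |
| `p` (LH) | 3, 5, 7, 9 | odd neighbourhood side for local heterogeneity |

With `t_swap = 0` every accepted swap strictly reduces the error, so the
trace is monotone. Negative `t_swap` admits bounded uphill moves — the
method's own device for leaving local optima — at the cost of a
non-monotone trace; the reported result is always the trace minimum.
Defaults mirror the reference analysis of 50 x 50 images of
gene-expression and molecular-descriptor tables. Tests and examples in
this package use scaled-down settings (e.g. `s_max = 2000`,
`s_con = 200` for 100-feature tables), chosen because such instances
converge within a few hundred iterations; the hyper-parameters only need
to let the optimisation reach its plateau.

## Numerical and design choices

**Tie handling in ranks.** Pixel grids produce massive distance ties. Tied
distances receive their *average* rank by default, which keeps the
lower-triangle rank sum at `m(m+1)/2` (`m = N(N-1)/2`) regardless of ties
and makes `R` and `Q` equivariant under relabeling; an `ordinal`
(first-occurrence) option exists. Average ranks introduce half-integer
values, which are exactly representable in floating point, so incremental
error updates remain exact.

**Deterministic tie-breaks.** `argmin h` and the best-partner `argmax`
both resolve ties to the smallest index; the best iteration `v*` resolves
to the earliest. The optimiser draws no random numbers at all, so reruns
are byte-identical.

**Division guards.** The acceptance and convergence criteria divide by the
current error. A zero error means the layout is exact; the relative test
is then defined as "not accepted" and the run is declared converged.

**Pixel geometry.** Pixel `p` (1-based) has integer coordinates
`(ceiling(p / Nc), ((p - 1) mod Nc) + 1)`. Only relative distances enter
the ranks, so the origin convention is immaterial; it is fixed for
reproducibility.

**Normalisation.** Feature distances are ranked on the raw table by
default (an option ranks on the normalised table); rendering uses
per-feature min-max scaling across samples, so a pixel is comparable
between the images of different samples. Constant features map to 0. The
choice of which table feeds the ranking affects Euclidean distances but
not the workflow; both are exposed because the convention is a genuine
free choice.

**PNG polarity and quantisation.** Intensity maps to gray directly
(0 = black) with half-up rounding to 8 bits (max round-trip error
1/510); an `invert` flag serves renderings where small values print near
white. The full-precision array archive (`.rds` container plus manifest)
is bit-exact on re-read.

**Local heterogeneity edges.** Only full `p x p` windows enter the LH
average — exactly the summation limits of the definition; no padding. LH
is computed on normalised images so layout comparisons use identical
values.

## Local optima and the planted-layout fixture

A planted instance applies a hidden permutation to `Q` itself, so the
global optimum error is exactly 0 and recovery can be verified. Pure
descent (`t_swap = 0`) reliably recovers planted layouts only for small
feature counts: from roughly 8–16 features on, states exist in which *no*
single swap reduces the error (verified by exhaustive scans over all
pairs at stuck points), and the deterministic uphill variant
(`t_swap < 0`) cycles rather than explores, so even it does not guarantee
recovery on a 4 x 4 grid. The package's recovery tests therefore assert
exact-zero recovery on grids of up to 8 pixels (with `t_swap = -0.1`,
`s_max = 20000`), and assert the weaker, always-true bounds — final error
between the exhaustive optimum and the initial error — elsewhere. This is
a property of the algorithm, not of the implementation: single-swap
neighbourhoods simply do not connect all local optima to the global one.

## The synthetic-data generator

`generate_block_correlated_table()` emulates the clustered similarity
structure of gene-expression and descriptor tables with a factor model:
feature `f` of block `b` is
`noise_sd * (sqrt(rho) z_b + sqrt(1 - rho) eps_f)`, giving exact
within-block population correlation `rho` and independence across blocks,
in `O(MN)` time with a closed-form target for Monte-Carlo checks. Defaults
for the directional layout experiments: 200 samples, 10 blocks of 10
features, `rho = 0.9`, a 10 x 10 grid — a desk-scale stand-in for the
thousands-of-features tables of the reference analysis. What the generator
does *not* model: realistic marginal distributions (e.g. negative
binomial counts), nested or overlapping correlation blocks, outlier
features. Passing layout tests on this fixture therefore shows the
optimiser groups block-mates, not that absolute LH values on real
cell-line or drug tables are reproduced — those require the real tables
and remain directional claims here.

`generate_paired_image_response()` plants a linear signal in the mean
intensities of paired images (each image mixes a per-image brightness draw
with pixel noise so the signal dominates the response noise). It exists to
show the two-tower network *learns* — beats the mean predictor on planted
signal and does not materially beat it on pure noise — not to benchmark
accuracy.

## The two-tower network

Each tower stacks three convolution layers (square 5 x 5 kernels, valid
padding) each followed by batch normalization, ReLU, and 2 x 2
non-overlapping max pooling; tower outputs are flattened, concatenated,
and passed through a fully connected head with dropout between the dense
layers and a single linear output trained with mean squared error.

The reference filter counts and dense widths are not stated in prose
anywhere; they are pinned by two reference trainable-parameter counts:
1,307,218 for paired 50 x 50 inputs at convolution stride 1, and
2,715,218 for 227 x 387 and 380 x 387 inputs at stride 2. Two
observations narrow the search. First, the difference between the two
counts, 1,408,000 = 2^10 * 5^3 * 11, must equal (flatten-size difference)
x (first dense width); under valid-padding convolutions with 2 x 2
pooling the flatten-size difference is exactly `22 * F3` (`F3` = last
tower filter count), whose factor 11 matches — alternative paddings and
pool geometries do not produce the factor naturally. Second, a parity
argument (tower parameters are doubled, hence even; a dense chain with
all-even widths ending in a biased single output is always odd) forces at
least one odd hidden width. The package adopts towers of 32-64-64 filters
and a 1000-385-256-1 head, which reproduces both counts exactly; the
width tuple is not unique under these constraints, so all widths are
exposed as configuration and `count_trainable_parameters()` (summing every
trainable tensor; batch-norm moving statistics excluded) is the guard on
the reading.

No deep-learning framework is involved: forward and backward passes
(im2col-style per-offset matrix multiplies for convolutions, standard
batch-norm backward, argmax-routed pooling gradients, Adam) are
implemented in the package and validated against numerical
differentiation. Note one analytic subtlety the gradient check respects:
a convolution bias immediately followed by batch normalization has an
exactly zero gradient, since the normalisation subtracts the batch mean.

Smoke training uses reduced widths (8-8-8 towers, 32-16 head on 38 x 38
images — the smallest inputs that survive three valid 5 x 5 convolutions
with pooling) and a few hundred image pairs, sized for a single CPU.

## Known limitations

- The swap search is greedy and deterministic; it has genuine local
  optima (see above) and no restarts. Negative `t_swap` mitigates but
  does not remove this.
- Missing values are rejected, not imputed; imputation is upstream.
- One feature per pixel: no multi-channel stacking, no irregular image
  shapes, no 1-D or higher-dimensional targets (straightforward
  extensions, out of scope here).
- Absolute LH magnitudes depend on the intensity normalisation
  convention; comparisons between layouts of the same data are the
  meaningful quantity.
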