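# igtd

Transform tabular data into compact grayscale images for convolutional
neural networks, by assigning features to pixels so that similar features
sit on nearby pixels.

## The problem

Tabular datasets common in drug discovery — gene-expression profiles of
cancer cell lines, molecular-descriptor tables of drugs — have no spatial
arrangement of features, so convolutional networks cannot exploit their
local-connectivity and weight-sharing machinery on them. This package
implements a distance-rank matching transformation: every sample (row) of
an `M x N` table becomes an `Nr x Nc` image (`Nr * Nc = N`) in which each
pixel shows the value of one feature, and the feature-to-pixel assignment
is optimised so that feature similarity is mirrored by pixel proximity.

## The method

Let `R` be the `N x N` matrix of ascending ranks of all pairwise feature
distances (small distance, small rank; zero diagonal), and `Q` the
analogous rank matrix of pairwise pixel distances for the `Nr x Nc` grid,
pixels linearised row by row. The objective is

    err(R, Q) = sum_{i>j} diff(r_ij, q_ij)

with `diff` the absolute or squared difference, summed over the strict
lower triangle. The optimiser reorders the rows and columns of `R`
(synchronously) by iterated feature swaps: at each iteration it takes the
feature `n*` not considered for the longest time (an `h` vector of
last-considered iterations drives this round-robin), finds the partner
`l*` whose swap yields the largest error reduction — computed
incrementally, touching only the two affected rows and columns — and
accepts the swap when the relative reduction exceeds a threshold `t_swap`
(non-negative `t_swap` makes the error trace monotone; negative values
allow escapes from local optima). The run stops at `S_max` iterations or
once the relative error reduction over a window of `S_con` iterations
stays below `t_con`, and returns the ordering of the best iteration.

Layout quality is judged by local heterogeneity (LH): the mean, over all
full `p x p` windows, of the average absolute intensity difference between
the window's centre and its `p^2 - 1` neighbours. Lower LH means similar
features sit closer. The package also builds the downstream two-tower
CNN (three 5x5-kernel convolution layers with batch normalization, ReLU
and max pooling per tower; flattened, concatenated, fully connected head)
for paired cell-line/drug images, with exact trainable-parameter
accounting and a desk-scale training loop.

## Worked example

```r
library(igtd)

tab <- generate_block_correlated_table(n_samples = 200, n_blocks = 10,
                                       block_size = 10,
                                       within_block_correlation = 0.9,
                                       seed = 7)
r   <- feature_rank_matrix(tab)
q   <- pixel_rank_matrix(image_grid(10, 10))
res <- igtd_optimize(r, q, igtd_config(s_max = 2000, s_con = 200,
                                       t_con = 1e-6, t_swap = 0))
res
#> igtd_result: 100 features; 585 iterations; converged
#>   error: 7197112 -> 4261855 (40.8% reduction)

ord  <- feature_ordering(res$ordering, image_grid(10, 10))
imgs <- render_images(normalize_features(tab), ord)

set.seed(1)
rand <- render_images(normalize_features(tab),
                      feature_ordering(sample(100), image_grid(10, 10)))
layout_lh_summary(imgs, c(3, 5), reference = rand)
#>   p lh_mean  lh_sd ref_lh_mean ref_lh_sd reduction_pct_mean reduction_pct_sd  p_value
#> 1 3   0.146 0.0271       0.198    0.0420               25.2             9.31 2.94e-70
#> 2 5   0.172 0.0381       0.198    0.0432               12.4            11.82 8.84e-32
```

The optimiser cuts the rank-matching error by ~41% and the optimised
layout reduces mean local heterogeneity at `p = 3` by ~25% relative to a
random layout of the same data: similar (block-correlated) features have
been pulled onto neighbouring pixels. `run_pipeline()` wraps the whole
workflow (selection/padding, ranking, optimisation, rendering, PNG or
array export, LH summary, manifest JSON), and a command-line front end
ships in `inst/cli/igtd.R` with `transform`, `metrics`, `synth` and
`cnn-smoke` subcommands.

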