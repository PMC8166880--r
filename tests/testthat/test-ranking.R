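test_that("feature rank matrix matches hand-computed distances", {
  # columns [0,0], [1,1], [3,3]: d12 = sqrt(2) < d23 = 2*sqrt(2) < d13 = 3*sqrt(2)
  x <- igtd_table(cbind(a = c(0, 0), b = c(1, 1), c = c(3, 3)))
  r <- feature_rank_matrix(x)
  expect_equal(r[2, 1], 1)
  expect_equal(r[3, 1], 3)
  expect_equal(r[3, 2], 2)
  expect_equal(r, t(r))
  expect_true(all(diag(r) == 0))
})

test_that("duplicated feature columns receive the smallest rank", {
  set.seed(5)
  x <- matrix(rnorm(4 * 5), 4, 5)
  x[, 5] <- x[, 2]
  r <- feature_rank_matrix(igtd_table(x))
  expect_equal(r[5, 2], min(r[lower.tri(r)]))
})

test_that("constant features raise an informative error under 1 - rho", {
  x <- igtd_table(cbind(f_ok = c(1, 2, 3), f_const = c(4, 4, 4),
                        f_ok2 = c(2, 0, 1)))
  expect_error(
    feature_rank_matrix(x, distance_spec(feature_metric = "one_minus_correlation")),
    "f_const")
})

test_that("jaccard ranking requires binary values and matches 1 - index", {
  xb <- igtd_table(cbind(a = c(1, 1, 0, 0), b = c(1, 0, 0, 0),
                         c = c(0, 0, 1, 1)))
  r <- feature_rank_matrix(xb, distance_spec(feature_metric = "one_minus_jaccard"))
  # d(a,b) = 1 - 1/2 = 0.5; d(a,c) = 1; d(b,c) = 1 -> ranks 1, 2.5, 2.5
  expect_equal(r[2, 1], 1)
  expect_equal(r[3, 1], 2.5)
  expect_equal(r[3, 2], 2.5)
  expect_error(
    feature_rank_matrix(igtd_table(matrix(c(0, 1, 2, 0), 2)),
                        distance_spec(feature_metric = "one_minus_jaccard")),
    "binary")
})

test_that("2x2 pixel grid has four average-rank-2.5 unit pairs and two 5.5 diagonals", {
  q <- pixel_rank_matrix(image_grid(2L, 2L))
  lower <- q[lower.tri(q)]
  expect_equal(sort(lower), c(2.5, 2.5, 2.5, 2.5, 5.5, 5.5))
  # adjacency: pixels (1,2), (1,3), (2,4), (3,4) are distance-1 neighbours
  expect_equal(q[2, 1], 2.5)
  expect_equal(q[4, 1], 5.5)
  expect_equal(q[3, 2], 5.5)
})

test_that("1x2 grid yields the single rank-1 pair", {
  q <- pixel_rank_matrix(image_grid(1L, 2L))
  expect_equal(q, matrix(c(0, 1, 1, 0), 2))
})

test_that("near-diagonal pixel pairs of a 50x50 grid rank below the median", {
  q <- pixel_rank_matrix(image_grid(50L, 50L))
  n <- nrow(q)
  med <- median(q[lower.tri(q)])
  near <- q[cbind(2:n, 1:(n - 1))]          # |i - j| = 1
  expect_true(mean(near < med) > 0.95)
})

test_that("rank sum over the lower triangle is fixed regardless of ties", {
  set.seed(13)
  for (case in 1:5) {
    n <- sample(4:12, 1)
    r <- random_rank_instance(n, seed = 100 + case)
    m <- n * (n - 1) / 2
    expect_equal(sum(r[lower.tri(r)]), m * (m + 1) / 2)
  }
  for (g in list(c(2, 2), c(3, 4), c(5, 5))) {
    q <- pixel_rank_matrix(image_grid(g[1], g[2]))
    m <- nrow(q) * (nrow(q) - 1) / 2
    expect_equal(sum(q[lower.tri(q)]), m * (m + 1) / 2)
  }
})

test_that("rank matrices are permutation-equivariant", {
  set.seed(17)
  for (case in 1:5) {
    x <- matrix(rnorm(6 * 8), 6, 8)
    perm <- sample(8)
    r <- feature_rank_matrix(igtd_table(x))
    r_perm <- feature_rank_matrix(igtd_table(x[, perm]))
    expect_equal(unname(r_perm), unname(r[perm, perm]))
  }
})

test_that("transposing the grid permutes Q consistently", {
  g <- image_grid(3L, 5L)
  gt <- image_grid(5L, 3L)
  q <- pixel_rank_matrix(g)
  qt <- pixel_rank_matrix(gt)
  # pixel (r, c) of the 3x5 grid is pixel (c, r) of the 5x3 grid
  co <- igtd:::pixel_coordinates(g)
  perm <- (co[, "col"] - 1L) * 3L + co[, "row"]
  expect_equal(q, qt[perm, perm])
})

test_that("manhattan pixel metric differs from euclidean where expected", {
  qe <- pixel_rank_matrix(image_grid(3L, 3L))
  qm <- pixel_rank_matrix(image_grid(3L, 3L),
                          distance_spec(pixel_metric = "manhattan"))
  # knight-like offset (1,2): euclidean sqrt(5) < 3 but manhattan 3 = 3
  expect_false(isTRUE(all.equal(qe, qm)))
  expect_equal(sum(qm[lower.tri(qm)]), sum(qe[lower.tri(qe)]))
})
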