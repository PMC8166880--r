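# Independent oracles used across the suite. These deliberately use naive
# formulations (double loops, full recomputation, exhaustive enumeration) so
# they share no code with the implementations they check.

# Naive double-loop local heterogeneity.
lh_oracle <- function(y, p) {
  h <- (p - 1L) / 2L
  nr <- nrow(y)
  nc <- ncol(y)
  tot <- 0
  cnt <- 0L
  for (i in (h + 1L):(nr - h)) {
    for (j in (h + 1L):(nc - h)) {
      s <- 0
      for (a in (i - h):(i + h)) {
        for (b in (j - h):(j + h)) {
          if (!(a == i && b == j)) s <- s + abs(y[a, b] - y[i, j])
        }
      }
      tot <- tot + s / (p * p - 1L)
      cnt <- cnt + 1L
    }
  }
  tot / cnt
}

# Full-recomputation swap-delta oracle: err before minus err after swapping
# rows/columns n and l, both errors summed from scratch.
swap_delta_oracle <- function(r, q, n, l, diff_fn) {
  idx <- seq_len(nrow(r))
  idx[c(n, l)] <- c(l, n)
  rank_error(r, q, diff_fn) - rank_error(r[idx, idx], q, diff_fn)
}

# All permutations of 1..n (n small), in lexicographic order.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# Exhaustive global minimum of rank_error over every feature ordering.
exhaustive_min_error <- function(r, q, diff_fn = "absolute") {
  best <- Inf
  for (perm in all_permutations(nrow(r))) {
    e <- rank_error(r[perm, perm], q, diff_fn)
    if (e < best) best <- e
  }
  best
}

# A random feature rank matrix built from a random gaussian table.
random_rank_instance <- function(n_features, n_samples = 6L, seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(n_samples * n_features), n_samples, n_features)
  feature_rank_matrix(igtd_table(x))
}

# A small grid whose pixel count is exactly n (prefers 2 rows when possible).
grid_for_n <- function(n) {
  if (n %% 2L == 0L && n >= 4L) image_grid(2L, n %/% 2L) else image_grid(1L, n)
}

# Mean LH at window p across a list of images.
mean_lh <- function(images, p) {
  mean(vapply(images, local_heterogeneity, numeric(1L), p = p))
}
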