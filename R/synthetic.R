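# Run code under a caller-supplied seed without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer; hidden global RNG state is not used")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a table with block-correlated features
#'
#' Emulates the clustered similarity structure of gene-expression or
#' molecular-descriptor tables: features come in blocks that share a latent
#' factor. Feature f in block b is
#' `noise_sd * (sqrt(rho) * z_b + sqrt(1 - rho) * eps_f)` with independent
#' standard normal `z_b` (one draw per sample and block) and `eps_f`, so the
#' population correlation of two features in the same block is exactly
#' `rho` and features in different blocks are independent. Block membership
#' is recorded in the feature names (`blkXX_fYYY`). Generation is O(M * N)
#' and bit-reproducible for a fixed seed.
#'
#' @param n_samples number of rows (M).
#' @param n_blocks number of feature blocks.
#' @param block_size features per block; total features
#'   `N = n_blocks * block_size`.
#' @param within_block_correlation rho in \[0, 1).
#' @param noise_sd overall scale of the features (positive).
#' @param seed mandatory integer seed.
#' @return An [igtd_table] with `n_samples` rows and
#'   `n_blocks * block_size` columns.
#' @export
generate_block_correlated_table <- function(n_samples, n_blocks, block_size,
                                            within_block_correlation = 0.9,
                                            noise_sd = 1, seed) {
  n_samples <- as.integer(n_samples)
  n_blocks <- as.integer(n_blocks)
  block_size <- as.integer(block_size)
  rho <- within_block_correlation
  if (n_samples < 2L) stop("need at least 2 samples")
  if (n_blocks < 1L || block_size < 1L || n_blocks * block_size < 2L) {
    stop("invalid block structure: need n_blocks * block_size >= 2")
  }
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    stop("within_block_correlation must be in [0, 1)")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be positive")
  nn <- n_blocks * block_size
  x <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_samples * n_blocks), n_samples, n_blocks)
    eps <- matrix(stats::rnorm(n_samples * nn), n_samples, nn)
    block_of <- rep(seq_len(n_blocks), each = block_size)
    noise_sd * (sqrt(rho) * z[, block_of, drop = FALSE] +
                sqrt(1 - rho) * eps)
  })
  feature_names <- sprintf("blk%02d_f%03d",
                           rep(seq_len(n_blocks), each = block_size),
                           seq_len(nn))
  igtd_table(x, sample_ids = sprintf("S%04d", seq_len(n_samples)),
             feature_names = feature_names)
}

#' Block membership of generated features
#'
#' Recovers the block index encoded in the feature names of a table from
#' [generate_block_correlated_table].
#'
#' @param data the generated [igtd_table].
#' @return Integer vector of block indices, one per feature.
#' @export
block_membership <- function(data) {
  data <- as_igtd_table(data)
  m <- regmatches(data$feature_names,
                  regexpr("(?<=^blk)[0-9]+", data$feature_names, perl = TRUE))
  if (length(m) != length(data$feature_names)) {
    stop("feature names do not carry blkXX_ block labels")
  }
  as.integer(m)
}

#' Instance with a planted optimal layout
#'
#' Builds a feature rank matrix R by applying a random permutation to the
#' pixel rank matrix Q of the given grid, so the global optimum of the
#' layout search is known to be exactly zero and the hidden permutation is
#' returned for recovery checks: `apply_ordering(R, truth)` equals Q.
#'
#' @param grid an [image_grid].
#' @param seed integer seed for the hidden permutation.
#' @param spec a [distance_spec] controlling the pixel metric and ties.
#' @return List with `r` (scrambled rank matrix), `q` (pixel rank matrix),
#'   and `truth` (permutation recovering Q from R).
#' @export
generate_planted_layout_instance <- function(grid, seed,
                                             spec = distance_spec()) {
  stopifnot(inherits(grid, "igtd_grid"))
  q <- pixel_rank_matrix(grid, spec)
  nn <- nrow(q)
  perm <- with_seed(seed, sample.int(nn))
  r <- q[perm, perm]
  list(r = r, q = q, truth = order(perm))
}

#' Paired synthetic images with a planted linear response
#'
#' Generates pairs of grayscale images (one per subnetwork, e.g. a
#' cell-line image and a drug image) and a response
#' `y = alpha * mean(image1) + beta * mean(image2) + noise`, the desk-scale
#' fixture used to check that the two-tower network learns a real signal.
#' Each image mixes a per-image brightness draw with pixel-level noise
#' (`0.5 * u_image + 0.5 * u_pixel`, both uniform on \[0, 1\]), so the mean
#' intensity varies substantially between images and the planted signal
#' dominates the response noise. Set `alpha = beta = 0` for a zero-signal
#' control.
#'
#' @param n number of pairs.
#' @param shape1,shape2 integer c(rows, cols) of the two image sets.
#' @param alpha,beta planted coefficients on the two mean intensities.
#' @param noise_sd response noise standard deviation.
#' @param seed mandatory integer seed.
#' @return List with arrays `x1` (n x rows1 x cols1), `x2`, and numeric
#'   response `y`.
#' @export
generate_paired_image_response <- function(n, shape1 = c(38L, 38L),
                                           shape2 = c(38L, 38L),
                                           alpha = 4, beta = -3,
                                           noise_sd = 0.05, seed) {
  n <- as.integer(n)
  with_seed(seed, {
    bright_noise_image <- function(shape) {
      u <- stats::runif(n)
      px <- array(stats::runif(n * prod(shape)), dim = c(n, shape))
      0.5 * array(rep(u, prod(shape)), dim = c(n, shape)) + 0.5 * px
    }
    x1 <- bright_noise_image(shape1)
    x2 <- bright_noise_image(shape2)
    m1 <- apply(x1, 1L, mean)
    m2 <- apply(x2, 1L, mean)
    y <- alpha * m1 + beta * m2 + stats::rnorm(n, sd = noise_sd)
    list(x1 = x1, x2 = x2, y = y)
  })
}
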