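#' Image grid geometry
#'
#' @param n_rows,n_cols positive integers; the optimised layout assigns one
#'   feature to each of the `n_rows * n_cols` pixels, linearised row by row.
#' @return An object of class `igtd_grid`.
#' @export
image_grid <- function(n_rows, n_cols) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (length(n_rows) != 1L || is.na(n_rows) || n_rows < 1L ||
      length(n_cols) != 1L || is.na(n_cols) || n_cols < 1L) {
    stop("grid dimensions must be positive integers")
  }
  if (n_rows * n_cols < 2L) stop("grid must contain at least 2 pixels")
  structure(list(n_rows = n_rows, n_cols = n_cols), class = "igtd_grid")
}

#' @export
print.igtd_grid <- function(x, ...) {
  cat("igtd_grid:", x$n_rows, "x", x$n_cols, "pixels\n")
  invisible(x)
}

#' Distance and tie-handling choices for rank matrices
#'
#' Features can be compared by Euclidean distance, by correlation distance
#' (1 - Pearson rho), or -- for binary tables -- by Jaccard distance
#' (1 - Jaccard index). Pixel coordinates can be compared by Euclidean or
#' Manhattan distance. Equal distances (ubiquitous on pixel grids) receive
#' their average rank by default, which keeps the rank-sum invariant and
#' makes the matrices symmetric under relabeling; `"ordinal"` ranks ties by
#' first occurrence instead.
#'
#' @param feature_metric one of `"euclidean"`, `"one_minus_correlation"`,
#'   `"one_minus_jaccard"`.
#' @param pixel_metric one of `"euclidean"`, `"manhattan"`.
#' @param ties one of `"average"`, `"ordinal"`.
#' @return An object of class `igtd_distance_spec`.
#' @export
distance_spec <- function(feature_metric = c("euclidean", "one_minus_correlation",
                                             "one_minus_jaccard"),
                          pixel_metric = c("euclidean", "manhattan"),
                          ties = c("average", "ordinal")) {
  structure(list(feature_metric = match.arg(feature_metric),
                 pixel_metric = match.arg(pixel_metric),
                 ties = match.arg(ties)),
            class = "igtd_distance_spec")
}

# Build an N x N symmetric rank matrix (zero diagonal) from a 'dist' object
# holding the N(N-1)/2 lower-triangle distances.
rank_matrix_from_dist <- function(d, ties, labels = NULL) {
  n <- attr(d, "Size")
  ties_method <- switch(ties, average = "average", ordinal = "first")
  r <- rank(as.numeric(d), ties.method = ties_method)
  out <- matrix(0, n, n)
  out[lower.tri(out)] <- r   # dist stores pairs in lower-triangle column order
  out <- out + t(out)
  if (!is.null(labels)) dimnames(out) <- list(labels, labels)
  out
}

#' Rank matrix of pairwise feature distances
#'
#' Computes all N(N-1)/2 pairwise distances between feature columns, ranks
#' them ascendingly (small distance, small rank) and arranges the ranks in a
#' symmetric N x N matrix R with a zero diagonal.
#'
#' @param data an [igtd_table].
#' @param spec a [distance_spec]; only its `feature_metric` and `ties`
#'   fields are used.
#' @return Numeric N x N rank matrix.
#' @export
feature_rank_matrix <- function(data, spec = distance_spec()) {
  data <- as_igtd_table(data)
  stopifnot(inherits(spec, "igtd_distance_spec"))
  x <- data$values
  d <- switch(spec$feature_metric,
    euclidean = stats::dist(t(x), method = "euclidean"),
    one_minus_correlation = {
      sds <- apply(x, 2L, stats::sd)
      if (any(sds == 0)) {
        stop("constant feature(s) have undefined correlation: ",
             paste(data$feature_names[sds == 0], collapse = ", "))
      }
      stats::as.dist(1 - stats::cor(x))
    },
    one_minus_jaccard = {
      if (!all(x %in% c(0, 1))) {
        stop("one_minus_jaccard requires a binary (0/1) table")
      }
      stats::dist(t(x), method = "binary")
    })
  dv <- as.numeric(d)
  if (!all(is.finite(dv))) {
    n <- ncol(x)
    idx <- which(!is.finite(dv))[1L]
    pair <- pair_from_dist_index(idx, n)
    stop("non-finite distance between features '",
         data$feature_names[pair[1L]], "' and '",
         data$feature_names[pair[2L]], "'")
  }
  rank_matrix_from_dist(d, spec$ties, labels = data$feature_names)
}

# Map a linear index of a 'dist' vector back to its (i, j) pair, i > j.
pair_from_dist_index <- function(idx, n) {
  j <- 1L
  offset <- 0L
  while (idx > offset + (n - j)) {
    offset <- offset + (n - j)
    j <- j + 1L
  }
  c(j + (idx - offset), j)
}

#' Rank matrix of pairwise pixel distances
#'
#' Pixels of an `n_rows x n_cols` grid are linearised row by row; pixel p has
#' integer coordinates (ceiling(p / n_cols), ((p - 1) mod n_cols) + 1).
#' Pairwise coordinate distances are ranked exactly as feature distances
#' are, giving the symmetric target matrix Q with zero diagonal.
#'
#' @param grid an [image_grid].
#' @param spec a [distance_spec]; only `pixel_metric` and `ties` are used.
#' @return Numeric N x N rank matrix, N = `n_rows * n_cols`.
#' @export
pixel_rank_matrix <- function(grid, spec = distance_spec()) {
  stopifnot(inherits(grid, "igtd_grid"), inherits(spec, "igtd_distance_spec"))
  coords <- pixel_coordinates(grid)
  method <- switch(spec$pixel_metric, euclidean = "euclidean",
                   manhattan = "manhattan")
  rank_matrix_from_dist(stats::dist(coords, method = method), spec$ties)
}

# Row-major integer pixel coordinates, 1-based: pixel p -> (row, col).
pixel_coordinates <- function(grid) {
  p <- seq_len(grid$n_rows * grid$n_cols)
  cbind(row = ceiling(p / grid$n_cols),
        col = ((p - 1L) %% grid$n_cols) + 1L)
}

# Validate the structural invariants of a rank matrix.
check_rank_matrix <- function(r, what = "rank matrix") {
  if (!is.matrix(r) || nrow(r) != ncol(r)) stop(what, " must be square")
  if (any(diag(r) != 0)) stop(what, " must have a zero diagonal")
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-12))) {
    stop(what, " must be symmetric")
  }
  invisible(r)
}

#' Write a square rank matrix as CSV for inspection
#'
#' @param r rank matrix (from [feature_rank_matrix] or [pixel_rank_matrix]).
#' @param path output file.
#' @export
write_rank_matrix_csv <- function(r, path) {
  utils::write.csv(as.data.frame(r), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
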