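#' Local heterogeneity of an image layout
#'
#' For every full p x p window (centres range over the
#' `(n_rows - p + 1) x (n_cols - p + 1)` interior positions; no padding),
#' the average absolute intensity difference between the centre pixel and
#' its p^2 - 1 neighbours is computed, and LH is the mean of these window
#' heterogeneities. A layout that places similar features on adjacent
#' pixels has a low LH; a constant image has LH 0. LH is invariant to
#' adding a constant to all pixels and scales linearly with multiplicative
#' intensity scaling.
#'
#' @param image an `igtd_image` or plain numeric matrix.
#' @param p odd neighbourhood side length, at least 3 and at most the
#'   smaller image dimension.
#' @return Non-negative scalar.
#' @export
local_heterogeneity <- function(image, p = 3L) {
  y <- as_intensity_matrix(image)
  p <- as.integer(p)
  if (length(p) != 1L || is.na(p) || p < 3L || p %% 2L == 0L) {
    stop("'p' must be an odd integer >= 3")
  }
  nr <- nrow(y)
  nc <- ncol(y)
  if (p > min(nr, nc)) {
    stop("neighbourhood size p = ", p, " exceeds image dimension ",
         min(nr, nc))
  }
  half <- (p - 1L) %/% 2L
  ci <- (half + 1L):(nr - half)
  cj <- (half + 1L):(nc - half)
  centre <- y[ci, cj, drop = FALSE]
  acc <- matrix(0, length(ci), length(cj))
  for (da in -half:half) {
    for (db in -half:half) {
      if (da == 0L && db == 0L) next
      acc <- acc + abs(y[ci + da, cj + db, drop = FALSE] - centre)
    }
  }
  mean(acc / (p * p - 1L))
}

#' Percentage by which one layout reduces local heterogeneity
#'
#' `(lh_other - lh_igtd) / lh_other * 100`: the relative LH reduction the
#' optimised layout achieves over a competing layout of the same data.
#' Negative values mean the optimised layout is worse.
#'
#' @param lh_other LH of the competing layout; must be positive.
#' @param lh_igtd LH of the optimised layout.
#' @return Percentage (scalar, may be negative).
#' @export
lh_reduction_percentage <- function(lh_other, lh_igtd) {
  if (!is.numeric(lh_other) || any(lh_other <= 0)) {
    stop("'lh_other' must be positive (the ratio is undefined at 0)")
  }
  (lh_other - lh_igtd) / lh_other * 100
}

#' Summarise local heterogeneity across images and window sizes
#'
#' Computes the mean and standard deviation of LH across a set of images at
#' each window size. When a second image set is supplied (same samples,
#' different layout), paired reduction percentages and a paired two-tailed
#' t-test p-value are added; the t-test is a standard convenience statistic,
#' not part of the layout method itself.
#'
#' @param images list of `igtd_image` (or matrices).
#' @param p_values odd window sizes to evaluate.
#' @param reference optional list of same-length images for a paired
#'   comparison; entry i must be the same sample as `images[[i]]` under the
#'   competing layout.
#' @return Data frame with one row per window size: `p`, `lh_mean`, `lh_sd`,
#'   and, when `reference` is given, `ref_lh_mean`, `ref_lh_sd`,
#'   `reduction_pct_mean`, `reduction_pct_sd`, `p_value`.
#' @export
layout_lh_summary <- function(images, p_values = c(3L, 5L, 7L, 9L),
                              reference = NULL) {
  if (!length(images)) stop("'images' must be a non-empty list")
  if (!is.null(reference) && length(reference) != length(images)) {
    stop("paired comparison needs equally many reference images (",
         length(reference), " vs ", length(images), ")")
  }
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  rows <- lapply(p_values, function(p) {
    lh <- vapply(images, local_heterogeneity, numeric(1L), p = p)
    row <- data.frame(p = as.integer(p), lh_mean = mean(lh), lh_sd = sd0(lh))
    if (!is.null(reference)) {
      lh_ref <- vapply(reference, local_heterogeneity, numeric(1L), p = p)
      red <- lh_reduction_percentage(lh_ref, lh)
      pv <- if (length(lh) > 1L && stats::sd(lh - lh_ref) > 0) {
        stats::t.test(lh, lh_ref, paired = TRUE)$p.value
      } else {
        NA_real_
      }
      row$ref_lh_mean <- mean(lh_ref)
      row$ref_lh_sd <- sd0(lh_ref)
      row$reduction_pct_mean <- mean(red)
      row$reduction_pct_sd <- sd0(red)
      row$p_value <- pv
    }
    row
  })
  do.call(rbind, rows)
}
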