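#' Feature-to-pixel assignment
#'
#' Wraps an optimiser ordering together with the grid geometry. Position `p`
#' of the ordering maps to pixel (row `ceiling(p / n_cols)`, column
#' `((p - 1) mod n_cols) + 1`), row-major -- the same linearisation used to
#' build the pixel rank matrix.
#'
#' @param permutation integer permutation; element `p` is the original
#'   feature index shown at pixel position `p`.
#' @param grid an [image_grid] with `n_rows * n_cols == length(permutation)`.
#' @return An object of class `igtd_ordering`.
#' @export
feature_ordering <- function(permutation, grid) {
  stopifnot(inherits(grid, "igtd_grid"))
  permutation <- as.integer(permutation)
  nn <- grid$n_rows * grid$n_cols
  if (length(permutation) != nn || !setequal(permutation, seq_len(nn))) {
    stop("'permutation' must be a permutation of 1..", nn,
         " (the grid pixel count)")
  }
  structure(list(permutation = permutation, grid = grid),
            class = "igtd_ordering")
}

#' @export
print.igtd_ordering <- function(x, ...) {
  cat("igtd_ordering:", length(x$permutation), "features on a",
      x$grid$n_rows, "x", x$grid$n_cols, "grid\n")
  invisible(x)
}

#' Render one grayscale image per sample
#'
#' Pixel position `p` of sample `m`'s image holds the value of feature
#' `ordering$permutation[p]` in row `m` of the table. Rendering is a pure
#' permutation: the multiset of pixel intensities equals the multiset of the
#' sample's feature values. The table is expected to be normalised (see
#' [normalize_features]) so intensities lie in \[0, 1\].
#'
#' @param data an [igtd_table] whose column count equals the grid size.
#' @param ordering an [igtd_ordering].
#' @return List of `igtd_image` objects (fields `intensities`, an
#'   `n_rows x n_cols` matrix, and `sample_id`).
#' @export
render_images <- function(data, ordering) {
  data <- as_igtd_table(data)
  stopifnot(inherits(ordering, "igtd_ordering"))
  grid <- ordering$grid
  nn <- grid$n_rows * grid$n_cols
  if (ncol(data$values) != nn) {
    stop("table has ", ncol(data$values), " features but the grid holds ",
         nn, " pixels; use pad_or_trim_to_grid() first")
  }
  lapply(seq_len(nrow(data$values)), function(m) {
    v <- data$values[m, ordering$permutation]
    structure(list(intensities = matrix(v, nrow = grid$n_rows,
                                        ncol = grid$n_cols, byrow = TRUE),
                   sample_id = data$sample_ids[m]),
              class = "igtd_image")
  })
}

#' @export
print.igtd_image <- function(x, ...) {
  cat("igtd_image '", x$sample_id, "': ", nrow(x$intensities), " x ",
      ncol(x$intensities), ", intensity range [",
      signif(min(x$intensities), 4L), ", ",
      signif(max(x$intensities), 4L), "]\n", sep = "")
  invisible(x)
}

as_intensity_matrix <- function(image) {
  if (inherits(image, "igtd_image")) image$intensities
  else if (is.matrix(image)) image
  else stop("expected an igtd_image or a numeric matrix")
}

#' Export rendered images to disk
#'
#' `png8` writes one 8-bit grayscale PNG per sample; intensities in \[0, 1\]
#' are scaled by 255 and rounded half-up, so an intensity of exactly 0.5
#' becomes pixel value 128. `array_archive` serialises the full-precision
#' M x n_rows x n_cols intensity array to a single `.rds` container so a
#' re-read is bit-exact. Both formats also write a `manifest.csv` of
#' (sample_id, path).
#'
#' @param images list of `igtd_image` (from [render_images]).
#' @param directory output directory, created if absent.
#' @param format `"png8"` or `"array_archive"`.
#' @param invert flip polarity on PNG export (large values dark), matching
#'   renderings where low values print near white.
#' @return Invisibly, the manifest data frame.
#' @export
export_images <- function(images, directory, format = c("png8", "array_archive"),
                          invert = FALSE) {
  format <- match.arg(format)
  if (!length(images)) stop("no images to export")
  if (!dir.exists(directory)) {
    dir.create(directory, recursive = TRUE)
  }
  ids <- vapply(images, function(im) im$sample_id, character(1L))
  if (format == "png8") {
    paths <- file.path(directory, paste0(make.names(ids), ".png"))
    for (i in seq_along(images)) {
      y <- images[[i]]$intensities
      if (any(y < 0 | y > 1)) {
        stop("intensities of sample '", ids[i],
             "' fall outside [0, 1]; normalise before png8 export")
      }
      v <- floor(y * 255 + 0.5)          # round half-up
      if (invert) v <- 255 - v
      ok <- tryCatch({ png::writePNG(v / 255, target = paths[i]); TRUE },
                     error = function(e) e)
      if (!isTRUE(ok)) {
        stop("failed to write PNG for sample '", ids[i], "': ",
             conditionMessage(ok))
      }
    }
  } else {
    nr <- nrow(images[[1L]]$intensities)
    nc <- ncol(images[[1L]]$intensities)
    arr <- array(NA_real_, dim = c(length(images), nr, nc),
                 dimnames = list(ids, NULL, NULL))
    for (i in seq_along(images)) arr[i, , ] <- images[[i]]$intensities
    archive <- file.path(directory, "images.rds")
    saveRDS(list(intensities = arr, sample_ids = ids), archive)
    paths <- rep(archive, length(images))
  }
  manifest <- data.frame(sample_id = ids, path = paths,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Re-read an image archive written by [export_images]
#'
#' @param path the `images.rds` archive.
#' @return List of `igtd_image`, bit-identical to what was exported.
#' @export
read_image_archive <- function(path) {
  payload <- readRDS(path)
  lapply(seq_along(payload$sample_ids), function(i) {
    structure(list(intensities = payload$intensities[i, , ],
                   sample_id = payload$sample_ids[i]),
              class = "igtd_image")
  })
}
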