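#' Numeric table of samples by features
#'
#' Container for an M x N numeric matrix whose rows are samples (e.g. cancer
#' cell lines, drugs) and whose columns are features (gene expression values,
#' molecular descriptors). All downstream steps -- feature selection,
#' distance ranking, layout optimisation and image rendering -- operate on
#' this structure.
#'
#' @param values numeric matrix with M >= 2 rows and N >= 2 columns; all
#'   entries must be finite.
#' @param sample_ids character vector of length M; defaults to rownames or
#'   `S1..SM`.
#' @param feature_names character vector of length N, unique; defaults to
#'   colnames or `F1..FN`.
#' @return An object of class `igtd_table` with elements `values`,
#'   `sample_ids`, `feature_names`.
#' @export
igtd_table <- function(values, sample_ids = NULL, feature_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  m <- nrow(values)
  n <- ncol(values)
  if (m < 2L) stop("need at least 2 samples (rows), got ", m)
  if (n < 2L) stop("need at least 2 features (columns), got ", n)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite value at row ", bad[1L], ", column ", bad[2L],
         "; impute or drop missing values upstream")
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(rownames(values))) rownames(values)
                  else paste0("S", seq_len(m))
  }
  if (is.null(feature_names)) {
    feature_names <- if (!is.null(colnames(values))) colnames(values)
                     else paste0("F", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  feature_names <- as.character(feature_names)
  if (length(sample_ids) != m) stop("sample_ids length must equal nrow(values)")
  if (length(feature_names) != n) stop("feature_names length must equal ncol(values)")
  if (anyDuplicated(feature_names)) {
    stop("feature_names must be unique; duplicated: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(list(values = values,
                 sample_ids = sample_ids,
                 feature_names = feature_names),
            class = "igtd_table")
}

#' @export
print.igtd_table <- function(x, ...) {
  cat("igtd_table:", nrow(x$values), "samples x", ncol(x$values), "features\n")
  cat("  samples: ", paste(utils::head(x$sample_ids, 3L), collapse = ", "),
      if (length(x$sample_ids) > 3L) ", ..." else "", "\n", sep = "")
  cat("  features: ", paste(utils::head(x$feature_names, 3L), collapse = ", "),
      if (length(x$feature_names) > 3L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.igtd_table <- function(x) dim(x$values)

as_igtd_table <- function(x) {
  if (inherits(x, "igtd_table")) return(x)
  igtd_table(x)
}

#' Read a delimited table of samples by features
#'
#' Expects a header row of feature names. The first column is taken as
#' sample identifiers when it is non-numeric (or when `sample_id_col` says
#' so explicitly).
#'
#' @param path CSV or TSV file path; the separator is sniffed from the
#'   extension (`.tsv`/`.txt` = tab) unless `sep` is given.
#' @param sample_id_col `NA` to auto-detect, `TRUE`/`FALSE` to force.
#' @param sep field separator; `NULL` to infer from the extension.
#' @return An [igtd_table].
#' @export
read_tabular_csv <- function(path, sample_id_col = NA, sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop("parsed fewer than 2 columns from ", path,
                          "; wrong separator?")
  has_ids <- if (is.na(sample_id_col)) !is.numeric(df[[1L]]) else isTRUE(sample_id_col)
  if (has_ids) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  } else {
    ids <- paste0("S", seq_len(nrow(df)))
  }
  num <- vapply(df, is.numeric, logical(1L))
  if (!all(num)) {
    stop("non-numeric feature column(s): ",
         paste(names(df)[!num], collapse = ", "))
  }
  igtd_table(as.matrix(df), sample_ids = ids, feature_names = names(df))
}

#' Write a table in the dialect [read_tabular_csv] reads
#'
#' @param data an [igtd_table].
#' @param path output CSV path; the first column holds sample identifiers.
#' @export
write_tabular_csv <- function(data, path) {
  data <- as_igtd_table(data)
  df <- data.frame(sample_id = data$sample_ids,
                   data$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep the k features with the largest variance
#'
#' Standard front-end reduction before layout optimisation: for example
#' keeping the 2,500 genes with the largest expression variation across cell
#' lines. Selected columns keep their original relative order. Ties at the
#' selection cutoff are resolved by first occurrence.
#'
#' @param data an [igtd_table].
#' @param k number of features to keep; must not exceed the feature count.
#' @return An [igtd_table] with k columns.
#' @export
select_top_variance_features <- function(data, k) {
  data <- as_igtd_table(data)
  n <- ncol(data$values)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) stop("'k' must be a positive integer")
  if (k > n) stop("k (", k, ") exceeds the number of features (", n, ")")
  v <- apply(data$values, 2L, stats::var)
  # order() is stable, so equal variances keep first-occurrence priority
  keep <- sort(order(v, decreasing = TRUE)[seq_len(k)])
  if (k < n && any(duplicated(signif(v, 12L))) ) {
    cutoff <- sort(v, decreasing = TRUE)[k]
    n_tied <- sum(v == cutoff)
    if (n_tied > 1L && sum(v > cutoff) + n_tied > k) {
      message("variance tie at the selection cutoff (", n_tied,
              " features); resolved by first-occurrence order")
    }
  }
  igtd_table(data$values[, keep, drop = FALSE],
             sample_ids = data$sample_ids,
             feature_names = data$feature_names[keep])
}

#' Match the feature count to an image grid
#'
#' If the table has fewer features than pixels, all-zero pseudo-features are
#' appended so every pixel represents a column. If it has more, the call
#' fails unless `trim = TRUE`, in which case the highest-variance features
#' are retained.
#'
#' @param data an [igtd_table].
#' @param grid an [image_grid].
#' @param trim allow dropping low-variance features when the table is wider
#'   than the grid.
#' @return An [igtd_table] with exactly `n_rows * n_cols` columns.
#' @export
pad_or_trim_to_grid <- function(data, grid, trim = FALSE) {
  data <- as_igtd_table(data)
  stopifnot(inherits(grid, "igtd_grid"))
  target <- grid$n_rows * grid$n_cols
  n <- ncol(data$values)
  if (n == target) return(data)
  if (n > target) {
    if (!isTRUE(trim)) {
      stop("table has ", n, " features but the grid holds ", target,
           " pixels; pass trim = TRUE to keep the top-variance features")
    }
    return(select_top_variance_features(data, target))
  }
  n_pad <- target - n
  pad_names <- paste0("pad", seq_len(n_pad))
  suffix <- 0L
  while (any(pad_names %in% data$feature_names)) {
    suffix <- suffix + 1L
    pad_names <- paste0("pad", seq_len(n_pad), ".", suffix)
  }
  pad <- matrix(0, nrow = nrow(data$values), ncol = n_pad,
                dimnames = list(NULL, pad_names))
  igtd_table(cbind(data$values, pad),
             sample_ids = data$sample_ids,
             feature_names = c(data$feature_names, pad_names))
}

#' Rescale each feature to the unit interval
#'
#' Min-max scaling is applied per feature across samples, so a given pixel is
#' comparable between the images of different samples. Constant features map
#' to zero.
#'
#' @param data an [igtd_table].
#' @param mode `"minmax"` or `"none"` (identity).
#' @return An [igtd_table] with values in \[0, 1\] when `mode = "minmax"`.
#' @export
normalize_features <- function(data, mode = c("minmax", "none")) {
  mode <- match.arg(mode)
  data <- as_igtd_table(data)
  if (mode == "none") return(data)
  x <- data$values
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  rng <- hi - lo
  scaled <- sweep(x, 2L, lo, "-")
  nz <- rng > 0
  scaled[, nz] <- sweep(scaled[, nz, drop = FALSE], 2L, rng[nz], "/")
  scaled[, !nz] <- 0
  igtd_table(scaled, sample_ids = data$sample_ids,
             feature_names = data$feature_names)
}
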