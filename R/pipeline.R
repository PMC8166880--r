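#' End-to-end transformation pipeline
#'
#' Runs the full table-to-images workflow: feature selection/padding to the
#' grid size, distance ranking, layout optimisation, rendering, export, and
#' a local-heterogeneity summary against a fixed number of random layouts.
#' All artefacts (ordering CSV, error-trace CSV, LH summary CSV, exported
#' images, run manifest JSON) are written under `output_dir`. The run is
#' fully deterministic for a given configuration: the optimiser draws no
#' random numbers, and the random-layout baseline is seeded from
#' `baseline_seed`.
#'
#' @param input path to a CSV/TSV table (see [read_tabular_csv]) or an
#'   [igtd_table].
#' @param output_dir directory for all outputs, created if absent.
#' @param grid an [image_grid]; defaults to 50 x 50 as in the reference run.
#' @param spec a [distance_spec].
#' @param config an [igtd_config]; defaults mirror the reference run
#'   (`s_max = 30000`, `s_con = 500`, `t_con = 1e-6`, `t_swap = 0`,
#'   absolute difference).
#' @param trim allow keeping only the top-variance features when the table
#'   is wider than the grid.
#' @param normalization `"minmax"` (default) or `"none"`; applied before
#'   rendering. Ranking uses the raw table.
#' @param rank_on_normalized rank feature distances on the normalised table
#'   instead of the raw one.
#' @param export_format `"png8"`, `"array_archive"`, or `"none"`.
#' @param lh_p window sizes for the LH summary.
#' @param n_random_layouts number of random layouts in the LH comparison
#'   (0 skips it).
#' @param baseline_seed seed for the random-layout baseline.
#' @param invert_png flip PNG polarity (large values dark).
#' @return Invisibly, the run manifest (also written as `manifest.json`):
#'   configuration echo, initial and final error, iteration count,
#'   convergence flag, LH summary and output file paths.
#' @export
run_pipeline <- function(input, output_dir,
                         grid = image_grid(50L, 50L),
                         spec = distance_spec(),
                         config = igtd_config(),
                         trim = FALSE,
                         normalization = c("minmax", "none"),
                         rank_on_normalized = FALSE,
                         export_format = c("png8", "array_archive", "none"),
                         lh_p = c(3L, 5L, 7L, 9L),
                         n_random_layouts = 0L,
                         baseline_seed = 1L,
                         invert_png = FALSE) {
  normalization <- match.arg(normalization)
  export_format <- match.arg(export_format)
  input_path <- NULL
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  data <- stage("read", {
    if (is.character(input)) {
      input_path <- input
      read_tabular_csv(input)
    } else {
      as_igtd_table(input)
    }
  })
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  data <- stage("pad_or_trim", pad_or_trim_to_grid(data, grid, trim = trim))
  normalized <- stage("normalize", normalize_features(data, normalization))
  rank_input <- if (rank_on_normalized) normalized else data
  r0 <- stage("feature_ranking", feature_rank_matrix(rank_input, spec))
  q <- stage("pixel_ranking", pixel_rank_matrix(grid, spec))
  result <- stage("optimize", igtd_optimize(r0, q, config))

  ordering <- feature_ordering(result$ordering, grid)
  coords <- pixel_coordinates(grid)
  ordering_df <- data.frame(
    feature_name = data$feature_names[ordering$permutation],
    pixel_row = coords[, "row"],
    pixel_col = coords[, "col"],
    linear_index = seq_along(ordering$permutation))
  ordering_path <- file.path(output_dir, "ordering.csv")
  utils::write.csv(ordering_df, ordering_path, row.names = FALSE, quote = FALSE)
  trace_path <- file.path(output_dir, "error_trace.csv")
  write_error_trace_csv(result, trace_path)

  images <- stage("render", render_images(normalized, ordering))
  image_manifest <- NULL
  if (export_format != "none") {
    image_manifest <- stage("export",
      export_images(images, file.path(output_dir, "images"),
                    format = export_format, invert = invert_png))
  }

  lh_p <- lh_p[lh_p <= min(grid$n_rows, grid$n_cols)]
  lh <- NULL
  lh_path <- NULL
  if (length(lh_p)) {
    lh <- stage("lh_summary", {
      if (n_random_layouts > 0L) {
        nn <- grid$n_rows * grid$n_cols
        rand_lh <- with_seed(baseline_seed, {
          sapply(seq_len(n_random_layouts), function(i) {
            rnd <- feature_ordering(sample.int(nn), grid)
            rnd_imgs <- render_images(normalized, rnd)
            vapply(lh_p, function(p) {
              mean(vapply(rnd_imgs, local_heterogeneity, numeric(1L), p = p))
            }, numeric(1L))
          })
        })
        rand_lh <- matrix(rand_lh, nrow = length(lh_p))
        s <- layout_lh_summary(images, lh_p)
        s$random_lh_mean <- rowMeans(rand_lh)
        s$reduction_pct_vs_random <-
          lh_reduction_percentage(rowMeans(rand_lh), s$lh_mean)
        s
      } else {
        layout_lh_summary(images, lh_p)
      }
    })
    lh_path <- file.path(output_dir, "lh_summary.csv")
    utils::write.csv(lh, lh_path, row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("igtd")),
    input = if (!is.null(input_path)) normalizePath(input_path) else "in-memory table",
    input_md5 = if (!is.null(input_path)) unname(tools::md5sum(input_path)) else NA,
    n_samples = nrow(data$values),
    n_features = ncol(data$values),
    grid = c(grid$n_rows, grid$n_cols),
    distance = unclass(spec),
    optimizer = unclass(config),
    normalization = normalization,
    rank_on_normalized = rank_on_normalized,
    export_format = export_format,
    n_random_layouts = n_random_layouts,
    baseline_seed = baseline_seed,
    initial_error = result$error_trace[1L],
    final_error = result$error,
    n_iterations = result$n_iterations,
    converged = result$converged,
    files = list(ordering = ordering_path, error_trace = trace_path,
                 lh_summary = lh_path,
                 images = if (!is.null(image_manifest))
                   file.path(output_dir, "images", "manifest.csv") else NULL))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
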