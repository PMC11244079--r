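#' Read and write silhouette images
#'
#' Silhouettes are stored one seed per file as white-on-black PNG (or TIFF,
#' when the `tiff` package is available). Reading collapses colour channels
#' to grey; writing maps foreground to white.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return `read_silhouette()`: a numeric matrix in `[0, 1]` (raster
#'   orientation) ready for [binarize()].
#' @export
read_silhouette <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("reading TIFF requires the `tiff` package")
      }
      tiff::readTIFF(path)
    },
    abort(sprintf("unsupported image format: .%s", ext))
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  img
}

#' @rdname read_silhouette
#' @param silhouette logical matrix (foreground = seed).
#' @export
write_silhouette <- function(silhouette, path) {
  img <- matrix(as.numeric(unclass(silhouette)), nrow(silhouette))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("writing TIFF requires the `tiff` package")
      }
      tiff::writeTIFF(img, path)
    },
    abort(sprintf("unsupported image format: .%s", ext))
  )
  invisible(path)
}

#' Write outlines to CSV
#'
#' One row per outline point, columns `sample_id`, `point_index`, `x`, `y`.
#'
#' @param outlines named list of outline tibbles, or a single outline.
#' @param path output CSV path.
#' @export
write_outlines_csv <- function(outlines, path) {
  if (is.data.frame(outlines)) outlines <- list(outline = outlines)
  long <- purrr::imap(outlines, function(o, id)
    tibble(sample_id = id, point_index = seq_len(nrow(o)), x = o$x, y = o$y))
  write.csv(dplyr::bind_rows(long), path, row.names = FALSE)
  invisible(path)
}

#' Write a per-sample feature table to CSV
#'
#' One row per sample: `sample_id` plus the 24 named coefficient columns
#' (and any extra label columns present).
#'
#' @param features tibble from [extract_features()].
#' @param path output CSV path.
#' @export
write_features_csv <- function(features, path) {
  if (!is.data.frame(features) || !"sample_id" %in% names(features)) {
    abort("`features` must be a data frame with a `sample_id` column")
  }
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read and write EFD sets as JSON
#'
#' Round-trips a `pip_efd` object (coefficients plus centroid/size/perimeter
#' metadata) through a JSON file, e.g. for storing small fixtures.
#'
#' @param e a `pip_efd` object.
#' @param path JSON path.
#' @export
write_efd_json <- function(e, path) {
  if (!inherits(e, "pip_efd")) abort("`e` must be a `pip_efd` object")
  payload <- list(
    coefficients = unname(apply(e$coefficients, 1L, identity,
                                simplify = FALSE)),
    n_harmonics = e$n_harmonics, centroid = unname(e$centroid),
    centroid_size = e$centroid_size, perimeter = e$perimeter,
    n_points = e$n_points
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_efd_json
#' @export
read_efd_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  coef <- do.call(rbind, lapply(p$coefficients, function(r)
    unlist(r, use.names = FALSE)))
  dimnames(coef) <- list(NULL, c("a", "b", "c", "d"))
  p$centroid <- unlist(p$centroid)
  structure(
    list(coefficients = coef, n_harmonics = p$n_harmonics,
         centroid = c(x = p$centroid[1], y = p$centroid[2]),
         centroid_size = p$centroid_size, perimeter = p$perimeter,
         n_points = p$n_points),
    class = "pip_efd"
  )
}

#' Serialise a fitted discriminant model to JSON
#'
#' Stores the selected features, group means, pooled within-class
#' covariance, priors and classification-function coefficients; the model
#' can be restored with [read_lda_json()].
#'
#' @param model a `pip_lda` object.
#' @param path output JSON path.
#' @export
write_lda_json <- function(model, path) {
  if (!inherits(model, "pip_lda")) abort("`model` must be a `pip_lda` object")
  payload <- list(
    features = model$features, groups = model$groups,
    counts = unname(model$counts), n = model$n,
    priors = unname(model$priors),
    means = unname(apply(model$means, 1L, identity, simplify = FALSE)),
    pooled_cov = unname(apply(model$pooled_cov, 1L, identity,
                              simplify = FALSE)),
    coef = unname(apply(model$coef, 2L, identity, simplify = FALSE)),
    const = unname(model$const)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lda_json
#' @export
read_lda_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  features <- unlist(p$features)
  groups <- unlist(p$groups)
  rows <- function(lst) do.call(rbind, lapply(lst, unlist, use.names = FALSE))
  structure(
    list(features = features, groups = groups,
         counts = setNames(unlist(p$counts), groups),
         means = `dimnames<-`(rows(p$means), list(groups, features)),
         pooled_cov = `dimnames<-`(rows(p$pooled_cov),
                                   list(features, features)),
         priors = setNames(unlist(p$priors), groups),
         coef = `dimnames<-`(t(rows(p$coef)), list(features, groups)),
         const = setNames(unlist(p$const), groups), n = p$n),
    class = "pip_lda"
  )
}

#' Write all outputs of a pipeline run
#'
#' Writes the feature tables, per-sample assignments, allocation report
#' tables, cultivar metadata, fitted models and a JSON manifest (config,
#' seed, package version, file inventory) into `out_dir`.
#'
#' @param run a `pip_run` object from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @export
write_run <- function(run, out_dir) {
  if (!inherits(run, "pip_run")) abort("`run` must be a `pip_run` object")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)
  write.csv(run$reference_features, out("reference_features.csv"),
            row.names = FALSE)
  write.csv(run$unknown_features, out("unknown_features.csv"),
            row.names = FALSE)
  write.csv(run$assignments, out("assignments.csv"), row.names = FALSE)
  write.csv(run$metadata, out("cultivar_metadata.csv"), row.names = FALSE)
  rep <- run$report
  write.csv(rep$status, out("allocation_status.csv"), row.names = FALSE)
  write.csv(rep$cultivar_counts, out("cultivar_counts_full.csv"),
            row.names = FALSE)
  write.csv(rep$cultivar_table, out("cultivar_counts_filtered.csv"),
            row.names = FALSE)
  write.csv(rep$colour, out("allocation_colour.csv"), row.names = FALSE)
  write.csv(rep$region, out("allocation_region.csv"), row.names = FALSE)
  write.csv(run$stage1$selection$trace, out("stage1_stepwise_trace.csv"),
            row.names = FALSE)
  write.csv(run$stage1$loocv$confusion, out("stage1_loocv_confusion.csv"),
            row.names = FALSE)
  write_lda_json(run$stage1$model, out("stage1_model.json"))
  write_lda_json(run$stage2$model, out("stage2_model.json"))
  manifest <- list(
    package = "pipmorph",
    version = as.character(utils::packageVersion("pipmorph")),
    seed = run$seed,
    config = run$config,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stage1_loocv_accuracy = run$stage1$loocv$accuracy,
    stage1_resubstitution_accuracy = run$stage1$resubstitution_accuracy,
    dropped_cultivars = run$stage2$dropped_cultivars,
    files = list.files(out_dir)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
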