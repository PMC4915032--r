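#' Write / read an image stack as multi-page TIFF with a JSON sidecar
#'
#' Stacks are stored as 16-bit multi-page TIFF (one page per z-section)
#' next to a `<path>.json` sidecar holding the voxel sizes, provenance and
#' the intensity scale. Integer intensities up to 65535 round-trip exactly.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack"))
    abort("`stack` must be an image_stack", class = "spinemorph_format_error")
  v <- stack$voxels
  if (max(v) > 65535)
    abort("intensities exceed the 16-bit TIFF range",
          class = "spinemorph_format_error")
  pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(pixel_size_xy_um = stack$pixel_size_xy,
               z_step_um = stack$z_step,
               n_z = dim(v)[3],
               intensity_scale = 65535,
               provenance = stack$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @return For `read_stack()`: the `image_stack`.
#' @export
read_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path))
    abort(sprintf("stack file not found: %s", path),
          class = "spinemorph_format_error")
  if (!file.exists(sidecar))
    abort(sprintf("missing metadata sidecar: %s", sidecar),
          class = "spinemorph_format_error")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("pixel_size_xy_um", "z_step_um", "intensity_scale"))
    if (is.null(meta[[f]]))
      abort(sprintf("metadata sidecar lacks field '%s'", f),
            class = "spinemorph_format_error")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  v <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) v[, , k] <- round(pages[[k]] * meta$intensity_scale)
  new_image_stack(v, meta$pixel_size_xy_um, meta$z_step_um,
                  provenance = meta$provenance %||% "")
}

#' Write / read tabular results as CSV
#'
#' Thin readr wrappers: the reader is tolerant (extra columns are preserved
#' and ignored by downstream code).
#'
#' @param x A data frame.
#' @param path CSV path.
#' @return `write_table()` returns `path` invisibly; `read_table_csv()`
#'   returns a tibble.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path))
    abort(sprintf("table not found: %s", path),
          class = "spinemorph_format_error")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Save / load a pipeline configuration as YAML
#'
#' Round-trips losslessly: `read_pipeline_config(write_pipeline_config(x))`
#' reproduces `x` exactly.
#'
#' @param config A [pipeline_config()].
#' @param path YAML path.
#' @return `path` invisibly; the reader returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  if (!inherits(config, "pipeline_config"))
    abort("`config` must be a pipeline_config",
          class = "spinemorph_format_error")
  plain <- list(seed = config$seed,
                n_spines_per_group = config$n_spines_per_group,
                dendrite_length = config$dendrite_length,
                D = config$D, alpha = config$alpha,
                groups = lapply(config$groups, unclass),
                imaging = unclass(config$imaging),
                morphometry = unclass(config$morphometry))
  yaml::write_yaml(plain, path, precision = 17L)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("config not found: %s", path),
          class = "spinemorph_format_error")
  y <- yaml::read_yaml(path)
  for (f in c("seed", "groups", "imaging", "morphometry"))
    if (is.null(y[[f]]))
      abort(sprintf("config lacks field '%s'", f),
            class = "spinemorph_format_error")
  restore <- function(x, cls, ints = character()) {
    for (f in ints) x[[f]] <- as.integer(x[[f]])
    structure(x, class = cls)
  }
  structure(list(
    seed = as.integer(y$seed),
    groups = lapply(y$groups, restore, cls = "morph_params"),
    n_spines_per_group = as.integer(y$n_spines_per_group),
    dendrite_length = y$dendrite_length,
    imaging = restore(y$imaging, "imaging_config",
                      ints = c("n_z", "subsample_xy", "subsample_z")),
    morphometry = restore(y$morphometry, "morph_options",
                          ints = "n_profiles"),
    D = y$D, alpha = y$alpha), class = "pipeline_config")
}

#' Write a result bundle for a synthetic experiment
#'
#' Writes the measured morphometry, ground truth, per-branch density and
#' statistics tables as CSV plus a JSON summary; every file name is listed
#' in `manifest.json` together with the configuration hash, so a rerun with
#' the same configuration is byte-identical.
#'
#' @param experiment A `spinemorph_experiment`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_result_bundle <- function(experiment, dir) {
  if (!inherits(experiment, "spinemorph_experiment"))
    abort("`experiment` must be a spinemorph_experiment",
          class = "spinemorph_format_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(morphometry = "morphometry.csv", ground_truth = "ground_truth.csv",
             density = "density.csv", stats = "stats.csv")
  for (nm in names(files))
    write_table(experiment[[nm]], file.path(dir, files[[nm]]))
  cfg_hash <- rlang::hash(experiment$config)
  summary <- list(config_hash = cfg_hash,
                  n_spines = nrow(experiment$morphometry),
                  groups = unique(experiment$morphometry$group),
                  files = unname(files))
  jsonlite::write_json(summary, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
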