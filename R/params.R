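#' Morphological parameters of a spine population
#'
#' Bundles the per-group population description used by
#' [sample_spine_population()]: mean and standard deviation of spine length,
#' head width, and neck width, plus the linear spine density along the
#' dendrite. Neck length is not an independent dial: geometries are built so
#' that neck length equals spine length minus head width (the path runs from
#' the dendrite base through the neck and across the full head), which keeps
#' every sampled geometry internally consistent.
#'
#' Two presets are built in. `"wt"` reproduces the wild-type group means
#' (spine length 0.82 um, head width 0.44 um, 11.5 spines per 10 um);
#' `"appps1"` reproduces the APP/PS1 transgenic group (length 0.81 um, head
#' width 0.49 um, 8.7 spines per 10 um) whose necks are correspondingly
#' shorter and wider. Population sds are fixed at values that give the two
#' groups realistically overlapping distributions (see the methods vignette).
#'
#' @param mean_spine_length,mean_head_width,mean_neck_width Population means, um.
#' @param sd_spine_length,sd_head_width,sd_neck_width Population sds, um.
#' @param spine_density Spines per 10 um of dendrite.
#' @param group_label Free-text group name carried into downstream tables.
#' @return A `morph_params` list.
#' @examples
#' morph_params("wt")
#' morph_params("appps1")$mean_head_width
#' @export
morph_params <- function(group_label = "custom",
                         mean_spine_length = 0.82, sd_spine_length = 0.20,
                         mean_head_width = 0.44, sd_head_width = 0.09,
                         mean_neck_width = 0.160, sd_neck_width = 0.05,
                         spine_density = 11.5) {
  if (group_label == "wt") {
    # printed wild-type group means; sds are package population choices
    mean_spine_length <- 0.82; mean_head_width <- 0.44
    mean_neck_width <- 0.160; spine_density <- 11.5
  } else if (group_label == "appps1") {
    # transgenic group: same overall length, larger head, shorter+wider neck
    # with neck width set so the mean compartmentalization factor matches wt
    mean_spine_length <- 0.81; mean_head_width <- 0.49
    mean_neck_width <- 0.173; spine_density <- 8.7
  }
  stopifnot_positive(mean_spine_length = mean_spine_length,
                     mean_head_width = mean_head_width,
                     mean_neck_width = mean_neck_width,
                     spine_density = spine_density)
  for (s in c(sd_spine_length, sd_head_width, sd_neck_width))
    if (!is.finite(s) || s < 0)
      abort("feature sds must be finite and >= 0",
            class = "spinemorph_parameter_error")
  structure(list(group_label = group_label,
                 mean_spine_length = mean_spine_length,
                 sd_spine_length = sd_spine_length,
                 mean_head_width = mean_head_width,
                 sd_head_width = sd_head_width,
                 mean_neck_length = mean_spine_length - mean_head_width,
                 mean_neck_width = mean_neck_width,
                 sd_neck_width = sd_neck_width,
                 spine_density = spine_density),
            class = "morph_params")
}

#' @export
print.morph_params <- function(x, ...) {
  cat("<morph_params> group:", x$group_label, "\n")
  cat(sprintf("  spine length %.3f +/- %.3f um, head width %.3f +/- %.3f um\n",
              x$mean_spine_length, x$sd_spine_length,
              x$mean_head_width, x$sd_head_width))
  cat(sprintf("  neck width %.3f +/- %.3f um, density %.1f / 10 um\n",
              x$mean_neck_width, x$sd_neck_width, x$spine_density))
  invisible(x)
}

#' Imaging configuration for STED-like stack rendering
#'
#' Defaults mirror the acquisition settings the synthetic stacks emulate:
#' 40 nm square pixels, 10 z-sections 192 nm apart, and a lateral point
#' spread function of 50 nm FWHM. The axial FWHM defaults to 600 nm: the
#' depletion pattern sharpens the lateral direction only, so z stays at a
#' confocal-like scale and all measurements are taken on the lateral
#' maximum-intensity projection.
#'
#' @param pixel_size_xy Lateral pixel size, um.
#' @param z_step Axial step, um.
#' @param n_z Number of z-sections.
#' @param psf_fwhm_xy,psf_fwhm_z Gaussian PSF FWHM, um.
#' @param photons_per_peak Expected photon count at the brightest voxel.
#' @param background Background photons per voxel.
#' @param noise_model `"none"`, `"poisson"`, or `"poisson+gaussian"`.
#' @param gaussian_sd Read-noise sd (photons), used by `"poisson+gaussian"`.
#' @param subsample_xy,subsample_z Sub-voxel rasterization factors; geometry
#'   is rasterized on this finer grid before PSF convolution to avoid
#'   aliasing of 0.1-0.2 um necks on 40 nm pixels.
#' @return An `imaging_config` list.
#' @export
imaging_config <- function(pixel_size_xy = 0.040, z_step = 0.192, n_z = 10,
                           psf_fwhm_xy = 0.050, psf_fwhm_z = 0.600,
                           photons_per_peak = 200, background = 10,
                           noise_model = c("poisson", "none", "poisson+gaussian"),
                           gaussian_sd = 2, subsample_xy = 4L, subsample_z = 2L) {
  noise_model <- match.arg(noise_model)
  stopifnot_positive(pixel_size_xy = pixel_size_xy, z_step = z_step,
                     psf_fwhm_xy = psf_fwhm_xy, psf_fwhm_z = psf_fwhm_z,
                     photons_per_peak = photons_per_peak)
  if (n_z < 1) abort("`n_z` must be >= 1", class = "spinemorph_parameter_error")
  if (background < 0) abort("`background` must be >= 0",
                            class = "spinemorph_parameter_error")
  structure(list(pixel_size_xy = pixel_size_xy, z_step = z_step,
                 n_z = as.integer(n_z),
                 psf_fwhm_xy = psf_fwhm_xy, psf_fwhm_z = psf_fwhm_z,
                 photons_per_peak = photons_per_peak, background = background,
                 noise_model = noise_model, gaussian_sd = gaussian_sd,
                 subsample_xy = as.integer(subsample_xy),
                 subsample_z = as.integer(subsample_z)),
            class = "imaging_config")
}

#' @export
print.imaging_config <- function(x, ...) {
  cat(sprintf("<imaging_config> %d z x %.0f nm px, z-step %.0f nm\n",
              x$n_z, x$pixel_size_xy * 1000, x$z_step * 1000))
  cat(sprintf("  PSF FWHM %.0f nm lateral / %.0f nm axial; %s noise\n",
              x$psf_fwhm_xy * 1000, x$psf_fwhm_z * 1000, x$noise_model))
  invisible(x)
}
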