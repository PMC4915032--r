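#' Render a STED-like image stack from a ground-truth annotation
#'
#' Rasterizes the scene (dendrite shaft as a cylinder, spine necks as
#' capsules following each spine's path, heads as spheres) as a binary
#' occupancy grid at sub-voxel resolution, convolves it with an anisotropic
#' Gaussian point spread function, scales the result so the brightest voxel
#' equals `photons_per_peak`, adds the background, and applies the configured
#' photon noise. With `noise_model = "none"` the output is deterministic.
#'
#' @param annotation A tibble from [sample_spine_population()], or an empty
#'   annotation made with [empty_annotation()].
#' @param imaging An [imaging_config()].
#' @param seed Integer seed for the noise draw.
#' @return An `image_stack`: list with `voxels` (array indexed y, x, z),
#'   `pixel_size_xy`, `z_step`, `provenance`.
#' @examples
#' ann <- sample_spine_population(morph_params("wt"), 3, 4, seed = 1)
#' stk <- render_stack(ann, imaging_config(noise_model = "none"))
#' dim(stk$voxels)
#' @export
render_stack <- function(annotation, imaging = imaging_config(), seed = 1L) {
  if (!inherits(imaging, "imaging_config"))
    abort("`imaging` must be an imaging_config object",
          class = "spinemorph_parameter_error")
  px <- imaging$pixel_size_xy
  sub <- imaging$subsample_xy
  subz <- imaging$subsample_z
  fov_x <- attr(annotation, "fov_x")
  fov_y <- attr(annotation, "fov_y")
  if (is.null(fov_x)) fov_x <- attr(annotation, "dendrite_length")
  if (is.null(fov_x) || is.null(fov_y))
    abort("annotation lacks field-of-view attributes",
          class = "spinemorph_parameter_error")
  nx <- as.integer(ceiling(fov_x / px))
  ny <- as.integer(ceiling(fov_y / px))
  nz <- imaging$n_z
  dxs <- px / sub
  dzs <- imaging$z_step / subz
  z_mid <- nz * imaging$z_step / 2

  segs <- matrix(numeric(0), 0, 7)
  sph <- matrix(numeric(0), 0, 4)
  dr <- attr(annotation, "dendrite_radius")
  if (!is.null(dr) && nrow(annotation) >= 0 && !is.null(attr(annotation, "dendrite_y"))) {
    yd <- attr(annotation, "dendrite_y")
    segs <- rbind(segs, c(0, yd, z_mid, fov_x, yd, z_mid, dr))
  }
  if (nrow(annotation) > 0) {
    for (i in seq_len(nrow(annotation))) {
      p <- annotation$path[[i]]
      # neck capsules: all path segments up to the head boundary
      nb <- nrow(p) - 2L # last two points are head centre and tip
      r <- annotation$neck_width[i] / 2
      if (nb >= 2) {
        a <- p[seq_len(nb - 1L), , drop = FALSE]
        b <- p[1L + seq_len(nb - 1L), , drop = FALSE]
        segs <- rbind(segs, cbind(a[, 1], a[, 2], z_mid, b[, 1], b[, 2], z_mid, r))
      }
      sph <- rbind(sph, c(annotation$head_x[i], annotation$head_y[i], z_mid,
                          annotation$head_width[i] / 2))
    }
    out_of_fov <- annotation$head_x < 0 | annotation$head_x > fov_x |
      annotation$head_y < 0 | annotation$head_y > fov_y
    if (any(out_of_fov))
      abort("spine geometry extends outside the field of view",
            class = "spinemorph_geometry_error")
  }

  vol <- cpp_rasterize(ny * sub, nx * sub, nz * subz, dxs, dxs, dzs,
                       segs, sph)
  sig_xy <- imaging$psf_fwhm_xy / (2 * sqrt(2 * log(2))) / dxs
  sig_z <- imaging$psf_fwhm_z / (2 * sqrt(2 * log(2))) / dzs
  vol <- cpp_sepconv3(vol, gauss_kernel(sig_xy), gauss_kernel(sig_xy),
                      gauss_kernel(sig_z))
  vox <- cpp_downsample3(vol, sub, sub, subz)
  mx <- max(vox)
  if (mx > 0) vox <- vox * (imaging$photons_per_peak / mx)
  vox <- vox + imaging$background

  if (imaging$noise_model != "none") {
    dims <- dim(vox)
    vox <- with_seed(seed, {
      v <- stats::rpois(length(vox), lambda = as.numeric(vox))
      if (imaging$noise_model == "poisson+gaussian")
        v <- v + rnorm(length(v), 0, imaging$gaussian_sd)
      v
    })
    vox <- pmax(vox, 0)
    dim(vox) <- dims
  }
  new_image_stack(vox, px, imaging$z_step,
                  provenance = sprintf("spinemorph synthetic render (%d spines)",
                                       nrow(annotation)))
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3.5 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

new_image_stack <- function(voxels, pixel_size_xy, z_step, provenance = "") {
  if (any(voxels < 0)) abort("intensities must be >= 0",
                             class = "spinemorph_parameter_error")
  structure(list(voxels = voxels, pixel_size_xy = pixel_size_xy,
                 z_step = z_step, provenance = provenance),
            class = "image_stack")
}

#' An annotation with no spines (background-only scene)
#'
#' @param fov_x,fov_y Field of view, um.
#' @param dendrite Include the dendrite shaft cylinder?
#' @param dendrite_radius Shaft radius, um.
#' @return An empty annotation tibble carrying the scene attributes.
#' @export
empty_annotation <- function(fov_x = 4, fov_y = 4, dendrite = FALSE,
                             dendrite_radius = 0.30) {
  out <- tibble::tibble(spine_id = character(), group = character(),
                        spine_length = numeric(), head_width = numeric(),
                        neck_length = numeric(), neck_width = numeric(),
                        attach_x = numeric(), attach_y = numeric(),
                        head_x = numeric(), head_y = numeric(),
                        side = numeric(), angle = numeric(),
                        sagitta = numeric(), arc_sign = numeric(),
                        path = list())
  attr(out, "fov_x") <- fov_x
  attr(out, "fov_y") <- fov_y
  if (dendrite) {
    attr(out, "dendrite_radius") <- dendrite_radius
    attr(out, "dendrite_y") <- fov_y / 2
    attr(out, "dendrite_length") <- fov_x
  }
  out
}

#' Single-spine annotation with fully specified geometry
#'
#' Convenience constructor used by tests and measurement studies: one spine
#' with exact feature values, centred in its own small field of view.
#'
#' @param spine_length,head_width,neck_width Feature values, um.
#' @param sagitta Neck-arc sagitta, um.
#' @param angle In-plane tilt from the dendrite normal, radians.
#' @param dendrite Include the dendrite shaft?
#' @param fov Field-of-view side length, um (defaults to fit the spine).
#' @param dendrite_radius Shaft radius, um.
#' @return A one-row annotation tibble.
#' @export
single_spine_annotation <- function(spine_length = 0.82, head_width = 0.44,
                                    neck_width = 0.16, sagitta = 0,
                                    angle = 0, dendrite = TRUE, fov = NULL,
                                    dendrite_radius = 0.30) {
  neck_length <- spine_length - head_width
  if (neck_length <= 0) abort("spine_length must exceed head_width",
                              class = "spinemorph_parameter_error")
  if (is.null(fov)) fov <- 2 * (spine_length + dendrite_radius) + 1.6
  y_dend <- fov / 2 - (spine_length + dendrite_radius) / 2
  attach <- c(fov / 2, y_dend + dendrite_radius)
  g <- spine_path_geometry(attach, pi / 2 + angle, neck_length, head_width,
                           min(sagitta, 0.3 * neck_length), arc_sign = 1)
  out <- tibble::tibble(
    spine_id = "spine_1", group = "synthetic",
    spine_length = spine_length, head_width = head_width,
    neck_length = neck_length, neck_width = neck_width,
    attach_x = attach[1], attach_y = attach[2],
    head_x = g$head_centre[1], head_y = g$head_centre[2],
    side = 1, angle = angle, sagitta = min(sagitta, 0.3 * neck_length),
    arc_sign = 1, path = list(g$path))
  attr(out, "fov_x") <- fov
  attr(out, "fov_y") <- fov
  attr(out, "dendrite_length") <- fov
  if (dendrite) {
    attr(out, "dendrite_radius") <- dendrite_radius
    attr(out, "dendrite_y") <- y_dend
  }
  attr(out, "fov_y") <- fov
  out
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d px, %d z-sections (%.0f nm px, %.0f nm step)\n",
              d[2], d[1], d[3], x$pixel_size_xy * 1000, x$z_step * 1000))
  cat(sprintf("  intensity range [%.1f, %.1f]; %s\n", min(x$voxels),
              max(x$voxels), x$provenance))
  invisible(x)
}

#' Maximum-intensity projection of a stack
#'
#' Projects along z; all morphometric measurements are taken on this lateral
#' projection, matching the lateral-resolution advantage of the imaging.
#'
#' @param stack An `image_stack`.
#' @return A `spine_image`: list with `image` (matrix indexed y, x) and
#'   `pixel_size_xy`.
#' @export
project_stack <- function(stack) {
  if (!inherits(stack, "image_stack"))
    abort("`stack` must be an image_stack", class = "spinemorph_parameter_error")
  v <- stack$voxels
  img <- v[, , 1]
  nz <- dim(v)[3]
  if (nz > 1) for (k in 2:nz) img <- pmax(img, v[, , k])
  structure(list(image = img, pixel_size_xy = stack$pixel_size_xy),
            class = "spine_image")
}

#' @export
print.spine_image <- function(x, ...) {
  cat(sprintf("<spine_image> %d x %d px at %.0f nm\n", ncol(x$image),
              nrow(x$image), x$pixel_size_xy * 1000))
  invisible(x)
}

#' Display a projected image or stack
#'
#' @param object An `image_stack` or `spine_image`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.image_stack <- function(object, ...) {
  autoplot.spine_image(project_stack(object), ...)
}

#' @rdname autoplot.image_stack
#' @export
autoplot.spine_image <- function(object, ...) {
  px <- object$pixel_size_xy
  df <- expand.grid(row = seq_len(nrow(object$image)),
                    col = seq_len(ncol(object$image)))
  df$x <- (df$col - 0.5) * px
  df$y <- (df$row - 0.5) * px
  df$intensity <- as.numeric(object$image)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "photons") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}
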