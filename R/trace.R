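#' Morphometry options
#'
#' Tunables of the tracing and width-measurement operators, with defaults
#' documented in the methods vignette.
#'
#' @param n_profiles Number of neck profiles averaged by [neck_width()].
#' @param neck_profile_length,head_profile_length Profile lengths, um.
#' @param smooth_sigma_px Gaussian smoothing applied before tracing, pixels.
#' @param threshold_frac Tracing threshold as a fraction of (max - background).
#' @param boundary_ratio Neck/head boundary trigger: local width exceeding
#'   this multiple of the running median neck width.
#' @param boundary_backtrack_ratio After the trigger, the boundary is walked
#'   back along the rising flank to the first position still above this
#'   (smaller) multiple of the median neck width.
#' @param trace_margin Crop margin around seed and hint, um.
#' @param head_search_radius Search radius for the distal head extent and the
#'   head intensity maximum, um.
#' @param width_model `"projected_chord"` (default) divides the fitted FWHM
#'   by sqrt(3)/2, reporting the diameter of the cylinder/sphere that
#'   projects the observed chord profile; `"raw_fwhm"` reports the apparent
#'   FWHM unchanged.
#' @param psf_correction Apply the quadrature PSF correction
#'   `w^2 = w_meas^2 - w_psf^2`? Off by default (apparent widths).
#' @param psf_fwhm_xy Lateral PSF FWHM used when `psf_correction = TRUE`, um.
#' @param max_rel_rmse Gaussian-fit convergence gate (see [gaussian_fwhm()]).
#' @return A `morph_options` list.
#' @export
morph_options <- function(n_profiles = 3L, neck_profile_length = 0.8,
                          head_profile_length = 1.3, smooth_sigma_px = 1,
                          threshold_frac = 0.05, boundary_ratio = 1.5,
                          boundary_backtrack_ratio = 1.15,
                          trace_margin = 1.1, head_search_radius = 0.35,
                          width_model = c("projected_chord", "raw_fwhm"),
                          psf_correction = FALSE, psf_fwhm_xy = 0.050,
                          max_rel_rmse = 0.2) {
  structure(list(n_profiles = as.integer(n_profiles),
                 neck_profile_length = neck_profile_length,
                 head_profile_length = head_profile_length,
                 smooth_sigma_px = smooth_sigma_px,
                 threshold_frac = threshold_frac,
                 boundary_ratio = boundary_ratio,
                 boundary_backtrack_ratio = boundary_backtrack_ratio,
                 trace_margin = trace_margin,
                 head_search_radius = head_search_radius,
                 width_model = match.arg(width_model),
                 psf_correction = psf_correction,
                 psf_fwhm_xy = psf_fwhm_xy,
                 max_rel_rmse = max_rel_rmse),
            class = "morph_options")
}

smooth_image <- function(image, sigma_px) {
  if (sigma_px <= 0) return(image)
  v <- array(image, c(nrow(image), ncol(image), 1))
  k <- gauss_kernel(sigma_px)
  out <- cpp_sepconv3(v, k, k, 1)
  matrix(out, nrow(image), ncol(image))
}

um_to_px <- function(u, pixel_size) as.integer(round(u / pixel_size + 0.5))

# Profile length adapted to the distance from the spine base: near the base
# a full-length orthogonal profile on a tilted spine would run into the
# dendrite shaft and corrupt the baseline.
profile_len_at <- function(s, full_length) {
  min(full_length, max(0.30, 1.8 * s))
}
px_to_um <- function(i, pixel_size) (i - 0.5) * pixel_size

backtrack <- function(parent, from_idx) {
  ny <- nrow(parent)
  idx <- from_idx
  out <- integer(0)
  while (idx != 0) {
    out <- c(idx, out)
    idx <- parent[idx]
  }
  out
}

#' Trace the ridge path of one spine
#'
#' Follows the intensity ridge from a seed point at the dendrite edge,
#' through a hint inside the spine head, to the most distal above-threshold
#' point of the head. The image is Gaussian-smoothed, thresholded relative
#' to the local background, and the path is the intensity-weighted geodesic
#' (8-connected) across the bright region. The neck/head boundary is set
#' where the local profile width first exceeds `boundary_ratio` times the
#' running median of the neck width estimate.
#'
#' @param image A `spine_image`.
#' @param seed Numeric length-2 (um): point on the dendrite edge at the
#'   spine base.
#' @param hint Numeric length-2 (um): point inside the spine head.
#' @param options A [morph_options()].
#' @return A `spine_path`: tibble of path points `x`, `y` (um) with
#'   attributes `base_index`, `head_boundary_index`, `boundary_fallback`,
#'   `pixel_size`.
#' @export
trace_spine_path <- function(image, seed, hint, options = morph_options()) {
  px <- image$pixel_size_xy
  img <- image$image
  m <- options$trace_margin
  r0 <- max(1L, um_to_px(min(seed[2], hint[2]) - m, px))
  r1 <- min(nrow(img), um_to_px(max(seed[2], hint[2]) + m, px))
  c0 <- max(1L, um_to_px(min(seed[1], hint[1]) - m, px))
  c1 <- min(ncol(img), um_to_px(max(seed[1], hint[1]) + m, px))
  crop <- img[r0:r1, c0:c1, drop = FALSE]
  sm <- smooth_image(crop, options$smooth_sigma_px)
  bg <- median(sm)
  mx <- max(sm)
  thr <- bg + options$threshold_frac * (mx - bg)
  if (mx <= bg)
    abort("no structure above background near the seed",
          class = "spinemorph_tracing_error")
  cost <- 1 / pmax(sm - bg, 0.02 * (mx - bg))
  cost[sm < thr] <- 0

  to_local <- function(p) c(um_to_px(p[2], px) - r0 + 1L,
                            um_to_px(p[1], px) - c0 + 1L)
  # snap a point to the brightest unblocked pixel within `r` of its rounded
  # position (the annotated point may fall on a rim pixel dimmed below
  # threshold by partial voxel coverage)
  snap <- function(p, r = 2L) {
    rr <- pmax(1L, pmin(nrow(crop), (p[1] - r):(p[1] + r)))
    cc <- pmax(1L, pmin(ncol(crop), (p[2] - r):(p[2] + r)))
    grid <- expand.grid(r = unique(rr), c = unique(cc))
    open <- cost[cbind(grid$r, grid$c)] > 0
    if (!any(open)) return(NULL)
    grid <- grid[open, ]
    d2 <- (grid$r - p[1])^2 + (grid$c - p[2])^2
    grid <- grid[order(d2, -sm[cbind(grid$r, grid$c)]), ]
    c(grid$r[1], grid$c[1])
  }
  sp <- snap(to_local(seed))
  hp <- snap(to_local(hint))
  nyc <- nrow(crop)
  if (is.null(sp))
    abort("seed point is not on an above-threshold structure",
          class = "spinemorph_tracing_error")
  if (is.null(hp))
    abort("head hint is not on an above-threshold structure",
          class = "spinemorph_tracing_error")

  run1 <- cpp_grid_dijkstra(cost, sp[1], sp[2])
  hidx <- (hp[2] - 1L) * nyc + hp[1]
  if (!is.finite(run1$dist[hp[1], hp[2]]))
    abort("no connected above-threshold path from seed to hint",
          class = "spinemorph_tracing_error")
  run2 <- cpp_grid_dijkstra(cost, hp[1], hp[2])

  # most distal above-threshold point of the head: reachable from the hint,
  # within the head search radius, beyond the hint as seen from the seed.
  # Distality is the projection onto the seed->hint axis, so the target sits
  # at the far pole of the head rather than a lateral corner.
  rows <- row(cost); cols <- col(cost)
  eu_hint <- sqrt(((rows - hp[1]))^2 + ((cols - hp[2]))^2) * px
  axis <- c(hp[1] - sp[1], hp[2] - sp[2])
  axis <- axis / max(sqrt(sum(axis^2)), 1e-9)
  proj <- ((rows - sp[1]) * axis[1] + (cols - sp[2]) * axis[2]) * px
  cand <- is.finite(run2$dist) & eu_hint <= options$head_search_radius &
    run1$dist >= run1$dist[hp[1], hp[2]]
  if (!any(cand)) {
    tgt <- hidx
  } else {
    scores <- ifelse(cand, proj, -Inf)
    tgt <- which.max(scores)
  }
  path1 <- backtrack(run1$parent, hidx)
  path2 <- backtrack(run2$parent, tgt)
  idxs <- c(path1, path2[-1])
  prow <- ((idxs - 1L) %% nyc) + 1L
  pcol <- ((idxs - 1L) %/% nyc) + 1L
  xs <- px_to_um(pcol + c0 - 1L, px)
  ys <- px_to_um(prow + r0 - 1L, px)
  if (length(xs) < 3)
    abort("traced path degenerate (fewer than 3 points)",
          class = "spinemorph_tracing_error")

  # moving-average smoothing, endpoints pinned
  smooth_coord <- function(v, w = 5L) {
    if (length(v) < w + 2) return(v)
    pad <- c(rep(v[1], w %/% 2), v, rep(v[length(v)], w %/% 2))
    out <- as.numeric(stats::filter(pad, rep(1 / w, w), sides = 2))
    out <- out[!is.na(out)]
    out[1] <- v[1]
    out[length(out)] <- v[length(v)]
    out
  }
  xs <- smooth_coord(xs)
  ys <- smooth_coord(ys)

  bnd <- locate_head_boundary(image, xs, ys, options)
  out <- tibble::tibble(x = xs, y = ys)
  attr(out, "base_index") <- 1L
  attr(out, "head_boundary_index") <- bnd$index
  attr(out, "boundary_fallback") <- bnd$fallback
  attr(out, "pixel_size") <- px
  class(out) <- c("spine_path", class(out))
  out
}

path_arclength <- function(xs, ys) {
  c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
}

path_tangent <- function(xs, ys, i) {
  n <- length(xs)
  a <- max(1L, i - 2L)
  b <- min(n, i + 2L)
  t <- c(xs[b] - xs[a], ys[b] - ys[a])
  nrm <- sqrt(sum(t^2))
  if (nrm == 0) c(1, 0) else t / nrm
}

# Scan local half-max widths along the path and mark where the profile
# first widens into the head.
locate_head_boundary <- function(image, xs, ys, options) {
  s <- path_arclength(xs, ys)
  total <- s[length(s)]
  idxs <- which(s >= 0.12 & s <= total - 0.05)
  widths <- rep(NA_real_, length(idxs))
  for (k in seq_along(idxs)) {
    i <- idxs[k]
    tg <- path_tangent(xs, ys, i)
    nv <- c(-tg[2], tg[1])
    prof <- tryCatch(
      extract_line_profile(image, c(xs[i], ys[i]), nv,
                           profile_len_at(s[i], options$neck_profile_length)),
      error = function(e) NULL)
    if (!is.null(prof))
      widths[k] <- halfmax_width(prof$position, prof$intensity)
  }
  ok <- which(!is.na(widths))
  boundary <- NA_integer_
  for (k in ok) {
    prior <- widths[ok[ok < k]]
    if (length(prior) >= 3) {
      med <- median(prior)
      if (widths[k] > options$boundary_ratio * med) {
        # refine: walk back over the rising flank to where the widening began
        j <- k
        while (j > 1 && !is.na(widths[j - 1]) &&
               widths[j - 1] > options$boundary_backtrack_ratio * med) {
          j <- j - 1
        }
        boundary <- idxs[j]
        break
      }
    }
  }
  # geometric cap: the path terminates at the distal head edge, so the head
  # occupies roughly one apparent head-diameter of terminal arclength; stubby
  # spines whose necks are shorter than the running-median warm-up would
  # otherwise never trigger the ratio rule
  fallback <- FALSE
  if (length(ok) > 0) {
    w_big <- quantile(widths[ok], 0.9, names = FALSE)
    cap <- which.min(abs(s - max(0.08, total - 0.8 * w_big)))
    boundary <- if (is.na(boundary)) cap else min(boundary, cap)
  }
  if (is.na(boundary)) {
    fallback <- TRUE
    boundary <- which.min(abs(s - 0.6 * total))
  }
  boundary <- max(2L, min(boundary, length(xs) - 1L))
  list(index = boundary, fallback = fallback)
}

#' Curvature-following spine length
#'
#' Sum of segment lengths along the full traced polyline, from the dendrite
#' base to the distal edge of the head.
#'
#' @param path A `spine_path`, or any two-column matrix / data frame of
#'   ordered points (um).
#' @return Length in um.
#' @examples
#' spine_length(rbind(c(0, 0), c(0, 0.82)))
#' @export
spine_length <- function(path) {
  p <- as.matrix(as.data.frame(path)[, 1:2])
  if (nrow(p) < 2) abort("path needs at least 2 points",
                         class = "spinemorph_parameter_error")
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Neck length along a traced path
#'
#' Arclength from the base to the neck/head boundary.
#'
#' @param path A `spine_path`.
#' @return Length in um.
#' @export
neck_length <- function(path) {
  s <- path_arclength(path$x, path$y)
  s[attr(path, "head_boundary_index")]
}

apply_width_model <- function(fwhm, options) {
  w <- fwhm
  if (options$psf_correction)
    w <- sqrt(pmax(w^2 - options$psf_fwhm_xy^2, 0))
  if (options$width_model == "projected_chord") w <- w / (sqrt(3) / 2)
  w
}

#' Spine neck width from averaged orthogonal profiles
#'
#' Extracts `n_profiles` line profiles at evenly spaced arclength positions
#' along the neck, each orthogonal to the local path tangent, fits a
#' Gaussian to each and averages the converged FWHMs; the configured width
#' model then maps the apparent FWHM to the reported width.
#'
#' @param image A `spine_image`.
#' @param path A `spine_path`.
#' @param options A [morph_options()]; `options$n_profiles` controls the
#'   number of profiles.
#' @return A list: `width` (um), `profiles` (tibble of per-profile fits),
#'   `n_converged`.
#' @export
neck_width <- function(image, path, options = morph_options()) {
  b <- attr(path, "head_boundary_index")
  s <- path_arclength(path$x, path$y)
  lo <- min(0.10, 0.25 * s[b])
  hi <- s[b] - min(0.08, 0.25 * s[b])
  if (hi <= lo) {
    lo <- 0.25 * s[b]
    hi <- 0.75 * s[b]
  }
  np <- options$n_profiles
  targets <- lo + (seq_len(np) - 0.5) / np * (hi - lo)
  rows <- vector("list", np)
  for (k in seq_len(np)) {
    i <- which.min(abs(s - targets[k]))
    tg <- path_tangent(path$x, path$y, i)
    nv <- c(-tg[2], tg[1])
    fit <- tryCatch({
      prof <- extract_line_profile(image, c(path$x[i], path$y[i]), nv,
                                   profile_len_at(s[i],
                                                  options$neck_profile_length))
      gaussian_fwhm(prof, max_rel_rmse = options$max_rel_rmse)
    }, error = function(e) NULL)
    rows[[k]] <- tibble::tibble(
      profile = k, arclength = s[i],
      dir_x = nv[1], dir_y = nv[2],
      fwhm = if (is.null(fit)) NA_real_ else fit$fwhm,
      converged = !is.null(fit) && isTRUE(fit$converged))
  }
  prof_tbl <- dplyr::bind_rows(rows)
  okw <- prof_tbl$fwhm[prof_tbl$converged]
  if (length(okw) == 0)
    abort("no neck profile produced a converged Gaussian fit",
          class = "spinemorph_measurement_error")
  list(width = apply_width_model(mean(okw), options),
       profiles = prof_tbl, n_converged = length(okw))
}

#' Spine head width orthogonal to the neck axis
#'
#' Finds the intensity maximum of the head (within `head_search_radius` of
#' the post-boundary path), extracts the profile through it orthogonal to
#' the neck axis (the tangent at the neck/head boundary), fits a Gaussian,
#' and maps the FWHM through the configured width model.
#'
#' @inheritParams neck_width
#' @return A list: `width` (um), `fit` (a `gaussian_fit`), `centre` (um).
#' @export
head_width <- function(image, path, options = morph_options()) {
  b <- attr(path, "head_boundary_index")
  px <- image$pixel_size_xy
  img <- image$image
  hx <- path$x[b:nrow(path)]
  hy <- path$y[b:nrow(path)]
  cx <- mean(range(hx))
  cy <- mean(range(hy))
  # keep the search off the dendrite: never reach closer to the spine base
  # than to the head region
  base_d <- sqrt((cx - path$x[1])^2 + (cy - path$y[1])^2)
  rad <- min(options$head_search_radius, max(0.12, 0.6 * base_d))
  r0 <- max(1L, um_to_px(cy - rad, px)); r1 <- min(nrow(img), um_to_px(cy + rad, px))
  c0 <- max(1L, um_to_px(cx - rad, px)); c1 <- min(ncol(img), um_to_px(cx + rad, px))
  win <- smooth_image(img[r0:r1, c0:c1, drop = FALSE], 1)
  dmask <- outer(px_to_um(r0:r1, px) - cy, px_to_um(c0:c1, px) - cx,
                 function(dy, dx) sqrt(dx^2 + dy^2)) > rad
  win[dmask] <- -Inf
  wmax <- which(win == max(win), arr.ind = TRUE)[1, ]
  # sub-pixel refinement: intensity-weighted centroid of the bright core
  core <- which(win >= 0.5 * max(win[is.finite(win)]), arr.ind = TRUE)
  wts <- win[core]
  centre <- c(px_to_um(sum(core[, 2] * wts) / sum(wts) + c0 - 1L, px),
              px_to_um(sum(core[, 1] * wts) / sum(wts) + r0 - 1L, px))
  tg <- path_tangent(path$x, path$y, b)
  nv <- c(-tg[2], tg[1])
  fit <- tryCatch({
    prof <- extract_line_profile(image, centre, nv, options$head_profile_length)
    gaussian_fwhm(prof, max_rel_rmse = options$max_rel_rmse)
  }, error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$converged))
    abort("head profile did not produce a converged Gaussian fit",
          class = "spinemorph_measurement_error")
  list(width = apply_width_model(fit$fwhm, options), fit = fit, centre = centre)
}

#' Measure one annotated spine on a projected image
#'
#' Runs trace, length, neck width and head width; a failed sub-measurement
#' sets its flag and leaves the value `NA` rather than aborting the batch.
#'
#' @param image A `spine_image`.
#' @param spine One annotation row (with `attach_x/attach_y` seed and
#'   `head_x/head_y` hint, um).
#' @param options A [morph_options()].
#' @return One-row tibble of measured quantities and flags.
#' @export
measure_spine <- function(image, spine, options = morph_options()) {
  base <- tibble::tibble(
    spine_id = spine$spine_id, group = spine$group,
    spine_length = NA_real_, neck_length = NA_real_,
    neck_width = NA_real_, neck_width_n_profiles = NA_integer_,
    head_width = NA_real_,
    flag_trace = FALSE, flag_neck = FALSE, flag_head = FALSE,
    boundary_fallback = NA)
  path <- tryCatch(
    trace_spine_path(image, c(spine$attach_x, spine$attach_y),
                     c(spine$head_x, spine$head_y), options),
    error = function(e) NULL)
  if (is.null(path)) {
    base$flag_trace <- TRUE
    base$flag_neck <- TRUE
    base$flag_head <- TRUE
    return(base)
  }
  base$spine_length <- spine_length(path)
  base$neck_length <- neck_length(path)
  base$boundary_fallback <- attr(path, "boundary_fallback")
  nw <- tryCatch(neck_width(image, path, options), error = function(e) NULL)
  if (is.null(nw)) base$flag_neck <- TRUE else {
    base$neck_width <- nw$width
    base$neck_width_n_profiles <- nw$n_converged
  }
  hw <- tryCatch(head_width(image, path, options), error = function(e) NULL)
  if (is.null(hw)) base$flag_head <- TRUE else base$head_width <- hw$width
  base
}

#' Measure every spine of an annotation on its rendered stack
#'
#' @param stack An `image_stack` (projected internally) or a `spine_image`.
#' @param annotation Annotation tibble from [sample_spine_population()].
#' @param options A [morph_options()].
#' @return Tibble with one row per annotated spine.
#' @export
measure_spines <- function(stack, annotation, options = morph_options()) {
  image <- if (inherits(stack, "image_stack")) project_stack(stack) else stack
  purrr::map_dfr(seq_len(nrow(annotation)),
                 function(i) measure_spine(image, annotation[i, ], options))
}
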