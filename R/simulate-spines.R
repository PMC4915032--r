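# Run `code` with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so generators are pure functions of (params, seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Truncated-normal draws by rejection; sd = 0 collapses to the mean.
rtruncnorm_floor <- function(n, mean, sd, floor) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < floor)
  guard <- 0L
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < floor]
    guard <- guard + 1L
    if (guard > 10000L) abort("truncation floor rejects essentially all draws",
                              class = "spinemorph_parameter_error")
  }
  out
}

#' Sample a ground-truth spine population along a dendrite
#'
#' Draws per-spine morphological features from truncated normal distributions
#' (truncation at `floor_um`), places attachment points along a straight
#' dendrite at jittered regular spacing, and builds the physical path of each
#' spine (base at the dendrite surface, a neck that may curve as a circular
#' arc, and a spherical head). Neck length is derived as spine length minus
#' head width so every geometry is internally consistent; rows violating
#' `head_width > neck_width` or a positive neck length are redrawn.
#'
#' @param params A [morph_params()] object.
#' @param n_spines Number of spines to draw.
#' @param dendrite_length Dendrite length, um.
#' @param seed Integer seed; identical seeds give identical output.
#' @param floor_um Physical truncation floor for all features, um.
#' @param sagitta Neck-arc sagitta, um (0 = straight necks).
#' @param angle_jitter Half-range of the uniform in-plane tilt of each spine
#'   away from the dendrite normal, radians.
#' @param dendrite_radius Dendrite shaft radius, um.
#' @return A tibble with one row per spine (`spine_id`, `group`, the four
#'   features, attachment and head-centre coordinates in um, `side`, `angle`,
#'   `sagitta`, and a `path` list-column of lateral (x, y) polylines; the
#'   whole scene sits in the mid-plane of the stack in z). Attributes
#'   `dendrite_length`, `dendrite_radius`, `params` carry the scene.
#' @examples
#' spines <- sample_spine_population(morph_params("wt"), 20, 20, seed = 1)
#' mean(spines$spine_length)
#' @export
sample_spine_population <- function(params, n_spines, dendrite_length,
                                    seed = 1L, floor_um = 0.05,
                                    sagitta = 0, angle_jitter = 0.5,
                                    dendrite_radius = 0.30) {
  if (!inherits(params, "morph_params"))
    abort("`params` must be a morph_params object",
          class = "spinemorph_parameter_error")
  if (n_spines < 1) abort("`n_spines` must be >= 1",
                          class = "spinemorph_parameter_error")
  stopifnot_positive(dendrite_length = dendrite_length, floor_um = floor_um)
  if (sagitta < 0) abort("`sagitta` must be >= 0",
                         class = "spinemorph_parameter_error")
  with_seed(seed, {
    len <- rtruncnorm_floor(n_spines, params$mean_spine_length,
                            params$sd_spine_length, floor_um)
    head <- rtruncnorm_floor(n_spines, params$mean_head_width,
                             params$sd_head_width, floor_um)
    neckw <- rtruncnorm_floor(n_spines, params$mean_neck_width,
                              params$sd_neck_width, floor_um)
    # enforce geometric consistency: positive neck and head wider than neck
    bad <- which(len - head < floor_um | head <= neckw)
    guard <- 0L
    while (length(bad) > 0) {
      len[bad] <- rtruncnorm_floor(length(bad), params$mean_spine_length,
                                   params$sd_spine_length, floor_um)
      head[bad] <- rtruncnorm_floor(length(bad), params$mean_head_width,
                                    params$sd_head_width, floor_um)
      neckw[bad] <- rtruncnorm_floor(length(bad), params$mean_neck_width,
                                     params$sd_neck_width, floor_um)
      bad <- bad[len[bad] - head[bad] < floor_um | head[bad] <= neckw[bad]]
      guard <- guard + 1L
      if (guard > 10000L) abort("feature constraints reject all draws",
                                class = "spinemorph_parameter_error")
    }
    neckl <- len - head

    margin <- 0.8 # lateral clearance so tilted heads stay inside the FOV
    spacing <- dendrite_length / n_spines
    attach_x <- margin + (seq_len(n_spines) - 0.5) * spacing +
      runif(n_spines, -0.25, 0.25) * spacing
    side <- sample(c(-1, 1), n_spines, replace = TRUE)
    angle <- runif(n_spines, -angle_jitter, angle_jitter)
    arc_sign <- sample(c(-1, 1), n_spines, replace = TRUE)

    max_extent <- max(len) + 0.3
    fov_y <- 2 * (dendrite_radius + max_extent) + 0.4
    y_dend <- fov_y / 2

    paths <- vector("list", n_spines)
    head_cx <- head_cy <- numeric(n_spines)
    for (i in seq_len(n_spines)) {
      g <- spine_path_geometry(
        attach = c(attach_x[i], y_dend + side[i] * dendrite_radius),
        dir_angle = pi / 2 * side[i] + angle[i] * side[i],
        neck_length = neckl[i], head_width = head[i],
        sagitta = min(sagitta, 0.3 * neckl[i]), arc_sign = arc_sign[i])
      paths[[i]] <- g$path
      head_cx[i] <- g$head_centre[1]
      head_cy[i] <- g$head_centre[2]
    }

    out <- tibble::tibble(
      spine_id = paste0(params$group_label, "_", seq_len(n_spines)),
      group = params$group_label,
      spine_length = len, head_width = head,
      neck_length = neckl, neck_width = neckw,
      attach_x = attach_x, attach_y = y_dend + side * dendrite_radius,
      head_x = head_cx, head_y = head_cy,
      side = side, angle = angle,
      sagitta = pmin(sagitta, 0.3 * neckl), arc_sign = arc_sign,
      path = paths)
    attr(out, "dendrite_length") <- dendrite_length
    attr(out, "fov_x") <- dendrite_length + 2 * margin
    attr(out, "dendrite_radius") <- dendrite_radius
    attr(out, "dendrite_y") <- y_dend
    attr(out, "fov_y") <- fov_y
    attr(out, "params") <- params
    out
  })
}

# Build one spine path in the lateral plane: a neck that is either straight
# or a circular arc of given arclength and sagitta, then a straight run of
# one head diameter through the head centre. Returns the polyline (n x 2, um
# from image origin), the head centre, and the tangent at the head boundary.
spine_path_geometry <- function(attach, dir_angle, neck_length,
                                head_width, sagitta, arc_sign, n_arc = 16) {
  u <- c(cos(dir_angle), sin(dir_angle))
  if (sagitta <= 1e-9) {
    s <- seq(0, neck_length, length.out = n_arc)
    neck_pts <- cbind(attach[1] + s * u[1], attach[2] + s * u[2])
    tangent <- u
  } else {
    # solve arc angle phi from sagitta = (arclength/phi) * (1 - cos(phi/2))
    f <- function(phi) (neck_length / phi) * (1 - cos(phi / 2)) - sagitta
    phi <- stats::uniroot(f, c(1e-6, 2 * pi - 1e-6))$root
    R <- neck_length / phi
    # arc in a local frame: starts at origin with tangent +x, curves by phi
    t_loc <- seq(0, phi, length.out = n_arc)
    xs <- R * sin(t_loc)
    ys <- arc_sign * R * (1 - cos(t_loc))
    tan_loc <- c(cos(phi), arc_sign * sin(phi))
    # rotate local +x onto the base direction u
    rot <- matrix(c(u[1], u[2], -u[2], u[1]), 2, 2)
    pts <- cbind(xs, ys) %*% t(rot)
    neck_pts <- cbind(attach[1] + pts[, 1], attach[2] + pts[, 2])
    tangent <- as.numeric(rot %*% tan_loc)
  }
  b <- neck_pts[nrow(neck_pts), ]
  head_centre <- b + tangent * head_width / 2
  tip <- b + tangent * head_width
  path <- rbind(neck_pts, head_centre, tip)
  list(path = path, head_centre = head_centre, tangent = tangent)
}

#' Linear spine density
#'
#' @param n_spines Spine count.
#' @param dendrite_length Dendrite length, um.
#' @return Spines per 10 um of dendrite.
#' @examples
#' spine_density(23, 20) # 11.5
#' @export
spine_density <- function(n_spines, dendrite_length) {
  if (any(dendrite_length <= 0)) abort("`dendrite_length` must be > 0",
                                       class = "spinemorph_parameter_error")
  if (any(n_spines < 0)) abort("`n_spines` must be >= 0",
                               class = "spinemorph_parameter_error")
  n_spines / dendrite_length * 10
}
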