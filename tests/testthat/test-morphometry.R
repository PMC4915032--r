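test_that("spine_length sums polyline segments", {
  expect_equal(spine_length(rbind(c(0, 0), c(0, 0.82))), 0.82)
  expect_equal(spine_length(rbind(c(0, 0), c(0.3, 0), c(0.3, 0.4))), 0.7)
  th <- seq(0, pi / 2, length.out = 1000)
  quarter <- cbind(cos(th), sin(th))
  expect_lt(abs(spine_length(quarter) - pi / 2), 1e-4)
  expect_error(spine_length(rbind(c(0, 0))),
               class = "spinemorph_parameter_error")
})

test_that("a straight spine traces straight", {
  # field of view chosen so the spine axis sits on a pixel centre (the
  # half-pixel tie case is exercised by the isotropy test instead)
  ann <- single_spine_annotation(fov = 3.88)
  image <- project_stack(render_stack(ann, imaging_config(noise_model = "none")))
  path <- trace_spine_path(image, c(ann$attach_x, ann$attach_y),
                           c(ann$head_x, ann$head_y))
  a <- c(path$x[1], path$y[1])
  b <- c(path$x[nrow(path)], path$y[nrow(path)])
  u <- (b - a) / sqrt(sum((b - a)^2))
  dev <- vapply(seq_len(nrow(path)), function(i) {
    v <- c(path$x[i], path$y[i]) - a
    abs(v[1] * u[2] - v[2] * u[1])
  }, numeric(1))
  expect_lt(max(dev), 0.04) # under one pixel
})

test_that("a curved neck traces with the arc's length, not its chord", {
  sag <- 0.1
  fx <- noiseless_spine(spine_length = 1.1, head_width = 0.44,
                        neck_width = 0.18, sagitta = sag)
  ann <- fx$ann
  path <- trace_spine_path(fx$image, c(ann$attach_x, ann$attach_y),
                           c(ann$head_x, ann$head_y))
  measured <- spine_length(path)
  truth <- ann$spine_length
  expect_lt(abs(measured / truth - 1), 0.10)
  p <- ann$path[[1]]
  nb <- nrow(p) - 2
  chord <- sqrt(sum((p[nb, ] - p[1, ])^2)) + ann$head_width
  expect_gt(measured, chord)
})

test_that("a seed in the background raises a tracing error", {
  fx <- noiseless_spine()
  far <- c(0.3, 0.3)
  expect_error(trace_spine_path(fx$image, far, far + c(0.2, 0)),
               class = "spinemorph_tracing_error")
})

test_that("neck width with one profile equals that profile's fit", {
  fx <- noiseless_spine(spine_length = 0.95, neck_width = 0.18)
  ann <- fx$ann
  path <- trace_spine_path(fx$image, c(ann$attach_x, ann$attach_y),
                           c(ann$head_x, ann$head_y))
  opts <- morph_options(n_profiles = 1L, width_model = "raw_fwhm")
  nw <- neck_width(fx$image, path, opts)
  expect_equal(nw$n_converged, 1L)
  expect_equal(nw$width, nw$profiles$fwhm[1])
})

test_that("neck profile directions are orthogonal to analytic arc normals", {
  # profiles on a rendered curved neck: their recorded directions must be
  # orthogonal to the local tangent of the true arc within 2 degrees
  sag <- 0.08
  fx <- noiseless_spine(spine_length = 1.2, head_width = 0.44,
                        neck_width = 0.20, sagitta = sag)
  ann <- fx$ann
  truep <- ann$path[[1]]
  # measure along the exact arc geometry so the tangent comparison is
  # against analytic normals
  path <- tibble::tibble(x = truep[, 1], y = truep[, 2])
  attr(path, "base_index") <- 1L
  attr(path, "head_boundary_index") <- nrow(truep) - 2L
  attr(path, "boundary_fallback") <- FALSE
  attr(path, "pixel_size") <- fx$image$pixel_size_xy
  class(path) <- c("spine_path", class(path))
  nw <- neck_width(fx$image, path, morph_options(n_profiles = 3L))
  ts <- c(0, cumsum(sqrt(rowSums(diff(truep)^2))))
  # analytic tangent of the circular arc at a given arclength
  neckl <- ann$spine_length - ann$head_width
  f <- function(phi) (neckl / phi) * (1 - cos(phi / 2)) - sag
  phi <- stats::uniroot(f, c(1e-6, 2 * pi - 1e-6))$root
  base_dir <- pi / 2 # straight-up base direction for single_spine_annotation
  for (i in seq_len(nrow(nw$profiles))) {
    s_i <- nw$profiles$arclength[i]
    t_loc <- s_i / neckl * phi
    ang <- base_dir + t_loc # arc_sign = 1 curves the tangent forward
    tg <- c(cos(ang), sin(ang))
    dot <- abs(nw$profiles$dir_x[i] * tg[1] + nw$profiles$dir_y[i] * tg[2])
    expect_lt(asin(min(1, dot)) * 180 / pi, 2)
  }
})

test_that("head width recovers a wild-type-scale sphere within 10%", {
  fx <- noiseless_spine()
  ann <- fx$ann
  path <- trace_spine_path(fx$image, c(ann$attach_x, ann$attach_y),
                           c(ann$head_x, ann$head_y))
  hw <- head_width(fx$image, path)
  expect_lt(abs(hw$width / 0.44 - 1), 0.10)
})

test_that("a point-like head reads back at the resolution limit", {
  # sub-resolution head measured along its ground-truth path (tracing a
  # sub-resolution spine is not the property under test here)
  ann <- single_spine_annotation(spine_length = 0.56, head_width = 0.06,
                                 neck_width = 0.03, dendrite = FALSE)
  img <- project_stack(render_stack(ann, imaging_config(noise_model = "none")))
  truep <- ann$path[[1]]
  path <- tibble::tibble(x = truep[, 1], y = truep[, 2])
  attr(path, "base_index") <- 1L
  attr(path, "head_boundary_index") <- nrow(truep) - 2L
  attr(path, "boundary_fallback") <- FALSE
  attr(path, "pixel_size") <- img$pixel_size_xy
  class(path) <- c("spine_path", class(path))
  hw <- head_width(img, path, morph_options(width_model = "raw_fwhm",
                                            head_search_radius = 0.15))
  expect_lt(hw$width, 0.11)
  expect_gt(hw$width, 0.04)
})

test_that("width measurements repeat across noise seeds", {
  ann <- single_spine_annotation()
  ws <- vapply(c(21, 22), function(s) {
    img <- project_stack(render_stack(ann, imaging_config(), seed = s))
    path <- trace_spine_path(img, c(ann$attach_x, ann$attach_y),
                             c(ann$head_x, ann$head_y))
    head_width(img, path)$width
  }, numeric(1))
  expect_lt(abs(ws[1] / ws[2] - 1), 0.10)
})

test_that("measured neck width increases with true neck width", {
  widths <- c(0.10, 0.15, 0.20, 0.25, 0.30)
  measured <- vapply(widths, function(w) {
    fx <- noiseless_spine(spine_length = 1.0, head_width = 0.5,
                          neck_width = w)
    ann <- fx$ann
    path <- trace_spine_path(fx$image, c(ann$attach_x, ann$attach_y),
                             c(ann$head_x, ann$head_y))
    neck_width(fx$image, path)$width
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("in-plane rotation changes measured widths by less than 5%", {
  res <- vapply(c(0, pi / 6, pi / 4, pi / 3), function(a) {
    fx <- noiseless_spine(angle = a)
    ann <- fx$ann
    path <- trace_spine_path(fx$image, c(ann$attach_x, ann$attach_y),
                             c(ann$head_x, ann$head_y))
    c(neck_width(fx$image, path)$width, head_width(fx$image, path)$width)
  }, numeric(2))
  neckspread <- diff(range(res[1, ])) / mean(res[1, ])
  headspread <- diff(range(res[2, ])) / mean(res[2, ])
  expect_lt(neckspread, 0.05)
  expect_lt(headspread, 0.05)
})

test_that("measure_spines conserves rows and flags unmeasurable spines", {
  ann <- sample_spine_population(morph_params("wt"), 12, 12, seed = 8)
  st <- render_stack(ann, imaging_config(), seed = 9)
  res <- measure_spines(st, ann)
  expect_equal(nrow(res), nrow(ann))
  expect_identical(res$spine_id, ann$spine_id)

  # sabotage one seed: point it into empty background
  ann2 <- ann
  ann2$attach_y[3] <- 0.06
  ann2$head_y[3] <- 0.02
  res2 <- measure_spines(st, ann2)
  expect_true(res2$flag_trace[3])
  expect_true(is.na(res2$spine_length[3]))
  expect_equal(nrow(res2), nrow(ann2))
})
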