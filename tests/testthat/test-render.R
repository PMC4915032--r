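test_that("an empty scene renders as uniform background", {
  st <- render_stack(empty_annotation(2, 2),
                     imaging_config(noise_model = "none", background = 7,
                                    n_z = 4))
  expect_true(all(st$voxels == 7))
  expect_equal(dim(st$voxels), c(50, 50, 4))
})

test_that("the neck cross-profile is symmetric about the neck axis", {
  fx <- noiseless_spine()
  ann <- fx$ann
  ny <- ann$attach_y + (ann$spine_length - ann$head_width) / 2
  prof <- extract_line_profile(fx$image, c(ann$attach_x, ny), c(1, 0), 0.6)
  y <- prof$intensity
  rel <- abs(y - rev(y)) / max(y)
  expect_lt(max(rel), 0.01)
})

test_that("rendered neck width matches the 1D disc-PSF forward model", {
  fx <- noiseless_spine(spine_length = 0.9, neck_width = 0.20)
  ann <- fx$ann
  ny <- ann$attach_y + (ann$spine_length - ann$head_width) / 2
  prof <- extract_line_profile(fx$image, c(ann$attach_x, ny), c(1, 0), 0.8)
  measured <- halfmax_crossing_width(prof$position, prof$intensity)
  oracle <- disc_psf_profile(0.20)
  expected <- halfmax_crossing_width(oracle$x, oracle$y)
  expect_lt(abs(measured / expected - 1), 0.06)
})

test_that("rendering is linear in the photon budget", {
  ann <- single_spine_annotation()
  s1 <- render_stack(ann, imaging_config(noise_model = "none",
                                         photons_per_peak = 100,
                                         background = 0))
  s2 <- render_stack(ann, imaging_config(noise_model = "none",
                                         photons_per_peak = 200,
                                         background = 0))
  expect_equal(s2$voxels, 2 * s1$voxels, tolerance = 1e-12)
})

test_that("a point source reads back the lateral PSF width", {
  ann <- single_spine_annotation(spine_length = 0.54, head_width = 0.04,
                                 neck_width = 0.02, dendrite = FALSE)
  img <- project_stack(render_stack(ann, imaging_config(noise_model = "none")))
  prof <- extract_line_profile(img, c(ann$head_x, ann$head_y), c(1, 0), 0.5)
  w <- halfmax_crossing_width(prof$position, prof$intensity)
  expect_lt(abs(w - 0.050), 0.040) # within one pixel of quantization
})

test_that("rendering is deterministic without noise and seeded with noise", {
  ann <- single_spine_annotation()
  a <- render_stack(ann, imaging_config(noise_model = "none"))
  b <- render_stack(ann, imaging_config(noise_model = "none"))
  expect_identical(a$voxels, b$voxels)
  c1 <- render_stack(ann, imaging_config(), seed = 11)
  c2 <- render_stack(ann, imaging_config(), seed = 11)
  c3 <- render_stack(ann, imaging_config(), seed = 12)
  expect_identical(c1$voxels, c2$voxels)
  expect_false(identical(c1$voxels, c3$voxels))
  expect_true(all(c1$voxels >= 0))
})

test_that("geometry outside the field of view raises a geometry error", {
  ann <- single_spine_annotation()
  ann$head_y <- attr(ann, "fov_y") + 1
  expect_error(render_stack(ann, imaging_config(noise_model = "none")),
               class = "spinemorph_geometry_error")
})

test_that("maximum-intensity projection matches a brute-force oracle", {
  st <- render_stack(single_spine_annotation(), imaging_config(), seed = 4)
  img <- project_stack(st)
  v <- st$voxels
  brute <- apply(v, c(1, 2), max)
  expect_equal(img$image, brute)
  # single z-section projects to itself
  one <- new_image_stack(v[, , 1, drop = FALSE], 0.04, 0.192)
  expect_equal(project_stack(one)$image, v[, , 1])
  # an all-zero second plane cannot change the projection
  two <- new_image_stack(array(c(v[, , 1], 0 * v[, , 1]), c(dim(v)[1:2], 2)),
                         0.04, 0.192)
  expect_equal(project_stack(two)$image, v[, , 1])
})
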