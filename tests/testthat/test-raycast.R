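no_overlays <- function(...) render_settings(...,
  overlays = list(plane_grid = FALSE, coordinate_readout = FALSE))

test_that("trilinear sampling matches the 8-corner oracle", {
  set.seed(401)
  vol <- quantize_volume(random_raw_array(c(8, 8, 8), 2),
                         volume_metadata(c(8, 8, 8), 2))
  # at a voxel center: the voxel's code/255 exactly
  expect_identical(sample_channels(vol, c(2.5, 3.5, 4.5)),
                   as.numeric(vol$codes[, 5, 4, 3] / 255))
  # midway between two voxels along x: arithmetic mean
  expect_equal(sample_channels(vol, c(3, 3.5, 4.5)),
               as.numeric((vol$codes[, 5, 4, 3] + vol$codes[, 5, 4, 4]) / 2 / 255))
  # random points (including outside: zero padding)
  for (i in 1:50) {
    p <- runif(3, -1, 9)
    got <- sample_channels(vol, p)
    for (ch in 1:2)
      expect_equal(got[ch], o_trilinear(vol$codes, ch, p), tolerance = 1e-12)
  }
})

test_that("compositing follows the front-to-back over-operator", {
  # fully opaque first sample occludes everything after it
  acc <- composite_step(list(C = c(0, 0, 0), alpha = 0),
                        list(c_rgb = c(1, 0, 0), alpha_s = 1))
  expect_equal(acc, list(C = c(1, 0, 0), alpha = 1))
  acc2 <- composite_step(acc, list(c_rgb = c(0, 1, 0), alpha_s = 0.7))
  expect_equal(acc2, acc)

  # two half-opacity samples, intensities 1 then 0: C = 0.5, alpha = 0.75
  a <- composite_step(list(C = c(0, 0, 0), alpha = 0),
                      list(c_rgb = c(1, 1, 1), alpha_s = 0.5))
  b <- composite_step(a, list(c_rgb = c(0, 0, 0), alpha_s = 0.5))
  expect_equal(b$C, c(0.5, 0.5, 0.5))
  expect_equal(b$alpha, 0.75)

  # transparent sample is a no-op
  expect_equal(composite_step(a, list(c_rgb = c(1, 0, 1), alpha_s = 0)), a)
})

test_that("channel blending uses union opacity and weighted color", {
  red <- channel_transfer(0, 0.5, 1, alpha = 1, color = c(1, 0, 0))
  green <- channel_transfer(0, 0.5, 1, alpha = 1, color = c(0, 1, 0))

  one <- channel_blend(0.5, list(red))
  expect_equal(one$alpha_s, 0.5)
  expect_equal(one$c_rgb, c(1, 0, 0))

  # a_1 = a_2 = 0.5: union alpha 0.75, color (0.5, 0.5, 0)
  two <- channel_blend(c(0.5, 0.5), list(red, green))
  expect_equal(two$alpha_s, 0.75)
  expect_equal(two$c_rgb, c(0.5, 0.5, 0))

  # below dark: completely transparent
  dimmed <- channel_transfer(0.3, 0.5, 1)
  none <- channel_blend(c(0.2, 0.25), list(dimmed, dimmed))
  expect_equal(none$alpha_s, 0)
  expect_equal(none$c_rgb, c(0, 0, 0))

  # invisible channels are skipped
  hidden <- channel_transfer(0, 0.5, 1, color = c(0, 0, 1), visible = FALSE)
  mix <- channel_blend(c(0.5, 1), list(red, hidden))
  expect_equal(mix, one)
})

test_that("render_frame matches the independent integrator per pixel", {
  set.seed(402)
  cam <- camera_model(viewport = c(16, 16))
  settings <- no_overlays(background = c(0.1, 0.05, 0.2))
  vol <- quantize_volume(random_raw_array(c(8, 8, 8), 2),
                         volume_metadata(c(8, 8, 8), 2, c(1, 1, 1.8)))
  transfers <- list(channel_transfer(0.1, 0.65, 0.9, alpha = 0.8),
                    channel_transfer(0, 0.4, 1, alpha = 0.6, color = c(0, 1, 0)))
  for (mode in c("off", "front", "plane")) {
    view <- view_params(rotation = random_rotation(), zoom = 1.2,
                        pan = c(0.05, -0.04), plane_depth = 0.1,
                        clip_mode = mode)
    frame <- render_frame(vol, transfers, view, cam, settings)
    for (k in 1:25) {
      px <- sample(16, 1); py <- sample(16, 1)
      o <- o_render_pixel(vol, transfers, view, cam, settings, px, py)
      expect_equal(as.numeric(frame$rgb[py, px, ]), o$rgb, tolerance = 1e-9)
      expect_equal(frame$alpha[py, px], o$alpha, tolerance = 1e-9)
    }
  }
})

test_that("an all-zero volume renders the exact background", {
  vol <- voxcast:::volume_from_array(array(0L, c(1, 8, 8, 8)),
                                     volume_metadata(c(8, 8, 8), 1))
  bg <- c(0.25, 0.5, 0.75)
  frame <- render_frame(vol, default_transfers(1), view_params(),
                        camera_model(viewport = c(12, 10)), no_overlays(bg))
  expect_equal(dim(frame$rgb), c(10, 12, 3))
  for (k in 1:3) expect_true(all(frame$rgb[, , k] == bg[k]))
  expect_true(all(frame$alpha == 0))
})

test_that("a hot voxel projects to a pure-color pixel; misses show background", {
  vol <- make_synthetic_volume("single_voxel", dims = c(9, 9, 9),
                               num_channels = 1, at = c(4, 4, 4))
  # bright = 0.1: anything sampled near the voxel saturates immediately
  transfers <- list(channel_transfer(0, 0.5, 0.1, alpha = 1,
                                     color = c(1, 0, 0)))
  cam <- camera_model(viewport = c(33, 33))
  frame <- render_frame(vol, transfers, view_params(), cam, no_overlays())
  expect_equal(as.numeric(frame$rgb[17, 17, ]), c(1, 0, 0))
  # corner pixel ray misses the box entirely
  expect_equal(as.numeric(frame$rgb[1, 1, ]), c(0, 0, 0))
  expect_equal(frame$alpha[1, 1], 0)
})

test_that("accumulated alpha is bounded and content behind saturation is occluded", {
  set.seed(403)
  meta <- volume_metadata(c(8, 8, 8), 1)
  # opaque wall on the camera-side face (high z indices)
  arr <- array(0L, c(1, 8, 8, 8))
  arr[1, 8, , ] <- 255L
  wall <- voxcast:::volume_from_array(arr, meta)
  transfers <- list(channel_transfer(0, 0.5, 0.5, alpha = 1))
  cam <- camera_model(viewport = c(16, 16))
  f1 <- render_frame(wall, transfers, view_params(), cam, no_overlays())
  expect_true(all(f1$alpha <= 1))
  # altering voxels strictly behind the wall changes nothing
  arr2 <- arr
  arr2[1, 1:4, , ] <- sample(0:255, 4 * 64, replace = TRUE)
  behind <- voxcast:::volume_from_array(arr2, meta)
  f2 <- render_frame(behind, transfers, view_params(), cam, no_overlays())
  expect_identical(f1$rgb, f2$rgb)
  expect_identical(f1$alpha, f2$alpha)
})

test_that("front clipping degenerates to off/background at the extremes", {
  vol <- make_synthetic_volume("blobs", dims = c(12, 12, 12), num_channels = 2,
                               seed = 9)
  transfers <- default_transfers(2)
  cam <- camera_model(viewport = c(16, 16))
  R <- rotation_matrix("x", 25)
  off <- render_frame(vol, transfers,
                      view_params(rotation = R, clip_mode = "off"),
                      cam, no_overlays())
  # the whole box behind the plane (plane on the camera side): front == off
  front_all <- render_frame(vol, transfers,
                            view_params(rotation = R, plane_depth = 2,
                                        clip_mode = "front"),
                            cam, no_overlays())
  expect_identical(off$rgb, front_all$rgb)
  # nothing behind the plane (plane beyond the far edge): background only
  front_none <- render_frame(vol, transfers,
                             view_params(rotation = R, plane_depth = -2,
                                         clip_mode = "front"),
                             cam, no_overlays())
  expect_true(all(front_none$alpha == 0))
})

test_that("channel permutation symmetry holds", {
  set.seed(404)
  vol <- quantize_volume(random_raw_array(c(8, 8, 8), 2),
                         volume_metadata(c(8, 8, 8), 2))
  perm <- vol
  perm$codes <- vol$codes[c(2, 1), , , , drop = FALSE]
  perm$norm <- vol$norm[c(2, 1), ]
  transfers <- list(channel_transfer(0.05, 0.6, 0.9, alpha = 0.7,
                                     color = c(1, 0, 0)),
                    channel_transfer(0, 0.45, 1, alpha = 0.9,
                                     color = c(0, 0, 1)))
  cam <- camera_model(viewport = c(12, 12))
  view <- view_params(rotation = rotation_matrix("y", 30))
  f1 <- render_frame(vol, transfers, view, cam, no_overlays())
  f2 <- render_frame(perm, transfers[c(2, 1)], view, cam, no_overlays())
  expect_equal(f1$rgb, f2$rgb, tolerance = 1e-12)
})

test_that("render_slice equals plane-mode render_frame and the direct slice", {
  set.seed(405)
  vol <- quantize_volume(random_raw_array(c(8, 8, 8), 2),
                         volume_metadata(c(8, 8, 8), 2))
  transfers <- list(channel_transfer(0, 0.6, 0.9, alpha = 0.8),
                    channel_transfer(0.1, 0.4, 1, alpha = 0.9,
                                     color = c(0, 1, 0)))
  cam <- camera_model(viewport = c(16, 16))
  settings <- no_overlays(background = c(0.1, 0.1, 0.1))
  view <- view_params(rotation = rotation_matrix("z", 40), plane_depth = 0.07,
                      clip_mode = "plane")
  s1 <- render_slice(vol, transfers, view, cam, settings)
  s2 <- render_frame(vol, transfers, view, cam, settings)
  expect_identical(s1$rgb, s2$rgb)

  # axis-aligned slice: each pixel equals the transfer-mapped sample at its
  # plane hit point (single-sample definitional check via the components)
  ext <- volume_world_box(vol$meta)$extents
  k <- 5L  # 0-based slice index z = 5
  depth <- ((k + 0.5) / 8 - 0.5) * ext[3]
  aview <- view_params(plane_depth = depth, clip_mode = "plane")
  sl <- render_slice(vol, transfers, aview, cam, settings)
  for (px in c(4L, 8L, 13L)) for (py in c(3L, 9L)) {
    r <- generate_ray(cam, aview, c(px, py))
    # identity rotation: view z of the unit direction is r$direction[3]
    t <- (cam$camera_distance - depth) / (-r$direction[3])
    p <- r$origin + t * r$direction
    cont <- (p / ext + 0.5) * vol$meta$dims
    bl <- channel_blend(sample_channels(vol, cont), transfers)
    expected <- bl$alpha_s * bl$c_rgb + (1 - bl$alpha_s) * settings$background
    expect_equal(as.numeric(sl$rgb[py, px, ]), pmin(1, pmax(0, expected)),
                 tolerance = 1e-12)
    # the slice is a single sample: voxels behind it cannot contribute
    expect_equal(sl$alpha[py, px], bl$alpha_s, tolerance = 1e-12)
  }

  # plane outside the box: background frame
  gone <- render_slice(vol, transfers,
                       view_params(plane_depth = 3, clip_mode = "plane"),
                       cam, settings)
  expect_true(all(gone$alpha == 0))
})

test_that("overlays draw only when the plane is active and toggle cleanly", {
  vol <- make_synthetic_volume("blobs", dims = c(12, 12, 12), num_channels = 1,
                               seed = 2)
  transfers <- default_transfers(1)
  cam <- camera_model(viewport = c(48, 48))
  on <- render_settings()  # overlays on by default
  off_view <- view_params(clip_mode = "off")
  front_view <- view_params(clip_mode = "front", plane_depth = 0)

  # clip off: overlay settings do not change the frame
  f_off1 <- render_frame(vol, transfers, off_view, cam, on)
  f_off2 <- render_frame(vol, transfers, off_view, cam, no_overlays())
  expect_identical(f_off1$rgb, f_off2$rgb)

  # plane active: grid pixels (pure yellow) appear, readout pixels too
  f_on <- render_frame(vol, transfers, front_view, cam, on)
  f_clean <- render_frame(vol, transfers, front_view, cam, no_overlays())
  expect_false(identical(f_on$rgb, f_clean$rgb))
  yellow <- f_on$rgb[, , 1] == 1 & f_on$rgb[, , 2] == 1 & f_on$rgb[, , 3] == 0
  expect_gt(sum(yellow), 0)
  # grid only: still differs from clean, but no readout in the corner rows
  grid_only <- render_settings(overlays = list(plane_grid = TRUE,
                                               coordinate_readout = FALSE))
  f_grid <- render_frame(vol, transfers, front_view, cam, grid_only)
  expect_false(identical(f_grid$rgb, f_clean$rgb))
})

test_that("empty (NULL) volume renders a uniform background frame", {
  f <- render_frame(NULL, list(), view_params(),
                    camera_model(viewport = c(6, 5)),
                    no_overlays(background = c(0.3, 0.3, 0.3)))
  expect_equal(dim(f$rgb), c(5, 6, 3))
  expect_true(all(f$rgb == 0.3))
})
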