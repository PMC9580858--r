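# Front-to-back multichannel alpha-compositing raycaster.
#
# Emission/absorption model only (no lighting): per sample, each channel's
# transfer function yields an emissive intensity e_c, the channel's global
# alpha scales it into an opacity contribution a_c = e_c * alpha_c, channels
# combine by union opacity 1 - prod(1 - a_c) with opacity-weighted color
# average, and samples accumulate with the over-operator on premultiplied
# color. The march step is step_scale times the smallest world-space voxel
# extent; rays terminate early once accumulated alpha reaches the threshold.

#' Render settings
#'
#' @param background RGB background triple in `[0, 1]`.
#' @param step_scale multiplier on the base sampling step (the smallest
#'   world-space voxel extent). 1 samples at voxel scale.
#' @param early_termination_alpha accumulated-opacity threshold at which a
#'   ray stops marching, in `(0, 1]`.
#' @param overlays list of logical toggles `plane_grid` (yellow sampling-plane
#'   grid) and `coordinate_readout` (voxel index under the viewport center).
#'   Overlays draw only while the sampling plane is active
#'   (`clip_mode != "off"`).
#' @return an object of class `vox_settings`.
#' @export
render_settings <- function(background = c(0, 0, 0), step_scale = 1,
                            early_termination_alpha = 0.995,
                            overlays = list(plane_grid = TRUE,
                                            coordinate_readout = TRUE)) {
  background <- as.numeric(background)
  if (length(background) != 3L || any(background < 0) || any(background > 1))
    stop("background must be an RGB triple in [0, 1]", call. = FALSE)
  if (!is.finite(step_scale) || step_scale <= 0)
    stop("step_scale must be > 0", call. = FALSE)
  if (!is.finite(early_termination_alpha) || early_termination_alpha <= 0 ||
      early_termination_alpha > 1)
    stop("early_termination_alpha must be in (0, 1]", call. = FALSE)
  overlays <- list(plane_grid = isTRUE(overlays$plane_grid),
                   coordinate_readout = isTRUE(overlays$coordinate_readout))
  structure(list(background = background, step_scale = step_scale,
                 early_termination_alpha = early_termination_alpha,
                 overlays = overlays),
            class = "vox_settings")
}

#' Trilinear multichannel sample at a continuous voxel coordinate
#'
#' Interpolates the normalized codes (`code / 255`) of every channel at a
#' continuous 0-based voxel coordinate (voxel centers at index + 0.5), with
#' zero padding outside the volume.
#'
#' @param vol a `vox_volume`.
#' @param p continuous voxel coordinate `(cx, cy, cz)`.
#' @return numeric vector, one normalized value per channel.
#' @export
sample_channels <- function(vol, p) {
  stopifnot(inherits(vol, "vox_volume"))
  d <- vol$meta$dims
  g <- p - 0.5
  i0 <- floor(g)
  f <- g - i0
  out <- numeric(vol$meta$num_channels)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ix <- i0[1] + dx; iy <- i0[2] + dy; iz <- i0[3] + dz
    if (ix < 0 || ix >= d[1] || iy < 0 || iy >= d[2] || iz < 0 || iz >= d[3])
      next
    w <- (if (dx) f[1] else 1 - f[1]) *
         (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    out <- out + w * vol$codes[, iz + 1L, iy + 1L, ix + 1L] / 255
  }
  out
}

#' One front-to-back compositing step
#'
#' The over-operator on premultiplied color:
#' `C <- C + (1 - alpha) * alpha_s * c_rgb`; `alpha <- alpha + (1 - alpha) * alpha_s`.
#'
#' @param acc list with `C` (premultiplied RGB) and `alpha` accumulated so far.
#' @param sample list with `c_rgb` (sample color) and `alpha_s` (sample opacity).
#' @return updated accumulator list.
#' @export
composite_step <- function(acc, sample) {
  w <- (1 - acc$alpha) * sample$alpha_s
  list(C = acc$C + w * sample$c_rgb, alpha = acc$alpha + w)
}

#' Blend per-channel values into one sample color and opacity
#'
#' Per channel, emissive intensity `e_c = apply_transfer(value_c)` and
#' opacity contribution `a_c = e_c * alpha_c` (invisible channels skipped).
#' The sample opacity is the union `1 - prod(1 - a_c)`; the color is the
#' opacity-weighted average of channel colors (zero when nothing emits).
#'
#' @param values per-channel normalized intensities.
#' @param transfers list of [channel_transfer()], same length.
#' @return list with `c_rgb` and `alpha_s`.
#' @export
channel_blend <- function(values, transfers) {
  stopifnot(length(values) == length(transfers))
  one_minus <- 1; sum_a <- 0; col <- c(0, 0, 0)
  for (ch in seq_along(values)) {
    tr <- transfers[[ch]]
    if (!tr$visible) next
    a_c <- apply_transfer(tr, values[ch]) * tr$alpha
    one_minus <- one_minus * (1 - a_c)
    sum_a <- sum_a + a_c
    col <- col + a_c * tr$color
  }
  list(c_rgb = if (sum_a > 0) col / sum_a else c(0, 0, 0),
       alpha_s = 1 - one_minus)
}

transfer_matrices <- function(transfers) {
  nch <- length(transfers)
  tf <- matrix(0, nch, 6)
  colors <- matrix(0, nch, 3)
  for (ch in seq_len(nch)) {
    tr <- transfers[[ch]]
    stopifnot(inherits(tr, "vox_transfer"))
    co <- solve_coefficients(tr)
    tf[ch, ] <- c(co$a, co$b, co$c, tr$dark, tr$bright,
                  if (tr$visible) tr$alpha else 0)
    colors[ch, ] <- tr$color
  }
  list(tf = tf, colors = colors)
}

uniform_frame <- function(cam, background) {
  W <- cam$viewport[1]; H <- cam$viewport[2]
  rgb <- array(rep(background, each = H * W), dim = c(H, W, 3))
  structure(list(rgb = rgb, alpha = matrix(0, H, W)), class = "vox_frame")
}

#' Render one frame
#'
#' Casts one perspective ray per pixel through the volume box, clips the ray
#' segment per `view$clip_mode` (`off`: full segment; `front`: only the
#' sub-segment at or behind the sampling plane; `plane`: a single sample
#' exactly at the plane intersection), marches front-to-back with uniform
#' voxel-scale steps and early termination, then composites the accumulated
#' color over the background. Overlays (plane grid, coordinate readout) are
#' drawn last, and only while the plane is active.
#'
#' @param vol a `vox_volume` (or `NULL` for a uniform background frame).
#' @param transfers list of [channel_transfer()], one per channel.
#' @param view a [view_params()].
#' @param cam a [camera_model()].
#' @param settings a [render_settings()].
#' @return a `vox_frame`: `rgb` (H x W x 3 in `[0, 1]`) plus the
#'   pre-background accumulated `alpha` raster (H x W).
#' @export
render_frame <- function(vol, transfers, view, cam,
                         settings = render_settings()) {
  stopifnot(inherits(view, "vox_view"), inherits(cam, "vox_camera"),
            inherits(settings, "vox_settings"))
  if (is.null(vol)) return(uniform_frame(cam, settings$background))
  stopifnot(inherits(vol, "vox_volume"),
            length(transfers) == vol$meta$num_channels)
  W <- cam$viewport[1]; H <- cam$viewport[2]
  box <- volume_world_box(vol$meta)

  px <- rep(seq_len(W), times = H)
  py <- rep(seq_len(H), each = W)
  rays <- pixel_rays(cam, view, px, py)
  its <- ray_box_intersect(rays$origin, rays$dirs, box$half, cam$near, cam$far)
  t0 <- its$t0; t1 <- its$t1
  tplane <- (cam$camera_distance - view$plane_depth) * rays$len
  plane_mode <- 0L
  if (view$clip_mode == "front") t0 <- pmax(t0, tplane)
  if (view$clip_mode == "plane") plane_mode <- 1L

  tm <- transfer_matrices(transfers)
  step <- settings$step_scale * min(box$extents / vol$meta$dims)
  res <- .raycast_core(vol$codes, dim(vol$codes), box$extents, rays$origin,
                       rays$dirs, t0, t1, tplane, plane_mode, tm$tf,
                       tm$colors, step, settings$early_termination_alpha)
  out <- res$rgb + outer(1 - res$alpha, settings$background)
  rgb <- array(0, dim = c(H, W, 3))
  for (k in 1:3) rgb[, , k] <- t(matrix(out[, k], nrow = W, ncol = H))
  rgb[rgb < 0] <- 0; rgb[rgb > 1] <- 1
  alpha <- t(matrix(res$alpha, nrow = W, ncol = H))
  frame <- structure(list(rgb = rgb, alpha = alpha), class = "vox_frame")

  if (view$clip_mode != "off") {
    if (settings$overlays$plane_grid)
      frame <- draw_plane_grid(frame, vol$meta, view, cam, rays, tplane)
    if (settings$overlays$coordinate_readout)
      frame <- draw_coordinate_readout(frame, vol$meta, view, cam)
  }
  frame
}

#' Render an oblique slice through the sampling plane
#'
#' Specialization of [render_frame()] with `clip_mode = "plane"`: one sample
#' per ray exactly at the view-aligned plane, composited over the background.
#' A plane outside the box yields a background frame.
#'
#' @inheritParams render_frame
#' @return a `vox_frame`.
#' @export
render_slice <- function(vol, transfers, view, cam,
                         settings = render_settings()) {
  view$clip_mode <- "plane"
  render_frame(vol, transfers, view, cam, settings)
}

# --- overlays -------------------------------------------------------------

# Yellow grid lines at every 1/8 of the sampling plane's visible extent
# (the rotated box's projection onto the view plane), drawn only where the
# plane point lies inside the volume box.
draw_plane_grid <- function(frame, meta, view, cam, rays, tplane) {
  half <- volume_world_box(meta)$half
  R <- view$rotation
  hx <- sum(half * abs(R[1, ])); hy <- sum(half * abs(R[2, ]))
  if (hx <= 0 || hy <= 0) return(frame)
  # plane hit in view space, relative to the volume center's view position
  lx <- rays$dirs_view[, 1] * tplane - view$pan[1]
  ly <- rays$dirs_view[, 2] * tplane - view$pan[2]
  # inside-box test in the volume frame
  p <- sweep(rays$dirs * tplane, 2, rays$origin, "+")  # N x 3 hit points
  eps <- 1e-9
  inside <- abs(p[, 1]) <= half[1] + eps & abs(p[, 2]) <= half[2] + eps &
            abs(p[, 3]) <= half[3] + eps & tplane > 0
  # world units per pixel at the plane depth
  wpp <- (cam$camera_distance - view$plane_depth) *
    2 * tan(cam$fov_y / 2 * pi / 180) / (cam$viewport[2] * view$zoom)
  lw <- 0.75 * abs(wpp)
  near_line <- function(u, h) {
    cell <- 2 * h / 8
    d <- abs(((u + h) %% cell) - cell / 2)
    abs(u) <= h + eps & (cell / 2 - d) < lw
  }
  on_grid <- inside & (near_line(lx, hx) | near_line(ly, hy))
  if (!any(on_grid)) return(frame)
  W <- cam$viewport[1]; H <- cam$viewport[2]
  sel <- which(on_grid)
  rows <- (sel - 1L) %/% W + 1L
  cols <- (sel - 1L) %% W + 1L
  frame$rgb[cbind(rows, cols, 1L)] <- 1
  frame$rgb[cbind(rows, cols, 2L)] <- 1
  frame$rgb[cbind(rows, cols, 3L)] <- 0
  frame
}

# 3x5 bitmap glyphs for the coordinate readout
.vox_font <- list(
  "0" = c("111", "101", "101", "101", "111"),
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "3" = c("111", "001", "111", "001", "111"),
  "4" = c("101", "101", "111", "001", "001"),
  "5" = c("111", "100", "111", "001", "111"),
  "6" = c("111", "100", "111", "101", "111"),
  "7" = c("111", "001", "010", "010", "010"),
  "8" = c("111", "101", "111", "101", "111"),
  "9" = c("111", "101", "111", "001", "111"),
  "," = c("000", "000", "000", "010", "100"))

# Voxel index under the viewport center, printed bottom-left in white.
draw_coordinate_readout <- function(frame, meta, view, cam) {
  center <- c((cam$viewport[1] + 1) / 2, (cam$viewport[2] + 1) / 2)
  idx <- pick_voxel(cam, view, meta, center)
  if (identical(idx, "outside")) return(frame)
  text <- paste(idx, collapse = ",")
  H <- dim(frame$rgb)[1]; W <- dim(frame$rgb)[2]
  row0 <- H - 7L; col <- 3L
  for (chr in strsplit(text, "")[[1]]) {
    glyph <- .vox_font[[chr]]
    if (!is.null(glyph)) {
      for (gy in 1:5) {
        bits <- strsplit(glyph[gy], "")[[1]] == "1"
        for (gx in 1:3) {
          rr <- row0 + gy - 1L; cc <- col + gx - 1L
          if (bits[gx] && rr >= 1 && rr <= H && cc >= 1 && cc <= W)
            frame$rgb[rr, cc, ] <- 1
        }
      }
    }
    col <- col + 4L
  }
  frame
}

#' Write a frame as an 8-bit RGB PNG
#'
#' @param frame a `vox_frame`.
#' @param path output path; when `NULL`, the encoded PNG is returned as a
#'   raw vector.
#' @return `path` invisibly, or the PNG bytes when `path` is `NULL`.
#' @export
write_frame_png <- function(frame, path = NULL) {
  stopifnot(inherits(frame, "vox_frame"))
  if (is.null(path)) return(png::writePNG(frame$rgb))
  png::writePNG(frame$rgb, path)
  invisible(path)
}
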