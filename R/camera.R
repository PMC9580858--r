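# Perspective camera and world/volume coordinate transforms.
#
# Conventions (documented once, used everywhere):
# * The volume's physical box (dims * physical_voxel_size, anisotropy
#   honored) is centered at the origin of the volume frame and uniformly
#   scaled so its largest physical extent is 1 world unit.
# * View frame: camera at (0, 0, camera_distance) looking down -z, +y up.
#   A volume-frame point p maps to view space as R p + (pan_x, pan_y, 0):
#   world_rotation orients the volume, pan translates it in the view plane.
# * Zoom scales the ray grid in view space (dolly-free), so picking math is
#   unchanged by zoom.
# * Pixels are 1-based; pixel (i, j) is sampled at its center. Fractional
#   pixel coordinates are allowed (used by the projection round-trip).
# * The sampling plane is view-aligned (perpendicular to the view axis) at
#   signed depth plane_depth from the volume center, positive toward the
#   camera.
# * Voxel indices are 0-based, cells half-open, centers at index + 0.5.

#' View parameters
#'
#' @param rotation 3x3 orthonormal world rotation matrix (volume
#'   orientation); re-orthonormalized on construction.
#' @param zoom positive scale factor applied to the ray grid.
#' @param pan translation of the volume in the view plane, world units.
#' @param plane_depth signed distance of the view-aligned sampling plane from
#'   the volume center along the view axis, positive toward the camera.
#' @param clip_mode `"off"`, `"front"` (render only content at or behind the
#'   plane) or `"plane"` (render only the slice intersecting the plane).
#' @return an object of class `vox_view`.
#' @export
view_params <- function(rotation = diag(3), zoom = 1, pan = c(0, 0),
                        plane_depth = 0, clip_mode = c("off", "front", "plane")) {
  clip_mode <- match.arg(clip_mode)
  rotation <- check_rotation(rotation)
  zoom <- as.numeric(zoom)
  if (!is.finite(zoom) || zoom <= 0) stop("zoom must be > 0", call. = FALSE)
  pan <- as.numeric(pan)
  if (length(pan) != 2L || any(!is.finite(pan)))
    stop("pan must be a real 2-vector", call. = FALSE)
  plane_depth <- as.numeric(plane_depth)
  if (!is.finite(plane_depth)) stop("plane_depth must be finite", call. = FALSE)
  structure(list(rotation = rotation, zoom = zoom, pan = pan,
                 plane_depth = plane_depth, clip_mode = clip_mode),
            class = "vox_view")
}

# validate (tolerantly) then snap to the nearest rotation
check_rotation <- function(m) {
  m <- matrix(as.numeric(m), 3, 3)
  if (any(!is.finite(m))) stop("rotation must be finite", call. = FALSE)
  if (abs(det(m) - 1) > 1e-3 ||
      max(abs(crossprod(m) - diag(3))) > 1e-6)
    stop("not a rotation matrix (must be orthonormal with det 1)",
         call. = FALSE)
  orthonormalize(m)
}

# nearest rotation by polar decomposition (prevents drift over long
# scripted movies)
orthonormalize <- function(m) {
  s <- svd(m)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    s$u[, 3] <- -s$u[, 3]
    r <- s$u %*% t(s$v)
  }
  r
}

#' Rotation matrix about a named axis
#'
#' @param axis `"x"`, `"y"`, `"z"` or a 3-vector.
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  if (is.character(axis))
    axis <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
                   stop("axis must be x, y or z", call. = FALSE))
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Perspective camera model
#'
#' Defaults (30 degree vertical field of view, camera 2.5 world units from
#' the volume center) place the unit box at roughly 70% of the viewport
#' height at zoom 1.
#'
#' @param fov_y vertical field of view in degrees, in (0, 180).
#' @param viewport `(width, height)` in pixels.
#' @param camera_distance distance from camera to volume center, world units.
#' @param near,far clip distances along the ray, `0 < near < far`.
#' @return an object of class `vox_camera`.
#' @export
camera_model <- function(fov_y = 30, viewport = c(512, 512),
                         camera_distance = 2.5, near = 0.01, far = 10) {
  viewport <- as.integer(viewport)
  if (length(viewport) != 2L || any(viewport < 1L))
    stop("viewport must be >= 1x1", call. = FALSE)
  if (!(fov_y > 0 && fov_y < 180)) stop("fov_y must be in (0, 180)", call. = FALSE)
  if (!(near > 0 && near < far)) stop("require 0 < near < far", call. = FALSE)
  structure(list(fov_y = fov_y, viewport = viewport,
                 camera_distance = camera_distance, near = near, far = far),
            class = "vox_camera")
}

#' World-space bounding box of a volume
#'
#' Physical extents `dims * physical_voxel_size` are uniformly rescaled so
#' the largest extent equals 1 world unit; aspect ratios (anisotropy) are
#' preserved and the box is centered at the origin.
#'
#' @param meta a [volume_metadata()].
#' @return list with `extents` (x, y, z) and `half` (= extents / 2).
#' @export
volume_world_box <- function(meta) {
  stopifnot(inherits(meta, "vox_meta"))
  phys <- meta$dims * meta$physical_voxel_size
  extents <- phys / max(phys)
  list(extents = extents, half = extents / 2)
}

# view-space tangent coordinates of (possibly fractional) pixel centers
pixel_tangents <- function(cam, px, py) {
  th <- tan(cam$fov_y / 2 * pi / 180)
  aspect <- cam$viewport[1] / cam$viewport[2]
  list(sx = ((px - 0.5) / cam$viewport[1] * 2 - 1) * th * aspect,
       sy = (1 - (py - 0.5) / cam$viewport[2] * 2) * th)
}

# rays for a vector of pixels; origin is shared (single perspective center).
# Returns view-space dirs, volume-frame origin/dirs and per-ray 1/|d_view_z|
# (the length factor converting view-depth differences to ray parameter t).
pixel_rays <- function(cam, view, px, py) {
  tg <- pixel_tangents(cam, px, py)
  sx <- tg$sx / view$zoom
  sy <- tg$sy / view$zoom
  len <- sqrt(sx^2 + sy^2 + 1)
  dv <- cbind(sx / len, sy / len, -1 / len)
  R <- view$rotation
  origin_v <- c(0, 0, cam$camera_distance)
  pan3 <- c(view$pan, 0)
  origin_w <- as.vector(t(R) %*% (origin_v - pan3))
  dw <- dv %*% R  # each row: t(R) %*% dv_row
  list(dirs_view = dv, origin = origin_w, dirs = dw, len = len)
}

#' Generate the view ray for one pixel
#'
#' Perspective ray through the pixel center, zoom and pan applied in view
#' space, expressed in the volume frame (unit direction).
#'
#' @param cam a [camera_model()].
#' @param view a [view_params()].
#' @param pixel `(px, py)`, 1-based pixel coordinates (fractional allowed),
#'   `py` increasing downward.
#' @return list with `origin` and `direction` in the volume frame.
#' @export
generate_ray <- function(cam, view, pixel) {
  r <- pixel_rays(cam, view, pixel[1], pixel[2])
  list(origin = r$origin, direction = as.vector(r$dirs[1, ]))
}

# vectorized slab intersection of rays (shared origin) with the centered box;
# returns per-ray [t0, t1], clipped to [near, far]; t1 < t0 means miss
ray_box_intersect <- function(origin, dirs, half, near, far) {
  n <- nrow(dirs)
  t0 <- rep(near, n); t1 <- rep(far, n)
  for (ax in 1:3) {
    d <- dirs[, ax]; o <- origin[ax]; h <- half[ax]
    para <- abs(d) < 1e-300
    ta <- (-h - o) / d
    tb <- (h - o) / d
    lo <- pmin(ta, tb); hi <- pmax(ta, tb)
    lo[para] <- if (abs(o) <= h) -Inf else Inf
    hi[para] <- if (abs(o) <= h) Inf else -Inf
    t0 <- pmax(t0, lo); t1 <- pmin(t1, hi)
  }
  list(t0 = t0, t1 = t1)
}

# half-extent of the rotated box projected on the view axis (view z)
view_axis_half_extent <- function(meta, rotation) {
  half <- volume_world_box(meta)$half
  sum(half * abs(rotation[3, ]))
}

#' Pick the voxel under a screen location
#'
#' Intersects the pixel's view ray with the view-aligned sampling plane at
#' `plane_depth` and maps the hit point to a 0-based integer voxel index
#' (continuous coordinate floored; voxel centers at index + 0.5). This is the
#' quantitative-visualization primitive: a screen location plus a plane depth
#' identifies an exact position in the raw image stack.
#'
#' @param cam a [camera_model()].
#' @param view a [view_params()].
#' @param meta a [volume_metadata()].
#' @param pixel `(px, py)` 1-based pixel coordinates (fractional allowed).
#' @return integer `(ix, iy, iz)` 0-based voxel index, or the string
#'   `"outside"` when the plane point lies beyond the volume.
#' @export
pick_voxel <- function(cam, view, meta, pixel) {
  r <- pixel_rays(cam, view, pixel[1], pixel[2])
  # view z along the ray: z(t) = camera_distance - t / len
  t <- (cam$camera_distance - view$plane_depth) * r$len[1]
  if (t <= 0) return("outside")
  p_w <- r$origin + t * as.vector(r$dirs[1, ])
  ext <- volume_world_box(meta)$extents
  cont <- (p_w / ext + 0.5) * meta$dims
  idx <- floor(cont)
  if (any(idx < 0) || any(idx >= meta$dims)) return("outside")
  as.integer(idx)
}

#' Compose a delta rotation into the view
#'
#' Applies `world_rotation <- delta %*% world_rotation`, then snaps to the
#' nearest rotation by polar decomposition so orthonormality cannot drift
#' over long scripted movies.
#'
#' @param view a [view_params()].
#' @param delta 3x3 rotation matrix (orthonormal within 1e-6).
#' @return the updated `vox_view`.
#' @export
compose_rotation <- function(view, delta) {
  stopifnot(inherits(view, "vox_view"))
  delta <- matrix(as.numeric(delta), 3, 3)
  if (abs(det(delta) - 1) > 1e-3 ||
      max(abs(crossprod(delta) - diag(3))) > 1e-6)
    stop("delta is not a rotation matrix", call. = FALSE)
  view$rotation <- orthonormalize(delta %*% view$rotation)
  view
}

#' Default view for a volume
#'
#' Identity rotation, zoom 1, no pan, clip off, and the sampling plane at
#' +half the box's view-axis extent (the box edge toward the camera).
#'
#' @param meta a [volume_metadata()].
#' @return a `vox_view`.
#' @export
reset_view <- function(meta) {
  view_params(rotation = diag(3), zoom = 1, pan = c(0, 0),
              plane_depth = view_axis_half_extent(meta, diag(3)),
              clip_mode = "off")
}
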