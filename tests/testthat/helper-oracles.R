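# Independent oracles. These re-derive every contract from the documented
# conventions with their own arithmetic (numeric linear solve, brute-force
# loops), sharing no code path with the implementation they check.

# quadratic coefficients by numeric solution of the 3x3 Vandermonde system
o_solve_abc <- function(dark, bright, mid_eff) {
  m <- (dark + bright) / 2
  A <- rbind(c(dark^2, dark, 1),
             c(bright^2, bright, 1),
             c(m^2, m, 1))
  as.numeric(solve(A, c(0, 1, mid_eff)))
}

o_eval_transfer <- function(v, dark, bright, abc) {
  if (v <= dark) return(0)
  if (v >= bright) return(1)
  min(1, max(0, abc[1] * v^2 + abc[2] * v + abc[3]))
}

# brute-force 8-corner trilinear interpolation of codes/255
o_trilinear <- function(codes, ch, p) {
  d <- dim(codes)  # (nc, nz, ny, nx)
  g <- p - 0.5
  i0 <- floor(g)
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ix <- i0[1] + dx; iy <- i0[2] + dy; iz <- i0[3] + dz
    if (ix < 0 || ix >= d[4] || iy < 0 || iy >= d[3] || iz < 0 || iz >= d[2])
      next
    fx <- g[1] - i0[1]; fy <- g[2] - i0[2]; fz <- g[3] - i0[3]
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    acc <- acc + w * codes[ch, iz + 1, iy + 1, ix + 1] / 255
  }
  acc
}

# Straight-line integrator for one pixel, written from the documented
# conventions: perspective tangents, volume->view transform R p + (pan, 0),
# camera at (0, 0, cd) looking -z, slab box clipping, samples at
# t0 + (k + 0.5) step for k < ceiling(L/step - 0.5), per-sample transfer ->
# union opacity -> over-operator, background composite.
o_render_pixel <- function(vol, transfers, view, cam, settings, px, py) {
  W <- cam$viewport[1]; H <- cam$viewport[2]
  th <- tan(cam$fov_y * pi / 360)
  aspect <- W / H
  sx <- ((px - 0.5) / W * 2 - 1) * th * aspect / view$zoom
  sy <- (1 - (py - 0.5) / H * 2) * th / view$zoom
  len <- sqrt(sx^2 + sy^2 + 1)
  dv <- c(sx, sy, -1) / len
  R <- view$rotation
  ov <- c(0, 0, cam$camera_distance)
  pan3 <- c(view$pan, 0)
  o <- as.numeric(t(R) %*% (ov - pan3))
  dir <- as.numeric(t(R) %*% dv)

  phys <- vol$meta$dims * vol$meta$physical_voxel_size
  ext <- phys / max(phys)
  half <- ext / 2
  t0 <- cam$near; t1 <- cam$far
  for (ax in 1:3) {
    if (abs(dir[ax]) < 1e-300) {
      if (abs(o[ax]) > half[ax]) { t0 <- Inf; t1 <- -Inf }
      next
    }
    ta <- (-half[ax] - o[ax]) / dir[ax]
    tb <- (half[ax] - o[ax]) / dir[ax]
    t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
  }
  tplane <- (cam$camera_distance - view$plane_depth) * len
  if (view$clip_mode == "front") t0 <- max(t0, tplane)

  prep <- lapply(transfers, function(tr)
    list(abc = o_solve_abc(tr$dark, tr$bright, tr$mid), dark = tr$dark,
         bright = tr$bright, alpha = if (tr$visible) tr$alpha else 0,
         color = tr$color))
  step <- settings$step_scale * min(ext / vol$meta$dims)
  term <- settings$early_termination_alpha

  if (view$clip_mode == "plane") {
    ts <- if (tplane >= t0 && tplane <= t1) tplane else numeric()
  } else {
    n <- if (t1 > t0) max(0, ceiling((t1 - t0) / step - 0.5)) else 0
    ts <- if (n > 0) t0 + (seq_len(n) - 0.5) * step else numeric()
  }
  C <- c(0, 0, 0); a <- 0
  for (t in ts) {
    p <- o + t * dir
    cont <- (p / ext + 0.5) * vol$meta$dims
    one_minus <- 1; sum_a <- 0; col <- c(0, 0, 0)
    for (ch in seq_along(prep)) {
      pc <- prep[[ch]]
      if (pc$alpha <= 0) next
      v <- o_trilinear(vol$codes, ch, cont)
      ac <- o_eval_transfer(v, pc$dark, pc$bright, pc$abc) * pc$alpha
      one_minus <- one_minus * (1 - ac)
      sum_a <- sum_a + ac
      col <- col + ac * pc$color
    }
    as_ <- 1 - one_minus
    if (sum_a > 0) col <- col / sum_a else col <- c(0, 0, 0)
    C <- C + (1 - a) * as_ * col
    a <- a + (1 - a) * as_
    if (a >= term) break
  }
  list(rgb = C + (1 - a) * settings$background, alpha = a)
}

# project the center of 0-based voxel `idx` to continuous screen coordinates
# and its view-space depth (for use as plane_depth)
o_project_voxel <- function(meta, view, cam, idx) {
  phys <- meta$dims * meta$physical_voxel_size
  ext <- phys / max(phys)
  pw <- ((idx + 0.5) / meta$dims - 0.5) * ext
  pv <- as.numeric(view$rotation %*% pw) + c(view$pan, 0)
  d <- pv - c(0, 0, cam$camera_distance)
  th <- tan(cam$fov_y * pi / 360)
  aspect <- cam$viewport[1] / cam$viewport[2]
  sx <- view$zoom * d[1] / (-d[3])
  sy <- view$zoom * d[2] / (-d[3])
  px <- (sx / (th * aspect) + 1) / 2 * cam$viewport[1] + 0.5
  py <- (1 - sy / th) / 2 * cam$viewport[2] + 0.5
  list(px = px, py = py, depth = pv[3])
}

# 26-neighborhood local maxima count (strictly greater than all neighbors)
o_local_max_count <- function(f) {
  d <- dim(f)
  n <- 0L
  for (z in 2:(d[1] - 1)) for (y in 2:(d[2] - 1)) for (x in 2:(d[3] - 1)) {
    nb <- f[(z - 1):(z + 1), (y - 1):(y + 1), (x - 1):(x + 1)]
    if (f[z, y, x] == max(nb) && sum(nb == max(nb)) == 1L) n <- n + 1L
  }
  n
}

# random rotation matrix (QR of Gaussian matrix, det forced to +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random float test volume as a raw (nc, nz, ny, nx) array
random_raw_array <- function(dims, nc) {
  array(runif(prod(dims) * nc), dim = c(nc, rev(dims)))
}
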