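# Synthetic volume generation. Stands in for real fluorescence stacks
# (e.g. H2B-labelled nuclei in a spheroid): seeded Gaussian blobs emulate
# nuclei, a single hot voxel probes picking/occlusion, a gradient ramp
# probes transfer-function mapping.

run_seeded <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# Continuous Gaussian-blob fields, one (nz, ny, nx) array per channel.
# Centers, widths and amplitudes are drawn from the seeded RNG; the
# separable exponential is evaluated exactly on the voxel-center grid.
blob_fields <- function(dims, num_channels, seed, n_blobs) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  xs <- seq_len(nx) - 0.5; ys <- seq_len(ny) - 0.5; zs <- seq_len(nz) - 0.5
  sig_max <- min(dims) / 9
  run_seeded(seed, {
    lapply(seq_len(num_channels), function(ch) {
      f <- array(0, dim = c(nz, ny, nx))
      # rejection-sample centers with a minimum separation so distinct
      # blobs stay distinct peaks (nuclei don't coincide)
      centers <- matrix(NA_real_, n_blobs, 3)
      for (b in seq_len(n_blobs)) {
        for (try in 1:200) {
          cand <- runif(3, 0.15, 0.85) * dims
          if (b == 1L) break
          dmin <- min(sqrt(rowSums(sweep(centers[seq_len(b - 1L), ,
                                                 drop = FALSE], 2, cand)^2)))
          if (dmin >= 2.5 * sig_max) break
        }
        centers[b, ] <- cand
      }
      for (b in seq_len(n_blobs)) {
        cx <- centers[b, 1]; cy <- centers[b, 2]; cz <- centers[b, 3]
        sig <- runif(1, min(dims) / 16, sig_max)
        amp <- runif(1, 0.5, 1)
        gz <- exp(-(zs - cz)^2 / (2 * sig^2))
        gy <- exp(-(ys - cy)^2 / (2 * sig^2))
        gx <- exp(-(xs - cx)^2 / (2 * sig^2))
        f <- f + amp * (gz %o% gy %o% gx)
      }
      f
    })
  })
}

#' Generate a synthetic test volume
#'
#' Three deterministic fixtures:
#' * `blobs` — per-channel sums of isotropic Gaussian spots at seeded random
#'   centers, a stand-in for nuclei-like fluorescence; quantized per channel.
#' * `single_voxel` — one voxel (channel 0) at `at` set to code 255, all else
#'   zero; probes projection, picking and occlusion exactly.
#' * `gradient` — codes increase linearly along x in every channel.
#'
#' @param kind `"blobs"`, `"single_voxel"` or `"gradient"`.
#' @param dims voxel counts `(x, y, z)`; blobs require >= 4 per axis.
#' @param num_channels number of channels.
#' @param seed RNG seed; identical seeds give identical volumes.
#' @param n_blobs Gaussian spots per channel (blobs only).
#' @param at 0-based `(x, y, z)` index of the hot voxel (single_voxel only);
#'   defaults to the volume center.
#' @param physical_voxel_size physical voxel size in micrometers.
#' @return a `vox_volume`.
#' @export
make_synthetic_volume <- function(kind = c("blobs", "single_voxel", "gradient"),
                                  dims = c(16, 16, 16), num_channels = 2L,
                                  seed = 1L, n_blobs = 5L, at = NULL,
                                  physical_voxel_size = c(1, 1, 1)) {
  kind <- match.arg(kind)
  dims <- as.integer(dims)
  meta <- volume_metadata(dims, num_channels, physical_voxel_size)
  nc <- meta$num_channels
  if (kind == "blobs") {
    if (any(dims < 4L)) stop("blobs require dims >= 4 per axis", call. = FALSE)
    fields <- blob_fields(dims, nc, seed, n_blobs)
    raw <- array(0, dim = c(nc, rev(dims)))
    for (ch in seq_len(nc)) raw[ch, , , ] <- fields[[ch]]
    quantize_volume(raw, meta)
  } else if (kind == "single_voxel") {
    if (is.null(at)) at <- dims %/% 2L
    at <- as.integer(at)
    if (any(at < 0L) || any(at >= dims))
      stop("'at' index out of range", call. = FALSE)
    codes <- array(0L, dim = c(nc, rev(dims)))
    codes[1L, at[3] + 1L, at[2] + 1L, at[1] + 1L] <- 255L
    new_volume(meta, codes, cbind(rep(0, nc), rep(1, nc)))
  } else {
    nx <- dims[1]
    ramp <- if (nx > 1L) as.integer(floor(255 * (seq_len(nx) - 1L) / (nx - 1L) + 0.5))
            else 0L
    codes <- array(0L, dim = c(nc, rev(dims)))
    for (x in seq_len(nx)) codes[, , , x] <- ramp[x]
    new_volume(meta, codes, cbind(rep(0, nc), rep(1, nc)))
  }
}
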