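#' Volume metadata
#'
#' Describes a multichannel 3-D image stack: voxel counts, channel count and
#' the physical voxel size in micrometers. Physical size matters: rendering
#' honors anisotropic voxels (e.g. a z-step larger than the xy pixel size) by
#' scaling the volume into physical space.
#'
#' @param dims integer triple `(x, y, z)` of voxel counts, all >= 1.
#' @param num_channels number of channels, >= 1.
#' @param physical_voxel_size positive real triple `(x, y, z)` in micrometers.
#' @param channel_names optional character vector, one per channel;
#'   auto-filled `"ch0"`, `"ch1"`, ... when absent.
#' @return an object of class `vox_meta`.
#' @export
volume_metadata <- function(dims, num_channels = 1L,
                            physical_voxel_size = c(1, 1, 1),
                            channel_names = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("dims must be a positive integer triple (x, y, z)", call. = FALSE)
  num_channels <- as.integer(num_channels)
  if (length(num_channels) != 1L || is.na(num_channels) || num_channels < 1L)
    stop("num_channels must be a positive integer", call. = FALSE)
  physical_voxel_size <- as.numeric(physical_voxel_size)
  if (length(physical_voxel_size) != 3L ||
      any(!is.finite(physical_voxel_size)) || any(physical_voxel_size <= 0))
    stop("physical_voxel_size must be a positive real triple", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(num_channels) - 1L)
  channel_names <- as.character(channel_names)
  if (length(channel_names) != num_channels)
    stop("channel_names length must equal num_channels", call. = FALSE)
  structure(list(dims = dims, num_channels = num_channels,
                 physical_voxel_size = physical_voxel_size,
                 channel_names = channel_names),
            class = "vox_meta")
}

#' @export
print.vox_meta <- function(x, ...) {
  cat(sprintf("<vox_meta> %d x %d x %d voxels, %d channel(s), voxel %.3g x %.3g x %.3g um\n",
              x$dims[1], x$dims[2], x$dims[3], x$num_channels,
              x$physical_voxel_size[1], x$physical_voxel_size[2],
              x$physical_voxel_size[3]))
  invisible(x)
}

new_volume <- function(meta, codes, norm) {
  stopifnot(inherits(meta, "vox_meta"))
  expect_dim <- c(meta$num_channels, rev(meta$dims))
  if (!identical(dim(codes), as.integer(expect_dim)))
    stop(sprintf("codes dim (%s) does not match metadata (%s)",
                 paste(dim(codes), collapse = ","),
                 paste(expect_dim, collapse = ",")), call. = FALSE)
  storage.mode(codes) <- "integer"
  if (anyNA(codes) || min(codes) < 0L || max(codes) > 255L)
    stop("codes must be integers in [0, 255]", call. = FALSE)
  norm <- matrix(as.numeric(norm), ncol = 2,
                 dimnames = list(NULL, c("offset", "scale")))
  if (nrow(norm) != meta$num_channels || any(norm[, "scale"] < 0))
    stop("norm_records must be one non-negative (offset, scale) per channel",
         call. = FALSE)
  structure(list(meta = meta, codes = codes, norm = norm),
            class = "vox_volume")
}

#' @export
print.vox_volume <- function(x, ...) {
  print(x$meta)
  cat(sprintf("  codes in [%d, %d]\n", min(x$codes), max(x$codes)))
  invisible(x)
}

#' Quantize a floating-point volume to 8 bits per channel
#'
#' Applies per-channel linear normalization: each channel's range
#' `[min_c, max_c]` is mapped linearly onto codes 0..255 with round-half-up,
#' which minimizes the quantization error for the stored 8-bit volume. The
#' inverse affine map (offset = `min_c`, scale = `(max_c - min_c)/255`) is
#' recorded per channel so raw intensities can be recovered to within half a
#' code. A constant channel maps wholly to code 0 with scale 0.
#'
#' @param raw 4-D numeric array, dim `(channel, z, y, x)`, finite values.
#' @param meta a [volume_metadata()] object matching `raw`.
#' @return a `vox_volume`: quantized codes plus per-channel norm records.
#' @export
quantize_volume <- function(raw, meta) {
  stopifnot(inherits(meta, "vox_meta"))
  expect_dim <- as.integer(c(meta$num_channels, rev(meta$dims)))
  if (is.null(dim(raw)) || !identical(as.integer(dim(raw)), expect_dim))
    stop(sprintf("raw dim (%s) does not match metadata (%s)",
                 paste(dim(raw), collapse = ","),
                 paste(expect_dim, collapse = ",")), call. = FALSE)
  if (any(!is.finite(raw)))
    stop("raw volume contains non-finite values", call. = FALSE)
  nc <- meta$num_channels
  codes <- array(0L, dim = expect_dim)
  norm <- matrix(0, nrow = nc, ncol = 2)
  for (ch in seq_len(nc)) {
    v <- raw[ch, , , , drop = FALSE]
    lo <- min(v); hi <- max(v)
    if (hi > lo) {
      # round-half-up, not banker's rounding
      codes[ch, , , ] <- as.integer(floor(255 * (v - lo) / (hi - lo) + 0.5))
      norm[ch, ] <- c(lo, (hi - lo) / 255)
    } else {
      norm[ch, ] <- c(lo, 0)
    }
  }
  new_volume(meta, codes, norm)
}

#' Recover approximate raw intensities for one channel
#'
#' Inverts the per-channel linear quantization: `value = offset + scale * code`.
#' Exact up to half-code error `(max - min)/510`.
#'
#' @param vol a `vox_volume`.
#' @param channel 0-based channel index.
#' @return 3-D numeric array, dim `(z, y, x)`.
#' @export
dequantize <- function(vol, channel) {
  stopifnot(inherits(vol, "vox_volume"))
  channel <- as.integer(channel)
  if (length(channel) != 1L || is.na(channel) || channel < 0L ||
      channel >= vol$meta$num_channels)
    stop(sprintf("channel %d out of range [0, %d)", channel,
                 vol$meta$num_channels), call. = FALSE)
  ch <- channel + 1L
  out <- vol$norm[ch, "offset"] + vol$norm[ch, "scale"] * vol$codes[ch, , , ]
  array(out, dim = rev(vol$meta$dims))
}

# Build a vox_volume from a 4-D array that may be float or already 8-bit.
# 8-bit integer input is taken as codes with identity norm records.
volume_from_array <- function(arr, meta) {
  if (is.integer(arr) && !anyNA(arr) && min(arr) >= 0L && max(arr) <= 255L) {
    new_volume(meta, arr, cbind(rep(0, meta$num_channels),
                                rep(1, meta$num_channels)))
  } else {
    quantize_volume(arr, meta)
  }
}
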