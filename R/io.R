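# Volume I/O.
#
# Reference dialect: raw little-endian uint8 bytes (channel-major: x fastest,
# then y, z, channel) + JSON metadata sidecar. This round-trips codes
# byte-identically. TIFF support is best-effort baseline multi-page grayscale
# (uncompressed, little-endian, 8/16-bit unsigned or 32-bit float), pages in
# z-major channel-interleaved order (page = z * num_channels + channel).

#' Save a volume
#'
#' Writes the 8-bit codes plus a JSON metadata sidecar. The `raw` format is
#' the bit-exact reference dialect; `tiff` writes an uncompressed baseline
#' multi-page grayscale TIFF (z-major, channel-interleaved pages).
#'
#' @param vol a `vox_volume`.
#' @param path output file path (`.raw`/`.bin` or `.tif`/`.tiff`).
#' @param meta_path sidecar JSON path; defaults to `path` with a `.json`
#'   extension.
#' @param format `"auto"` (from extension), `"raw"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path, meta_path = NULL, format = "auto") {
  stopifnot(inherits(vol, "vox_volume"))
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "raw"
  if (is.null(meta_path)) meta_path <- paste0(sub("\\.[^.]+$", "", path), ".json")
  meta <- vol$meta
  side <- list(dims = meta$dims, num_channels = meta$num_channels,
               physical_voxel_size = meta$physical_voxel_size,
               channel_names = meta$channel_names,
               norm_records = unname(vol$norm),
               dtype = "uint8", order = "channel-major")
  writeLines(jsonlite::toJSON(side, digits = NA, auto_unbox = FALSE,
                              pretty = TRUE), meta_path)
  if (format == "raw") {
    # (nc, nz, ny, nx) -> x fastest, then y, z, channel
    arr <- aperm(vol$codes, c(4L, 3L, 2L, 1L))
    writeBin(as.raw(as.vector(arr)), path)
  } else {
    d <- meta$dims; nc <- meta$num_channels
    pages <- vector("list", d[3] * nc)
    for (z in seq_len(d[3])) for (ch in seq_len(nc))
      pages[[(z - 1L) * nc + ch]] <- vol$codes[ch, z, , ]
    write_tiff(path, pages, bits = 8L, sample_format = 1L)
  }
  invisible(path)
}

read_meta_sidecar <- function(meta_path,
                              required = c("dims", "num_channels",
                                           "physical_voxel_size")) {
  side <- jsonlite::fromJSON(readLines(meta_path, warn = FALSE),
                             simplifyVector = TRUE)
  for (f in required)
    if (is.null(side[[f]]))
      stop(sprintf("metadata file %s is missing required field '%s'",
                   meta_path, f), call. = FALSE)
  side
}

#' Load a volume
#'
#' Reads either the raw+JSON reference dialect or a multi-page grayscale TIFF
#' (pages in z-major channel-interleaved order). Float and 16-bit inputs are
#' quantized per [quantize_volume()]; 8-bit inputs are taken as codes with
#' identity norm records.
#'
#' @param path volume file (`.raw`/`.bin` or `.tif`/`.tiff`).
#' @param meta_path JSON metadata sidecar. Defaults to `path` with `.json`
#'   extension; for TIFF a missing sidecar falls back to a single channel and
#'   unit voxel size.
#' @return a `vox_volume`.
#' @export
load_volume <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  default_meta <- paste0(sub("\\.[^.]+$", "", path), ".json")
  if (is.null(meta_path)) meta_path <- default_meta
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (is_tiff) return(load_volume_tiff(path, meta_path))

  if (!file.exists(meta_path))
    stop("raw volume requires a JSON metadata sidecar; not found: ",
         meta_path, call. = FALSE)
  side <- read_meta_sidecar(meta_path)
  meta <- volume_metadata(side$dims, side$num_channels,
                          side$physical_voxel_size, side$channel_names)
  d <- meta$dims; nc <- meta$num_channels
  nbytes <- prod(d) * nc
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) != nbytes)
    stop(sprintf("field 'dims': raw payload is %d bytes but dims x channels imply %d",
                 length(bytes), nbytes), call. = FALSE)
  arr <- array(as.integer(bytes), dim = c(d[1], d[2], d[3], nc))
  codes <- aperm(arr, c(4L, 3L, 2L, 1L))
  norm <- if (!is.null(side$norm_records)) {
    matrix(as.numeric(side$norm_records), ncol = 2)
  } else cbind(rep(0, nc), rep(1, nc))
  new_volume(meta, codes, norm)
}

load_volume_tiff <- function(path, meta_path) {
  pages <- read_tiff(path)
  side <- if (file.exists(meta_path)) {
    # dims are implied by the TIFF pages themselves
    read_meta_sidecar(meta_path, required = "num_channels")
  } else list(num_channels = 1L)
  if (is.null(side$physical_voxel_size)) side$physical_voxel_size <- c(1, 1, 1)
  nc <- as.integer(side$num_channels)
  if (length(pages) %% nc != 0L)
    stop(sprintf("field 'num_channels': %d TIFF pages not divisible by %d channels",
                 length(pages), nc), call. = FALSE)
  nz <- length(pages) %/% nc
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  if (!is.null(side$dims) &&
      !identical(as.integer(side$dims), as.integer(c(nx, ny, nz))))
    stop(sprintf("field 'dims': sidecar says (%s) but TIFF pages imply (%d,%d,%d)",
                 paste(side$dims, collapse = ","), nx, ny, nz), call. = FALSE)
  meta <- volume_metadata(c(nx, ny, nz), nc, side$physical_voxel_size,
                          side$channel_names)
  arr <- array(0, dim = c(nc, nz, ny, nx))
  for (z in seq_len(nz)) for (ch in seq_len(nc))
    arr[ch, z, , ] <- pages[[(z - 1L) * nc + ch]]
  eightbit <- attr(pages, "bits") == 8L && attr(pages, "sample_format") == 1L
  if (eightbit) storage.mode(arr) <- "integer"
  volume_from_array(arr, meta)
}

# --- minimal baseline TIFF codec (little-endian, grayscale, uncompressed) ---

write_tiff <- function(path, pages, bits = 8L, sample_format = 1L) {
  stopifnot(length(pages) >= 1L, bits %in% c(8L, 16L, 32L),
            sample_format %in% c(1L, 3L))
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(as.integer(x), con, size = size,
                                  endian = "little")
  writeChar("II", con, eos = NULL); w(42L, 2)
  bytes_pp <- bits %/% 8L
  npage <- length(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  page_bytes <- W * H * bytes_pp
  ifd_size <- 2L + 10L * 12L + 4L
  data_start <- 8L + 4L  # header + first-IFD pointer handled below
  # layout: 8-byte header (incl. first IFD offset), then all page data,
  # then all IFDs
  data0 <- 8L
  ifd0 <- data0 + npage * page_bytes
  w(ifd0, 4)  # first IFD offset
  for (p in seq_len(npage)) {
    m <- pages[[p]]
    if (nrow(m) != H || ncol(m) != W) stop("TIFF pages must share dimensions")
    v <- as.vector(t(m))  # row-major: x fastest
    if (sample_format == 3L) {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      w(v, bytes_pp)
    }
  }
  entry <- function(tag, type, count, value) {
    w(tag, 2); w(type, 2); w(count, 4)
    if (type == 3L) { w(value, 2); w(0L, 2) } else w(value, 4)
  }
  for (p in seq_len(npage)) {
    w(10L, 2)  # entry count
    entry(256L, 4L, 1L, W)                         # ImageWidth
    entry(257L, 4L, 1L, H)                         # ImageLength
    entry(258L, 3L, 1L, bits)                      # BitsPerSample
    entry(259L, 3L, 1L, 1L)                        # Compression: none
    entry(262L, 3L, 1L, 1L)                        # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data0 + (p - 1L) * page_bytes)  # StripOffsets
    entry(277L, 3L, 1L, 1L)                        # SamplesPerPixel
    entry(278L, 4L, 1L, H)                         # RowsPerStrip
    entry(279L, 4L, 1L, page_bytes)                # StripByteCounts
    entry(339L, 3L, 1L, sample_format)             # SampleFormat
    nxt <- if (p < npage) ifd0 + p * ifd_size else 0L
    w(nxt, 4)
  }
  invisible(path)
}

read_tiff <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  rd <- function(pos, n, size, what = "integer") {
    readBin(bytes[pos:(pos + n * size - 1L)], what, n = n, size = size,
            endian = "little", signed = size >= 4L)
  }
  if (rawToChar(bytes[1:2]) != "II")
    stop("only little-endian TIFF is supported", call. = FALSE)
  if (rd(3L, 1L, 2L) != 42L) stop("not a TIFF file", call. = FALSE)
  ifd <- rd(5L, 1L, 4L)
  pages <- list()
  bits <- 8L; fmt <- 1L
  while (ifd != 0) {
    nent <- rd(ifd + 1L, 1L, 2L)
    tags <- list()
    for (i in seq_len(nent)) {
      e <- ifd + 2L + (i - 1L) * 12L + 1L
      tag <- rd(e, 1L, 2L); type <- rd(e + 2L, 1L, 2L)
      count <- rd(e + 4L, 1L, 4L)
      tsize <- c(1L, 1L, 2L, 4L)[min(type, 4L)]
      if (count * tsize <= 4L) {
        val <- rd(e + 8L, count, tsize)
      } else {
        off <- rd(e + 8L, 1L, 4L)
        val <- rd(off + 1L, count, tsize)
      }
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) stop("TIFF missing required tag ", tag, call. = FALSE)
      v
    }
    W <- need(256L); H <- need(257L)
    bits <- if (is.null(tags[["258"]])) 8L else tags[["258"]][1]
    fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]][1]
    comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]
    if (comp != 1L) stop("compressed TIFF is not supported", call. = FALSE)
    if (!bits %in% c(8L, 16L, 32L))
      stop("unsupported TIFF bit depth: ", bits, call. = FALSE)
    offs <- need(273L); cnts <- need(279L)
    raw_page <- do.call(c, lapply(seq_along(offs), function(s)
      bytes[(offs[s] + 1L):(offs[s] + cnts[s])]))
    vals <- if (fmt == 3L) {
      readBin(raw_page, "numeric", n = W * H, size = 4, endian = "little")
    } else {
      readBin(raw_page, "integer", n = W * H, size = bits %/% 8L,
              endian = "little", signed = FALSE)
    }
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = W, ncol = H))
    ifd <- rd(ifd + 2L + nent * 12L + 1L, 1L, 4L)
  }
  attr(pages, "bits") <- as.integer(bits)
  attr(pages, "sample_format") <- as.integer(fmt)
  pages
}
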