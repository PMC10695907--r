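#' @title Volume input/output
#'
#' @description Read and write grayscale volumes and binary masks with
#' voxel-size metadata. Two on-disk layouts are supported:
#'
#' * multi-page grayscale TIFF (8- or 16-bit unsigned; page = z slice),
#' * raw binary plus a plain-text sidecar, in C order (z slowest, x
#'   fastest), as `uint8`, `uint16` or `float32`.
#'
#' TIFF tags written by the available writer do not persist a voxel size,
#' so both layouts carry their metadata in a small `key=value` sidecar
#' file at `<path>.meta`. A foreign TIFF without a sidecar can still be
#' read by passing `voxel_edge_um` explicitly. 32-bit data go through the
#' raw layout, where they round-trip bit-exactly at float32 precision.
#'
#' @name volume_io
NULL

sidecar_path <- function(path) paste0(path, ".meta")

dtype_name <- function(bits) switch(as.character(bits),
  "8" = "uint8", "16" = "uint16", "32" = "float32",
  stop("unsupported bit depth: ", bits, call. = FALSE))

dtype_bits_of <- function(name) switch(name,
  uint8 = 8L, uint16 = 16L, float32 = 32L,
  stop("unsupported dtype in sidecar: ", name, call. = FALSE))

write_sidecar <- function(path, dims, dtype_bits, voxel_edge_um) {
  lines <- c(
    paste0("dims=", paste(dims, collapse = " ")),
    paste0("dtype=", dtype_name(dtype_bits)),
    "byte_order=little",
    paste0("voxel_edge_um=", format(voxel_edge_um, digits = 17)))
  writeLines(lines, sidecar_path(path))
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  lines <- readLines(sp, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1]]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")),
                 character(1))
  meta <- as.list(vals)
  names(meta) <- keys
  if (!is.null(meta$dims))
    meta$dims <- as.integer(strsplit(meta$dims, "\\s+")[[1]])
  if (!is.null(meta$voxel_edge_um))
    meta$voxel_edge_um <- as.numeric(meta$voxel_edge_um)
  meta
}

is_tiff_path <- function(path)
  tolower(tools::file_ext(path)) %in% c("tif", "tiff")

#' Read a 3D grayscale volume
#'
#' Reads a multi-page TIFF stack (slice index = z) or a raw binary file
#' with its `<path>.meta` sidecar. Voxel size comes from the sidecar
#' unless overridden with `voxel_edge_um`; a TIFF with neither is an
#' error.
#'
#' @param path file to read (`.tif`/`.tiff`, else treated as raw binary).
#' @param voxel_edge_um optional isotropic voxel edge length in
#'   micrometres, overriding file metadata.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, voxel_edge_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- read_sidecar(path)
  if (is_tiff_path(path)) {
    slices <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    dims2 <- lapply(slices, dim)
    if (length(unique(vapply(dims2, paste, character(1), collapse = "x"))) != 1L)
      stop("TIFF slices have inconsistent shapes", call. = FALSE)
    if (any(vapply(slices, function(s) length(dim(s)) != 2L, logical(1))))
      stop("only single-channel grayscale TIFF is supported", call. = FALSE)
    bits <- attr(slices[[1]], "bits.per.sample")
    if (is.null(bits) || !bits %in% c(8L, 16L, 32L))
      stop("unsupported TIFF bit depth: ", bits, call. = FALSE)
    ny <- dim(slices[[1]])[1]; nx <- dim(slices[[1]])[2]
    nz <- length(slices)
    arr <- array(0, dim = c(nz, ny, nx))
    for (z in seq_len(nz)) {
      s <- slices[[z]]
      if (bits < 32L) s <- round(s * (2^bits - 1)) # undo reader normalisation
      arr[z, , ] <- s
    }
    dims <- c(nz, ny, nx)
  } else {
    if (is.null(meta))
      stop("raw volume needs a sidecar file: ", sidecar_path(path),
           call. = FALSE)
    if (is.null(meta$dims) || length(meta$dims) != 3L || any(meta$dims < 1L))
      stop("sidecar must give three positive dims", call. = FALSE)
    dims <- meta$dims
    bits <- dtype_bits_of(meta$dtype %||% "uint8")
    endian <- switch(meta$byte_order %||% "little",
                     little = "little", big = "big",
                     stop("bad byte_order in sidecar", call. = FALSE))
    n <- prod(dims)
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- switch(as.character(bits),
      "8"  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE,
                                endian = endian)),
      "16" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                                endian = endian)),
      "32" = readBin(con, "numeric", n, size = 4, endian = endian))
    if (length(vals) != n)
      stop("raw file shorter than sidecar dims imply", call. = FALSE)
    # file is C-ordered (z slowest, x fastest); R arrays are column-major
    arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  }
  if (!is.null(meta$dims) && !identical(as.integer(meta$dims),
                                        as.integer(dims)))
    stop("sidecar dims disagree with file contents", call. = FALSE)
  edge <- voxel_edge_um %||% meta$voxel_edge_um
  if (is.null(edge))
    stop("voxel size unknown: no sidecar metadata for ", path,
         "; pass `voxel_edge_um`", call. = FALSE)
  voxel_volume(arr, voxel_edge_um = edge, dtype_bits = bits)
}

#' Write a 3D grayscale volume
#'
#' `.tif`/`.tiff` paths are written as uncompressed multi-page grayscale
#' TIFF (8- or 16-bit data only); any other path is written as raw binary
#' in C order. A `<path>.meta` sidecar carrying dims, dtype, byte order
#' and voxel size is always written alongside.
#'
#' @param volume a [voxel_volume()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  dims <- dim(volume$data)
  bits <- volume$dtype_bits
  if (is_tiff_path(path)) {
    if (bits == 32L)
      stop("32-bit volumes are not written as TIFF; use the raw layout ",
           "(non-.tif path)", call. = FALSE)
    if (any(volume$data < 0) || any(volume$data > 2^bits - 1) ||
        any(volume$data != round(volume$data)))
      stop("TIFF output requires integer data in [0, 2^bits - 1]",
           call. = FALSE)
    slices <- lapply(seq_len(dims[1]), function(z)
      volume$data[z, , , drop = TRUE] / (2^bits - 1))
    # single-slice volumes: keep matrix shape
    slices <- lapply(slices, function(s) {
      if (is.null(dim(s))) dim(s) <- dims[2:3]
      s
    })
    tiff::writeTIFF(slices, path, bits.per.sample = bits,
                    compression = "none", reduce = FALSE)
  } else {
    con <- file(path, "wb")
    vals <- as.vector(aperm(volume$data, c(3, 2, 1))) # C order on disk
    if (bits == 8L) {
      if (any(vals < 0 | vals > 255 | vals != round(vals)))
        stop("uint8 output requires integers in [0, 255]", call. = FALSE)
      writeBin(as.raw(vals), con)
    } else if (bits == 16L) {
      if (any(vals < 0 | vals > 65535 | vals != round(vals)))
        stop("uint16 output requires integers in [0, 65535]", call. = FALSE)
      v <- as.integer(vals)
      v <- ifelse(v > 32767L, v - 65536L, v) # two's-complement for writeBin
      writeBin(v, con, size = 2, endian = "little")
    } else {
      writeBin(as.numeric(vals), con, size = 4, endian = "little")
    }
    close(con)
  }
  write_sidecar(path, dims, bits, volume$voxel_edge_um)
  invisible(path)
}

#' Write a binary mask
#'
#' Stored as a 0/1-valued 8-bit volume (TIFF or raw, by extension) so that
#' [read_volume()]/[read_mask()] round-trip it exactly.
#'
#' @param mask a [binary_mask()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  vol <- voxel_volume(array(as.numeric(mask$data), dim = dim(mask$data)),
                      voxel_edge_um = mask$voxel_edge_um, dtype_bits = 8L)
  write_volume(vol, path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @inheritParams read_volume
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, voxel_edge_um = NULL) {
  vol <- read_volume(path, voxel_edge_um = voxel_edge_um)
  if (!all(vol$data %in% c(0, 1)))
    stop("file is not a 0/1 mask: ", path, call. = FALSE)
  binary_mask(vol$data != 0, voxel_edge_um = vol$voxel_edge_um)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
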