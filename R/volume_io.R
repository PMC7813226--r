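#' Read a stack of single-channel TIFF slices as a volume
#'
#' Slice `i` of the ordered list becomes plane `z = i`; all slices must share
#' width, height and sample depth (8- or 16-bit unsigned, single channel).
#' RGB or floating-point TIFFs are rejected.
#'
#' @param paths character vector of slice files, bottom slice first.
#' @param voxel_size_um voxel size `(dz, dy, dx)` in µm.
#' @param name volume name (default: directory of the first slice).
#' @return A [tomo_volume()] with `dims = (n_slices, height, width)`.
#' @export
read_tiff_stack <- function(paths, voxel_size_um = c(1, 1, 1), name = NULL) {
  if (length(paths) == 0L) err_empty_in("no TIFF slices given")
  slices <- vector("list", length(paths))
  bits <- NULL
  for (i in seq_along(paths)) {
    img <- tiff::readTIFF(paths[i], as.is = TRUE, info = TRUE)
    if (length(dim(img)) == 3L)
      err_format(sprintf("slice %s has %d channels; single-channel required",
                         paths[i], dim(img)[3]))
    fmt <- attr(img, "sample.format")
    if (!is.null(fmt) && !identical(fmt, "uint"))
      err_format(sprintf("slice %s has sample format '%s'; unsigned integer required",
                         paths[i], fmt))
    b <- attr(img, "bits.per.sample")
    if (is.null(b) || !b %in% c(8L, 16L))
      err_format(sprintf("slice %s: only 8- and 16-bit samples supported", paths[i]))
    if (is.null(bits)) bits <- b
    if (b != bits)
      err_format("mixed sample depths across slices")
    if (i > 1L && !identical(dim(img), dim(slices[[1]])))
      err_dim(sprintf("slice %s dimensions %s differ from first slice %s",
                      paths[i], paste(dim(img), collapse = "x"),
                      paste(dim(slices[[1]]), collapse = "x")))
    slices[[i]] <- img
  }
  h <- nrow(slices[[1]]); w <- ncol(slices[[1]])
  data <- array(0, c(length(paths), h, w))
  for (i in seq_along(slices)) data[i, , ] <- slices[[i]]
  if (is.null(name)) name <- basename(dirname(paths[1]))
  tomo_volume(data, bit_depth = bits, voxel_size_um = voxel_size_um, name = name)
}

#' Write a volume as a stack of single-channel TIFF slices
#'
#' @param vol a [tomo_volume()].
#' @param dir output directory (created if needed).
#' @param prefix slice file prefix; files are `prefix_0001.tif`, ...
#' @return character vector of written slice paths, in z order.
#' @export
write_tiff_stack <- function(vol, dir, prefix = "slice") {
  stopifnot(inherits(vol, "tomo_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  maxcode <- 2^vol$bit_depth - 1
  paths <- file.path(dir, sprintf("%s_%04d.tif", prefix, seq_len(vol$dims[1])))
  for (z in seq_len(vol$dims[1])) {
    tiff::writeTIFF(vol$data[z, , , drop = TRUE] / maxcode, paths[z],
                    bits.per.sample = vol$bit_depth)
  }
  paths
}

# sidecar schema: JSON object with dims, bit_depth, endianness, voxel_size_um,
# data_file (relative), name, and optional kind ("volume" | "mask" | "tags")
read_header <- function(header_path) {
  if (!file.exists(header_path)) err_io(paste("header not found:", header_path))
  hdr <- jsonlite::fromJSON(header_path)
  need <- c("dims", "bit_depth", "data_file")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) err_corrupt(paste("header missing fields:", paste(miss, collapse = ", ")))
  if (is.null(hdr$endianness)) hdr$endianness <- "little"
  if (is.null(hdr$voxel_size_um)) hdr$voxel_size_um <- c(1, 1, 1)
  if (is.null(hdr$name)) hdr$name <- tools::file_path_sans_ext(basename(header_path))
  if (is.null(hdr$kind)) hdr$kind <- "volume"
  if (!hdr$endianness %in% c("little", "big")) err_corrupt("endianness must be little or big")
  hdr
}

#' Read a raw binary volume with a plain-text sidecar header
#'
#' The sidecar is a JSON document declaring `dims` `(nz, ny, nx)`, `bit_depth`
#' (8 or 16), `endianness` (`little`/`big`, default little), `voxel_size_um`
#' and the relative `data_file`. Storage is slice-major: x varies fastest
#' within a slice, z slowest. The declared byte count must match the file.
#'
#' @param header_path path to the sidecar JSON.
#' @return A [tomo_volume()].
#' @export
read_raw <- function(header_path) {
  hdr <- read_header(header_path)
  if (!hdr$bit_depth %in% c(8, 16))
    err_format(sprintf("unsupported bit depth %s", hdr$bit_depth))
  dims <- as.integer(hdr$dims)
  if (length(dims) != 3L || any(dims <= 0)) err_corrupt("dims must be 3 positive integers")
  data_path <- file.path(dirname(header_path), hdr$data_file)
  if (!file.exists(data_path)) err_io(paste("data file not found:", data_path))
  nbytes_decl <- prod(dims) * (hdr$bit_depth / 8)
  nbytes <- file.info(data_path)$size
  if (nbytes != nbytes_decl)
    err_corrupt(sprintf("data file has %d bytes, header declares %d", nbytes, nbytes_decl))
  con <- file(data_path, "rb"); on.exit(close(con))
  n <- prod(dims)
  v <- readBin(con, "integer", n = n, size = hdr$bit_depth / 8, signed = FALSE,
               endian = hdr$endianness)
  # file order x-fastest -> array (nx, ny, nz) -> permute to [z, y, x]
  data <- aperm(array(as.numeric(v), dim = rev(dims)), c(3, 2, 1))
  tomo_volume(data, bit_depth = hdr$bit_depth, voxel_size_um = hdr$voxel_size_um,
              name = hdr$name)
}

#' Write a volume as raw binary plus a sidecar header
#'
#' Inverse of [read_raw()]: `read_raw(write_raw(vol, p))` reproduces the
#' volume bit-exactly (data, dims, bit depth, voxel size). Writes
#' `<out_prefix>.raw` and `<out_prefix>.json`.
#'
#' @param vol a [tomo_volume()].
#' @param out_prefix output path prefix.
#' @param endianness `"little"` (default) or `"big"`; always recorded in the
#'   header.
#' @param kind sidecar tag for what the grid holds: `"volume"`, `"mask"` or
#'   `"tags"`.
#' @param extra named list merged into the sidecar (e.g. provenance seed).
#' @return the header path, invisibly usable by [read_raw()].
#' @export
write_raw <- function(vol, out_prefix, endianness = "little", kind = "volume",
                      extra = NULL) {
  stopifnot(inherits(vol, "tomo_volume"))
  raw_path <- paste0(out_prefix, ".raw")
  hdr_path <- paste0(out_prefix, ".json")
  v <- as.vector(aperm(vol$data, c(3, 2, 1)))  # x fastest
  v <- as.integer(round(v))
  ok <- tryCatch({
    con <- file(raw_path, "wb")
    if (vol$bit_depth == 8L) {
      writeBin(as.raw(v), con)
    } else {
      lo <- as.raw(v %% 256L); hi <- as.raw(v %/% 256L)
      b <- if (endianness == "little") rbind(lo, hi) else rbind(hi, lo)
      writeBin(as.vector(b), con)
    }
    close(con)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) err_io(sprintf("cannot write %s: %s", raw_path, conditionMessage(ok)))
  hdr <- c(list(
    dims = vol$dims, bit_depth = vol$bit_depth, endianness = endianness,
    voxel_size_um = vol$voxel_size_um, data_file = basename(raw_path),
    name = vol$name, kind = kind
  ), extra)
  jsonlite::write_json(hdr, hdr_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  hdr_path
}

#' Write a selection mask as 8-bit raw (0/255) with sidecar
#' @param mask 3D logical array.
#' @param out_prefix output path prefix.
#' @param voxel_size_um voxel size recorded in the sidecar.
#' @return the header path.
#' @export
write_mask_raw <- function(mask, out_prefix, voxel_size_um = c(1, 1, 1)) {
  m <- as_mask_array(mask)
  vol <- tomo_volume(array(ifelse(m, 255, 0), dim(m)), bit_depth = 8,
                     voxel_size_um = voxel_size_um, name = "mask")
  write_raw(vol, out_prefix, kind = "mask")
}

#' Read a selection mask written by [write_mask_raw()]
#' @param header_path sidecar path.
#' @return 3D logical array.
#' @export
read_mask_raw <- function(header_path) {
  vol <- read_raw(header_path)
  vol$data > 0
}

#' Write a tag volume as 8-bit raw with sidecar
#' @param tags 3D integer array, values 0..255.
#' @param out_prefix output path prefix.
#' @param voxel_size_um voxel size recorded in the sidecar.
#' @param extra named list merged into the sidecar.
#' @return the header path.
#' @export
write_tags_raw <- function(tags, out_prefix, voxel_size_um = c(1, 1, 1),
                           extra = NULL) {
  tags <- check_tags(tags)
  vol <- tomo_volume(tags, bit_depth = 8, voxel_size_um = voxel_size_um,
                     name = "tags")
  write_raw(vol, out_prefix, kind = "tags", extra = extra)
}

#' Read a tag volume written by [write_tags_raw()]
#' @param header_path sidecar path.
#' @return 3D integer array.
#' @export
read_tags_raw <- function(header_path) {
  vol <- read_raw(header_path)
  array(as.integer(vol$data), vol$dims)
}
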