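#' Construct a CT volume
#'
#' A `tomo_volume` is a 3D grid of non-negative integer voxel values indexed
#' `[z, y, x]`, with a bit depth (8 or 16), a physical voxel size in
#' micrometres per axis `(dz, dy, dx)`, and a free-text name. This is the
#' container every import routine produces and every voxel operator consumes
#' (after [normalize()]).
#'
#' @param data 3D numeric array indexed `[z, y, x]` with values in
#'   `[0, 2^bit_depth - 1]`.
#' @param bit_depth integer, 8 or 16.
#' @param voxel_size_um positive numeric length 3 `(dz, dy, dx)` in µm, or a
#'   single value recycled to all axes.
#' @param name free-text identifier carried through processing.
#' @return An object of class `tomo_volume` with elements `data`, `dims`,
#'   `bit_depth`, `voxel_size_um`, `name`.
#' @examples
#' v <- tomo_volume(array(0:7, c(2, 2, 2)), bit_depth = 8)
#' dim(v$data)
#' @export
tomo_volume <- function(data, bit_depth = 16, voxel_size_um = c(1, 1, 1),
                        name = "volume") {
  if (!is.array(data) || length(dim(data)) != 3L)
    err_arg("volume data must be a 3D array indexed [z, y, x]")
  if (!bit_depth %in% c(8L, 16L)) err_format("bit_depth must be 8 or 16")
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    err_arg("voxel_size_um must be 3 positive values (dz, dy, dx)")
  maxcode <- 2^bit_depth - 1
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > maxcode)
    err_arg(sprintf("voxel values outside [0, %d] for %d-bit volume", maxcode, bit_depth))
  structure(
    list(
      data = data, dims = dim(data), bit_depth = as.integer(bit_depth),
      voxel_size_um = as.numeric(voxel_size_um), name = as.character(name)
    ),
    class = "tomo_volume"
  )
}

#' @export
print.tomo_volume <- function(x, ...) {
  cat(sprintf(
    "<tomo_volume '%s'> %d x %d x %d (z,y,x), %d-bit, voxel %.3g x %.3g x %.3g um\n",
    x$name, x$dims[1], x$dims[2], x$dims[3], x$bit_depth,
    x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]
  ))
  cat(sprintf("  value range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Normalize a volume to the unit interval
#'
#' Maps raw integer codes to `[0, 1]` by `v / (2^bit_depth - 1)`. All gradient
#' operators and threshold specifications are defined on this unit scale, where
#' the clamp of the gradient measures to `[0, 1]` is meaningful.
#'
#' @param vol a [tomo_volume()].
#' @return A `tomo_normvol`: same shape, `data` in `[0, 1]`.
#' @export
normalize <- function(vol) {
  stopifnot(inherits(vol, "tomo_volume"))
  structure(
    list(
      data = vol$data / (2^vol$bit_depth - 1), dims = vol$dims,
      voxel_size_um = vol$voxel_size_um, name = vol$name
    ),
    class = "tomo_normvol"
  )
}

#' @export
print.tomo_normvol <- function(x, ...) {
  cat(sprintf(
    "<tomo_normvol '%s'> %d x %d x %d (z,y,x), values in [%.4f, %.4f]\n",
    x$name, x$dims[1], x$dims[2], x$dims[3], min(x$data), max(x$data)
  ))
  invisible(x)
}

# accept a tomo_normvol or a bare numeric 3D array in [0,1]
as_norm_array <- function(nv) {
  if (inherits(nv, "tomo_normvol")) return(nv$data)
  if (is.array(nv) && length(dim(nv)) == 3L) return(nv)
  err_arg("expected a tomo_normvol or a 3D numeric array")
}

# accept a logical 3D array (selection mask)
as_mask_array <- function(mask) {
  if (is.array(mask) && length(dim(mask)) == 3L) return(mask != 0)
  err_arg("expected a 3D logical array selection mask")
}

#' Create an empty tag volume
#'
#' Tag volumes are integer label grids parallel to a scan: 0 means untagged,
#' tags run 1..255 (8-bit storage convention).
#'
#' @param dims integer length-3 `(nz, ny, nx)`.
#' @return integer 3D array of zeros.
#' @export
tag_volume <- function(dims) {
  array(0L, dim = as.integer(dims))
}

check_tags <- function(tags) {
  if (!is.array(tags) || length(dim(tags)) != 3L)
    err_arg("tag volume must be a 3D integer array")
  if (min(tags) < 0L || max(tags) > 255L)
    err_arg("tags must lie in [0, 255]")
  tags
}
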