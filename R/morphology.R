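# -- binary 3D morphology -----------------------------------------------------

# neighbour offsets for a radius-1 structuring element:
# 6 = faces, 18 = faces + edges, 26 = full 3x3x3 shell
se_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    err_arg("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
    "6"  = nz == 1L,
    "18" = nz >= 1L & nz <= 2L,
    "26" = nz >= 1L
  )
  off[keep, , drop = FALSE]
}

# shift a logical array by (dz,dy,dx), filling vacated voxels with `fill`
shift_fill <- function(m, dz, dy, dx, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, d)
  src_z <- max(1, 1 - dz):min(d[1], d[1] - dz)
  src_y <- max(1, 1 - dy):min(d[2], d[2] - dy)
  src_x <- max(1, 1 - dx):min(d[3], d[3] - dx)
  out[src_z + dz, src_y + dy, src_x + dx] <- m[src_z, src_y, src_x]
  out
}

#' Binary dilation of a 3D selection mask
#'
#' A voxel is set in the output iff itself or any neighbour under the chosen
#' connectivity was set. Grows object boundaries and fills small holes.
#' Volume borders are treated as outside (no wrap-around).
#'
#' @param mask 3D logical array.
#' @param connectivity structuring element: 6 (faces), 18 (faces + edges) or
#'   26 (full shell). Default 6, the most conservative growth.
#' @param iterations number of passes (>= 1).
#' @return 3D logical array, a superset of `mask`.
#' @export
dilate_mask <- function(mask, connectivity = 6L, iterations = 1L) {
  m <- as_mask_array(mask)
  if (iterations < 1L) err_arg("iterations must be >= 1")
  off <- se_offsets(connectivity)
  for (i in seq_len(iterations)) {
    out <- m
    for (j in seq_len(nrow(off)))
      out <- out | shift_fill(m, off[j, 1], off[j, 2], off[j, 3], FALSE)
    m <- out
  }
  m
}

#' Binary erosion of a 3D selection mask
#'
#' A voxel survives iff itself and all neighbours under the chosen
#' connectivity were set; out-of-volume neighbours count as unset. Removes
#' islands and small objects so only substantive structures remain.
#'
#' @inheritParams dilate_mask
#' @return 3D logical array, a subset of `mask`.
#' @export
erode_mask <- function(mask, connectivity = 6L, iterations = 1L) {
  m <- as_mask_array(mask)
  if (iterations < 1L) err_arg("iterations must be >= 1")
  off <- se_offsets(connectivity)
  for (i in seq_len(iterations)) {
    out <- m
    for (j in seq_len(nrow(off)))
      out <- out & shift_fill(m, off[j, 1], off[j, 2], off[j, 3], FALSE)
    m <- out
  }
  m
}

#' Morphology applied per tag of a label volume
#'
#' Runs [dilate_mask()] or [erode_mask()] on each tag's voxel set
#' independently. When dilation would grow two tags into the same voxel, the
#' smallest tag wins (deterministic tie-break in ascending tag order); voxels
#' already carrying another tag are never overwritten.
#'
#' @param tags 3D integer tag volume (0 = untagged).
#' @param op `"dilate"` or `"erode"`.
#' @param connectivity 6, 18 or 26.
#' @param iterations number of passes.
#' @return a new tag volume.
#' @export
morph_tags <- function(tags, op = c("dilate", "erode"), connectivity = 6L,
                       iterations = 1L) {
  op <- match.arg(op)
  tags <- check_tags(tags)
  present <- sort(setdiff(unique(as.vector(tags)), 0L))
  out <- array(0L, dim(tags))
  for (tg in present) {
    m <- tags == tg
    m2 <- if (op == "dilate") dilate_mask(m, connectivity, iterations)
          else erode_mask(m, connectivity, iterations)
    if (op == "dilate") {
      # claim only free voxels outside other tags' original territory
      claim <- m2 & out == 0L & (tags == 0L | tags == tg)
      out[claim] <- tg
    } else {
      out[m2] <- tg
    }
  }
  out
}
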