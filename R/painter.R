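# -- 3D freeform painter: spherical brush, tags, growing, extraction ----------

#' Voxels covered by a spherical brush
#'
#' A voxel is covered iff the Euclidean distance from its centre (integer
#' coordinates) to the brush centre is at most `radius_vox`; the footprint is
#' clipped to the volume. The brush is a sphere in voxel units (anisotropy is
#' ignored at paint time).
#'
#' @param center numeric `(z, y, x)` continuous coordinates, 1-based (voxel
#'   `(1,1,1)` has its centre at coordinate `(1,1,1)`).
#' @param radius_vox brush radius in voxels (>= 0).
#' @param dims volume dims `(nz, ny, nx)`.
#' @return integer matrix with columns `z, y, x`, one covered voxel per row.
#' @export
sphere_voxels <- function(center, radius_vox, dims) {
  if (radius_vox < 0) err_arg("radius must be >= 0")
  lo <- pmax(ceiling(center - radius_vox), 1L)
  hi <- pmin(floor(center + radius_vox), as.integer(dims))
  if (any(lo > hi)) return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("z", "y", "x"))))
  g <- expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3])
  d2 <- (g$z - center[1])^2 + (g$y - center[2])^2 + (g$x - center[3])^2
  m <- as.matrix(g[d2 <= radius_vox^2 + 1e-12, , drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, c("z", "y", "x"))
  m
}

#' Define a brush stroke
#'
#' @param centers numeric matrix (or single vector) of `(z, y, x)` continuous
#'   coordinates, one row per polyline vertex.
#' @param radius_vox sphere radius in voxels.
#' @param tag integer tag 1..255 written (paint) or cleared (erase).
#' @param mode `"paint"` or `"erase"`.
#' @return A `brush_stroke` list.
#' @export
brush_stroke <- function(centers, radius_vox, tag, mode = c("paint", "erase")) {
  mode <- match.arg(mode)
  if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1)
  centers <- as.matrix(centers)
  if (nrow(centers) < 1L || ncol(centers) != 3L)
    err_arg("centers must be a non-empty matrix of (z, y, x) rows")
  if (radius_vox < 0) err_arg("radius must be >= 0")
  tag <- as.integer(tag)
  if (tag < 0L || tag > 255L) err_arg("tag must lie in [0, 255]")
  structure(list(centers = centers, radius_vox = radius_vox, tag = tag, mode = mode),
            class = "brush_stroke")
}

# sample points along the stroke polyline densely enough that consecutive
# sphere stamps overlap: spacing <= 0.5 * radius (for radius 0, vertices only)
stroke_samples <- function(stroke) {
  cs <- stroke$centers
  if (nrow(cs) == 1L || stroke$radius_vox <= 0) return(cs)
  step <- 0.5 * stroke$radius_vox
  pts <- list(cs[1, , drop = FALSE])
  for (i in seq_len(nrow(cs) - 1L)) {
    a <- cs[i, ]; b <- cs[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / step))
    t <- seq_len(n) / n
    pts[[length(pts) + 1L]] <- cbind(a[1] + t * (b[1] - a[1]),
                                     a[2] + t * (b[2] - a[2]),
                                     a[3] + t * (b[3] - a[3]))
  }
  do.call(rbind, pts)
}

#' Apply a brush stroke to a tag volume
#'
#' Stamps the spherical footprint at every polyline vertex and along each
#' segment (sampled at half-radius spacing, so the swept tube has no gaps).
#' `paint` writes the stroke's tag over any prior value (last write wins);
#' `erase` resets covered voxels *of that same tag* to 0, protecting other
#' structures. With a `restrict` mask only voxels where the mask is true are
#' modified — the scriptable counterpart of painting inside an active
#' threshold selection.
#'
#' @param tags 3D integer tag volume.
#' @param stroke a [brush_stroke()].
#' @param restrict optional 3D logical mask limiting modification.
#' @return the updated tag volume.
#' @export
apply_stroke <- function(tags, stroke, restrict = NULL) {
  tags <- check_tags(tags)
  stopifnot(inherits(stroke, "brush_stroke"))
  if (stroke$mode == "paint" && stroke$tag == 0L)
    err_arg("paint mode requires tag >= 1")
  if (!is.null(restrict)) {
    restrict <- as_mask_array(restrict)
    if (!identical(dim(restrict), dim(tags))) err_dim("restrict mask dims differ")
  }
  d <- dim(tags)
  pts <- stroke_samples(stroke)
  cov <- array(FALSE, d)
  for (i in seq_len(nrow(pts))) {
    vox <- sphere_voxels(pts[i, ], stroke$radius_vox, d)
    if (nrow(vox)) cov[vox] <- TRUE
  }
  if (!is.null(restrict)) cov <- cov & restrict
  if (stroke$mode == "paint") {
    tags[cov] <- stroke$tag
  } else {
    tags[cov & tags == stroke$tag] <- 0L
  }
  tags
}

#' Read brush strokes from a JSON-lines script
#'
#' One JSON object per line: `{"centers": [[z,y,x], ...], "radius": r,
#' "tag": t, "mode": "paint"|"erase"}`.
#'
#' @param path script file.
#' @return list of [brush_stroke()] objects.
#' @export
read_strokes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) err_empty_in("stroke script is empty")
  lapply(lines, function(ln) {
    s <- jsonlite::fromJSON(ln)
    centers <- s$centers
    if (is.null(dim(centers))) centers <- matrix(unlist(centers), ncol = 3, byrow = TRUE)
    brush_stroke(centers, s$radius, s$tag, if (is.null(s$mode)) "paint" else s$mode)
  })
}

#' Region growing from a seed inside a selection mask
#'
#' Returns exactly the connected component of the mask containing the seed,
#' under the given connectivity (flood fill).
#'
#' @param mask 3D logical array.
#' @param seed integer `(z, y, x)` voxel index, 1-based; must satisfy the mask.
#' @param connectivity 6 (default) or 18/26.
#' @return 3D logical array, a connected subset of `mask`.
#' @export
region_grow <- function(mask, seed, connectivity = 6L) {
  m <- as_mask_array(mask)
  d <- dim(m)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    err_seed("seed lies outside the volume")
  if (!m[seed[1], seed[2], seed[3]])
    err_seed("seed voxel is not inside the selection")
  grown <- array(FALSE, d)
  grown[seed[1], seed[2], seed[3]] <- TRUE
  repeat {
    nxt <- dilate_mask(grown, connectivity, 1L) & m
    if (sum(nxt) == sum(grown)) break
    grown <- nxt
  }
  grown
}

#' Connected components of a selection mask
#'
#' Labels components 1..K in first-encounter order of a raster scan (z
#' outermost, then y, then x fastest).
#'
#' @param mask 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @return list with `labels` (3D integer array, 0 = background) and `sizes`
#'   (integer vector, `sizes[k]` = voxel count of component k).
#' @export
connected_components <- function(mask, connectivity = 6L) {
  m <- as_mask_array(mask)
  d <- dim(m)
  labels <- array(0L, d)
  sizes <- integer(0)
  # raster order: x fastest, then y, then z  -> order voxels by (z, y, x)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx)) {
    ord <- order(idx[, 1], idx[, 2], idx[, 3])
    idx <- idx[ord, , drop = FALSE]
    for (i in seq_len(nrow(idx))) {
      p <- idx[i, ]
      if (labels[p[1], p[2], p[3]] != 0L) next
      comp <- region_grow(m, p, connectivity)
      k <- length(sizes) + 1L
      labels[comp] <- k
      sizes[k] <- sum(comp)
    }
  }
  list(labels = labels, sizes = sizes)
}

#' Extract the sub-volume covered by one tag
#'
#' Crops to the tight bounding box of the tag; voxels carrying the tag keep
#' their original value, all others are set to `pad_value`. Bit depth and
#' voxel size are inherited — this is the tagging-function export that turns a
#' painted region of interest into a stand-alone volume.
#'
#' @param vol a [tomo_volume()].
#' @param tags 3D integer tag volume with the same dims.
#' @param tag tag to extract (must be present).
#' @param pad_value raw value for non-tag voxels inside the box (default 0).
#' @return A [tomo_volume()] of the bounding-box dims.
#' @export
extract_tag <- function(vol, tags, tag, pad_value = 0) {
  stopifnot(inherits(vol, "tomo_volume"))
  tags <- check_tags(tags)
  if (!identical(dim(tags), vol$dims)) err_dim("tag volume dims differ from volume dims")
  sel <- tags == as.integer(tag)
  if (!any(sel)) err_empty_sel(sprintf("tag %d not present", as.integer(tag)))
  idx <- which(sel, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  sub <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  selc <- sel[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out <- array(pad_value, dim(sub))
  out[selc] <- sub[selc]
  tomo_volume(out, bit_depth = vol$bit_depth, voxel_size_um = vol$voxel_size_um,
              name = sprintf("%s_tag%d", vol$name, as.integer(tag)))
}
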