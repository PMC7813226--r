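# -- isosurface meshing, smoothing, decimation, stats, IO ---------------------

#' Construct a triangle mesh object
#'
#' @param vertices numeric matrix `n x 3` of `(x, y, z)` positions in µm.
#' @param faces integer matrix `m x 3` of 1-based vertex indices.
#' @return A `tomo_mesh`.
#' @export
tomo_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || (nrow(faces) && ncol(faces) != 3L))
    err_arg("vertices and faces must have 3 columns")
  if (nrow(faces)) {
    if (max(faces) > nrow(vertices) || min(faces) < 1L)
      err_arg("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3]))
      err_arg("faces must not repeat a vertex")
  }
  colnames(vertices) <- c("x", "y", "z")
  structure(list(vertices = vertices, faces = faces), class = "tomo_mesh")
}

#' @export
print.tomo_mesh <- function(x, ...) {
  s <- mesh_stats(x)
  cat(sprintf("<tomo_mesh> %d vertices, %d faces, Euler %d, %swatertight\n",
              s$vertex_count, s$face_count, s$euler_characteristic,
              if (s$watertight) "" else "not "))
  invisible(x)
}

#' Extract an isosurface mesh from a binary mask
#'
#' Binarizes the mask to a 0/1 field, zero-pads it by one voxel (so
#' boundary-touching selections still produce a closed surface) and extracts
#' the 0.5 isosurface by marching tetrahedra on the Kuhn 6-tetrahedra cell
#' decomposition. Unlike the classic cube lookup table this decomposition has
#' no ambiguous configurations, so the output is always a closed,
#' consistently outward-oriented 2-manifold. Vertices are scaled to µm by the
#' per-axis voxel size.
#'
#' @param mask 3D logical array (a selection mask, or `tags == k` for one tag).
#' @param voxel_size_um voxel size `(dz, dy, dx)` in µm.
#' @param iso iso-level on the binarized field (default 0.5).
#' @return A [tomo_mesh()] in µm world units.
#' @export
marching_cubes <- function(mask, voxel_size_um = c(1, 1, 1), iso = 0.5) {
  m <- as_mask_array(mask)
  if (!any(m)) err_empty_sel("mask is empty; no surface to extract")
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  d <- dim(m)
  field <- array(0, d + 2L)
  field[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(m)
  res <- .mt_isosurface(as.vector(field), dim(field), iso)
  verts <- res$vertices
  # un-pad (indices shifted by 1) and map voxel index i to world (i-1)*size;
  # vertex columns are (x, y, z); voxel_size_um is (dz, dy, dx)
  verts[, 1] <- (verts[, 1] - 2) * voxel_size_um[3]
  verts[, 2] <- (verts[, 2] - 2) * voxel_size_um[2]
  verts[, 3] <- (verts[, 3] - 2) * voxel_size_um[1]
  tomo_mesh(verts, res$faces)
}

# undirected edge list (u < v) from a face matrix
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e
}

#' Volume-preserving mesh smoothing
#'
#' Each smoothing step is a two-pass (shrink then inflate) uniform-weight
#' neighbourhood average: `v <- v + s * (mean(neighbours) - v)` with
#' `s = lambda` then `s = mu` (`mu < -lambda`), the classic
#' shrink-compensated fairing that smooths without the systematic volume loss
#' of plain averaging. The smoothing factor is the number of such steps;
#' factor 0 returns the mesh unchanged. Connectivity is untouched.
#'
#' @param mesh a [tomo_mesh()].
#' @param factor non-negative integer iteration count (the recommended
#'   pipeline setting is 2).
#' @param lambda,mu step sizes of the shrink and inflate passes.
#' @return A smoothed [tomo_mesh()] with identical faces.
#' @export
smooth_mesh <- function(mesh, factor = 2L, lambda = 0.5, mu = -0.53) {
  stopifnot(inherits(mesh, "tomo_mesh"))
  if (factor < 0) err_arg("factor must be >= 0")
  if (factor == 0L || nrow(mesh$faces) == 0L) return(mesh)
  V <- mesh$vertices
  e <- mesh_edges(mesh$faces)
  e <- unique(e)
  from <- c(e[, 1], e[, 2]); to <- c(e[, 2], e[, 1])
  deg <- tabulate(from, nbins = nrow(V))
  step <- function(V, s) {
    nb <- rowsum(V[to, , drop = FALSE], from)
    nb <- nb[order(as.integer(rownames(nb))), , drop = FALSE]
    V + s * (nb / deg - V)
  }
  for (i in seq_len(factor)) {
    V <- step(V, lambda)
    V <- step(V, mu)
  }
  tomo_mesh(V, mesh$faces)
}

#' Decimate a mesh by quadric edge collapse
#'
#' Iteratively collapses the cheapest edge under the quadric error metric
#' until the face count reaches `ceiling(F * (1 - percent/100))`; only
#' manifold-safe collapses are performed (link condition, no normal flips).
#' 50% decimation halves the triangle count — and roughly halves the file
#' size — while preserving most shape detail.
#'
#' @param mesh a [tomo_mesh()] with at least 8 faces.
#' @param percent_remove percentage of triangles to remove, in `[0, 100)`.
#' @return A decimated [tomo_mesh()].
#' @export
decimate_mesh <- function(mesh, percent_remove) {
  stopifnot(inherits(mesh, "tomo_mesh"))
  if (percent_remove < 0 || percent_remove >= 100)
    err_arg("percent_remove must lie in [0, 100)")
  if (percent_remove == 0) return(mesh)
  nf <- nrow(mesh$faces)
  if (nf < 8L) err_arg("mesh must have at least 8 faces")
  target <- as.integer(ceiling(nf * (1 - percent_remove / 100)))
  res <- .qem_decimate(mesh$vertices, mesh$faces, target)
  tomo_mesh(res$vertices, res$faces)
}

#' Mesh statistics
#'
#' Counts, Euler characteristic `V - E + F`, total surface area, enclosed
#' volume by signed tetrahedra (meaningful when the mesh is watertight), and a
#' watertightness flag (every undirected edge shared by exactly two faces).
#'
#' @param mesh a [tomo_mesh()].
#' @return list with `vertex_count`, `face_count`, `edge_count`,
#'   `euler_characteristic`, `surface_area_um2`, `enclosed_volume_um3`,
#'   `watertight`.
#' @export
mesh_stats <- function(mesh) {
  stopifnot(inherits(mesh, "tomo_mesh"))
  V <- mesh$vertices; Fm <- mesh$faces
  nv <- nrow(V); nf <- nrow(Fm)
  if (nf == 0L) {
    return(list(vertex_count = nv, face_count = 0L, edge_count = 0L,
                euler_characteristic = nv, surface_area_um2 = 0,
                enclosed_volume_um3 = 0, watertight = FALSE))
  }
  e <- mesh_edges(Fm)
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  ne <- length(tab)
  a <- V[Fm[, 1], , drop = FALSE]
  b <- V[Fm[, 2], , drop = FALSE]
  cc <- V[Fm[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  area <- sum(sqrt(rowSums(cr^2))) / 2
  vol <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
             a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
             a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
  list(
    vertex_count = nv, face_count = nf, edge_count = ne,
    euler_characteristic = nv - ne + nf,
    surface_area_um2 = area, enclosed_volume_um3 = vol,
    watertight = all(tab == 2L)
  )
}

# -- mesh file formats --------------------------------------------------------

mesh_format_of <- function(path, format = NULL) {
  if (!is.null(format)) return(format)
  tolower(tools::file_ext(path))
}

#' Write a mesh to STL (binary), PLY (ascii) or OBJ (ascii)
#'
#' @param mesh a [tomo_mesh()].
#' @param path output file.
#' @param format `"stl"`, `"ply"` or `"obj"`; inferred from the extension if
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "tomo_mesh"))
  format <- mesh_format_of(path, format)
  switch(format,
    stl = write_stl_binary(mesh, path),
    ply = write_ply_ascii(mesh, path),
    obj = write_obj_ascii(mesh, path),
    err_format(sprintf("unknown mesh format '%s'", format))
  )
  invisible(path)
}

#' Read a mesh written by [write_mesh()]
#'
#' PLY/OBJ reproduce the vertex and face lists; binary STL stores a triangle
#' soup, so vertices are re-merged with tolerance 1e-6.
#'
#' @param path mesh file.
#' @param format `"stl"`, `"ply"` or `"obj"`; inferred from the extension if
#'   omitted.
#' @return A [tomo_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  format <- mesh_format_of(path, format)
  switch(format,
    stl = read_stl_binary(path),
    ply = read_ply_ascii(path),
    obj = read_obj_ascii(path),
    err_format(sprintf("unknown mesh format '%s'", format))
  )
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb"); on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "tomoseg binary STL"))[1:80]
  writeBin(header, con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  V <- mesh$vertices; Fm <- mesh$faces
  a <- V[Fm[, 1], , drop = FALSE]; b <- V[Fm[, 2], , drop = FALSE]
  cc <- V[Fm[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  # 12 float32 per record, interleaved with a 2-byte attribute count of 0
  floats <- t(cbind(n, a, b, cc))  # 12 x nf
  fr <- writeBin(as.numeric(floats), raw(), size = 4, endian = "little")
  fr <- matrix(fr, nrow = 48)
  rec <- rbind(fr, matrix(as.raw(0), nrow = 2, ncol = nf))
  writeBin(as.vector(rec), con)
}

read_stl_binary <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 84) err_corrupt("STL file too short")
  nf <- readBin(bytes[81:84], "integer", size = 4, endian = "little")
  need <- 84 + 50 * nf
  if (length(bytes) < need) err_corrupt("STL triangle records truncated")
  rec <- matrix(bytes[85:need], nrow = 50)
  floats <- readBin(as.vector(rec[1:48, , drop = FALSE]), "numeric",
                    n = 12 * nf, size = 4, endian = "little")
  fm <- matrix(floats, nrow = 12)  # rows: normal, v1, v2, v3
  tri <- rbind(t(fm[4:6, , drop = FALSE]), t(fm[7:9, , drop = FALSE]),
               t(fm[10:12, , drop = FALSE]))
  ord <- as.vector(t(matrix(seq_len(3 * nf), ncol = 3)))  # v1,v2,v3 per tri
  tri <- tri[ord, , drop = FALSE]
  key <- paste(round(tri[, 1], 6), round(tri[, 2], 6), round(tri[, 3], 6))
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  verts <- tri[uk, , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  tomo_mesh(verts, faces)
}

write_ply_ascii <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0", "comment tomoseg",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- which(lines == "end_header")[1]
  if (is.na(endh)) err_corrupt("PLY header not terminated")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face ", lines, value = TRUE)[1]))
  vl <- lines[(endh + 1):(endh + nv)]
  fl <- if (nf > 0) lines[(endh + nv + 1):(endh + nv + nf)] else character(0)
  verts <- matrix(as.numeric(unlist(strsplit(vl, " ", fixed = TRUE))), ncol = 3, byrow = TRUE)
  fv <- matrix(as.integer(unlist(strsplit(fl, " ", fixed = TRUE))), ncol = 4, byrow = TRUE)
  tomo_mesh(verts, fv[, 2:4, drop = FALSE] + 1L)
}

write_obj_ascii <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# tomoseg OBJ", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

read_obj_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  verts <- matrix(as.numeric(unlist(strsplit(sub("^v ", "", vl), " "))), ncol = 3, byrow = TRUE)
  faces <- matrix(as.integer(unlist(strsplit(sub("^f ", "", fl), " "))), ncol = 3, byrow = TRUE)
  tomo_mesh(verts, faces)
}
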