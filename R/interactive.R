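# -- seeded segmentation: graph cut, livewire, contour interpolation ----------

#' Graph-cut parameters
#'
#' @param lambda_boundary non-negative weight of the boundary term.
#' @param sigma positive contrast scale of the boundary weights.
#' @param connectivity 6 or 26 voxel adjacency.
#' @return A `graph_cut_params` list.
#' @export
graph_cut_params <- function(lambda_boundary = 1, sigma = 0.1, connectivity = 6L) {
  if (lambda_boundary < 0) err_arg("lambda_boundary must be >= 0")
  if (sigma <= 0) err_arg("sigma must be > 0")
  if (!connectivity %in% c(6L, 26L)) err_arg("connectivity must be 6 or 26")
  structure(list(lambda_boundary = lambda_boundary, sigma = sigma,
                 connectivity = as.integer(connectivity)),
            class = "graph_cut_params")
}

#' Seed set for seeded segmentation
#'
#' @param foreground,background integer matrices of `(z, y, x)` voxel rows,
#'   1-based; the two sets must be disjoint and inside the volume.
#' @return A `seed_set` list.
#' @export
seed_set <- function(foreground, background) {
  fix <- function(m) {
    if (is.null(m) || (is.matrix(m) && nrow(m) == 0L)) return(matrix(integer(0), 0, 3))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    m <- as.matrix(m); storage.mode(m) <- "integer"
    m
  }
  structure(list(foreground = fix(foreground), background = fix(background)),
            class = "seed_set")
}

# histogram data terms: 32-bin seed-intensity histograms, probability floor
# 1e-6, D = -log P
GC_BINS <- 32L
GC_PFLOOR <- 1e-6

seed_neg_loglik <- function(values, seed_values) {
  bins <- pmin(floor(seed_values * GC_BINS) + 1L, GC_BINS)
  p <- tabulate(bins, nbins = GC_BINS) / length(seed_values)
  p <- pmax(p, GC_PFLOOR)
  vb <- pmin(floor(values * GC_BINS) + 1L, GC_BINS)
  -log(p[vb])
}

lin_index <- function(idx, d) {
  as.integer(idx[, 1] + (idx[, 2] - 1L) * d[1] + (idx[, 3] - 1L) * d[1] * d[2])
}

#' Seeded binary segmentation by exact min-cut
#'
#' Minimizes the standard seeded energy
#' `E(L) = sum_p D(p, L_p) + lambda * sum_(p,q adj) exp(-(v_p - v_q)^2 / (2 sigma^2)) * [L_p != L_q]`
#' where for non-seed voxels `D(p, fg) = -log P_fg(v_p)` and
#' `D(p, bg) = -log P_bg(v_p)`, with `P` estimated from 32-bin histograms of
#' the seed intensities (probability floor 1e-6), and seeds carry an infinite
#' penalty for flipping. Solved exactly by max-flow/min-cut; the returned
#' labeling is the minimal foreground side of the cut, so voxels indifferent
#' between the labels go to background (deterministic tie-break).
#'
#' Intended for user-cropped sub-volumes: graph memory scales with voxel
#' count.
#'
#' @param nv `tomo_normvol` or 3D array in `[0, 1]`.
#' @param seeds a [seed_set()]; both lists non-empty.
#' @param params a [graph_cut_params()].
#' @return 3D logical array: the foreground labeling (seeds always keep their
#'   labels).
#' @export
graph_cut <- function(nv, seeds, params = graph_cut_params()) {
  a <- as_norm_array(nv)
  d <- dim(a)
  stopifnot(inherits(seeds, "seed_set"), inherits(params, "graph_cut_params"))
  if (nrow(seeds$foreground) == 0L) err_seeds("foreground seeds are empty")
  if (nrow(seeds$background) == 0L) err_seeds("background seeds are empty")
  chk <- rbind(seeds$foreground, seeds$background)
  if (any(chk < 1L) || any(t(chk) > d)) err_arg("seed outside volume")
  fg_lin <- lin_index(seeds$foreground, d)
  bg_lin <- lin_index(seeds$background, d)
  if (length(intersect(fg_lin, bg_lin))) err_arg("foreground and background seeds overlap")

  n <- prod(d)
  v <- as.vector(a)
  d_fg <- seed_neg_loglik(v, v[fg_lin])  # cost of labeling fg
  d_bg <- seed_neg_loglik(v, v[bg_lin])

  # n-links: unordered neighbour pairs under the connectivity
  off <- se_offsets(params$connectivity)
  off <- off[off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
             (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0), , drop = FALSE]
  pairs <- list(); wts <- list()
  arr <- array(seq_len(n), d)
  for (j in seq_len(nrow(off))) {
    dz <- off[j, 1]; dy <- off[j, 2]; dx <- off[j, 3]
    z1 <- 1:(d[1] - max(dz, 0)); z1 <- z1[z1 >= 1 - min(dz, 0)]
    zr <- max(1, 1 - dz):min(d[1], d[1] - dz)
    yr <- max(1, 1 - dy):min(d[2], d[2] - dy)
    xr <- max(1, 1 - dx):min(d[3], d[3] - dx)
    p <- as.vector(arr[zr, yr, xr, drop = FALSE])
    q <- as.vector(arr[zr + dz, yr + dy, xr + dx, drop = FALSE])
    w <- exp(-(v[p] - v[q])^2 / (2 * params$sigma^2))
    pairs[[j]] <- cbind(p, q); wts[[j]] <- params$lambda_boundary * w
  }
  pq <- do.call(rbind, pairs); w <- unlist(wts)

  # terminal capacities: cutting s->p labels p background (pays D(p,bg));
  # cutting p->t labels p foreground (pays D(p,fg)); seeds get a huge
  # capacity on the forbidden side
  cap_s <- d_bg; cap_t <- d_fg
  K <- sum(w) + sum(pmin(cap_s, cap_t)) + 1
  cap_s[fg_lin] <- K; cap_t[fg_lin] <- 0
  cap_t[bg_lin] <- K; cap_s[bg_lin] <- 0

  s_id <- n + 1L; t_id <- n + 2L
  from <- c(rep(s_id, n), seq_len(n), pq[, 1], pq[, 2])
  to   <- c(seq_len(n), rep(t_id, n), pq[, 2], pq[, 1])
  cap  <- c(cap_s, cap_t, w, w)
  keep <- cap > 0
  from <- from[keep]; to <- to[keep]; cap <- cap[keep]

  g <- igraph::make_graph(rbind(from, to), n = n + 2L, directed = TRUE)
  mf <- igraph::max_flow(g, source = s_id, target = t_id, capacity = cap)
  flow <- mf$flow

  # residual BFS from the source: forward residual cap - flow, reverse
  # residual = flow; reachable voxels form the minimal foreground side
  eps <- 1e-9
  rf <- c(from[cap - flow > eps], to[flow > eps])
  rt <- c(to[cap - flow > eps], from[flow > eps])
  adj <- split(rt, factor(rf, levels = seq_len(n + 2L)))
  reach <- logical(n + 2L)
  frontier <- s_id; reach[s_id] <- TRUE
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!reach[nxt]]
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  array(reach[seq_len(n)], d)
}

#' Livewire boundary tracing on a slice
#'
#' Minimal-cost 8-connected path between two pixels of a 2D slice. The cost of
#' stepping into pixel `q` is `(w_g * (1 - G(q)) + w_u) * len`, with `len` 1
#' for axial and `sqrt(2)` for diagonal steps, and `G` the central-difference
#' gradient magnitude of the slice normalized by its maximum (identically 0 on
#' a constant slice). High-gradient pixels are cheap, so the path snaps to
#' phase boundaries. Dijkstra search with deterministic tie-breaks:
#' lexicographically smallest node (row-major `(y, x)` order) is expanded
#' first and paths are only replaced on strict improvement.
#'
#' @param slice numeric matrix `[y, x]` with values in `[0, 1]`.
#' @param start_px,end_px integer `(y, x)` pixels, 1-based, distinct.
#' @param gradient_weight,uniform_weight cost weights `w_g` and `w_u`
#'   (defaults 1 and 0.1).
#' @return integer matrix of `(y, x)` path pixels from start to end, with
#'   attribute `cost` (total path cost).
#' @export
livewire <- function(slice, start_px, end_px, gradient_weight = 1,
                     uniform_weight = 0.1) {
  if (!is.matrix(slice) || length(slice) < 2L)
    err_arg("slice must be a matrix with at least 2 pixels")
  ny <- nrow(slice); nx <- ncol(slice)
  start_px <- as.integer(start_px); end_px <- as.integer(end_px)
  inb <- function(p) all(p >= 1L) && p[1] <= ny && p[2] <= nx
  if (!inb(start_px) || !inb(end_px)) err_arg("endpoint outside slice")
  if (all(start_px == end_px)) err_arg("start and end pixels must differ")

  G <- slice_gradient(slice)
  into_cost <- gradient_weight * (1 - G) + uniform_weight  # per unit length

  # row-major ids: id = (y-1)*nx + x  (lexicographic (y, x) order)
  id_of <- function(y, x) (y - 1L) * nx + x
  ntot <- ny * nx
  cost_px <- as.vector(t(into_cost))  # by id
  offs <- cbind(dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  lens <- sqrt(abs(offs[, 1]) + abs(offs[, 2]))

  dist <- rep(Inf, ntot); prev <- rep(NA_integer_, ntot); done <- rep(FALSE, ntot)
  s <- id_of(start_px[1], start_px[2]); e <- id_of(end_px[1], end_px[2])
  dist[s] <- 0
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (done[u] || !is.finite(dist[u])) break
    done[u] <- TRUE
    if (u == e) break
    uy <- (u - 1L) %/% nx + 1L; ux <- (u - 1L) %% nx + 1L
    for (j in 1:8) {
      vy <- uy + offs[j, 1]; vx <- ux + offs[j, 2]
      if (vy < 1L || vy > ny || vx < 1L || vx > nx) next
      vid <- id_of(vy, vx)
      if (done[vid]) next
      nd <- dist[u] + cost_px[vid] * lens[j]
      if (nd < dist[vid]) { dist[vid] <- nd; prev[vid] <- u }
    }
  }
  if (!is.finite(dist[e])) err_arg("no path found")  # cannot happen on a grid
  path <- integer(0); u <- e
  while (!is.na(u)) { path <- c(u, path); u <- prev[u] }
  out <- cbind(y = (path - 1L) %/% nx + 1L, x = (path - 1L) %% nx + 1L)
  attr(out, "cost") <- dist[e]
  out
}

# 2D central-difference gradient magnitude, replicate padding, normalized by
# the slice maximum (0 if constant)
slice_gradient <- function(slice) {
  ny <- nrow(slice); nx <- ncol(slice)
  up <- slice[pmax(seq_len(ny) - 1L, 1L), , drop = FALSE]
  dn <- slice[pmin(seq_len(ny) + 1L, ny), , drop = FALSE]
  lf <- slice[, pmax(seq_len(nx) - 1L, 1L), drop = FALSE]
  rt <- slice[, pmin(seq_len(nx) + 1L, nx), drop = FALSE]
  G <- sqrt(((dn - up) / 2)^2 + ((rt - lf) / 2)^2)
  mx <- max(G)
  if (mx > 0) G / mx else G * 0
}

#' Interpolate intermediate contours between two slice masks
#'
#' Blends the signed Euclidean distance fields of the two masks (negative
#' inside) and thresholds at zero: intermediate `k` of `n` is
#' `{(1 - t) d_a + t d_b <= 0}` at `t = k / (n + 1)`. Shapes morph smoothly
#' between the endpoint contours.
#'
#' Interpolated contours are a modelling convenience, not observed data: the
#' function warns (class `tomoseg_warning_reproducibility`) because
#' interpolated slices are not reproducible anatomy and are discouraged for
#' palaeontological material.
#'
#' @param mask_a,mask_b 2D logical matrices of the same shape, both non-empty.
#' @param n_intermediate number of intermediate masks (>= 1).
#' @return list of `n_intermediate` logical matrices.
#' @export
interpolate_contours <- function(mask_a, mask_b, n_intermediate = 1L) {
  if (!is.matrix(mask_a) || !is.matrix(mask_b)) err_arg("masks must be 2D matrices")
  if (!identical(dim(mask_a), dim(mask_b))) err_dim("mask shapes differ")
  a <- mask_a != 0; b <- mask_b != 0
  if (!any(a) || !any(b)) err_contour("both contours must be non-empty")
  if (n_intermediate < 1L) err_arg("n_intermediate must be >= 1")
  warning(warningCondition(
    "interpolated contours are synthesized, not observed; not recommended for palaeontological data",
    class = c("tomoseg_warning_reproducibility", "tomoseg_warning", "warning", "condition")
  ))
  da <- signed_distance(a); db <- signed_distance(b)
  lapply(seq_len(n_intermediate), function(k) {
    t <- k / (n_intermediate + 1)
    ((1 - t) * da + t * db) <= 0
  })
}

# signed Euclidean distance: positive outside, negative inside
signed_distance <- function(m) {
  outside <- EBImage::distmap(matrix(as.numeric(!m), nrow(m), ncol(m)))
  inside <- EBImage::distmap(matrix(as.numeric(m), nrow(m), ncol(m)))
  as.matrix(outside) - as.matrix(inside)
}
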