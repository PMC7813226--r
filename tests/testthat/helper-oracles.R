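# Brute-force oracles, kept deliberately independent of the package's
# vectorized implementations: explicit loops, no shared helpers.

random_mask <- function(dims, p = 0.4, seed = 1) {
  withr::local_seed(seed)
  array(runif(prod(dims)) < p, dims)
}

random_volume <- function(dims, bit_depth = 16, seed = 1) {
  withr::local_seed(seed)
  maxcode <- 2^bit_depth - 1
  tomo_volume(array(sample.int(maxcode + 1, prod(dims), replace = TRUE) - 1, dims),
              bit_depth = bit_depth)
}

bf_offsets <- function(connectivity) {
  out <- NULL
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    s <- abs(dz) + abs(dy) + abs(dx)
    keep <- switch(as.character(connectivity),
                   "6" = s == 1, "18" = s >= 1 && s <= 2, "26" = s >= 1)
    if (keep) out <- rbind(out, c(dz, dy, dx))
  }
  out
}

bf_dilate <- function(m, connectivity) {
  d <- dim(m); off <- bf_offsets(connectivity)
  out <- array(FALSE, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    v <- m[z, y, x]
    if (!v) for (j in seq_len(nrow(off))) {
      nz <- z + off[j, 1]; ny <- y + off[j, 2]; nx <- x + off[j, 3]
      if (nz >= 1 && nz <= d[1] && ny >= 1 && ny <= d[2] && nx >= 1 && nx <= d[3] &&
          m[nz, ny, nx]) { v <- TRUE; break }
    }
    out[z, y, x] <- v
  }
  out
}

bf_erode <- function(m, connectivity) {
  d <- dim(m); off <- bf_offsets(connectivity)
  out <- array(FALSE, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    v <- m[z, y, x]
    if (v) for (j in seq_len(nrow(off))) {
      nz <- z + off[j, 1]; ny <- y + off[j, 2]; nx <- x + off[j, 3]
      if (nz < 1 || nz > d[1] || ny < 1 || ny > d[2] || nx < 1 || nx > d[3] ||
          !m[nz, ny, nx]) { v <- FALSE; break }
    }
    out[z, y, x] <- v
  }
  out
}

# stack-based flood-fill labeling; returns an integer array whose labels
# induce the same partition as any correct component labeling
bf_components <- function(m, connectivity) {
  d <- dim(m); off <- bf_offsets(connectivity)
  lab <- array(0L, d); k <- 0L
  for (z0 in 1:d[1]) for (y0 in 1:d[2]) for (x0 in 1:d[3]) {
    if (!m[z0, y0, x0] || lab[z0, y0, x0] != 0L) next
    k <- k + 1L
    stack <- list(c(z0, y0, x0)); lab[z0, y0, x0] <- k
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (j in seq_len(nrow(off))) {
        q <- p + off[j, ]
        if (all(q >= 1) && all(q <= d) && m[q[1], q[2], q[3]] &&
            lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- k
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# two labelings induce the same partition of the set voxels
same_partition <- function(l1, l2) {
  on1 <- which(l1 != 0); on2 <- which(l2 != 0)
  if (!identical(on1, on2)) return(FALSE)
  identical(
    as.integer(factor(l1[on1], levels = unique(l1[on1]))),
    as.integer(factor(l2[on2], levels = unique(l2[on2])))
  )
}

# -- graph-cut energy oracle (from the stated energy, explicit loops) --------

gc_oracle_dataterm <- function(values, seed_values) {
  nb <- 32L
  counts <- numeric(nb)
  for (v in seed_values) {
    b <- min(floor(v * nb) + 1, nb)
    counts[b] <- counts[b] + 1
  }
  p <- pmax(counts / length(seed_values), 1e-6)
  vapply(values, function(v) -log(p[min(floor(v * nb) + 1, nb)]), 0)
}

gc_oracle_energy <- function(a, fg_label, fg_seed_lin, bg_seed_lin, lambda, sigma,
                             connectivity) {
  d <- dim(a); v <- as.vector(a)
  dfg <- gc_oracle_dataterm(v, v[fg_seed_lin])
  dbg <- gc_oracle_dataterm(v, v[bg_seed_lin])
  lab <- as.vector(fg_label)
  seeds <- c(fg_seed_lin, bg_seed_lin)
  e <- 0
  for (p in seq_along(v)) {
    if (p %in% seeds) next
    e <- e + if (lab[p]) dfg[p] else dbg[p]
  }
  off <- bf_offsets(connectivity)
  lin <- function(z, y, x) z + (y - 1) * d[1] + (x - 1) * d[1] * d[2]
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    for (j in seq_len(nrow(off))) {
      q <- c(z, y, x) + off[j, ]
      if (any(q < 1) || any(q > d)) next
      p1 <- lin(z, y, x); p2 <- lin(q[1], q[2], q[3])
      if (p1 < p2 && lab[p1] != lab[p2])
        e <- e + lambda * exp(-(v[p1] - v[p2])^2 / (2 * sigma^2))
    }
  }
  e
}

# minimum energy over all labelings consistent with the seeds (exhaustive)
gc_oracle_min_energy <- function(a, fg_seed_lin, bg_seed_lin, lambda, sigma,
                                 connectivity) {
  n <- length(a)
  free <- setdiff(seq_len(n), c(fg_seed_lin, bg_seed_lin))
  best <- Inf
  for (bits in 0:(2^length(free) - 1)) {
    lab <- logical(n)
    lab[fg_seed_lin] <- TRUE
    if (length(free))
      lab[free] <- bitwAnd(bits, 2^(seq_along(free) - 1)) > 0
    e <- gc_oracle_energy(a, array(lab, dim(a)), fg_seed_lin, bg_seed_lin,
                          lambda, sigma, connectivity)
    if (e < best) best <- e
  }
  best
}

# -- livewire oracle: igraph shortest path on the same weighted lattice ------

lw_oracle_cost <- function(slice, start_px, end_px, w_g = 1, w_u = 0.1) {
  ny <- nrow(slice); nx <- ncol(slice)
  gx <- matrix(0, ny, nx); gy <- matrix(0, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    xm <- max(x - 1, 1); xp <- min(x + 1, nx)
    ym <- max(y - 1, 1); yp <- min(y + 1, ny)
    gx[y, x] <- (slice[y, xp] - slice[y, xm]) / 2
    gy[y, x] <- (slice[yp, x] - slice[ym, x]) / 2
  }
  G <- sqrt(gx^2 + gy^2)
  if (max(G) > 0) G <- G / max(G)
  id <- function(y, x) (y - 1) * nx + x
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (y in 1:ny) for (x in 1:nx) for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    y2 <- y + dy; x2 <- x + dx
    if (y2 < 1 || y2 > ny || x2 < 1 || x2 > nx) next
    from <- c(from, id(y, x)); to <- c(to, id(y2, x2))
    wt <- c(wt, (w_g * (1 - G[y2, x2]) + w_u) * sqrt(dy^2 + dx^2))
  }
  g <- igraph::make_graph(rbind(from, to), n = ny * nx, directed = TRUE)
  igraph::distances(g, v = id(start_px[1], start_px[2]),
                    to = id(end_px[1], end_px[2]), mode = "out", weights = wt)[1, 1]
}

# mesh helpers used across test files
mesh_component_count <- function(mesh) {
  e <- unique(rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)]))
  g <- igraph::make_graph(t(e), n = nrow(mesh$vertices), directed = FALSE)
  igraph::count_components(g)
}

digital_ball <- function(radius = 10, margin = 3) {
  n <- 2 * (radius + margin) + 1
  ctr <- radius + margin + 1
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  array((g$z - ctr)^2 + (g$y - ctr)^2 + (g$x - ctr)^2 <= radius^2, c(n, n, n))
}

# closed unit cube surface: 8 vertices, 12 consistently oriented triangles
unit_cube_mesh <- function(edge = 1) {
  v <- as.matrix(expand.grid(x = c(0, edge), y = c(0, edge), z = c(0, edge)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0 face (normal -z)
    c(5, 6, 7), c(6, 8, 7),  # z = 1
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = 1
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6)   # x = 1
  )
  tomo_mesh(v, f)
}
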