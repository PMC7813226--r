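# -- gradient operator fields and value/gradient selection --------------------

# replicate-pad a 3D array by k voxels on every side (border values repeated)
pad_replicate <- function(a, k) {
  d <- dim(a)
  iz <- pmin(pmax(seq_len(d[1] + 2 * k) - k, 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2] + 2 * k) - k, 1L), d[2])
  ix <- pmin(pmax(seq_len(d[3] + 2 * k) - k, 1L), d[3])
  a[iz, iy, ix, drop = FALSE]
}

# view into padded array shifted by (dz, dy, dx), same size as the original
shift_view <- function(ap, d, k, dz, dy, dx) {
  ap[(1 + k + dz):(d[1] + k + dz),
     (1 + k + dy):(d[2] + k + dy),
     (1 + k + dx):(d[3] + k + dx), drop = FALSE]
}

# separable box sum over a (2k+1)^3 neighbourhood with replicate padding
box_sum <- function(a, k) {
  d <- dim(a)
  for (axis in 1:3) {
    ap <- pad_replicate(a, k)
    acc <- array(0, d)
    for (off in -k:k) {
      sh <- c(0L, 0L, 0L); sh[axis] <- off
      acc <- acc + shift_view(ap, d, k, sh[1], sh[2], sh[3])
    }
    a <- acc
  }
  a
}

#' Gradient operator types
#'
#' Three per-voxel gradient measures on a normalized volume, each clamped to
#' `[0, 1]`:
#' * `type1` — magnitude (Euclidean norm) of the central-difference gradient
#'   vector, `g = ||(gx, gy, gz)||` with `gx = (v[x+1] - v[x-1]) / 2` etc.;
#' * `type2` — `g = |v - S/10|` where `S` is the sum over the 3×3×3
#'   neighbourhood minus the central value (26 neighbours);
#' * `type3` — `g = |v - S/70|` where `S` is the sum over the 5×5×5
#'   neighbourhood minus the central value (124 neighbours).
#'
#' Borders use replicate padding, so a constant volume yields a constant
#' field. For types 2 and 3 the measure on a constant volume grows with the
#' constant value — the intensity-shifted behaviour that lets these operators
#' separate phases of different brightness, at the price of sensitivity to
#' intensity inhomogeneity.
#'
#' @param nv a `tomo_normvol` (see [normalize()]) or a 3D array in `[0, 1]`.
#' @param gtype `"type1"`, `"type2"` or `"type3"` (`"none"` is rejected).
#' @return 3D numeric array of gradient values in `[0, 1]`, same dims as `nv`.
#' @examples
#' nv <- array(0.5, c(4, 4, 4))
#' unique(as.vector(gradient_field(nv, "type2")))  # 0.8 everywhere
#' @export
gradient_field <- function(nv, gtype = c("type1", "type2", "type3")) {
  if (identical(gtype, "none")) err_arg("gradient type 'none' has no field")
  gtype <- match.arg(gtype)
  a <- as_norm_array(nv)
  d <- dim(a)
  g <- switch(gtype,
    type1 = {
      ap <- pad_replicate(a, 1L)
      gx <- (shift_view(ap, d, 1L, 0, 0, 1) - shift_view(ap, d, 1L, 0, 0, -1)) / 2
      gy <- (shift_view(ap, d, 1L, 0, 1, 0) - shift_view(ap, d, 1L, 0, -1, 0)) / 2
      gz <- (shift_view(ap, d, 1L, 1, 0, 0) - shift_view(ap, d, 1L, -1, 0, 0)) / 2
      sqrt(gx^2 + gy^2 + gz^2)
    },
    type2 = abs(a - (box_sum(a, 1L) - a) / 10),
    type3 = abs(a - (box_sum(a, 2L) - a) / 70)
  )
  array(pmin(pmax(g, 0), 1), d)
}

#' Brute-force reference for [gradient_field()]
#'
#' Identical contract, computed voxel-by-voxel with explicit neighbourhood
#' loops and clamped indices. Slow by construction; used as the independent
#' reference in tests.
#'
#' @inheritParams gradient_field
#' @return 3D numeric array of gradient values in `[0, 1]`.
#' @export
gradient_field_oracle <- function(nv, gtype = c("type1", "type2", "type3")) {
  if (identical(gtype, "none")) err_arg("gradient type 'none' has no field")
  gtype <- match.arg(gtype)
  a <- as_norm_array(nv)
  d <- dim(a)
  at <- function(z, y, x) {
    a[min(max(z, 1L), d[1]), min(max(y, 1L), d[2]), min(max(x, 1L), d[3])]
  }
  g <- array(0, d)
  k <- if (gtype == "type3") 2L else 1L
  divisor <- if (gtype == "type3") 70 else 10
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (gtype == "type1") {
      gx <- (at(z, y, x + 1) - at(z, y, x - 1)) / 2
      gy <- (at(z, y + 1, x) - at(z, y - 1, x)) / 2
      gz <- (at(z + 1, y, x) - at(z - 1, y, x)) / 2
      val <- sqrt(gx^2 + gy^2 + gz^2)
    } else {
      s <- 0
      for (dz in -k:k) for (dy in -k:k) for (dx in -k:k)
        s <- s + at(z + dz, y + dy, x + dx)
      s <- s - a[z, y, x]
      val <- abs(a[z, y, x] - s / divisor)
    }
    g[z, y, x] <- min(max(val, 0), 1)
  }
  g
}

#' Threshold specification combining a value range and a gradient range
#'
#' A voxel is selected iff its normalized value lies in
#' `[value_lo, value_hi]` and, when `gtype != "none"`, its gradient measure
#' lies in `[grad_lo, grad_hi]`. Both intervals are closed.
#'
#' @param value_lo,value_hi normalized value range in `[0, 1]`.
#' @param gtype gradient operator (`"none"` disables the gradient predicate).
#' @param grad_lo,grad_hi gradient range in `[0, 1]`.
#' @return A `threshold_spec` list.
#' @export
threshold_spec <- function(value_lo = 0, value_hi = 1,
                           gtype = c("none", "type1", "type2", "type3"),
                           grad_lo = 0, grad_hi = 1) {
  gtype <- match.arg(gtype)
  if (value_lo > value_hi) err_arg("value_lo must be <= value_hi")
  if (grad_lo > grad_hi) err_arg("grad_lo must be <= grad_hi")
  if (any(c(value_lo, value_hi, grad_lo, grad_hi) < 0) ||
      any(c(value_lo, value_hi, grad_lo, grad_hi) > 1))
    err_arg("threshold bounds must lie in [0, 1]")
  structure(list(value_lo = value_lo, value_hi = value_hi, gtype = gtype,
                 grad_lo = grad_lo, grad_hi = grad_hi),
            class = "threshold_spec")
}

#' Select voxels by combined value and gradient thresholding
#'
#' Multiple-thresholding: the conjunction of a closed value range with a
#' closed gradient range. This is typically the first step of segmenting a
#' volume; combining the two predicates sharpens phase boundaries that value
#' ranges alone cannot isolate.
#'
#' @param nv a `tomo_normvol` or 3D array in `[0, 1]`.
#' @param spec a [threshold_spec()].
#' @param gf optional precomputed gradient field matching `spec$gtype` (saves
#'   recomputation when sweeping ranges).
#' @return 3D logical selection mask, same dims as `nv`.
#' @export
threshold_select <- function(nv, spec, gf = NULL) {
  stopifnot(inherits(spec, "threshold_spec"))
  a <- as_norm_array(nv)
  sel <- a >= spec$value_lo & a <= spec$value_hi
  if (spec$gtype != "none") {
    if (is.null(gf)) gf <- gradient_field(a, spec$gtype)
    if (!identical(dim(gf), dim(a))) err_dim("gradient field dims differ from volume dims")
    sel <- sel & gf >= spec$grad_lo & gf <= spec$grad_hi
  }
  array(sel, dim(a))
}

#' 2D value-gradient histogram
#'
#' Joint counts of (normalized value, gradient measure) over uniform bins on
#' `[0, 1] x [0, 1]`; the scatter practitioners bracket to pick threshold
#' ranges. The last bin of each axis is right-closed so counts always sum to
#' the voxel count.
#'
#' @param nv a `tomo_normvol` or 3D array in `[0, 1]`.
#' @param gf gradient field with the same dims (see [gradient_field()]).
#' @param value_bins,grad_bins number of bins per axis (>= 1).
#' @return integer matrix `value_bins x grad_bins`; `dimnames` give the left
#'   bin edges.
#' @export
histogram2d <- function(nv, gf, value_bins = 64L, grad_bins = 64L) {
  a <- as_norm_array(nv)
  if (!identical(dim(gf), dim(a))) err_dim("gradient field dims differ from volume dims")
  if (value_bins < 1L || grad_bins < 1L) err_arg("bins must be >= 1")
  bi <- pmin(floor(as.vector(a) * value_bins) + 1L, value_bins)
  bj <- pmin(floor(as.vector(gf) * grad_bins) + 1L, grad_bins)
  counts <- matrix(0L, value_bins, grad_bins)
  t <- table(factor(bi, levels = seq_len(value_bins)),
             factor(bj, levels = seq_len(grad_bins)))
  counts[] <- as.integer(t)
  dimnames(counts) <- list(
    value = sprintf("%.6g", (seq_len(value_bins) - 1) / value_bins),
    gradient = sprintf("%.6g", (seq_len(grad_bins) - 1) / grad_bins)
  )
  counts
}

#' Export a 2D histogram as CSV
#'
#' Long format with columns `value_bin`, `grad_bin` (left edges) and `count`.
#'
#' @param h matrix from [histogram2d()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_histogram2d_csv <- function(h, path) {
  df <- data.frame(
    value_bin = rep(as.numeric(rownames(h)), times = ncol(h)),
    grad_bin = rep(as.numeric(colnames(h)), each = nrow(h)),
    count = as.vector(h)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
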