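test_that("graph cut separates a two-phase volume from one seed per phase", {
  a <- array(0, c(2, 2, 4)); a[, , 1:2] <- 0.1; a[, , 3:4] <- 0.9
  seeds <- seed_set(foreground = c(1, 1, 4), background = c(1, 1, 1))
  m <- graph_cut(a, seeds, graph_cut_params(1, 0.1, 6))
  expect_equal(m, a == 0.9)
})

test_that("graph cut always respects seeds and rejects empty seed lists", {
  for (seed in 1:5) {
    nv <- normalize(random_volume(c(3, 3, 3), seed = 60 + seed))
    fg <- c(1, 1, 1); bg <- c(3, 3, 3)
    m <- graph_cut(nv, seed_set(fg, bg), graph_cut_params(0.5, 0.2, 6))
    expect_true(m[1, 1, 1])
    expect_false(m[3, 3, 3])
  }
  a <- array(0.5, c(2, 2, 2))
  expect_error(graph_cut(a, seed_set(NULL, c(1, 1, 1))),
               class = "tomoseg_error_missing_seeds")
  expect_error(graph_cut(a, seed_set(c(1, 1, 1), NULL)),
               class = "tomoseg_error_missing_seeds")
  expect_error(graph_cut(a, seed_set(c(1, 1, 1), c(1, 1, 1))),
               class = "tomoseg_error_invalid_argument")
})

test_that("with no boundary term each voxel follows its larger seed likelihood", {
  # z-fastest fill: a[1,1,1]=0.05, a[2,1,1]=0.1, a[1,2,1]=0.12, a[2,2,1]=0.9,
  #                 a[1,1,2]=0.95, a[2,1,2]=0.88, a[1,2,2]=0.5, a[2,2,2]=0.15
  a <- array(c(0.05, 0.1, 0.12, 0.9, 0.95, 0.88, 0.5, 0.15), c(2, 2, 2))
  seeds <- seed_set(foreground = c(2, 2, 1), background = c(1, 1, 1))
  m <- graph_cut(a, seeds, graph_cut_params(0, 0.1, 6))
  # the single-value seed histograms make bin [0.875, 0.90625) the only
  # high-likelihood foreground bin: 0.9 (seed) and 0.88 go foreground
  expect_true(m[2, 2, 1] && m[2, 1, 2])
  # 0.05 matches the background bin; everything off both histograms ties at
  # the probability floor and resolves to background
  expect_false(m[1, 1, 1] || m[2, 1, 1] || m[1, 2, 1] || m[1, 1, 2] ||
               m[1, 2, 2] || m[2, 2, 2])
})

test_that("ties on a constant volume resolve to background", {
  a <- array(0.5, c(2, 2, 2))
  m <- graph_cut(a, seed_set(c(1, 1, 1), c(2, 2, 2)), graph_cut_params(1, 0.1, 6))
  expect_equal(sum(m), 1)  # only the foreground seed itself
  expect_true(m[1, 1, 1])
})

test_that("graph cut attains the exhaustive minimum energy on small instances", {
  for (seed in 1:6) {
    dims <- if (seed %% 2) c(2, 2, 3) else c(2, 2, 4)
    nv <- normalize(random_volume(dims, seed = 200 + seed))
    a <- nv$data
    fg <- c(1, 1, dims[3]); bg <- c(1, 1, 1)
    fg_lin <- fg[1] + (fg[2] - 1) * dims[1] + (fg[3] - 1) * dims[1] * dims[2]
    bg_lin <- bg[1] + (bg[2] - 1) * dims[1] + (bg[3] - 1) * dims[1] * dims[2]
    lambda <- c(0.3, 1, 2)[seed %% 3 + 1]; sigma <- 0.15
    m <- graph_cut(a, seed_set(fg, bg), graph_cut_params(lambda, sigma, 6))
    e_impl <- gc_oracle_energy(a, m, fg_lin, bg_lin, lambda, sigma, 6)
    e_min <- gc_oracle_min_energy(a, fg_lin, bg_lin, lambda, sigma, 6)
    expect_equal(e_impl, e_min, tolerance = 1e-9)
  }
})

test_that("livewire takes straight and diagonal geodesics on a constant slice", {
  s <- matrix(0.5, 6, 8)
  p <- livewire(s, c(1, 1), c(1, 6))
  expect_equal(nrow(p), 6)
  expect_true(all(p[, 1] == 1))
  expect_equal(p[, 2], 1:6)

  # diagonal: cost 3*sqrt(2)*w_u when only the uniform term is active
  p2 <- livewire(s, c(1, 1), c(4, 4), gradient_weight = 0, uniform_weight = 0.1)
  expect_equal(attr(p2, "cost"), 3 * sqrt(2) * 0.1, tolerance = 1e-12)
  # with the gradient term active on a constant slice, G == 0 adds w_g per unit
  p3 <- livewire(s, c(1, 1), c(4, 4))
  expect_equal(attr(p3, "cost"), 3 * sqrt(2) * 1.1, tolerance = 1e-12)
  expect_equal(nrow(p3), 4)
})

test_that("livewire hugs the high-gradient flanks of a dark ridge", {
  s <- matrix(0.8, 7, 7)
  s[4, ] <- 0.1
  # the central difference vanishes on the ridge line itself; the cheap
  # high-gradient pixels are its flanking rows
  p <- livewire(s, c(4, 1), c(4, 7))
  expect_true(all(p[, 1] %in% 3:5))
  expect_true(any(p[, 1] != 4) || nrow(p) == 7)
  # a step edge keeps the path inside the two high-gradient rows
  e <- matrix(0.1, 7, 7); e[4:7, ] <- 0.9
  pe <- livewire(e, c(4, 1), c(4, 7))
  expect_true(all(pe[, 1] %in% 3:5))
})

test_that("livewire cost equals the independent shortest-path oracle", {
  for (seed in 1:6) {
    withr::local_seed(300 + seed)
    ny <- sample(4:8, 1); nx <- sample(4:8, 1)
    s <- matrix(runif(ny * nx), ny, nx)
    from <- c(sample(ny, 1), sample(nx, 1))
    repeat {
      to <- c(sample(ny, 1), sample(nx, 1))
      if (any(to != from)) break
    }
    p <- livewire(s, from, to)
    expect_equal(attr(p, "cost"), lw_oracle_cost(s, from, to), tolerance = 1e-9)
  }
})

test_that("livewire is deterministic and validates its inputs", {
  withr::local_seed(17)
  s <- matrix(runif(64), 8, 8)
  p1 <- livewire(s, c(1, 1), c(8, 8))
  p2 <- livewire(s, c(1, 1), c(8, 8))
  expect_identical(p1, p2)
  expect_error(livewire(matrix(0.5, 1, 1), c(1, 1), c(1, 1)),
               class = "tomoseg_error_invalid_argument")
  expect_error(livewire(s, c(1, 1), c(1, 1)), class = "tomoseg_error_invalid_argument")
  expect_error(livewire(s, c(0, 1), c(2, 2)), class = "tomoseg_error_invalid_argument")
})

disk_mask <- function(n, center, r) {
  g <- expand.grid(y = 1:n, x = 1:n)
  matrix((g$y - center[1])^2 + (g$x - center[2])^2 <= r^2, n, n)
}

test_that("contour interpolation warns, fixes identical inputs, and validates", {
  a <- disk_mask(16, c(8, 8), 4)
  expect_warning(interpolate_contours(a, a, 2),
                 class = "tomoseg_warning_reproducibility")
  mids <- suppressWarnings(interpolate_contours(a, a, 3))
  for (m in mids) expect_equal(m, a)
  expect_error(suppressWarnings(interpolate_contours(a, a[1:8, ], 1)),
               class = "tomoseg_error_dimension_mismatch")
  none <- matrix(FALSE, 16, 16)
  expect_error(suppressWarnings(interpolate_contours(a, none, 1)),
               class = "tomoseg_error_empty_contour")
  expect_error(suppressWarnings(interpolate_contours(a, a, 0)),
               class = "tomoseg_error_invalid_argument")
})

test_that("midway between concentric disks is a disk of the mean radius", {
  n <- 24
  a <- disk_mask(n, c(12, 12), 2)
  b <- disk_mask(n, c(12, 12), 6)
  mid <- suppressWarnings(interpolate_contours(a, b, 1))[[1]]
  # area within one pixel ring of the analytic radius-4 disk
  expect_lte(abs(sum(mid) - pi * 16), pi * (4.5^2 - 3.5^2))
  # and the intermediate is itself centred and connected
  expect_true(mid[12, 12])
})

test_that("interpolation is symmetric under swapping endpoints and reversing t", {
  n <- 20
  a <- disk_mask(n, c(8, 8), 3)
  b <- disk_mask(n, c(13, 12), 5)
  f <- suppressWarnings(interpolate_contours(a, b, 3))
  r <- suppressWarnings(interpolate_contours(b, a, 3))
  for (k in 1:3) expect_equal(f[[k]], r[[4 - k]])
})

test_that("intermediate areas stay between the endpoint areas (within 10%)", {
  # translated disks close enough that the blended distance fields overlap
  # (for widely separated shapes the zero level set of the blend can vanish)
  n <- 24
  a <- disk_mask(n, c(11, 10), 3)
  b <- disk_mask(n, c(13, 15), 5)
  mids <- suppressWarnings(interpolate_contours(a, b, 3))
  lo <- min(sum(a), sum(b)) * 0.9
  hi <- max(sum(a), sum(b)) * 1.1
  for (m in mids) {
    expect_gte(sum(m), lo)
    expect_lte(sum(m), hi)
  }
})
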