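test_that("sphere footprint counts match hand-enumerated distances", {
  expect_equal(nrow(sphere_voxels(c(3, 3, 3), 0, c(5, 5, 5))), 1)
  # radius 1: centre + 6 face neighbours; corners at sqrt(2) excluded
  expect_equal(nrow(sphere_voxels(c(3, 3, 3), 1, c(5, 5, 5))), 7)
  # radius 10 from a corner covers the whole 4^3 volume (max distance 3*sqrt(3))
  expect_equal(nrow(sphere_voxels(c(1, 1, 1), 10, c(4, 4, 4))), 64)
  # clipping: radius 1 at the corner keeps in-volume voxels only
  expect_equal(nrow(sphere_voxels(c(1, 1, 1), 1, c(5, 5, 5))), 4)
})

test_that("painting a point stroke tags exactly one voxel and erase inverts it", {
  tg <- tag_volume(c(5, 5, 5))
  s <- brush_stroke(c(3, 3, 3), 0, tag = 5)
  tg2 <- apply_stroke(tg, s)
  expect_equal(sum(tg2 > 0), 1)
  expect_equal(tg2[3, 3, 3], 5L)
  tg3 <- apply_stroke(tg2, brush_stroke(c(3, 3, 3), 0, tag = 5, mode = "erase"))
  expect_equal(tg3, tg)
})

test_that("erase clears only the stroke's own tag", {
  tg <- tag_volume(c(5, 5, 5))
  tg <- apply_stroke(tg, brush_stroke(c(3, 3, 3), 1.5, tag = 2))
  tg[3, 3, 3] <- 7L
  out <- apply_stroke(tg, brush_stroke(c(3, 3, 3), 1.5, tag = 2, mode = "erase"))
  expect_equal(sum(out == 2L), 0)
  expect_equal(out[3, 3, 3], 7L)  # other tag protected
})

test_that("a swept stroke is gap-free and restricted painting stays in the mask", {
  d <- c(9, 9, 21)
  tg <- apply_stroke(tag_volume(d), brush_stroke(rbind(c(5, 5, 3), c(5, 5, 19)), 2, tag = 1))
  cc <- connected_components(tg == 1L, 6)
  expect_equal(length(cc$sizes), 1)  # simply connected tube

  restrict <- array(FALSE, d); restrict[, , 1:10] <- TRUE
  tg2 <- apply_stroke(tag_volume(d), brush_stroke(rbind(c(5, 5, 3), c(5, 5, 19)), 2, tag = 1),
                      restrict = restrict)
  expect_true(all(restrict[tg2 == 1L]))
  expect_gt(sum(tg2), 0)
})

test_that("strokes never modify voxels outside footprint and restriction", {
  d <- c(7, 7, 7)
  base <- tag_volume(d); base[1, 1, 1] <- 9L
  s <- brush_stroke(c(4, 4, 4), 1.2, tag = 3)
  out <- apply_stroke(base, s)
  foot <- array(FALSE, d); foot[sphere_voxels(c(4, 4, 4), 1.2, d)] <- TRUE
  expect_equal(out[!foot], base[!foot])
  expect_error(apply_stroke(base, brush_stroke(c(4, 4, 4), 1, tag = 0)),
               class = "tomoseg_error_invalid_argument")
})

test_that("paint order matters only where footprints overlap (last write wins)", {
  tg <- tag_volume(c(5, 5, 9))
  a <- brush_stroke(c(3, 3, 4), 2, tag = 1)
  b <- brush_stroke(c(3, 3, 6), 2, tag = 2)
  ab <- apply_stroke(apply_stroke(tg, a), b)
  ba <- apply_stroke(apply_stroke(tg, b), a)
  fa <- array(FALSE, c(5, 5, 9)); fa[sphere_voxels(c(3, 3, 4), 2, c(5, 5, 9))] <- TRUE
  fb <- array(FALSE, c(5, 5, 9)); fb[sphere_voxels(c(3, 3, 6), 2, c(5, 5, 9))] <- TRUE
  both <- fa & fb
  expect_equal(ab[!both], ba[!both])
  expect_true(all(ab[both] == 2L) && all(ba[both] == 1L))
})

test_that("stroke scripts round-trip through JSON lines", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"centers": [[3,3,3],[3,3,5]], "radius": 1, "tag": 2, "mode": "paint"}',
    '{"centers": [[3,3,3]], "radius": 0, "tag": 2, "mode": "erase"}'
  ), path)
  strokes <- read_strokes(path)
  expect_length(strokes, 2)
  tg <- tag_volume(c(5, 5, 7))
  for (s in strokes) tg <- apply_stroke(tg, s)
  expect_equal(tg[3, 3, 3], 0L)
  expect_equal(tg[3, 3, 5], 2L)
})

test_that("region growing returns exactly the seed's connected component", {
  m <- array(FALSE, c(5, 5, 9))
  m[2:3, 2:3, 2:3] <- TRUE   # block A
  m[2:3, 2:3, 6:8] <- TRUE   # block B, separated along x
  ra <- region_grow(m, c(2, 2, 2), 6)
  expect_equal(sum(ra), 8)
  expect_true(all(which(ra) %in% which(m)))
  rb <- region_grow(m, c(3, 3, 7), 6)
  expect_equal(sum(ra) + sum(rb), sum(m))

  full <- array(TRUE, c(4, 4, 4))
  expect_equal(region_grow(full, c(2, 3, 1), 6), full)
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_equal(sum(region_grow(single, c(2, 2, 2), 26)), 1)
  expect_error(region_grow(m, c(1, 1, 5), 6), class = "tomoseg_error_seed_not_in_selection")
  expect_error(region_grow(m, c(99, 1, 1), 6), class = "tomoseg_error_seed_not_in_selection")
})

test_that("connectivity decides whether diagonal voxels join a component", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  expect_length(connected_components(m, 6)$sizes, 2)
  expect_length(connected_components(m, 26)$sizes, 1)
  m2 <- array(FALSE, c(3, 3, 3)); m2[1, 1, 1] <- TRUE; m2[1, 2, 2] <- TRUE
  expect_length(connected_components(m2, 6)$sizes, 2)
  expect_length(connected_components(m2, 18)$sizes, 1)
})

test_that("component labeling matches the flood-fill oracle on random masks", {
  for (seed in 1:4) {
    m <- random_mask(c(5, 5, 5), p = 0.35, seed = 50 + seed)
    for (conn in c(6, 26)) {
      cc <- connected_components(m, conn)
      expect_true(same_partition(cc$labels, bf_components(m, conn)))
      expect_equal(sum(cc$sizes), sum(m))
      expect_equal(as.vector(table(cc$labels[cc$labels > 0])), cc$sizes)
    }
  }
  empty <- array(FALSE, c(3, 3, 3))
  expect_length(connected_components(empty, 6)$sizes, 0)
})

test_that("component labels follow first-encounter raster order (z, then y, then x)", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 3] <- TRUE  # encountered first: same z,y, larger x than nothing else in z=1,y=1
  m[1, 3, 1] <- TRUE
  m[3, 1, 1] <- TRUE
  cc <- connected_components(m, 6)
  expect_equal(cc$labels[1, 1, 3], 1L)
  expect_equal(cc$labels[1, 3, 1], 2L)
  expect_equal(cc$labels[3, 1, 1], 3L)
})

test_that("tag extraction crops to the bounding box and pads foreign voxels", {
  vol <- random_volume(c(10, 10, 10), bit_depth = 8, seed = 77)
  tg <- tag_volume(c(10, 10, 10))
  tg[4:5, 6:7, 2:3] <- 1L
  sub <- extract_tag(vol, tg, 1)
  expect_identical(sub$dims, c(2L, 2L, 2L))
  expect_equal(sub$data, vol$data[4:5, 6:7, 2:3])

  whole <- tag_volume(c(10, 10, 10)); whole[] <- 2L
  expect_equal(extract_tag(vol, whole, 2)$data, vol$data)

  # L-shaped region: box is the L's bounding box, non-tag voxels padded
  lt <- tag_volume(c(10, 10, 10))
  lt[2, 2, 2:5] <- 3L; lt[2, 3:4, 2] <- 3L
  sub <- extract_tag(vol, lt, 3, pad_value = 0)
  expect_identical(sub$dims, c(1L, 3L, 4L))
  expect_equal(sub$data[1, 1, ], vol$data[2, 2, 2:5])
  expect_equal(sub$data[1, 2, 2:4], rep(0, 3))
  # value multiset: tagged originals plus pads
  expect_setequal(as.vector(sub$data), c(vol$data[lt == 3L], rep(0, 12 - 6)))

  expect_error(extract_tag(vol, tg, 9), class = "tomoseg_error_empty_selection")
})
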