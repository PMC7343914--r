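test_that("normalisation makes polygons clockwise starting at twelve o'clock", {
  # counter-clockwise unit square (image coords, y down)
  sq <- contour(1, rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  n <- normalize_contour(sq)
  # clockwise = negative signed area with y growing downward
  expect_lt(speleoclean:::polygon_signed_area(n$vertices), 0)
  # starts at the top-left vertex (minimal image y, ties to smallest x)
  expect_equal(n$vertices[1, ], c(0, 0))
  expect_setequal(apply(n$vertices, 1, paste, collapse = ","),
                  apply(sq$vertices, 1, paste, collapse = ","))
  # idempotence
  expect_equal(normalize_contour(n)$vertices, n$vertices)
})

test_that("twelve o'clock ties break toward smaller x", {
  # regular hexagon with a flat top: two equally-top vertices
  th <- pi / 6 + (0:5) * pi / 3
  hexv <- cbind(cos(th), sin(th))  # y here is image-down; top = min y
  ctr <- normalize_contour(contour(1, hexv))
  tops <- hexv[hexv[, 2] == min(hexv[, 2]), , drop = FALSE]
  expect_equal(ctr$vertices[1, ], tops[which.min(tops[, 1]), ],
               tolerance = 1e-12)
})

test_that("invalid polygons are rejected", {
  expect_error(contour(1, rbind(c(0, 0), c(1, 1))), "3 vertices")
  bowtie <- contour(1, rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)))
  expect_error(normalize_contour(bowtie), "self-intersecting")
})

test_that("rasterisation follows the strict pixel-center even-odd rule", {
  # axis-aligned square covering exactly the 2x2 pixel centers (0,0)..(1,1)
  sq <- contour(1, rbind(c(-0.4, -0.4), c(1.4, -0.4), c(1.4, 1.4), c(-0.4, 1.4)))
  m <- rasterize_contour(sq, c(1, 1, 1), c(5, 5, 1))
  expect_identical(sum(m), 4L)
  expect_true(all(m[1:2, 1:2]))
  # shifted so centers fall outside on one edge: only one column remains
  sq2 <- contour(1, rbind(c(0.6, -0.4), c(1.4, -0.4), c(1.4, 1.4), c(0.6, 1.4)))
  m2 <- rasterize_contour(sq2, c(1, 1, 1), c(5, 5, 1))
  expect_identical(sum(m2), 2L)
  expect_true(all(m2[2, 1:2]))
})

test_that("rasterisation matches a brute-force even-odd oracle", {
  set.seed(42)
  for (rep in 1:5) {
    # random simple star-shaped polygon
    k <- sample(5:12, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    rad <- runif(k, 2, 6)
    v <- cbind(6 + rad * cos(ang), 6 + rad * sin(ang))
    ctr <- contour(1, v)
    m <- rasterize_contour(ctr, c(1, 1, 1), c(13, 13, 1))
    centers <- expand.grid(x = 0:12, y = 0:12)
    vn <- normalize_contour(ctr)$vertices
    oracle <- brute_pip(centers$x, centers$y, vn[, 1], vn[, 2])
    expect_identical(as.vector(m), oracle)
  }
})

test_that("multiple contours on one slice rasterise as their union", {
  a <- contour(1, rbind(c(-0.4, -0.4), c(1.4, -0.4), c(1.4, 1.4), c(-0.4, 1.4)))
  b <- contour(1, rbind(c(3.6, 3.6), c(5.4, 3.6), c(5.4, 5.4), c(3.6, 5.4)))
  m <- speleoclean:::rasterize_slice(list(a, b), c(1, 1, 1), c(7, 7, 1))
  expect_identical(sum(m), 8L)
  expect_true(all(m[1:2, 1:2]) && all(m[5:6, 5:6]))
})

test_that("mask interpolation is exact at endpoints and identity for equal masks", {
  disc <- function(r, n = 48) {
    cx <- matrix(rep(0:(n - 1), n), n) - (n - 1) / 2
    cy <- t(cx)
    cx^2 + cy^2 <= r^2
  }
  a <- disc(10)
  expect_identical(interpolate_masks(a, a, 0.3), a)
  b <- disc(20)
  expect_identical(interpolate_masks(a, b, 0), a)
  expect_identical(interpolate_masks(a, b, 1), b)
})

test_that("SDF blending of concentric discs yields the mid-radius disc", {
  n <- 48
  cx <- matrix(rep(0:(n - 1), n), n) - (n - 1) / 2
  cy <- t(cx)
  rr <- sqrt(cx^2 + cy^2)
  a <- rr <= 10
  b <- rr <= 20
  mid <- interpolate_masks(a, b, 0.5)
  # disc of radius 15 up to a 1-pixel boundary band
  expect_true(all(mid[rr <= 14]))
  expect_false(any(mid[rr >= 16]))
})

test_that("interpolation is symmetric and rejects double-empty input", {
  set.seed(5)
  n <- 32
  cx <- matrix(rep(0:(n - 1), n), n) - (n - 1) / 2
  cy <- t(cx)
  a <- (cx + 4)^2 + cy^2 <= 64
  b <- (cx - 6)^2 + (cy - 3)^2 <= 36
  for (t in c(0.25, 0.5, 0.8))
    expect_identical(interpolate_masks(a, b, t), interpolate_masks(b, a, 1 - t))
  e <- matrix(FALSE, n, n)
  expect_error(interpolate_masks(e, e, 0.5), "empty")
  # one empty side: the shape shrinks toward the empty end
  sizes <- vapply(c(0.2, 0.5, 0.8), function(t) sum(interpolate_masks(a, e, t)), 0)
  expect_true(all(diff(sizes) <= 0))
  expect_lt(sizes[3], sum(a))
})

test_that("dense mask is exact on keyframes and empty outside the support", {
  ph <- quiet_phantom()
  cs <- simulate_reader(ph, every_k = 10, vertex_noise_sd = 0,
                        n_vertices = 800, seed = 2)
  dm <- build_dense_mask(cs, ph$volume)
  keys <- keyframe_slices(cs)
  for (s in keys[c(1, 3, length(keys))]) {
    by_slice <- Filter(function(ctr) ctr$slice_index == s, cs$contours)
    expect_identical(dm$data[, , s],
                     speleoclean:::rasterize_slice(by_slice, cs$spacing, cs$shape))
  }
  expect_false(any(dm$data[, , seq_len(keys[1] - 1)]))
  nz <- dim(dm$data)[3]
  if (max(keys) < nz)
    expect_false(any(dm$data[, , (max(keys) + 1):nz]))
  # every slice between the first and last keyframe is populated
  expect_true(all(apply(dm$data[, , keys[1]:max(keys)], 3, any)))
})

test_that("a single keyframe is rejected with guidance", {
  ph <- quiet_phantom()
  cs <- simulate_reader(ph, every_k = 10, vertex_noise_sd = 0,
                        n_vertices = 200, seed = 2)
  one <- contour_set(cs$reader_id,
                     Filter(function(ctr) ctr$slice_index == keyframe_slices(cs)[1],
                            cs$contours),
                     cs$spacing, cs$shape)
  expect_error(build_dense_mask(one, ph$volume), "at\\s+least 2 slices")
})

test_that("interpolation fidelity improves monotonically with keyframe density", {
  ph <- quiet_phantom()
  dices <- vapply(c(20, 10, 5, 1), function(k) {
    cs <- simulate_reader(ph, every_k = k, vertex_noise_sd = 0,
                          n_vertices = 800, seed = 1)
    dice_coefficient(build_dense_mask(cs, ph$volume), ph$bone_mask)
  }, 0)
  expect_gte(dices[2], 0.97)
  expect_true(all(diff(dices) >= 0))
  expect_equal(dices[4], 1)
})

test_that("mask edits replace single slices and append provenance", {
  ph <- quiet_phantom()
  mask <- ph$bone_mask
  s <- which(apply(mask$data, 3, any))[5]
  same <- edit_mask(mask, s, mask$data[, , s])
  expect_identical(same$data, mask$data)
  empty <- edit_mask(mask, s, matrix(FALSE, dim(mask$data)[1], dim(mask$data)[2]))
  expect_identical(sum(empty$data), sum(mask$data) - sum(mask$data[, , s]))
  twice <- edit_mask(empty, s + 1L,
                     matrix(FALSE, dim(mask$data)[1], dim(mask$data)[2]))
  np <- length(mask$provenance)
  expect_identical(tail(twice$provenance, 2),
                   c(sprintf("edit: slice %d replaced", s),
                     sprintf("edit: slice %d replaced", s + 1L)))
  expect_error(edit_mask(mask, 10000L, matrix(FALSE, 2, 2)), "out of range")
})

test_that("contour sets round-trip through the .contours.json format", {
  ph <- quiet_phantom()
  cs <- simulate_reader(ph, every_k = 20, vertex_noise_sd = 0.2,
                        n_vertices = 60, seed = 3)
  f <- withr::local_tempfile(fileext = ".contours.json")
  write_contours(cs, f)
  cs2 <- read_contours(f)
  expect_identical(cs2$reader_id, cs$reader_id)
  expect_equal(cs2$spacing, cs$spacing)
  expect_identical(cs2$shape, cs$shape)
  expect_length(cs2$contours, length(cs$contours))
  for (i in seq_along(cs$contours)) {
    expect_identical(cs2$contours[[i]]$slice_index, cs$contours[[i]]$slice_index)
    expect_equal(cs2$contours[[i]]$vertices, cs$contours[[i]]$vertices)
  }
})
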