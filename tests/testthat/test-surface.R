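test_that("sphere mesh area and volume match the closed forms", {
  m <- sphere_mesh()  # R = 10 mm at 0.5 mm spacing, iso at half-max
  expect_lt(abs(mesh_area(m) / (4 * pi * 100) - 1), 0.02)
  expect_lt(abs(mesh_volume(m) / (4 / 3 * pi * 1000) - 1), 0.01)
  # positive volume = consistently outward winding
  expect_gt(mesh_volume(m), 0)
})

test_that("an isotropic object survives anisotropic sampling", {
  v <- sphere_field(R = 10, spacing = c(0.33, 0.33, 0.67))
  m <- extract_isosurface(v, 500)
  ex <- diff(range(m$vertices[, 1]))
  ez <- diff(range(m$vertices[, 3]))
  expect_lt(abs(ex - ez), 0.67)  # within one z voxel
})

test_that("surface extraction commutes with world-origin shifts", {
  v <- sphere_field(R = 6, spacing = c(0.5, 0.5, 0.5))
  m1 <- extract_isosurface(v, 500)
  v2 <- ct_volume(v$data, v$spacing, v$origin + c(5, -3, 11))
  m2 <- extract_isosurface(v2, 500)
  expect_equal(m2$vertices,
               m1$vertices + matrix(c(5, -3, 11), nrow(m1$vertices), 3,
                                    byrow = TRUE))
  expect_identical(m2$triangles, m1$triangles)
})

test_that("volumes with no threshold crossing are rejected", {
  v <- ct_volume(array(100, dim = c(4, 4, 4)), c(1, 1, 1))
  expect_error(extract_isosurface(v, 500), "empty surface")
})

test_that("mesh volume agrees with voxel-count volume on a smooth phantom", {
  ph <- quiet_phantom()
  cl <- compute_masked_preview(ph$volume, ph$bone_mask)
  m <- suppressMessages(largest_component(extract_isosurface(cl)))
  vox_vol <- sum(ph$bone_mask$data) * prod(ph$volume$spacing)
  expect_lt(abs(mesh_volume(m) / vox_vol - 1), 0.03)
})

test_that("largest_component keeps the dominant part and reports the rest", {
  m <- sphere_mesh()
  expect_identical(largest_component(m)$triangles, m$triangles)
  # append a small detached cube far outside the sphere
  cube_v <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2))) +
    matrix(c(30, 30, 30), 8, 3, byrow = TRUE)
  cube_t <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
                  c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
                  c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  both <- surface_mesh(rbind(m$vertices, cube_v),
                       rbind(m$triangles, cube_t + nrow(m$vertices)))
  kept <- largest_component(both)
  expect_identical(nrow(kept$triangles), nrow(m$triangles))
  expect_length(attr(kept, "discarded"), 1L)
  expect_equal(attr(kept, "discarded"), 8, tolerance = 1e-9)
})

test_that("equal-volume component ties keep the smallest vertex index", {
  cube_v <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  cube_t <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
                  c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
                  c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  two <- surface_mesh(rbind(cube_v,
                            cube_v + matrix(c(10, 0, 0), 8, 3, byrow = TRUE)),
                      rbind(cube_t, cube_t + 8L))
  expect_warning(kept <- largest_component(two), "equal-volume")
  expect_lt(max(kept$vertices[, 1]), 5)  # the first cube survives
})

test_that("binary STL round-trips the triangulation", {
  m <- sphere_mesh()
  f <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, f)
  expect_identical(file.info(f)$size, 84 + 50 * nrow(m$triangles))
  m2 <- read_stl(f)
  expect_identical(nrow(m2$triangles), nrow(m$triangles))
  # enclosed volume preserved to single precision
  expect_lt(abs(mesh_volume(m2) - mesh_volume(m)) / abs(mesh_volume(m)), 1e-5)
  expect_match(m2$provenance$source, "speleoclean")
})

test_that("a two-triangle STL file has the exact record size", {
  m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                    rbind(c(1, 2, 3), c(2, 4, 3)))
  f <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, f)
  expect_identical(file.info(f)$size, 80 + 4 + 2 * 50)
})

test_that("non-finite coordinates are rejected before writing", {
  expect_error(surface_mesh(rbind(c(0, 0, NaN), c(1, 0, 0), c(0, 1, 0)),
                            rbind(c(1, 2, 3))),
               "finite")
})

test_that("PLY export carries the per-vertex scalar channel", {
  m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    rbind(c(1, 2, 3)))
  f <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, f, scalars = c(0.1, 0.2, 0.3))
  lines <- readLines(f)
  expect_true("property float quality" %in% lines)
  expect_identical(sum(lines == "end_header"), 1L)
  body <- lines[(which(lines == "end_header") + 1):length(lines)]
  expect_length(body, 3 + 1)
  expect_error(write_ply(m, f, scalars = 1:2), "one value per vertex")
})
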