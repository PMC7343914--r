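# Implicit surface-of-revolution sampler: radius profile r(z) about the z
# axis, used to construct shapes with known calipers.
revolve_field <- function(rfun, zlim, rmax, spacing = c(0.5, 0.5, 0.5)) {
  lo <- c(-rmax - 2, -rmax - 2, zlim[1] - 2)
  hi <- c(rmax + 2, rmax + 2, zlim[2] + 2)
  n <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  cx <- lo[1] + (seq_len(n[1]) - 1) * spacing[1]
  cy <- lo[2] + (seq_len(n[2]) - 1) * spacing[2]
  cz <- lo[3] + (seq_len(n[3]) - 1) * spacing[3]
  X <- array(cx, dim = n)
  Y <- array(rep(cy, each = n[1]), dim = n)
  Z <- array(rep(cz, each = n[1] * n[2]), dim = n)
  rho <- sqrt(X^2 + Y^2)
  zin <- pmin(pmax(Z, zlim[1]), zlim[2])
  sdf <- rfun(zin) - rho
  sdf <- pmin(sdf, Z - zlim[1], zlim[2] - Z)  # capped ends
  ct_volume(pmin(pmax(0.5 + sdf / (2 * max(spacing)), 0), 1) * 1000,
            spacing, lo)
}

test_that("the shaft axis is recovered within 2 degrees", {
  m <- quiet_mesh()
  ai <- shaft_axis(m)
  expect_lt(acos(min(1, abs(ai$axis[3]))) * 180 / pi, 2)
  # axis points toward the head (+z in the phantom's frame)
  expect_gt(ai$axis[3], 0)
})

test_that("the axis is equivariant under a known rotation", {
  m <- quiet_mesh()
  withr::with_seed(12, {
    rot <- random_rotation()
    m2 <- transform_mesh(m, rot, c(20, -5, 12))
    expected <- as.numeric(rot %*% c(0, 0, 1))
    ai <- shaft_axis(m2)
    expect_lt(acos(min(1, abs(sum(ai$axis * expected)))) * 180 / pi, 2)
  })
})

test_that("non-elongated meshes are rejected", {
  expect_error(shaft_axis(sphere_mesh()), "not elongated")
})

test_that("SD finds a constructed waist", {
  # cylinder radius 10 with a smooth waist dipping to radius 8
  v <- revolve_field(function(z) 10 - 2 * exp(-((z - 30) / 8)^2),
                     c(0, 60), 10)
  m <- extract_isosurface(v, 500)
  ai <- list(axis = c(0, 0, 1), extent = c(0, 60), shaft_range = c(0, 45))
  sd1 <- measure_sd(m, ai, station_step = 0.5)
  expect_lt(abs(sd1 - 16), 1.0)
  expect_lt(abs(attr(sd1, "station") - 30), 2)
  # refinement stability: halving the station step barely moves the result
  sd2 <- measure_sd(m, ai, station_step = 0.25)
  expect_lt(abs(sd1 - sd2), 0.3)
})

test_that("DC sphere fit is accurate and flags non-spherical regions", {
  m <- sphere_mesh()  # analytic R = 10
  dc <- measure_dc(m, axis_info = list(axis = c(0, 0, 1)),
                   head_region = rep(TRUE, nrow(m$vertices)))
  expect_lt(abs(dc - 20), 0.2)
  expect_lt(attr(dc, "rms"), 0.01 * attr(dc, "radius"))
  # a region that is mostly shaft must error as non-spherical
  mq <- quiet_mesh()
  ai <- shaft_axis(mq)
  s <- as.numeric(mq$vertices %*% ai$axis)
  shaft_sel <- s < min(s) + 0.5 * diff(range(s))
  expect_error(measure_dc(mq, ai, head_region = shaft_sel), "not spherical")
})

test_that("phantom osteometrics are recovered within 2 voxels at zero noise", {
  ph <- quiet_phantom()
  m <- quiet_mesh()
  rep <- osteometric_report(m)
  tol <- 2 * max(ph$volume$spacing)
  expect_lt(abs(rep$measures["Bp"] - ph$true_measures["Bp"]), tol)
  expect_lt(abs(rep$measures["DC"] - ph$true_measures["DC"]), tol)
  expect_lt(abs(rep$measures["SD"] - ph$true_measures["SD"]), tol)
  expect_equal(sqrt(sum(rep$axis^2)), 1)
  expect_gte(rep$measures["Bp"], rep$measures["SD"])
})

test_that("measures are invariant under rigid transforms within 0.5%", {
  m <- quiet_mesh()
  r0 <- osteometric_report(m)
  withr::with_seed(77, {
    for (i in 1:2) {
      m2 <- transform_mesh(m, random_rotation(), stats::runif(3, -40, 40))
      r2 <- osteometric_report(m2)
      expect_true(all(abs(r2$measures - r0$measures) / r0$measures < 0.005))
    }
  })
})

test_that("a full proximal region keeps Bp at least SD", {
  m <- quiet_mesh()
  ai <- shaft_axis(m)
  bp_full <- measure_bp(m, ai, proximal_fraction = 1.0)
  sd_ <- measure_sd(m, ai)
  expect_gte(bp_full, as.numeric(sd_))
})

test_that("tilted phantoms measure the same as upright ones", {
  sp <- phantom_spec(spacing = c(0.8, 0.8, 1.2), noise_sd = 0, seed = 21,
                     tilt_deg = 20)
  ph <- generate_phantom(sp)
  m <- suppressMessages(largest_component(extract_isosurface(
    compute_masked_preview(ph$volume, ph$bone_mask))))
  ai <- shaft_axis(m)
  expected <- c(sin(20 * pi / 180), 0, cos(20 * pi / 180))
  expect_lt(acos(min(1, abs(sum(ai$axis * expected)))) * 180 / pi, 2)
  rep <- osteometric_report(m)
  tol <- 2 * max(sp$spacing)
  expect_true(all(abs(rep$measures - ph$true_measures) < tol))
})

test_that("comparison against direct measurements reports mean and sd", {
  virt <- c(Bp = 75.0, DC = 30.7, SD = 29.6)
  expect_equal(compare_to_direct(virt, virt), list(differences = virt - virt,
                                                   mean = 0, sd = 0))
  direct <- c(Bp = 75.1, DC = 30.3, SD = 28.9)
  cmp <- compare_to_direct(virt, direct)
  expect_equal(unname(cmp$differences), c(0.1, 0.4, 0.7))
  expect_equal(cmp$mean, 0.4)
  expect_equal(cmp$sd, 0.3)
  expect_warning(one <- compare_to_direct(c(Bp = 75), c(Bp = 74.5)), "sd")
  expect_equal(one$sd, 0)
  expect_error(compare_to_direct(virt, c(GL = 100)), "match")
})
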