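# Shared fixtures, built once per test run and cached. All synthetic; sizes
# chosen so the whole suite stays light: test phantoms use coarser spacing
# than the study default, which scales voxel counts without changing any of
# the contracts under test.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# the workhorse phantom: default geometry, coarsened grid, no noise
quiet_phantom <- function() fixture("quiet_phantom", function() {
  generate_phantom(phantom_spec(spacing = c(0.66, 0.66, 1.0),
                                noise_sd = 0, seed = 7))
})

# its cleaned volume and mesh via the truth mask (no reader in the loop)
quiet_mesh <- function() fixture("quiet_mesh", function() {
  ph <- quiet_phantom()
  cl <- compute_masked_preview(ph$volume, ph$bone_mask)
  suppressMessages(largest_component(extract_isosurface(cl)))
})

# analytic sphere sampled as a smooth occupancy field: the iso-contour of
# value `iso` sits exactly at radius R, so mesh area/volume have closed forms
sphere_field <- function(R = 10, spacing = c(0.5, 0.5, 0.5), margin = 3,
                         value = 1000) {
  n <- as.integer(ceiling(2 * (R + margin) / spacing)) + 1L
  orig <- -(n - 1) / 2 * spacing
  cx <- orig[1] + (seq_len(n[1]) - 1) * spacing[1]
  cy <- orig[2] + (seq_len(n[2]) - 1) * spacing[2]
  cz <- orig[3] + (seq_len(n[3]) - 1) * spacing[3]
  X <- array(cx, dim = n)
  Y <- array(rep(cy, each = n[1]), dim = n)
  Z <- array(rep(cz, each = n[1] * n[2]), dim = n)
  r <- sqrt(X^2 + Y^2 + Z^2)
  h <- max(spacing)
  occ <- pmin(pmax(0.5 + (R - r) / (2 * h), 0), 1)
  ct_volume(occ * value, spacing, orig)
}

sphere_mesh <- function() fixture("sphere_mesh", function() {
  extract_isosurface(sphere_field(), 500)
})

# brute-force nearest-neighbour oracle (independent of the kd-tree path)
brute_nn <- function(a, b) {
  apply(a, 1, function(p) sqrt(min(colSums((t(b) - p)^2))))
}

# brute-force even-odd point-in-polygon oracle in plain R
brute_pip <- function(px, py, vx, vy) {
  n <- length(vx)
  vapply(seq_along(px), function(q) {
    x <- px[q]; y <- py[q]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((vy[i] > y) != (vy[j] > y)) {
        xc <- vx[j] + (y - vy[j]) * (vx[i] - vx[j]) / (vy[i] - vy[j])
        if (x < xc) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

random_rotation <- function() {
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])),
              c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0),
              c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

transform_mesh <- function(mesh, rot, shift = c(0, 0, 0)) {
  surface_mesh(mesh$vertices %*% t(rot) +
                 matrix(shift, nrow(mesh$vertices), 3, byrow = TRUE),
               mesh$triangles, mesh$provenance)
}

# identity calibration curve: mu(t) = t with zero curve error
identity_curve <- function(from = 6000, to = 4000) {
  calibration_curve(seq(from, to), seq(from, to), rep(0, from - to + 1),
                    "identity")
}

has_python_pydicom <- function() {
  isTRUE(tryCatch(
    system2("python", c("-c", shQuote("import pydicom")), stdout = FALSE,
            stderr = FALSE) == 0,
    error = function(e) FALSE))
}
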