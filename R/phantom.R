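# Synthetic encrusted-specimen phantoms with analytic ground truth.
#
# The bone is a proximal femur-like solid: a capped cylindrical shaft (axis
# along z, optionally tilted), a constant-radius oblique neck cylinder
# inclined 45 degrees laterally, a spherical head at the neck's end, and a
# lateral spherical bump standing in for the greater trochanter. The crust is
# a shell of spatially varying thickness around the bone. Bone and crust
# voxels draw HU from overlapping normal distributions — the regime that
# makes plain thresholding fail on the real specimen class — then the volume
# is Gaussian-blurred (partial-volume surrogate) and corrupted with additive
# noise. The returned bone mask is the pre-degradation rasterisation, and the
# three osteometric truths have closed forms from the construction:
# SD = 2 * shaft_radius, DC = 2 * head_radius,
# Bp = shaft_radius + trochanter_bump_radius + neck_length/sqrt(2) + head_radius.

NECK_INCLINATION <- pi / 4  # lateral inclination of the neck axis

#' Phantom specification
#'
#' Defaults mirror the study conditions: anisotropic voxel size
#' 0.33 x 0.33 x 0.67 mm, a shaft radius of 14.8 mm and head radius of
#' 15.35 mm (so the smallest shaft diameter and head depth echo a wild-boar
#' proximal femur), and bone/calcite HU distributions close enough to overlap
#' substantially.
#'
#' @param shaft_radius,shaft_length,head_radius,neck_radius,neck_length,trochanter_bump_radius
#'   bone geometry in mm; `head_radius` must exceed `neck_radius`.
#' @param crust_thickness_mean,crust_thickness_sd crust shell thickness (mm):
#'   mean and the amplitude scale of its smooth spatial variation.
#' @param hu_bone_mean,hu_bone_sd,hu_calcite_mean,hu_calcite_sd,hu_background
#'   HU distribution parameters for bone and crust voxels, and the constant
#'   background (air) value.
#' @param blur_sigma Gaussian blur sigma in mm (partial-volume surrogate).
#' @param noise_sd additive HU noise standard deviation.
#' @param spacing voxel size (dx, dy, dz) mm.
#' @param tilt_deg rotation of the whole bone about the y axis, degrees.
#' @param seed integer seed; the generator is bit-reproducible per seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shaft_radius = 14.8, shaft_length = 90,
                         head_radius = 15.35, neck_radius = 11,
                         neck_length = 25, trochanter_bump_radius = 12,
                         crust_thickness_mean = 4, crust_thickness_sd = 1,
                         hu_bone_mean = 1300, hu_bone_sd = 150,
                         hu_calcite_mean = 1400, hu_calcite_sd = 150,
                         hu_background = -1024,
                         blur_sigma = 0.4, noise_sd = 20,
                         spacing = c(0.33, 0.33, 0.67),
                         tilt_deg = 0, seed = 42L) {
  spec <- list(shaft_radius = shaft_radius, shaft_length = shaft_length,
               head_radius = head_radius, neck_radius = neck_radius,
               neck_length = neck_length,
               trochanter_bump_radius = trochanter_bump_radius,
               crust_thickness_mean = crust_thickness_mean,
               crust_thickness_sd = crust_thickness_sd,
               hu_bone_mean = hu_bone_mean, hu_bone_sd = hu_bone_sd,
               hu_calcite_mean = hu_calcite_mean, hu_calcite_sd = hu_calcite_sd,
               hu_background = hu_background,
               blur_sigma = blur_sigma, noise_sd = noise_sd,
               spacing = as.numeric(spacing), tilt_deg = tilt_deg,
               seed = as.integer(seed))
  pos <- c("shaft_radius", "shaft_length", "head_radius", "neck_radius",
           "neck_length", "trochanter_bump_radius", "crust_thickness_mean",
           "blur_sigma")
  for (f in pos)
    if (!is.finite(spec[[f]]) || spec[[f]] <= 0)
      stop("`", f, "` must be positive")
  if (any(spec$spacing <= 0)) stop("spacing must be positive")
  if (spec$head_radius <= spec$neck_radius)
    stop("head_radius must exceed neck_radius (head_radius = ",
         head_radius, ", neck_radius = ", neck_radius, ")")
  if (spec$crust_thickness_mean + 2 * abs(spec$crust_thickness_sd) <
      max(spec$spacing))
    stop("crust thinner than one voxel everywhere: degenerate phantom")
  class(spec) <- "phantom_spec"
  spec
}

#' Closed-form ground-truth osteometrics of a phantom spec
#' @param spec a [phantom_spec].
#' @return named vector `c(Bp, DC, SD)` in mm.
#' @export
phantom_true_measures <- function(spec) {
  c(Bp = spec$shaft_radius + spec$trochanter_bump_radius +
        spec$neck_length * sin(NECK_INCLINATION) + spec$head_radius,
    DC = 2 * spec$head_radius,
    SD = 2 * spec$shaft_radius)
}

phantom_geometry <- function(spec) {
  u <- c(sin(NECK_INCLINATION), 0, cos(NECK_INCLINATION))
  C <- c(0, 0, spec$shaft_length)                 # shaft top center
  H <- C + spec$neck_length * u                   # head center
  Tb <- c(-spec$shaft_radius, 0, spec$shaft_length) # trochanter bump center
  list(u = u, C = C, H = H, T = Tb)
}

# membership of world points (rows of P, canonical frame) in the bone solid,
# optionally inflated by a per-point offset `infl` (mm)
phantom_bone_membership <- function(spec, X, Y, Z, infl = 0) {
  g <- phantom_geometry(spec)
  r2 <- X^2 + Y^2
  shaft <- (r2 <= (spec$shaft_radius + infl)^2) &
    (Z >= -infl) & (Z <= spec$shaft_length + infl)
  head <- ((X - g$H[1])^2 + Y^2 + (Z - g$H[3])^2) <= (spec$head_radius + infl)^2
  troch <- ((X - g$T[1])^2 + Y^2 + (Z - g$T[3])^2) <=
    (spec$trochanter_bump_radius + infl)^2
  # oblique neck cylinder from C to H
  vx <- X - g$C[1]; vz <- Z - g$C[3]
  tproj <- (vx * g$u[1] + vz * g$u[3]) / spec$neck_length
  tc <- pmin(pmax(tproj, 0), 1)
  ax <- g$C[1] + tc * spec$neck_length * g$u[1]
  az <- g$C[3] + tc * spec$neck_length * g$u[3]
  neck <- ((X - ax)^2 + Y^2 + (Z - az)^2) <= (spec$neck_radius + infl)^2
  shaft | head | troch | neck
}

gaussian_blur3d <- function(a, sigma_vox) {
  # separable shift-and-add convolution with replicate edges
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- dnorm(seq(-r, r), sd = s)
    w <- w / sum(w)
    out <- array(0, dim = d)
    n <- d[ax]
    for (q in seq(-r, r)) {
      idx <- pmin(pmax(seq_len(n) + q, 1L), n)
      shifted <- switch(ax,
                        a[idx, , , drop = FALSE],
                        a[, idx, , drop = FALSE],
                        a[, , idx, drop = FALSE])
      out <- out + w[q + r + 1] * shifted
    }
    a <- out
  }
  a
}

#' Generate a synthetic encrusted-specimen CT volume with ground truth
#'
#' @param spec a [phantom_spec].
#' @return A `phantom_truth` list with elements `volume` (a [ct_volume]),
#'   `bone_mask` (a [binary_mask]; the exact pre-blur rasterisation),
#'   `true_measures` (closed-form `Bp`, `DC`, `SD` in mm), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  tmax <- spec$crust_thickness_mean + 2 * abs(spec$crust_thickness_sd)
  margin <- tmax + 2
  # canonical-frame bounds of bone + crust + margin
  lo <- c(g$T[1] - spec$trochanter_bump_radius - margin,
          -max(spec$shaft_radius, spec$head_radius,
               spec$trochanter_bump_radius) - margin,
          -margin)
  hi <- c(g$H[1] + spec$head_radius + margin,
          max(spec$shaft_radius, spec$head_radius,
              spec$trochanter_bump_radius) + margin,
          g$H[3] + spec$head_radius + margin)
  if (spec$tilt_deg != 0) {  # bounds of the rotated canonical box
    th <- spec$tilt_deg * pi / 180
    corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                     c(lo[3], hi[3])))
    rot <- cbind(c(cos(th), 0, -sin(th)), c(0, 1, 0), c(sin(th), 0, cos(th)))
    wc <- corners %*% t(rot)
    lo <- apply(wc, 2, min); hi <- apply(wc, 2, max)
  }
  nvox <- pmax(2L, as.integer(ceiling((hi - lo) / spec$spacing)) + 1L)
  origin <- lo
  cx <- origin[1] + (seq_len(nvox[1]) - 1) * spec$spacing[1]
  cy <- origin[2] + (seq_len(nvox[2]) - 1) * spec$spacing[2]
  cz <- origin[3] + (seq_len(nvox[3]) - 1) * spec$spacing[3]
  X <- array(cx, dim = nvox)
  Y <- array(rep(cy, each = nvox[1]), dim = nvox)
  Z <- array(rep(cz, each = nvox[1] * nvox[2]), dim = nvox)
  if (spec$tilt_deg != 0) {
    # rotate sampling points back into the canonical bone frame (about y)
    th <- -spec$tilt_deg * pi / 180
    Xc <- cos(th) * X + sin(th) * Z
    Zc <- -sin(th) * X + cos(th) * Z
    X <- Xc; Z <- Zc
  }

  vol <- withr::with_seed(spec$seed, {
    bone <- phantom_bone_membership(spec, X, Y, Z)
    # smooth spatially varying crust thickness
    ph <- stats::runif(4, 0, 2 * pi)
    theta <- atan2(Y, X)
    zspan <- max(1, g$H[3] + spec$head_radius)
    thick <- spec$crust_thickness_mean +
      spec$crust_thickness_sd * (sin(theta + ph[1]) *
                                   cos(2 * pi * Z / zspan + ph[2]) +
                                 0.6 * sin(2 * theta + ph[3]) *
                                   sin(2 * pi * Z / (0.5 * zspan) + ph[4]))
    thick <- pmax(thick, 0.1)
    crust <- phantom_bone_membership(spec, X, Y, Z, infl = thick) & !bone
    hu <- array(spec$hu_background, dim = nvox)
    nb <- sum(bone); nc <- sum(crust)
    hu[bone] <- rnorm(nb, spec$hu_bone_mean, spec$hu_bone_sd)
    hu[crust] <- rnorm(nc, spec$hu_calcite_mean, spec$hu_calcite_sd)
    hu <- gaussian_blur3d(hu, spec$blur_sigma / spec$spacing)
    if (spec$noise_sd > 0)
      hu <- hu + array(rnorm(length(hu), 0, spec$noise_sd), dim = nvox)
    list(hu = hu, bone = bone)
  })

  truth <- structure(
    list(volume = ct_volume(vol$hu, spec$spacing, origin,
                            meta = list(derivation = "phantom")),
         bone_mask = binary_mask(array(vol$bone, dim = nvox),
                                 provenance = sprintf(
                                   "phantom ground truth (seed %d)", spec$seed)),
         true_measures = phantom_true_measures(spec),
         spec = spec),
    class = "phantom_truth")
  truth
}

#' @export
print.phantom_truth <- function(x, ...) {
  tm <- x$true_measures
  cat(sprintf(paste0("<phantom_truth> grid %s; true Bp %.2f, DC %.2f, ",
                     "SD %.2f mm; seed %d\n"),
              paste(dim(x$volume$data), collapse = " x "),
              tm["Bp"], tm["DC"], tm["SD"], x$spec$seed))
  invisible(x)
}

#' Simulate an imperfect human reader
#'
#' On every `every_k`-th slice intersecting the bone (starting from the first
#' bone-bearing slice), traces the exact in-plane boundary of each connected
#' component of the truth mask, resamples it to `n_vertices` points, and
#' perturbs each vertex radially (about the component centroid) by
#' `N(0, vertex_noise_sd)` mm. With zero noise and `n_vertices` at least the
#' traced boundary length, the contours rasterise back to the true slice mask
#' exactly. When the resample count is below the boundary vertex count the
#' polygon is a uniform arc-length approximation.
#'
#' @param truth a `phantom_truth` from [generate_phantom].
#' @param every_k keyframe stride in slices (10 emulates drawing on every
#'   tenth slice).
#' @param vertex_noise_sd radial vertex jitter sd in mm.
#' @param n_vertices points per contour after resampling.
#' @param seed reader-specific seed.
#' @return A [contour_set] (reader id records the seed and noise).
#' @export
simulate_reader <- function(truth, every_k = 10L, vertex_noise_sd = 0,
                            n_vertices = 200L, seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (every_k < 1L) stop("every_k must be >= 1")
  mask <- truth$bone_mask$data
  spacing <- truth$volume$spacing
  nz <- dim(mask)[3]
  bone_slices <- which(apply(mask, 3, any))
  if (length(bone_slices) < 2L) stop("bone mask present on fewer than 2 slices")
  keys <- bone_slices[seq(1L, length(bone_slices), by = every_k)]
  contours <- withr::with_seed(seed, {
    out <- list()
    for (s in keys) {
      loops <- trace_boundary_loops(mask[, , s])
      for (lp in loops) {
        v_px <- resample_polygon(lp, n_vertices)
        v_mm <- cbind((v_px[, 1] - 1) * spacing[1],
                      (v_px[, 2] - 1) * spacing[2])
        if (vertex_noise_sd > 0) {
          cen <- colMeans(v_mm)
          rel <- sweep(v_mm, 2, cen)
          rr <- sqrt(rowSums(rel^2))
          rr[rr == 0] <- 1
          # radial jitter can fold a locally concave boundary into a
          # self-intersection; redraw (still within this seed's stream,
          # hence deterministic) until the polygon is simple
          for (attempt in 1:25) {
            noise <- rnorm(nrow(v_mm), 0, vertex_noise_sd)
            cand <- v_mm + rel / rr * noise
            if (!.polygon_self_intersects(cand[, 1], cand[, 2])) break
            if (attempt == 25)
              stop("could not draw a simple noisy contour on slice ", s,
                   "; vertex_noise_sd is too large for this boundary")
          }
          v_mm <- cand
        }
        out[[length(out) + 1L]] <- normalize_contour(contour(s, v_mm))
      }
    }
    out
  })
  contour_set(sprintf("sim-seed%d-noise%.3g", seed, vertex_noise_sd),
              contours, spacing, dim(mask))
}

# Resample a closed polygon to exactly n vertices. If n >= nrow(poly) the
# original vertices are all kept and extra points are inserted on the longest
# edges (collinear, so the geometry is unchanged); otherwise vertices are
# placed uniformly by arc length (inscribed approximation).
resample_polygon <- function(poly, n) {
  m <- nrow(poly)
  if (n >= m) {
    extra <- n - m
    if (extra == 0) return(poly)
    seg <- sqrt(rowSums((poly[c(2:m, 1), ] - poly)^2))
    counts <- integer(m)
    # spread extra points over edges proportionally to length
    alloc <- floor(extra * seg / sum(seg))
    counts <- alloc
    rem <- extra - sum(alloc)
    if (rem > 0) {
      ord <- order(seg, decreasing = TRUE)
      counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
    }
    pieces <- vector("list", m)
    for (i in seq_len(m)) {
      a <- poly[i, ]; b <- poly[if (i == m) 1L else i + 1L, ]
      k <- counts[i]
      ts <- seq(0, 1, length.out = k + 2L)[1:(k + 1L)]
      pieces[[i]] <- cbind(a[1] + ts * (b[1] - a[1]),
                           a[2] + ts * (b[2] - a[2]))
    }
    do.call(rbind, pieces)
  } else {
    closed <- rbind(poly, poly[1, ])
    seg <- sqrt(rowSums(diff(closed)^2))
    cum <- c(0, cumsum(seg))
    total <- cum[length(cum)]
    ts <- seq(0, total, length.out = n + 1L)[seq_len(n)]
    xi <- approx(cum, closed[, 1], xout = ts)$y
    yi <- approx(cum, closed[, 2], xout = ts)$y
    cbind(xi, yi)
  }
}

#' Histogram overlap coefficient of bone vs crust HU populations
#'
#' Utility for characterising how confusable the two materials are in a
#' generated phantom: the overlap coefficient (shared area) of the two
#' normalised HU histograms, computed on a common bin grid.
#'
#' @param truth a `phantom_truth`.
#' @param nbins histogram bin count.
#' @return overlap coefficient in `[0, 1]`.
#' @export
hu_overlap_coefficient <- function(truth, nbins = 200L) {
  spec <- truth$spec
  g <- phantom_geometry(spec)
  vol <- truth$volume$data
  bone <- truth$bone_mask$data
  # crust = supra-background voxels outside the bone mask (the blurred shell)
  thr <- (spec$hu_background + min(spec$hu_bone_mean, spec$hu_calcite_mean)) / 2
  crust <- (vol > thr) & !bone
  a <- vol[bone]; b <- vol[crust]
  rng <- range(c(a, b))
  brk <- seq(rng[1], rng[2], length.out = nbins + 1L)
  ha <- hist(a, breaks = brk, plot = FALSE)$counts
  hb <- hist(b, breaks = brk, plot = FALSE)$counts
  sum(pmin(ha / sum(ha), hb / sum(hb)))
}
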