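# Mesh-based osteometry: explicit geometric renderings of the three von den
# Driesch caliper measurements used for proximal femora —
#   Bp: greatest breadth of the proximal end (caliper width perpendicular to
#       the shaft axis over the proximal region),
#   DC: depth (diameter) of the femoral head (least-squares sphere fit),
#   SD: smallest diameter of the diaphysis (minimum over cross-section
#       stations of the maximal in-plane caliper width).
# Hands-on caliper definitions do not fix a computation; each report states
# its method so numbers are comparable only within-method.

principal_axes <- function(pts) {
  cen <- colMeans(pts)
  e <- eigen(stats::cov(pts), symmetric = TRUE)
  list(center = cen, vectors = e$vectors, values = e$values)
}

axial_extent <- function(pts, axis) range(pts %*% axis)

cross_section_caliper <- function(pts, axis, at, tol) {
  # maximal caliper width of the point slab within +/- tol of station `at`
  s <- as.numeric(pts %*% axis)
  sel <- abs(s - at) <= tol
  if (sum(sel) < 3) return(NA_real_)
  basis <- svd(diag(3) - tcrossprod(axis))$u[, 1:2]
  p2 <- pts[sel, , drop = FALSE] %*% basis
  hull <- chull(p2)
  hp <- p2[hull, , drop = FALSE]
  max(stats::dist(hp))
}

#' Infer the shaft axis of an elongated bone mesh
#'
#' Principal axis of the vertex set restricted to the `shaft_fraction` of the
#' bone's length farthest from the head end. The head end is auto-detected as
#' the extremity with the larger cross-sectional caliper width (override with
#' `head_end`). The returned unit axis points from the shaft toward the head.
#'
#' @param mesh a [surface_mesh].
#' @param shaft_fraction fraction of the axial length, measured from the end
#'   opposite the head, used for the axis fit (default 0.4).
#' @param head_end optional override: `+1` if the head lies at the positive
#'   end of the first principal axis, `-1` for the negative end.
#' @return list with `axis` (unit vector), `extent` (axial range, mm),
#'   `head_end` (+1/-1 along the returned axis: always +1), and
#'   `shaft_range` (axial band used for the fit).
#' @export
shaft_axis <- function(mesh, shaft_fraction = 0.4, head_end = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  pts <- mesh$vertices
  pa <- principal_axes(pts)
  exts <- vapply(1:3, function(i) diff(range(pts %*% pa$vectors[, i])), 0)
  ord <- order(exts, decreasing = TRUE)
  if (exts[ord[1]] < 1.5 * exts[ord[2]])
    stop(sprintf("mesh is not elongated (principal extents %.1f vs %.1f mm)",
                 exts[ord[1]], exts[ord[2]]))
  ax <- pa$vectors[, ord[1]]
  s <- as.numeric(pts %*% ax)
  lo <- min(s); hi <- max(s); len <- hi - lo
  if (is.null(head_end)) {
    band <- 0.15 * len
    wlo <- cross_section_caliper(pts, ax, lo + band / 2, band / 2)
    whi <- cross_section_caliper(pts, ax, hi - band / 2, band / 2)
    head_end <- if (isTRUE(whi >= wlo)) +1 else -1
  }
  if (head_end < 0) { ax <- -ax; s <- -s; tmp <- lo; lo <- -hi; hi <- -tmp }
  # Refine on the shaft region (farthest from the head): the line through
  # the cross-section centroids. Centroids of a cylinder's plane sections
  # lie exactly on its axis whatever the cutting angle, so this converges
  # where surface-point PCA stays biased by the head/trochanter asymmetry.
  ax2 <- ax
  tr <- mesh$triangles
  for (it in 1:4) {
    s_cur <- as.numeric(pts %*% ax2)
    L <- diff(range(s_cur))
    lo_cut <- min(s_cur) + 0.06 * L        # stay clear of the broken end
    hi_cut <- min(s_cur) + shaft_fraction * L
    stations <- seq(lo_cut, hi_cut, length.out = 25)
    sv <- matrix(s_cur[tr], ncol = 3)
    smin <- pmin(sv[, 1], sv[, 2], sv[, 3])
    smax <- pmax(sv[, 1], sv[, 2], sv[, 3])
    cents <- t(vapply(stations, function(st) {
      cross <- (smin < st) & (smax > st)
      if (!any(cross)) return(c(NA_real_, NA, NA))
      colMeans(section_points(pts, tr[cross, , drop = FALSE], s_cur, st))
    }, c(0, 0, 0)))
    cents <- cents[stats::complete.cases(cents), , drop = FALSE]
    if (nrow(cents) < 5) stop("shaft region contains too few cross-sections")
    pa2 <- principal_axes(cents)
    ax_new <- pa2$vectors[, which.max(pa2$values)]
    if (sum(ax_new * ax2) < 0) ax_new <- -ax_new
    delta <- acos(min(1, abs(sum(ax_new * ax2))))
    ax2 <- ax_new
    if (delta < 1e-4) break
  }
  s2 <- as.numeric(pts %*% ax2)
  list(axis = ax2, extent = range(s2), head_end = +1,
       shaft_range = c(min(s2), min(s2) + shaft_fraction * diff(range(s2))))
}

#' Smallest diameter of the diaphysis (SD)
#'
#' Slices the mesh by planes perpendicular to the shaft axis at regular
#' stations along the shaft region; at each station computes the maximal
#' in-plane caliper width of the cross-section (intersection of mesh edges
#' with the plane); SD is the minimum over stations.
#'
#' @param mesh a [surface_mesh].
#' @param axis_info result of [shaft_axis] (computed if omitted).
#' @param station_step station spacing along the axis, mm.
#' @return SD in mm, with attribute `station` (axial position of the
#'   minimum).
#' @export
measure_sd <- function(mesh, axis_info = NULL, station_step = 0.5) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(axis_info)) axis_info <- shaft_axis(mesh)
  ax <- axis_info$axis
  v <- mesh$vertices
  s <- as.numeric(v %*% ax)
  rng <- axis_info$shaft_range
  # keep clear of the broken end: planes near the transverse break cut only
  # an oblique sliver of the cap, which would fake a small caliper
  trim <- 0.06 * diff(axis_info$extent)
  stations <- seq(rng[1] + trim, rng[2], by = station_step)
  basis <- svd(diag(3) - tcrossprod(ax))$u[, 1:2]
  tr <- mesh$triangles
  sv <- matrix(s[tr], ncol = 3)
  smin <- pmin(sv[, 1], sv[, 2], sv[, 3])
  smax <- pmax(sv[, 1], sv[, 2], sv[, 3])
  widths <- vapply(stations, function(st) {
    cross <- (smin < st) & (smax > st)
    if (!any(cross)) return(NA_real_)
    pts <- section_points(v, tr[cross, , drop = FALSE], s, st)
    if (nrow(pts) < 3) return(NA_real_)
    p2 <- pts %*% basis
    hp <- p2[chull(p2), , drop = FALSE]
    max(stats::dist(hp))
  }, 0)
  interior <- stations > rng[1] + station_step & stations < rng[2] - station_step
  if (any(is.na(widths[interior])))
    stop("empty cross-section at an interior station: broken mesh?")
  ok <- !is.na(widths)
  i <- which.min(widths[ok])
  out <- min(widths, na.rm = TRUE)
  attr(out, "station") <- stations[ok][i]
  out
}

section_points <- function(v, tris, s, st) {
  # intersection points of triangle edges with the plane s == st
  edges <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  sa <- s[edges[, 1]]; sb <- s[edges[, 2]]
  cross <- (sa - st) * (sb - st) < 0
  e <- edges[cross, , drop = FALSE]
  t <- (st - s[e[, 1]]) / (s[e[, 2]] - s[e[, 1]])
  v[e[, 1], , drop = FALSE] + t * (v[e[, 2], , drop = FALSE] - v[e[, 1], , drop = FALSE])
}

#' Depth of the femoral head (DC) by least-squares sphere fit
#'
#' Fits a sphere (algebraic least squares) to the vertices of the head
#' region — by default the band of axial positions within the top
#' `head_band_fraction` of the bone's length at the head end — and reports
#' the fitted diameter. Errors if the fit RMS exceeds 10% of the radius
#' (region not spherical).
#'
#' @param mesh a [surface_mesh].
#' @param axis_info result of [shaft_axis] (computed if omitted).
#' @param head_band_fraction fraction of the axial length, at the head end,
#'   taken as the head region (default 0.12).
#' @param head_region optional explicit vertex subset (logical or index
#'   vector) overriding the band selection.
#' @return DC in mm, with attributes `radius`, `center`, `rms`.
#' @export
measure_dc <- function(mesh, axis_info = NULL, head_band_fraction = 0.12,
                       head_region = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(axis_info)) axis_info <- shaft_axis(mesh)
  v <- mesh$vertices
  if (is.null(head_region)) {
    s <- as.numeric(v %*% axis_info$axis)
    hi <- max(s); len <- diff(range(s))
    head_region <- s >= hi - head_band_fraction * len
  }
  pts <- v[head_region, , drop = FALSE]
  if (nrow(pts) < 10) stop("head region contains too few vertices")
  # algebraic sphere fit: |x|^2 = 2 c.x + (r^2 - |c|^2)
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  q <- qr.solve(A, b)
  center <- q[1:3]
  r2 <- q[4] + sum(center^2)
  if (r2 <= 0) stop("sphere fit failed on head region")
  radius <- sqrt(r2)
  rms <- sqrt(mean((sqrt(rowSums(sweep(pts, 2, center)^2)) - radius)^2))
  if (rms > 0.1 * radius)
    stop(sprintf("head region not spherical: fit RMS %.2f mm exceeds 10%% of radius %.2f mm",
                 rms, radius))
  out <- 2 * radius
  attr(out, "radius") <- radius
  attr(out, "center") <- center
  attr(out, "rms") <- rms
  out
}

#' Greatest breadth of the proximal end (Bp)
#'
#' Projects the proximal region (the `proximal_fraction` of the axial length
#' at the head end) onto the plane perpendicular to the shaft axis and takes
#' the maximal caliper width: the maximum over in-plane directions of the
#' projected extent.
#'
#' @param mesh a [surface_mesh].
#' @param axis_info result of [shaft_axis] (computed if omitted).
#' @param proximal_fraction fraction of axial length forming the proximal
#'   region (default 0.35).
#' @param n_angles in-plane directions scanned (default 1440, i.e. 0.125
#'   degree steps over the half-circle).
#' @return Bp in mm.
#' @export
measure_bp <- function(mesh, axis_info = NULL, proximal_fraction = 0.35,
                       n_angles = 1440L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(axis_info)) axis_info <- shaft_axis(mesh)
  v <- mesh$vertices
  s <- as.numeric(v %*% axis_info$axis)
  hi <- max(s); len <- diff(range(s))
  sel <- s >= hi - proximal_fraction * len
  if (!any(sel)) stop("empty proximal region")
  basis <- svd(diag(3) - tcrossprod(axis_info$axis))$u[, 1:2]
  p2 <- v[sel, , drop = FALSE] %*% basis
  hp <- p2[chull(p2), , drop = FALSE]
  th <- seq(0, pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  dirs <- rbind(cos(th), sin(th))
  proj <- hp %*% dirs
  max(apply(proj, 2, max) - apply(proj, 2, min))
}

#' Full osteometric report for a cleaned-specimen mesh
#'
#' @param mesh a [surface_mesh].
#' @param shaft_fraction,station_step,head_band_fraction,proximal_fraction
#'   tuning parameters of the individual measurements.
#' @return An `osteometric_report`: measures `Bp`, `DC`, `SD` (mm), the
#'   inferred `axis`, region bounds, and per-measure method notes.
#' @export
osteometric_report <- function(mesh, shaft_fraction = 0.4, station_step = 0.5,
                               head_band_fraction = 0.12,
                               proximal_fraction = 0.35) {
  ai <- shaft_axis(mesh, shaft_fraction)
  sd_ <- measure_sd(mesh, ai, station_step)
  dc_ <- measure_dc(mesh, ai, head_band_fraction)
  bp_ <- measure_bp(mesh, ai, proximal_fraction)
  structure(list(
    measures = c(Bp = as.numeric(bp_), DC = as.numeric(dc_),
                 SD = as.numeric(sd_)),
    axis = ai$axis, axial_extent = ai$extent,
    shaft_range = ai$shaft_range,
    methods = c(
      Bp = sprintf("max caliper perpendicular to shaft axis over proximal %.0f%% of length",
                   100 * proximal_fraction),
      DC = sprintf("2 x least-squares sphere radius over head band (top %.0f%%), fit RMS %.3f mm",
                   100 * head_band_fraction, attr(dc_, "rms")),
      SD = sprintf("min over %.1f mm stations of max in-plane caliper (shaft %.0f%%)",
                   station_step, 100 * shaft_fraction))),
    class = "osteometric_report")
}

#' @export
print.osteometric_report <- function(x, ...) {
  m <- x$measures
  cat(sprintf("<osteometric_report> Bp %.1f mm, DC %.1f mm, SD %.1f mm\n",
              m["Bp"], m["DC"], m["SD"]))
  for (k in names(x$methods)) cat(sprintf("  %s: %s\n", k, x$methods[k]))
  invisible(x)
}

#' Compare virtual measurements with direct measurements
#'
#' The validation statistic of the protocol: absolute per-measure differences
#' between mesh-derived and directly taken values, with their mean and
#' standard deviation.
#'
#' @param report an `osteometric_report` (or named numeric vector).
#' @param direct_measures named numeric vector with matching names.
#' @return list with `differences`, `mean`, `sd`.
#' @export
compare_to_direct <- function(report, direct_measures) {
  virt <- if (inherits(report, "osteometric_report")) report$measures else report
  keys <- names(direct_measures)
  if (is.null(keys) || !all(keys %in% names(virt)))
    stop("direct_measures names must match the report's measure names (",
         paste(names(virt), collapse = ", "), ")")
  d <- abs(virt[keys] - direct_measures)
  if (length(d) < 2L) {
    warning("single measurement pair: sd reported as 0")
    return(list(differences = d, mean = mean(d), sd = 0))
  }
  list(differences = d, mean = mean(d), sd = sd(d))
}
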