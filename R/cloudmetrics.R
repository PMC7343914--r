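# Point-cloud congruence statistics between independently produced models:
# area-weighted surface sampling, nearest-neighbour cloud-to-cloud distances,
# and per-pair deviation summaries mirroring a multi-reader validation.

#' Sample points uniformly on a mesh surface
#'
#' Area-weighted triangle selection with uniform barycentric placement
#' (square-root trick), deterministic for a fixed seed. The study-scale
#' default is one million points per model.
#'
#' @param mesh a [surface_mesh].
#' @param n number of points (exactly `n` are returned).
#' @param seed integer seed.
#' @return A `point_cloud`: list with `points` (n x 3 mm), `source`, `seed`.
#' @export
sample_points <- function(mesh, n = 1e6, seed = 1L) {
  stopifnot(inherits(mesh, "surface_mesh"), n >= 1)
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  areas <- sqrt(rowSums(cr^2)) / 2
  if (sum(areas) <= 0) stop("zero-area mesh")
  pts <- withr::with_seed(as.integer(seed), {
    idx <- sample.int(nrow(tr), n, replace = TRUE, prob = areas)
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
    w0 <- 1 - r1; w1 <- r1 * (1 - r2); w2 <- r1 * r2
    v[tr[idx, 1], , drop = FALSE] * w0 +
      v[tr[idx, 2], , drop = FALSE] * w1 +
      v[tr[idx, 3], , drop = FALSE] * w2
  })
  structure(list(points = pts,
                 source = mesh$provenance$source %||% "mesh",
                 seed = as.integer(seed)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %s points from %s (seed %d)\n",
              format(nrow(x$points), big.mark = ","), x$source, x$seed))
  invisible(x)
}

#' Cloud-to-cloud nearest-neighbour distances
#'
#' For each point of `a`, the Euclidean distance to its nearest neighbour in
#' `b` (kd-tree accelerated, exact). Asymmetric by definition: `a -> b`.
#'
#' @param a,b `point_cloud` objects or n x 3 matrices.
#' @return numeric vector of unsigned distances (mm), one per point of `a`.
#' @export
cloud_to_cloud <- function(a, b) {
  pa <- if (inherits(a, "point_cloud")) a$points else as.matrix(a)
  pb <- if (inherits(b, "point_cloud")) b$points else as.matrix(b)
  if (!nrow(pa) || !nrow(pb)) stop("both clouds must be non-empty")
  as.numeric(RANN::nn2(pb, pa, k = 1, treetype = "kd",
                       searchtype = "standard", eps = 0)$nn.dists)
}

#' Summarise a set of deviations
#'
#' @param distances unsigned distances (mm).
#' @param thresholds distances (mm) at which to report the fraction of points
#'   strictly within (`d < threshold`); default 1 mm.
#' @param pair label for the comparison (e.g. `"R1->R2"`).
#' @return A `deviation_report`: mean, sd, max, n, and `fraction_within`.
#' @export
deviation_summary <- function(distances, thresholds = 1.0, pair = "") {
  if (!length(distances)) stop("no distances to summarise")
  fw <- vapply(thresholds, function(th) mean(distances < th), 0)
  names(fw) <- format(thresholds)
  structure(list(pair = pair, n = length(distances),
                 mean = mean(distances),
                 sd = if (length(distances) > 1) sd(distances) else 0,
                 max = max(distances), fraction_within = fw),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("<deviation_report> %s: n=%s mean=%.3f sd=%.3f max=%.3f mm\n",
              if (nzchar(x$pair)) x$pair else "(unlabelled)",
              format(x$n, big.mark = ","), x$mean, x$sd, x$max))
  for (i in seq_along(x$fraction_within))
    cat(sprintf("  within %s mm: %.1f%%\n", names(x$fraction_within)[i],
                100 * x$fraction_within[i]))
  invisible(x)
}

#' Pairwise reader comparisons in cyclic order
#'
#' Compares each model with the following one (M1->M2, M2->M3, ..., Mk->M1),
#' each via [sample_points], [cloud_to_cloud] and [deviation_summary]. One
#' shared seed is sub-seeded per mesh deterministically from the seed and the
#' mesh content, so every mesh is sampled once, each sampling is
#' reproducible, and identical models receive identical clouds (and hence
#' report exactly zero deviation).
#'
#' @param meshes ordered list of [surface_mesh] objects (>= 2).
#' @param n sample size per model.
#' @param seed top-level seed.
#' @param thresholds passed to [deviation_summary].
#' @param labels optional model labels (default `R1`, `R2`, ...).
#' @return list of `deviation_report`s, one per cyclic pair.
#' @export
pairwise_readers <- function(meshes, n = 1e6, seed = 1L, thresholds = 1.0,
                             labels = NULL) {
  k <- length(meshes)
  if (k < 2L) stop("need at least 2 meshes")
  if (is.null(labels)) labels <- paste0("R", seq_len(k))
  mesh_subseed <- function(mesh) {
    v <- mesh$vertices
    as.integer((as.numeric(seed) * 7919 +
                  round(sum(abs(v)) + 13 * nrow(v))) %% 2147483647)
  }
  clouds <- lapply(seq_len(k), function(i)
    sample_points(meshes[[i]], n, seed = mesh_subseed(meshes[[i]])))
  lapply(seq_len(k), function(i) {
    j <- if (i == k) 1L else i + 1L
    deviation_summary(cloud_to_cloud(clouds[[i]], clouds[[j]]),
                      thresholds, pair = paste0(labels[i], "->", labels[j]))
  })
}

#' Deviation report table
#'
#' One row per pair: pair, n, mean, sd, max and one column per
#' `fraction_within` threshold — the tabular counterpart of a deviation
#' boxplot, consumable by any stats tool.
#'
#' @param reports list of `deviation_report`s.
#' @return data.frame.
#' @export
deviation_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    fw <- as.list(r$fraction_within)
    names(fw) <- paste0("fraction_within_", names(r$fraction_within), "mm")
    c(list(pair = r$pair, n = r$n, mean_mm = r$mean, sd_mm = r$sd,
           max_mm = r$max), fw)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

#' Per-vertex deviation scalars for heat maps
#'
#' For every mesh vertex, the nearest-neighbour distance to a reference
#' cloud; export via [write_ply] to get a colour-mappable deviation surface.
#'
#' @param mesh a [surface_mesh].
#' @param reference a `point_cloud` (or n x 3 matrix).
#' @return numeric vector, one distance (mm) per mesh vertex.
#' @export
heatmap_scalars <- function(mesh, reference) {
  stopifnot(inherits(mesh, "surface_mesh"))
  cloud_to_cloud(mesh$vertices, reference)
}
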