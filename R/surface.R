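# Threshold isosurface extraction and mesh IO.

#' Surface mesh container
#'
#' @param vertices n x 3 numeric matrix of world coordinates in mm.
#' @param triangles m x 3 integer matrix of 1-based vertex indices, wound so
#'   normals point outward (away from the supra-threshold region).
#' @param provenance named list (threshold, source tag, ...).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, provenance = list()) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (any(!is.finite(vertices))) stop("mesh vertices must be finite")
  if (nrow(triangles) && (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles,
                 provenance = provenance),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles", nrow(x$vertices),
              nrow(x$triangles)))
  if (!is.null(x$provenance$iso_hu))
    cat(sprintf(" (iso %.4g HU)", x$provenance$iso_hu))
  cat("\n")
  invisible(x)
}

#' Extract a threshold isosurface from a CT volume
#'
#' Marching-tetrahedra surface at `iso_hu`, with vertex coordinates in world
#' mm (scaled by the voxel spacing and offset by the volume origin) and
#' triangle normals oriented away from the supra-threshold region. If
#' `iso_hu` is omitted, the default is the midpoint between the volume's
#' background level and the 5th percentile of supra-background voxels, with
#' a logged notice.
#'
#' @param volume a [ct_volume].
#' @param iso_hu threshold in HU.
#' @return A [surface_mesh].
#' @export
extract_isosurface <- function(volume, iso_hu = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.null(iso_hu)) {
    bg <- min(volume$data)
    supra <- volume$data[volume$data > bg + 1]
    if (!length(supra)) stop("empty surface: volume is constant")
    iso_hu <- (bg + stats::quantile(supra, 0.05)) / 2
    .sc_log("no iso_hu given; defaulting to %.1f HU (midpoint of background %.0f and 5th percentile of supra-background %.0f)",
            iso_hu, bg, stats::quantile(supra, 0.05))
  }
  rng <- range(volume$data)
  if (iso_hu <= rng[1] || iso_hu >= rng[2])
    stop(sprintf("empty surface: no crossing of iso_hu = %g (volume HU range [%g, %g])",
                 iso_hu, rng[1], rng[2]))
  res <- .mt_isosurface(as.numeric(volume$data), dim(volume$data),
                        iso_hu, volume$spacing, volume$origin)
  if (nrow(res$triangles) == 0L)
    stop("empty surface: no crossing of iso_hu = ", iso_hu)
  surface_mesh(res$vertices, res$triangles,
               provenance = list(iso_hu = iso_hu,
                                 source = volume$meta$derivation %||% "volume"))
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [surface_mesh].
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a closed mesh (mm^3), via the divergence theorem
#'
#' Positive for consistently outward-wound closed surfaces.
#' @param mesh a [surface_mesh].
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  p1 <- v[tr[, 1], , drop = FALSE]
  p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p3[, 2] * p2[, 3]) -
      p2[, 1] * (p1[, 2] * p3[, 3] - p3[, 2] * p1[, 3]) +
      p3[, 1] * (p1[, 2] * p2[, 3] - p2[, 2] * p1[, 3])) / 6
}

mesh_components <- function(mesh) {
  # connected components over shared vertices (union-find)
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  tr <- mesh$triangles
  for (i in seq_len(nrow(tr))) {
    a <- find(tr[i, 1]); b <- find(tr[i, 2]); c <- find(tr[i, 3])
    parent[b] <- a; parent[c] <- a
  }
  roots <- vapply(seq_len(nv), find, 0L)
  comp <- match(roots, unique(roots))
  tri_comp <- comp[tr[, 1]]
  list(vertex_comp = comp, tri_comp = tri_comp, n = length(unique(roots)))
}

#' Keep the largest connected component of a mesh
#'
#' Retains the component with the largest enclosed absolute volume
#' (suppressing speckle from isolated noise voxels) and reports the discarded
#' components and their volumes. Ties go to the component containing the
#' smallest vertex index, with a warning.
#'
#' @param mesh a [surface_mesh].
#' @return The filtered [surface_mesh]; discarded component volumes are
#'   attached as attribute `discarded`.
#' @export
largest_component <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$triangles) == 0L) stop("empty mesh")
  cc <- mesh_components(mesh)
  # only components that carry triangles count (vertices left over from
  # degenerate-triangle suppression are not surface components)
  comp_ids <- sort(unique(cc$tri_comp))
  if (length(comp_ids) == 1L) return(mesh)
  vols <- vapply(comp_ids, function(ci) {
    sub <- mesh$triangles[cc$tri_comp == ci, , drop = FALSE]
    abs(mesh_volume(surface_mesh(mesh$vertices, sub, mesh$provenance)))
  }, 0)
  best <- comp_ids[vols == max(vols)]
  if (length(best) > 1L) {
    minvtx <- vapply(best, function(ci) min(which(cc$vertex_comp == ci)), 0L)
    best <- best[which.min(minvtx)]
    warning("equal-volume components; keeping the one with the smallest vertex index")
  }
  keepv <- cc$vertex_comp == best
  remap <- cumsum(keepv)
  tr <- mesh$triangles[cc$tri_comp == best, , drop = FALSE]
  out <- surface_mesh(mesh$vertices[keepv, , drop = FALSE],
                      matrix(remap[tr], ncol = 3),
                      mesh$provenance)
  attr(out, "discarded") <- sort(vols[comp_ids != best], decreasing = TRUE)
  out
}

# ---- STL --------------------------------------------------------------------

#' Write a mesh as binary STL
#'
#' Little-endian binary STL; the 80-byte header carries the provenance tag.
#' Coordinates are stored in single precision (the format's own precision).
#'
#' @param mesh a [surface_mesh].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (any(!is.finite(mesh$vertices))) stop("non-finite vertex coordinates")
  header <- sprintf("speleoclean %s iso=%s",
                    mesh$provenance$source %||% "mesh",
                    format(mesh$provenance$iso_hu %||% NA))
  hraw <- charToRaw(substr(header, 1, 80))
  hraw <- c(hraw, raw(80 - length(hraw)))
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  nt <- nrow(tr)
  # 12 floats per facet: normal + 3 vertices
  ff <- t(cbind(nrm, v[tr[, 1], ], v[tr[, 2], ], v[tr[, 3], ]))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hraw, con)
  writeBin(nt, con, size = 4, endian = "little")
  payload <- writeBin(as.numeric(ff), raw(), size = 4, endian = "little")
  dim(payload) <- c(48L, nt)
  rec <- rbind(payload, matrix(as.raw(0), 2L, nt))  # 2-byte attribute counts
  writeBin(as.raw(rec), con)
  invisible(path)
}

#' Read a binary STL file
#'
#' Vertices are de-duplicated by exact (single-precision) coordinate match,
#' so write-then-read is the identity on the triangulation up to
#' single-precision rounding.
#'
#' @param path STL file.
#' @return A [surface_mesh]; the header text is kept in the provenance.
#' @export
read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (sz != 84 + 50 * nt)
    stop("corrupt binary STL (size mismatch): ", path)
  rec <- readBin(con, "raw", 50 * nt)
  dim(rec) <- c(50L, nt)
  floats <- readBin(as.raw(rec[1:48, ]), "numeric", n = 12 * nt, size = 4,
                    endian = "little")
  dim(floats) <- c(12L, nt)
  verts <- matrix(as.numeric(floats[4:12, ]), ncol = 3, byrow = TRUE)
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uniq <- !duplicated(key)
  vid <- match(key, unique(key))
  tri <- matrix(vid, ncol = 3, byrow = TRUE)
  surface_mesh(verts[uniq, , drop = FALSE], tri,
               provenance = list(source = trimws(rawToChar(header[header != as.raw(0)]))))
}

# ---- PLY --------------------------------------------------------------------

#' Write a mesh as ASCII PLY with an optional per-vertex scalar channel
#'
#' The scalar channel (property `quality`) carries deviation heat-map values.
#'
#' @param mesh a [surface_mesh].
#' @param path output file.
#' @param scalars optional numeric vector, one value per vertex.
#' @return Invisibly, `path`.
#' @export
write_ply <- function(mesh, path, scalars = NULL) {
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  if (!is.null(scalars) && length(scalars) != nv)
    stop("scalars must have one value per vertex")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("comment speleoclean", mesh$provenance$source %||% "mesh"),
               paste("element vertex", nv),
               "property float x", "property float y", "property float z",
               if (!is.null(scalars)) "property float quality",
               paste("element face", nt),
               "property list uchar int vertex_indices",
               "end_header"), con)
  vm <- mesh$vertices
  if (!is.null(scalars)) vm <- cbind(vm, scalars)
  writeLines(apply(format(vm, trim = TRUE, digits = 9), 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
  invisible(path)
}
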