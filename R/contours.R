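# Sparse planar contours and shape-based inter-slice interpolation.
#
# A contour is a closed simple polygon on one axial slice, with vertices in
# in-plane mm relative to the slice origin. Drawing convention (normalised
# form): clockwise in image coordinates (y grows downward), starting at the
# "twelve o'clock" vertex — the vertex of maximal anatomical-up (minimal
# image y) relative to the centroid, ties broken by smallest x.

#' Create a contour
#'
#' @param slice_index 1-based index of the axial slice the polygon lies on.
#' @param vertices n x 2 matrix of (x, y) in-plane mm coordinates relative to
#'   the slice origin; at least 3 rows; the polygon is implicitly closed.
#' @return An object of class `contour`.
#' @export
contour <- function(slice_index, vertices) {
  vertices <- matrix(as.numeric(vertices), ncol = 2)
  if (nrow(vertices) < 3L) stop("a contour needs at least 3 vertices")
  if (any(!is.finite(vertices))) stop("contour vertices must be finite")
  structure(list(slice_index = as.integer(slice_index), vertices = vertices,
                 closed = TRUE),
            class = "contour")
}

#' Create a contour set
#'
#' The sparse manual input: one reader's collection of planar polygons
#' attached to slice indices, plus the grid they annotate.
#'
#' @param reader_id text identifier (e.g. `"R1"`).
#' @param contours list of [contour] objects (possibly several per slice).
#' @param spacing voxel spacing (dx, dy, dz) mm of the annotated grid.
#' @param shape grid dimensions (nx, ny, nz).
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(reader_id, contours, spacing, shape) {
  shape <- as.integer(shape)
  idx <- vapply(contours, `[[`, 0L, "slice_index")
  if (length(idx) && (min(idx) < 1L || max(idx) > shape[3]))
    stop("contour slice_index outside grid bounds")
  structure(list(reader_id = reader_id, contours = contours,
                 spacing = as.numeric(spacing), shape = shape),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> reader %s: %d contours on %d slices of %d\n",
              x$reader_id, length(x$contours),
              length(unique(vapply(x$contours, `[[`, 0L, "slice_index"))),
              x$shape[3]))
  invisible(x)
}

#' Slices carrying contours (the interpolation support)
#' @param cs a [contour_set].
#' @return sorted integer vector of keyframe slice indices.
#' @export
keyframe_slices <- function(cs) {
  sort(unique(vapply(cs$contours, `[[`, 0L, "slice_index")))
}

polygon_signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Normalise a contour to the drawing convention
#'
#' Reorders the vertex cycle so the polygon runs clockwise in image
#' coordinates (negative signed area with y growing downward) and starts at
#' its twelve o'clock vertex: the vertex of minimal image y (maximal
#' anatomical up) relative to the centroid, ties broken by smallest x. The
#' geometry is unchanged — the vertex set is only cyclically rotated and/or
#' reversed. Errors on polygons with fewer than 3 vertices or with
#' self-intersections.
#'
#' @param ctr a [contour].
#' @return The normalised [contour].
#' @export
normalize_contour <- function(ctr) {
  stopifnot(inherits(ctr, "contour"))
  v <- ctr$vertices
  # drop an explicitly repeated closing vertex
  if (nrow(v) > 3L && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L) stop("a contour needs at least 3 distinct vertices")
  if (.polygon_self_intersects(v[, 1], v[, 2]))
    stop("self-intersecting contour on slice ", ctr$slice_index)
  a <- polygon_signed_area(v)
  if (a == 0) stop("degenerate (zero-area) contour on slice ", ctr$slice_index)
  if (a > 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]  # make clockwise
  start <- order(v[, 2], v[, 1])[1]  # min image y, then min x
  if (start > 1L) v <- v[c(start:nrow(v), 1:(start - 1L)), , drop = FALSE]
  contour(ctr$slice_index, v)
}

#' Rasterise a contour onto a slice grid
#'
#' A pixel belongs to the fill iff its center lies strictly inside the
#' polygon by the even-odd rule. Pixel centers are at
#' `((i-1)*dx, (j-1)*dy)` in slice mm coordinates. Vertices extending beyond
#' the grid are clipped (to the grid's pixel support) with a warning.
#'
#' @param ctr a [contour] (normalised first if it is not already).
#' @param spacing grid spacing (dx, dy[, dz]) mm.
#' @param shape grid shape (nx, ny[, nz]).
#' @return nx x ny logical matrix.
#' @export
rasterize_contour <- function(ctr, spacing, shape) {
  ctr <- normalize_contour(ctr)
  v <- ctr$vertices
  nx <- shape[1]; ny <- shape[2]
  xmax <- (nx - 1) * spacing[1]; ymax <- (ny - 1) * spacing[2]
  if (min(v[, 1]) < -spacing[1] / 2 || max(v[, 1]) > xmax + spacing[1] / 2 ||
      min(v[, 2]) < -spacing[2] / 2 || max(v[, 2]) > ymax + spacing[2] / 2)
    warning("contour on slice ", ctr$slice_index,
            " extends outside the grid; clipped to grid support")
  cx <- (seq_len(nx) - 1) * spacing[1]
  cy <- (seq_len(ny) - 1) * spacing[2]
  px <- rep(cx, times = ny)
  py <- rep(cy, each = nx)
  matrix(.pip_evenodd(px, py, v[, 1], v[, 2]), nrow = nx, ncol = ny)
}

rasterize_slice <- function(contours, spacing, shape) {
  # union of all contours on one slice
  m <- matrix(FALSE, shape[1], shape[2])
  for (ctr in contours) m <- m | rasterize_contour(ctr, spacing, shape)
  m
}

# ---- signed distance fields -------------------------------------------------

signed_distance <- function(mask, cap) {
  # negative inside, positive outside, in pixel units (isotropic in-plane)
  if (!any(mask)) return(matrix(cap, nrow(mask), ncol(mask)))
  if (all(mask)) {
    d_in <- EBImage::distmap(EBImage::Image(mask * 1))
    return(-pmin(as.matrix(d_in), cap))
  }
  d_in <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  d_out <- as.matrix(EBImage::distmap(EBImage::Image((!mask) * 1)))
  pmin(d_out, cap) - pmin(d_in, cap)
}

#' Shape-based interpolation between two slice masks
#'
#' Computes the signed Euclidean distance field of each mask (negative
#' inside), blends them linearly, `d = (1-t) d_a + t d_b`, and returns the
#' sub-zero set. Endpoints are exact: `t = 0` returns `mask_a` bit-exactly,
#' `t = 1` returns `mask_b`. If exactly one mask is empty its distance field
#' is taken as a constant cap (the grid diagonal in pixels), so the non-empty
#' shape shrinks toward its own medial interior as `t` approaches the empty
#' side. Both masks empty is an error.
#'
#' @param mask_a,mask_b congruent logical matrices.
#' @param t interpolation fraction in `[0, 1]`.
#' @return logical matrix of the interpolated shape.
#' @export
interpolate_masks <- function(mask_a, mask_b, t) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("mask grids are not congruent")
  if (!any(mask_a) && !any(mask_b)) stop("both masks are empty")
  if (t < 0 || t > 1) stop("t must be in [0, 1]")
  if (t == 0) return(mask_a)
  if (t == 1) return(mask_b)
  cap <- sqrt(sum(dim(mask_a)^2))
  da <- signed_distance(mask_a, cap)
  db <- signed_distance(mask_b, cap)
  res <- ((1 - t) * da + t * db) < 0
  matrix(as.logical(res), nrow(mask_a), ncol(mask_a))  # strip Image class
}

# ---- dense masks ------------------------------------------------------------

#' Create a binary mask congruent with a CT grid
#' @param data 3D logical array.
#' @param provenance character vector describing how the mask was made.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, provenance = character()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "logical"
  structure(list(data = data, provenance = provenance), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels set of %s\n",
              format(sum(x$data), big.mark = ","),
              paste(dim(x$data), collapse = " x ")))
  for (p in x$provenance) cat("  - ", p, "\n", sep = "")
  invisible(x)
}

#' Build a dense 3D mask from sparse contours
#'
#' Keyframe slices (those carrying contours) are rasterised exactly;
#' intermediate slices are filled by [interpolate_masks] at the fractional
#' position between the enclosing keyframes; slices before the first and
#' after the last keyframe stay empty.
#'
#' @param cs a [contour_set] with contours on at least 2 slices.
#' @param volume the [ct_volume] the contours annotate (geometry reference).
#' @return A [binary_mask] with provenance recording reader and keyframes.
#' @export
build_dense_mask <- function(cs, volume) {
  stopifnot(inherits(cs, "contour_set"))
  shape <- dim(volume$data)
  if (!all(cs$shape == shape))
    stop("contour set annotates a different grid than the volume")
  keys <- keyframe_slices(cs)
  if (length(keys) < 2L)
    stop("only ", length(keys), " keyframe slice(s); add contours on at ",
         "least 2 slices before interpolating")
  by_slice <- split(cs$contours, vapply(cs$contours, `[[`, 0L, "slice_index"))
  out <- array(FALSE, dim = shape)
  kf <- list()
  for (s in keys)
    kf[[as.character(s)]] <- rasterize_slice(by_slice[[as.character(s)]],
                                             cs$spacing, shape)
  for (s in keys) out[, , s] <- kf[[as.character(s)]]
  if (length(keys) > 1L) {
    for (g in seq_len(length(keys) - 1L)) {
      k1 <- keys[g]; k2 <- keys[g + 1L]
      if (k2 - k1 < 2L) next
      ma <- kf[[as.character(k1)]]; mb <- kf[[as.character(k2)]]
      for (s in (k1 + 1L):(k2 - 1L)) {
        t <- (s - k1) / (k2 - k1)
        out[, , s] <- interpolate_masks(ma, mb, t)
      }
    }
  }
  binary_mask(out, provenance = sprintf(
    "dense mask: reader %s, %d keyframes (stride ~%s) on grid %s",
    cs$reader_id, length(keys),
    if (length(keys) > 1) paste0(round(stats::median(diff(keys)))) else "-",
    paste(shape, collapse = "x")))
}

#' Replace one slice of a mask (programmatic manual correction)
#'
#' @param mask a [binary_mask].
#' @param slice_index slice to replace (1-based).
#' @param replacement_slice logical matrix congruent with a mask slice.
#' @return A new [binary_mask] with the slice replaced and the edit appended
#'   to its provenance.
#' @export
edit_mask <- function(mask, slice_index, replacement_slice) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  if (slice_index < 1L || slice_index > d[3])
    stop("slice_index ", slice_index, " out of range 1..", d[3])
  replacement_slice <- as.matrix(replacement_slice)
  if (!all(dim(replacement_slice) == d[1:2]))
    stop("replacement slice shape mismatch")
  out <- mask$data
  out[, , slice_index] <- as.logical(replacement_slice)
  binary_mask(out, provenance = c(mask$provenance,
                                  sprintf("edit: slice %d replaced", slice_index)))
}

#' Dice overlap coefficient of two masks
#' @param a,b congruent [binary_mask] objects or logical arrays.
#' @return `2|A∩B| / (|A|+|B|)`.
#' @export
dice_coefficient <- function(a, b) {
  da <- if (inherits(a, "binary_mask")) a$data else a
  db <- if (inherits(b, "binary_mask")) b$data else b
  if (!all(dim(da) == dim(db))) stop("masks are not congruent")
  2 * sum(da & db) / (sum(da) + sum(db))
}

# ---- contour file format ----------------------------------------------------

#' Write a contour set to the `.contours.json` interchange format
#'
#' Top-level object with `reader_id`, `spacing`, `shape`, and a list of
#' `{slice_index, vertices_mm: [[x, y], ...]}` records (slice_index 1-based).
#'
#' @param cs a [contour_set].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_contours <- function(cs, path) {
  recs <- lapply(cs$contours, function(ctr)
    list(slice_index = ctr$slice_index,
         vertices_mm = unname(ctr$vertices)))
  jsonlite::write_json(list(format = "speleoclean-contours-v1",
                            reader_id = cs$reader_id,
                            spacing = cs$spacing, shape = cs$shape,
                            contours = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a `.contours.json` file
#' @param path file path.
#' @return A [contour_set].
#' @export
read_contours <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (!identical(j$format, "speleoclean-contours-v1"))
    stop("not a speleoclean contours file: ", path)
  contours <- lapply(seq_len(nrow(j$contours)), function(i)
    contour(j$contours$slice_index[i],
            j$contours$vertices_mm[[i]]))
  contour_set(j$reader_id, contours, j$spacing, j$shape)
}

# ---- pixel-boundary tracing -------------------------------------------------
# Exact boundary polygons of a binary slice: the outline of the union of the
# pixel squares (corners at pixel centers +/- half a pixel). Every mask pixel
# center is strictly inside its loop and every outside center strictly
# outside, so rasterising the loops recovers the mask exactly. One loop per
# connected boundary; holes come out as separate loops.

trace_boundary_loops <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  if (!any(mask)) return(list())
  padded <- matrix(FALSE, nx + 2L, ny + 2L)
  padded[2:(nx + 1L), 2:(ny + 1L)] <- mask
  idx <- which(padded, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  inm <- function(ii, jj) padded[cbind(ii, jj)]
  # directed boundary edges between pixel corners, interior kept on the left
  # corners keyed on the (i-1/2, j-1/2) lattice; corner (a,b) = pixel corner
  # at center coords (a - 1.5 - 0.5, b - 1.5 - 0.5) of the padded frame
  edges <- list()
  add <- function(f_i, f_j, t_i, t_j) {
    edges[[length(edges) + 1L]] <<- cbind(f_i, f_j, t_i, t_j)
  }
  # For pixel (i,j) with neighbour outside: emit that side, directed so the
  # pixel is on the left when walking from -> to (image coords, y down).
  s <- !inm(i, j - 1L)  # top side (smaller j): walk +x
  if (any(s)) add(i[s], j[s], i[s] + 1L, j[s])
  s <- !inm(i + 1L, j)  # right side: walk +y
  if (any(s)) add(i[s] + 1L, j[s], i[s] + 1L, j[s] + 1L)
  s <- !inm(i, j + 1L)  # bottom side: walk -x
  if (any(s)) add(i[s] + 1L, j[s] + 1L, i[s], j[s] + 1L)
  s <- !inm(i - 1L, j)  # left side: walk -y
  if (any(s)) add(i[s], j[s] + 1L, i[s], j[s])
  e <- do.call(rbind, edges)
  nkey <- (max(e[, c(2, 4)]) + 2L)
  from_key <- e[, 1] * nkey + e[, 2]
  to_key <- e[, 3] * nkey + e[, 4]
  # map corner -> outgoing edge indices (at checkerboard touches there are 2)
  ord <- order(from_key)
  fk_sorted <- from_key[ord]
  first_of <- which(!duplicated(fk_sorted))
  lookup <- new.env(hash = TRUE, size = length(first_of))
  for (a in seq_along(first_of)) {
    k <- fk_sorted[first_of[a]]
    upper <- if (a < length(first_of)) first_of[a + 1L] - 1L else length(fk_sorted)
    assign(as.character(k), ord[first_of[a]:upper], envir = lookup)
  }
  used <- logical(nrow(e))
  loops <- list()
  for (start in seq_len(nrow(e))) {
    if (used[start]) next
    cur <- start
    loop_i <- integer(0); loop_j <- integer(0)
    repeat {
      used[cur] <- TRUE
      loop_i <- c(loop_i, e[cur, 1]); loop_j <- c(loop_j, e[cur, 2])
      nk <- to_key[cur]
      cand <- get(as.character(nk), envir = lookup)
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      cur <- cand[1]
    }
    # corner lattice -> pixel-center coordinates of the unpadded mask:
    # padded pixel (i,j) = mask pixel (i-1, j-1); corner (a,b) sits at
    # center coords (a - 1 - 0.5, b - 1 - 0.5) in 1-based mask pixel units
    loops[[length(loops) + 1L]] <- cbind(loop_i - 1.5, loop_j - 1.5)
  }
  loops
}
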