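#' CT volume container
#'
#' A `ct_volume` holds a 3D scalar grid of Hounsfield units together with the
#' geometry needed to place every voxel in the scanner (world) frame. The
#' array is indexed `data[ix, iy, iz]` (column, row, slice; 1-based); the
#' world coordinate of voxel `(i, j, k)` is
#' `origin + ((i-1)*dx, (j-1)*dy, (k-1)*dz)` in mm. Slices are axial and
#' ordered by strictly increasing world z.
#'
#' @param data 3D numeric array of HU values, dim `(nx, ny, nz)`.
#' @param spacing numeric length-3, voxel size `(dx, dy, dz)` in mm, all > 0.
#' @param origin numeric length-3, world position (mm) of voxel `(1,1,1)`.
#' @param meta named list of carry-through series metadata. The element
#'   `derivation` tags derived series (e.g. `"crust-template"`).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0), meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)")
  if (any(!is.finite(data)))
    stop("HU values must all be finite")
  structure(list(data = data, spacing = spacing, origin = origin, meta = meta),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm; HU range [%.0f, %.0f]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  if (!is.null(x$meta$derivation))
    cat(sprintf("  derivation: %s\n", x$meta$derivation))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' World coordinates of voxel indices
#'
#' @param volume a [ct_volume].
#' @param ijk integer matrix (n x 3) of 1-based voxel indices `(i, j, k)`.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(volume, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

# ---- raw + metadata fallback format ----------------------------------------
# One JSON ".ctmeta" sidecar (shape, spacing, origin, dtype, derivation) plus
# one little-endian float64 ".raw" file, for tests and pipelines that must not
# depend on DICOM plumbing.

write_ct_raw <- function(volume, stem) {
  meta <- list(format = "speleoclean-ctmeta-v1",
               shape = dim(volume$data), spacing = volume$spacing,
               origin = volume$origin, dtype = "float64-le",
               derivation = volume$meta$derivation %||% "original")
  jsonlite::write_json(meta, paste0(stem, ".ctmeta"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(stem, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(volume$data), con, size = 8, endian = "little")
  invisible(c(paste0(stem, ".ctmeta"), paste0(stem, ".raw")))
}

read_ct_raw <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".ctmeta"), simplifyVector = TRUE)
  if (!identical(meta$format, "speleoclean-ctmeta-v1"))
    stop("not a speleoclean ctmeta file: ", stem)
  n <- prod(meta$shape)
  con <- file(paste0(stem, ".raw"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  ct_volume(array(vals, dim = meta$shape), meta$spacing, meta$origin,
            meta = list(derivation = meta$derivation))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- series-level API -------------------------------------------------------

#' Read a CT series from a directory
#'
#' Reads either a DICOM series (one single-frame axial file per slice,
#' Explicit VR Little Endian) or the package's raw+metadata fallback format
#' (a single `.ctmeta`/`.raw` pair). DICOM slices are sorted by their world z
#' position (never by file name), the rescale slope/intercept is applied so
#' values are in HU, and the z spacing is measured from inter-slice world
#' positions rather than taken from the nominal slice-thickness tag.
#'
#' @param path directory containing the series.
#' @return A [ct_volume].
#' @export
read_ct_series <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  ctmeta <- list.files(path, pattern = "\\.ctmeta$", full.names = TRUE)
  if (length(ctmeta) == 1L)
    return(read_ct_raw(sub("\\.ctmeta$", "", ctmeta)))
  if (length(ctmeta) > 1L)
    stop("multiple .ctmeta files in ", path, "; expected one series")
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) < 2L)
    stop("need at least 2 DICOM slices in ", path)
  read_dicom_series(files)
}

#' Write a CT series to a directory
#'
#' @param volume a [ct_volume].
#' @param path output directory (created if missing).
#' @param derivation_tag text recorded in the series metadata so derived
#'   series (crust template, virtually cleaned) are distinguishable from
#'   originals.
#' @param format `"dicom"` (one file per slice) or `"raw"` (fallback pair).
#' @return Invisibly, the vector of files written.
#' @export
write_ct_series <- function(volume, path, derivation_tag = "original",
                            format = c("dicom", "raw")) {
  format <- match.arg(format)
  stopifnot(inherits(volume, "ct_volume"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  vol <- volume
  vol$meta$derivation <- derivation_tag
  if (format == "raw")
    return(invisible(write_ct_raw(vol, file.path(path, "series"))))
  write_dicom_series(vol, path, derivation_tag)
}
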