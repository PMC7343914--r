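# Minimal single-frame CT DICOM IO, Explicit VR Little Endian only.
# Scope: exactly the subset of Part 10 this pipeline needs — axial
# single-frame CT slices with identity orientation, 16-bit signed pixels and
# a linear rescale to HU. Anything else (implicit VR, compressed transfer
# syntaxes, oblique orientations, multi-frame objects) is rejected with an
# error rather than guessed at.

DICOM_UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_UID_CT_STORAGE  <- "1.2.840.10008.5.1.4.1.1.2"
DICOM_UID_ROOT        <- "1.2.826.0.1.3680043.10.1462" # generated org root

sc_uid <- function(suffix) paste0(DICOM_UID_ROOT, ".", suffix)

.series_counter <- new.env(parent = emptyenv())
next_series_counter <- function() {
  n <- (get0("n", envir = .series_counter) %||% 0L) + 1L
  assign("n", n, envir = .series_counter)
  n
}

# ---- writing ----------------------------------------------------------------

dcm_elem <- function(group, elem, vr, value_raw) {
  # even-length padding
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0x00) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  tag <- writeBin(c(as.integer(group), as.integer(elem)), raw(),
                  size = 2, endian = "little")
  long_vr <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  if (long_vr) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(tag, charToRaw(vr),
      writeBin(length(value_raw), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

dcm_str <- function(x) charToRaw(as.character(x))
dcm_ds  <- function(x) charToRaw(paste(formatC(x, format = "fg", digits = 10),
                                       collapse = "\\"))
dcm_us  <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

write_dicom_slice <- function(file, pixmat_stored, meta) {
  # pixmat_stored: integer matrix [ix, iy] of stored values (int16)
  m <- meta
  ds <- c(
    dcm_elem(0x0008, 0x0016, "UI", dcm_str(DICOM_UID_CT_STORAGE)),
    dcm_elem(0x0008, 0x0018, "UI", dcm_str(m$sop_uid)),
    dcm_elem(0x0008, 0x0060, "CS", dcm_str("CT")),
    dcm_elem(0x0008, 0x103E, "LO", dcm_str(m$derivation)),
    dcm_elem(0x0008, 0x2111, "ST", dcm_str(m$derivation)),
    dcm_elem(0x0020, 0x000D, "UI", dcm_str(m$study_uid)),
    dcm_elem(0x0020, 0x000E, "UI", dcm_str(m$series_uid)),
    dcm_elem(0x0020, 0x0011, "IS", dcm_str("1")),
    dcm_elem(0x0020, 0x0013, "IS", dcm_str(m$instance)),
    dcm_elem(0x0020, 0x0032, "DS", dcm_ds(m$ipp)),
    dcm_elem(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
    dcm_elem(0x0028, 0x0002, "US", dcm_us(1)),
    dcm_elem(0x0028, 0x0004, "CS", dcm_str("MONOCHROME2")),
    dcm_elem(0x0028, 0x0010, "US", dcm_us(m$rows)),
    dcm_elem(0x0028, 0x0011, "US", dcm_us(m$cols)),
    dcm_elem(0x0028, 0x0030, "DS", dcm_ds(c(m$dy, m$dx))),
    dcm_elem(0x0028, 0x0100, "US", dcm_us(16)),
    dcm_elem(0x0028, 0x0101, "US", dcm_us(16)),
    dcm_elem(0x0028, 0x0102, "US", dcm_us(15)),
    dcm_elem(0x0028, 0x0103, "US", dcm_us(1)),
    dcm_elem(0x0028, 0x1052, "DS", dcm_ds(m$intercept)),
    dcm_elem(0x0028, 0x1053, "DS", dcm_ds(m$slope))
  )
  # pixel data: row-major stream (row y outer, column x inner); the [ix, iy]
  # matrix flattened column-major is exactly that order
  pix <- writeBin(as.integer(pixmat_stored), raw(), size = 2,
                  endian = "little")
  ds <- c(ds, dcm_elem(0x7FE0, 0x0010, "OW", pix))

  grp2 <- c(
    dcm_elem(0x0002, 0x0002, "UI", dcm_str(DICOM_UID_CT_STORAGE)),
    dcm_elem(0x0002, 0x0003, "UI", dcm_str(m$sop_uid)),
    dcm_elem(0x0002, 0x0010, "UI", dcm_str(DICOM_UID_EXPLICIT_LE)),
    dcm_elem(0x0002, 0x0012, "UI", dcm_str(sc_uid("1")))
  )
  meta_grp <- c(dcm_elem(0x0002, 0x0000, "UL",
                         writeBin(length(grp2), raw(), size = 4,
                                  endian = "little")),
                grp2)
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_grp, ds), con)
  invisible(file)
}

write_dicom_series <- function(volume, path, derivation_tag) {
  d <- dim(volume$data)
  slope <- 1; intercept <- -1024
  stored <- (volume$data - intercept) / slope
  stored <- round(stored)
  if (min(stored) < -32768 || max(stored) > 32767)
    stop(sprintf(paste0("HU range [%.0f, %.0f] exceeds the representable ",
                        "stored range after inverse rescale (slope %g, ",
                        "intercept %g); refusing to clip"),
                 min(volume$data), max(volume$data), slope, intercept))
  # unique per call without touching the RNG stream (reproducibility contract)
  series_uid <- sc_uid(paste0("2.", format(as.integer(Sys.time())), ".",
                              Sys.getpid(), ".", next_series_counter()))
  study_uid <- sc_uid("3.1")
  files <- character(d[3])
  for (k in seq_len(d[3])) {
    f <- file.path(path, sprintf("slice%05d.dcm", k))
    ipp <- volume$origin + c(0, 0, (k - 1) * volume$spacing[3])
    write_dicom_slice(f, stored[, , k],
                      list(sop_uid = sc_uid(paste0("4.", k)),
                           study_uid = study_uid, series_uid = series_uid,
                           instance = k, ipp = ipp,
                           rows = d[2], cols = d[1],
                           dx = volume$spacing[1], dy = volume$spacing[2],
                           intercept = intercept, slope = slope,
                           derivation = derivation_tag))
    files[k] <- f
  }
  invisible(files)
}

# ---- reading ----------------------------------------------------------------

read_dicom_file <- function(file) {
  buf <- readBin(file, "raw", n = file.info(file)$size)
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", file)
  pos <- 133L
  n <- length(buf)
  out <- list()
  u16 <- function(i) readBin(buf[i:(i + 1)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(buf[i:(i + 3)], "integer", size = 4,
                             endian = "little")
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- u16(pos + 6L); vstart <- pos + 8L
    } else {
      stop(sprintf("implicit VR or unsupported element at offset %d in %s",
                   pos, file))
    }
    if (len < 0 || vstart + len - 1L > n)
      stop("truncated DICOM element in ", file)
    key <- sprintf("%04x,%04x", group, elem)
    val <- buf[vstart:(vstart + len - 1L)]
    out[[key]] <- list(vr = vr, raw = val)
    pos <- vstart + len
  }
  get_str <- function(key) {
    e <- out[[key]]
    if (is.null(e)) return(NULL)
    trimws(gsub("\\x00", "", rawToChar(e$raw), useBytes = TRUE))
  }
  get_ds <- function(key) {
    s <- get_str(key)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  get_us <- function(key) {
    e <- out[[key]]
    if (is.null(e)) return(NULL)
    readBin(e$raw, "integer", n = length(e$raw) / 2, size = 2,
            endian = "little", signed = FALSE)[1]
  }
  ts <- get_str("0002,0010")
  if (!is.null(ts) && ts != DICOM_UID_EXPLICIT_LE)
    stop("unsupported transfer syntax ", ts, " in ", file,
         " (only Explicit VR Little Endian is supported)")
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  pxsp <- get_ds("0028,0030")
  if (is.null(pxsp))
    stop("missing PixelSpacing (0028,0030) in ", file)
  iop <- get_ds("0020,0037")
  if (!is.null(iop) && max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("oblique acquisition (ImageOrientationPatient != axial identity) ",
         "is not supported: ", file)
  ipp <- get_ds("0020,0032")
  if (is.null(ipp)) stop("missing ImagePositionPatient in ", file)
  pr <- get_us("0028,0103") %||% 0L
  pix_raw <- out[["7fe0,0010"]]
  if (is.null(pix_raw)) stop("missing PixelData in ", file)
  pix <- readBin(pix_raw$raw, "integer", n = rows * cols, size = 2,
                 endian = "little", signed = (pr == 1L))
  slope <- (get_ds("0028,1053") %||% 1)[1]
  intercept <- (get_ds("0028,1052") %||% 0)[1]
  # row-major stream -> [ix, iy] matrix
  slice <- matrix(pix * slope + intercept, nrow = cols, ncol = rows)
  list(slice = slice, ipp = ipp,
       dx = pxsp[2], dy = pxsp[1],
       series_uid = get_str("0020,000e") %||% "",
       derivation = get_str("0008,103e") %||% "",
       rows = rows, cols = cols)
}

read_dicom_series <- function(files) {
  slices <- lapply(files, read_dicom_file)
  uids <- unique(vapply(slices, `[[`, "", "series_uid"))
  if (length(uids) > 1L)
    stop("directory mixes series ", paste(uids, collapse = " and "))
  zs <- vapply(slices, function(s) s$ipp[3], 0)
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  if (anyDuplicated(zs))
    stop("duplicate slice world-z positions in series")
  dz_all <- diff(zs)
  dz <- stats::median(dz_all)
  if (any(abs(dz_all - dz) > 0.01 * dz))
    stop(sprintf("non-uniform inter-slice spacing (%.4f..%.4f mm) beyond 1%% tolerance",
                 min(dz_all), max(dz_all)))
  dims <- vapply(slices, function(s) c(s$cols, s$rows), c(0, 0))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("slice dimensions differ across the series")
  dat <- array(0, dim = c(dims[1, 1], dims[2, 1], length(slices)))
  for (k in seq_along(slices)) dat[, , k] <- slices[[k]]$slice
  s1 <- slices[[1]]
  ct_volume(dat, c(s1$dx, s1$dy, dz),
            origin = c(s1$ipp[1], s1$ipp[2], zs[1]),
            meta = list(derivation = s1$derivation,
                        series_uid = s1$series_uid))
}
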