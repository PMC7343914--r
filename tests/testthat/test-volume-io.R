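test_that("raw fallback format round-trips data, spacing, origin and tag", {
  v <- ct_volume(array(rnorm(10 * 8 * 4, 0, 200), dim = c(10, 8, 4)),
                 c(0.33, 0.33, 0.67), c(-5, 2, 100))
  d <- withr::local_tempdir()
  write_ct_series(v, d, "crust-template", format = "raw")
  v2 <- read_ct_series(d)
  expect_identical(v2$data, v$data)
  expect_equal(v2$spacing, v$spacing)
  expect_equal(v2$origin, v$origin)
  expect_identical(v2$meta$derivation, "crust-template")
})

test_that("DICOM series round-trips exactly and applies the HU rescale", {
  v <- ct_volume(array(round(rnorm(12 * 9 * 5, 0, 300)), dim = c(12, 9, 5)),
                 c(0.33, 0.33, 0.67), c(-3, -2, 10))
  d <- withr::local_tempdir()
  files <- write_ct_series(v, d, "virtually-cleaned")
  expect_length(list.files(d, pattern = "\\.dcm$"), 5L)
  v2 <- read_ct_series(d)
  # integer HU: quantisation-free round trip
  expect_identical(v2$data, v$data)
  expect_equal(v2$spacing, v$spacing)
  expect_equal(v2$origin, v$origin)
  expect_identical(v2$meta$derivation, "virtually-cleaned")
})

test_that("one file is written per slice", {
  nz <- 23L
  v <- ct_volume(array(0, dim = c(4, 4, nz)), c(1, 1, 1))
  d <- withr::local_tempdir()
  write_ct_series(v, d, "original")
  expect_length(list.files(d, pattern = "\\.dcm$"), nz)
})

test_that("slices are ordered by world z, not by file name", {
  set.seed(1)
  v <- ct_volume(array(as.numeric(seq_len(6 * 5 * 8)), dim = c(6, 5, 8)),
                 c(1, 1, 2), c(0, 0, 50))
  d <- withr::local_tempdir()
  write_ct_series(v, d, "original")
  # shuffle the file names; world positions inside the files are untouched
  files <- list.files(d, full.names = TRUE)
  tmp <- file.path(d, paste0("x", sample(length(files)), ".dcm"))
  file.rename(files, tmp)
  v2 <- read_ct_series(d)
  expect_identical(v2$data, v$data)
  expect_equal(v2$origin[3], 50)
})

test_that("mixed series and non-uniform slice spacing are rejected", {
  v <- ct_volume(array(0, dim = c(4, 4, 3)), c(1, 1, 1))
  d <- withr::local_tempdir()
  write_ct_series(v, d, "original")
  d2 <- withr::local_tempdir()
  write_ct_series(v, d2, "original")
  file.copy(list.files(d2, full.names = TRUE)[1],
            file.path(d, "other00001.dcm"))
  expect_error(read_ct_series(d), "mixes series")

  v5 <- ct_volume(array(0, dim = c(4, 4, 5)), c(1, 1, 1))
  d3 <- withr::local_tempdir()
  write_ct_series(v5, d3, "original")
  # removing an interior slice leaves a 2 mm gap in a 1 mm series
  file.remove(file.path(d3, "slice00003.dcm"))
  expect_error(read_ct_series(d3), "non-uniform")
})

test_that("HU outside the representable stored range is an error, not a clip", {
  v <- ct_volume(array(40000, dim = c(4, 4, 2)), c(1, 1, 1))
  d <- withr::local_tempdir()
  expect_error(write_ct_series(v, d, "original"), "refusing to clip")
})

test_that("voxel (i,j,k) maps to origin + ((i-1)dx, (j-1)dy, (k-1)dz)", {
  v <- ct_volume(array(0, dim = c(5, 5, 5)), c(0.5, 0.25, 2), c(10, -4, 7))
  expect_equal(voxel_to_world(v, rbind(c(1, 1, 1))), rbind(c(10, -4, 7)))
  expect_equal(voxel_to_world(v, rbind(c(3, 2, 5))),
               rbind(c(10 + 2 * 0.5, -4 + 1 * 0.25, 7 + 4 * 2)))
})

test_that("volume invariants are enforced at construction", {
  expect_error(ct_volume(array(0, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(ct_volume(array(0, c(2, 2, 2)), c(1, 0, 1)), "positive")
  expect_error(ct_volume(array(c(NA, rep(0, 7)), c(2, 2, 2)), c(1, 1, 1)),
               "finite")
})

test_that("written DICOM is readable by an independent implementation", {
  # cross-check against pydicom (independent oracle; never the implementation)
  expect_true(has_python_pydicom())
  v <- ct_volume(array(round(rnorm(8 * 6 * 2, 0, 100)), dim = c(8, 6, 2)),
                 c(0.4, 0.5, 1.25), c(1, 2, 3))
  d <- withr::local_tempdir()
  write_ct_series(v, d, "crust-template")
  f <- sort(list.files(d, full.names = TRUE))[1]
  out <- system2("python", c("-c", shQuote(paste0(
    "import pydicom, json\n",
    "ds = pydicom.dcmread(", deparse(f), ")\n",
    "px = ds.pixel_array * float(ds.RescaleSlope) + float(ds.RescaleIntercept)\n",
    "print(json.dumps({'rows': int(ds.Rows), 'cols': int(ds.Columns),\n",
    " 'spacing': [float(x) for x in ds.PixelSpacing],\n",
    " 'ipp': [float(x) for x in ds.ImagePositionPatient],\n",
    " 'desc': str(ds.SeriesDescription),\n",
    " 'row0': [float(x) for x in px[0, :]],\n",
    " 'col0': [float(x) for x in px[:, 0]]}))\n"))), stdout = TRUE)
  j <- jsonlite::fromJSON(out)
  expect_identical(j$rows, 6L)
  expect_identical(j$cols, 8L)
  expect_equal(j$spacing, c(0.5, 0.4))   # DICOM order: row (dy), column (dx)
  expect_equal(j$ipp, c(1, 2, 3))
  expect_identical(j$desc, "crust-template")
  expect_equal(j$row0, v$data[, 1, 1])
  expect_equal(j$col0, v$data[1, , 1])
})
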