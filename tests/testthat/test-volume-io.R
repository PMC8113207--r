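# volume_io: containers, validation, NIfTI round-trips, metadata parsing.

test_that("voxel_volume validates geometry and derives voxel size", {
  v <- voxel_volume(array(0, dim = c(4, 4, 4)), spacing_mm = rep(4.42, 3))
  expect_equal(voxel_size_ml(v), 4.42^3 / 1000)  # 0.086350888 ml
  expect_equal(voxel_size_ml(v), 0.0864, tolerance = 1e-3)

  expect_error(voxel_volume(matrix(0, 2, 2), rep(1, 3)), "3-D")
  expect_error(voxel_volume(array(0, dim = c(2, 2, 2)), c(1, 0, 1)),
               "positive")
  expect_error(voxel_volume(array(NA_real_, dim = c(2, 2, 2)), rep(1, 3)),
               "finite")
})

test_that("negative voxels are clipped to zero with a logged count", {
  a <- array(1, dim = c(3, 3, 3))
  a[2, 2, 2] <- -3
  expect_message(v <- voxel_volume(a, rep(1, 3)), "clipped 1 negative")
  expect_equal(v$values[2, 2, 2], 0)
  expect_equal(attr(v, "n_clipped"), 1)
  expect_true(all(v$values >= 0))
})

test_that("volume round-trip is bit-exact for values, 1e-6 mm for spacing", {
  set.seed(42)
  a <- array(runif(4^3, 0, 100), dim = c(4, 4, 4))
  v <- voxel_volume(a, spacing_mm = c(4.42, 4.42, 4.42),
                    origin_mm = c(-10, 5, 2.5))
  for (ext in c(".nii", ".nii.gz")) {
    path <- tempfile(fileext = ext)
    write_volume(v, path)
    v2 <- read_volume(path)
    expect_identical(v2$values, v$values)
    expect_lt(max(abs(v2$spacing_mm - v$spacing_mm)), 1e-6)
    expect_equal(v2$origin_mm, v$origin_mm, tolerance = 1e-5)
    unlink(path)
  }
})

test_that("mask round-trip preserves the exact label multiset", {
  set.seed(7)
  lab <- array(sample(0:5, 6^3, replace = TRUE), dim = c(6, 6, 6))
  lm <- c(LV_LATERAL = 1L, IVS = 2L, APEX = 3L, RV_FREE_WALL = 4L,
          STERNUM = 5L)
  m <- region_mask_set(lab, lm, spacing_mm = rep(2.5, 3))
  path <- tempfile(fileext = ".nii.gz")
  write_mask_set(m, path)
  m2 <- read_mask_set(path, lm)
  expect_identical(table(m2$labels), table(m$labels))
  expect_identical(m2$labels, m$labels)
  unlink(path)
})

test_that("reader rejects bad files and headers", {
  expect_error(read_volume(tempfile()), "not found")
  p <- tempfile(fileext = ".nii")
  writeBin(raw(100), p)
  expect_error(read_volume(p), "NIfTI")
  unlink(p)
  # 4-D with a non-singleton 4th dim is rejected
  p4 <- tempfile(fileext = ".nii")
  dpdquant:::write_nifti(array(0, dim = c(2, 2, 4)), p4, rep(1, 3))
  raw4 <- readBin(p4, "raw", file.size(p4))
  raw4[41:42] <- writeBin(4L, raw(), size = 2, endian = "little")  # dim[0]=4
  raw4[49:50] <- writeBin(2L, raw(), size = 2, endian = "little")  # nz=2
  raw4[51:52] <- writeBin(2L, raw(), size = 2, endian = "little")  # nt=2
  writeBin(raw4, p4)
  expect_error(read_volume(p4), "not 3-D")
  unlink(p4)
})

test_that("mask constructor enforces congruence and flags empty labels", {
  v <- uniform_volume(1, n = 4, spacing = rep(4.42, 3))
  lab <- array(0L, dim = c(4, 4, 4)); lab[1:2, , ] <- 1L; lab[3, , ] <- 2L
  # shape mismatch
  expect_error(region_mask_set(array(0L, dim = c(3, 3, 3)),
                               c(IVS = 1L), rep(4.42, 3), volume = v),
               "shape")
  # spacing mismatch
  expect_error(region_mask_set(lab, c(IVS = 1L), rep(4, 3), volume = v),
               "spacing")
  # label absent from grid -> warning naming the region
  expect_warning(region_mask_set(lab, c(IVS = 1L, APEX = 9L), rep(4.42, 3),
                                 volume = v),
                 "APEX")
  # valid two-region map
  m <- region_mask_set(lab, c(IVS = 1L, APEX = 2L), rep(4.42, 3), volume = v)
  expect_length(region_voxels(m, "IVS"), 32)
  expect_length(region_voxels(m, "APEX"), 16)
  expect_error(region_voxels(m, "STERNUM"), "not in label map")
  expect_error(region_mask_set(lab, c(A = 1L, B = 1L), rep(4.42, 3)),
               "same label")
})

test_that("acquisition metadata validates fields and parses JSON", {
  m <- acquisition_meta(740, "2020-01-01 09:00:00", "2020-01-01 12:00:00",
                        74.6)
  expect_equal(uptake_time_h(m), 3)
  expect_equal(m$half_life_h, 6.0067)
  expect_error(acquisition_meta(-1, "2020-01-01", "2020-01-01", 70),
               "injected_activity")
  expect_error(acquisition_meta(740, "2020-01-01 12:00:00",
                                "2020-01-01 09:00:00", 70),
               "precedes")

  path <- tempfile(fileext = ".json")
  write_meta(m, path)
  m2 <- read_meta(path)
  expect_equal(m2$injected_activity_MBq, 740)
  expect_equal(uptake_time_h(m2), 3)
  expect_equal(m2$body_weight_kg, 74.6)

  # missing required field is named in the error
  j <- jsonlite::read_json(path)
  j$body_weight_kg <- NULL
  jsonlite::write_json(j, path, auto_unbox = TRUE)
  expect_error(read_meta(path), "body_weight_kg")
  unlink(path)
})

test_that("our NIfTI files agree with nibabel (independent oracle)", {
  set.seed(11)
  a <- array(round(runif(5 * 4 * 3, 0, 50), 3), dim = c(5, 4, 3))
  v <- voxel_volume(a, spacing_mm = c(2, 3, 4), origin_mm = c(1, -2, 3))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  script <- paste0(
    "import nibabel, numpy as np\n",
    "img = nibabel.load('", path, "')\n",
    "d = np.asanyarray(img.dataobj)\n",
    "print(d.shape[0], d.shape[1], d.shape[2])\n",
    "print(repr(float(d.sum())))\n",
    "print(repr(float(d[2,1,0])))\n",
    "z = img.header.get_zooms()\n",
    "print(z[0], z[1], z[2])\n")
  out <- suppressWarnings(system2("python", "-", input = script,
                                  stdout = TRUE, stderr = TRUE))
  expect_true(length(out) >= 4)
  expect_equal(scan(text = out[1], quiet = TRUE), c(5, 4, 3))
  expect_equal(as.numeric(out[2]), sum(a), tolerance = 1e-10)
  expect_equal(as.numeric(out[3]), a[3, 2, 1], tolerance = 1e-10)
  expect_equal(scan(text = out[4], quiet = TRUE), c(2, 3, 4),
               tolerance = 1e-5)
  unlink(path)

  # reverse direction: read a nibabel-written file
  path2 <- tempfile(fileext = ".nii.gz")
  script2 <- paste0(
    "import nibabel, numpy as np\n",
    "d = np.arange(24, dtype=np.float32).reshape((2,3,4), order='F')\n",
    "aff = np.diag([1.5, 2.5, 3.5, 1.0])\n",
    "nibabel.save(nibabel.Nifti1Image(d, aff), '", path2, "')\n")
  status <- suppressWarnings(system2("python", "-", input = script2))
  expect_equal(status, 0)
  v2 <- read_volume(path2)
  expect_equal(dim(v2$values), c(2L, 3L, 4L))
  expect_equal(as.vector(v2$values), as.double(0:23))
  expect_equal(v2$spacing_mm, c(1.5, 2.5, 3.5), tolerance = 1e-6)
  unlink(path2)
})
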