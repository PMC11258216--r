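test_that("energy binning enforces its invariants", {
  expect_error(energy_binning(c(20, 7)), "increasing")
  expect_error(energy_binning(c(-5, 20)), "positive")
  expect_error(energy_binning(c(7, 20, 30), usable = c(TRUE, TRUE)),
               "one flag per bin")
  bn <- default_binning()
  expect_equal(n_bins(bn), 5L)
  expect_equal(which(bn$usable), 2:4)
  expect_equal(bin_interval(bn, 5, cap_keV = 80), c(73, 80))
  expect_error(bin_interval(bn, 6), "out of range")
})

test_that("spectral volume validates bin count, voxel size and finiteness", {
  bn <- default_binning()
  expect_error(spectral_volume(array(0, c(3, 3, 3, 4)), bn), "mismatch")
  expect_error(spectral_volume(array(0, c(3, 3, 3, 5)), bn,
                               voxel_size_um = -1), "positive")
  bad <- array(0, c(3, 3, 3, 5)); bad[1] <- NA
  expect_error(spectral_volume(bad, bn), "finite")
  # negatives are preserved, not clamped
  d <- array(-0.1, c(2, 2, 2, 5))
  expect_equal(min(spectral_volume(d, bn)$data), -0.1)
})

test_that("write/read round-trip preserves data and metadata exactly", {
  v <- tiny_volume()
  path <- file.path(withr::local_tempdir(), "vol.nii")
  write_spectral_volume(v, path)
  v2 <- read_spectral_volume(path)
  expect_identical(dim(v2$data), dim(v$data))
  expect_identical(as.numeric(v2$data), as.numeric(v$data))
  expect_equal(v2$binning$edges_keV, v$binning$edges_keV)
  expect_equal(v2$binning$usable, v$binning$usable)
  expect_equal(v2$voxel_size_um, v$voxel_size_um)
  expect_equal(v2$orientation, v$orientation)
})

test_that("sidecar bin-count mismatch and missing keys are format errors", {
  v <- tiny_volume()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "vol.nii")
  write_spectral_volume(v, path)
  sc <- jsonlite::read_json(file.path(dir, "vol.json"),
                            simplifyVector = TRUE)
  sc$edges_keV <- sc$edges_keV[1:4]  # declares 4 bins for 5-bin data
  sc$usable <- sc$usable[1:4]
  jsonlite::write_json(sc, file.path(dir, "vol.json"), auto_unbox = TRUE)
  expect_error(read_spectral_volume(path), "mismatch")
  sc$edges_keV <- NULL
  jsonlite::write_json(sc, file.path(dir, "vol.json"), auto_unbox = TRUE)
  expect_error(read_spectral_volume(path), "missing keys")
})

test_that("a directory of per-bin files reads as a multi-bin volume", {
  v <- tiny_volume()
  dir <- withr::local_tempdir()
  bindir <- file.path(dir, "bins")
  dir.create(bindir)
  for (b in 1:5)
    RNifti::writeNifti(RNifti::asNifti(v$data[, , , b],
                                       datatype = "double"),
                       file.path(bindir, sprintf("bin%d.nii", b - 1)))
  jsonlite::write_json(
    list(edges_keV = c(7, 20, 30, 47, 73), open_top = TRUE,
         usable = c(FALSE, TRUE, TRUE, TRUE, FALSE), voxel_size_um = 90,
         orientation = "mouse_prone_display"),
    file.path(dir, "side.json"), auto_unbox = TRUE)
  v2 <- read_spectral_volume(bindir, file.path(dir, "side.json"))
  expect_equal(n_bins(v2$binning), 5L)
  expect_equal(which(v2$binning$usable), 2:4)
  expect_equal(as.numeric(v2$data), as.numeric(v$data))
  # wrong file count is a format error
  file.remove(file.path(bindir, "bin4.nii"))
  expect_error(read_spectral_volume(bindir, file.path(dir, "side.json")),
               "5 bins")
})

test_that("slice extraction applies the prone-display flip and inverts", {
  bn <- default_binning()
  d <- array(0, c(6, 5, 4, 5))
  d[2, 3, 4, ] <- 1  # marker voxel
  v <- spectral_volume(d, bn)
  sl <- extract_slice(v, "axial", 4)
  # marker column mirrored: x = 2 displays at 6 + 1 - 2 = 5
  expect_equal(which(sl[, , 1] == 1, arr.ind = TRUE)[1, ],
               c(row = 5, col = 3))
  expect_error(extract_slice(v, "axial", 5), "out of range")

  # re-inserting the un-flipped slice recovers the stored volume
  unflipped <- sl[rev(seq_len(dim(sl)[1])), , , drop = FALSE]
  rebuilt <- v$data
  rebuilt[, , 4, ] <- unflipped
  expect_identical(rebuilt, v$data)
})

test_that("coronal slices match the direct-indexing oracle per depth", {
  v <- tiny_volume(nx = 6, ny = 7, nz = 5)
  for (j in c(2, 6)) {
    sl <- extract_slice(v, "coronal", j, flip = FALSE)
    oracle <- v$data[, j, , ]
    expect_equal(as.numeric(sl), as.numeric(oracle))
  }
  expect_false(identical(extract_slice(v, "coronal", 2),
                         extract_slice(v, "coronal", 6)))
})

test_that("axial slices over all indices partition the volume", {
  v <- tiny_volume()
  rebuilt <- array(NA_real_, dim = dim(v$data))
  for (k in seq_len(dim(v$data)[3])) {
    sl <- extract_slice(v, "axial", k)
    rebuilt[, , k, ] <- sl[rev(seq_len(dim(sl)[1])), , , drop = FALSE]
  }
  expect_identical(rebuilt, v$data)
})

test_that("usable_channels is a pure projection of bins 2-4", {
  v <- tiny_volume()
  ch <- usable_channels(v)
  expect_identical(dim(ch)[4], 3L)
  expect_identical(as.numeric(ch), as.numeric(v$data[, , , 2:4]))

  # bin-constant volume projects to the matching channel constants
  bn <- default_binning()
  d <- array(rep(1:5, each = 8), dim = c(2, 2, 2, 5))
  ch2 <- usable_channels(spectral_volume(d, bn))
  expect_equal(unique(as.numeric(ch2[, , , 1])), 2)
  expect_equal(unique(as.numeric(ch2[, , , 3])), 4)

  allzero <- spectral_volume(array(0, c(2, 2, 2, 5)), bn)
  expect_true(all(usable_channels(allzero) == 0))

  bad <- energy_binning(c(7, 20, 30, 47, 73), usable = rep(TRUE, 5))
  expect_error(usable_channels(spectral_volume(d, bad)), "3 usable")
})

test_that("roi_set validates geometry and roles", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  rs <- roi_set(list(t1 = m, bg = m),
                labels = c(t1 = "tumor", bg = "background_muscle"))
  expect_named(roi_masks(rs, "tumor"), "t1")
  expect_error(roi_set(list(t1 = m, bg = array(FALSE, c(2, 2, 2))),
                       labels = c(t1 = "tumor", bg = "background_muscle")),
               "grid")
})

test_that("masks survive a NIfTI round trip", {
  m <- array(runif(60) > 0.5, dim = c(5, 4, 3))
  path <- file.path(withr::local_tempdir(), "mask.nii")
  write_mask(m, path)
  expect_identical(read_mask(path), m)
})
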