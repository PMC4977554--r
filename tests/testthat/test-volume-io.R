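test_that("volume3d enforces shape, units and intensity convention", {
  arr <- array(rnorm(10 * 12 * 14), c(10, 12, 14))
  v <- volume3d(arr, 0.35)
  expect_equal(v$voxel_size, rep(0.35, 3))
  expect_equal(voxel_volume(v), 0.35^3)
  expect_error(volume3d(matrix(1, 8, 8), 0.35), class = "nucmorph_shape_error")
  expect_error(volume3d(array(1, c(4, 8, 8)), 0.35), class = "nucmorph_shape_error")
  expect_error(volume3d(arr, c(0.35, -1, 0.35)), class = "nucmorph_unit_error")
  expect_error(volume3d(arr, numeric(0)), class = "nucmorph_unit_error")
})

test_that("label_mask validates values and records its role", {
  fg <- array(FALSE, c(8, 8, 8)); fg[3:5, 3:5, 3:5] <- TRUE
  m <- label_mask(fg, 0.5, role = "nucleus")
  expect_identical(sort(unique(as.vector(m$data))), c(0L, 1L))
  expect_equal(m$role, "nucleus")
  bad <- array(0, c(8, 8, 8)); bad[1] <- -2
  expect_error(label_mask(bad, 0.5), class = "nucmorph_value_error")
  bad2 <- array(0.5, c(8, 8, 8))
  expect_error(label_mask(bad2, 0.5), class = "nucmorph_value_error")
})

test_that("TIFF stacks round-trip volumes at sample precision, exactly for
          integer data", {
  set.seed(42)
  ints <- array(sample.int(5000, 64^3, replace = TRUE) - 1, c(64, 64, 64))
  v_int <- volume3d(ints * 1.0, c(0.35, 0.35, 0.35))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(v_int, path)
  back_int <- read_stack(path)
  expect_identical(back_int$data, v_int$data)
  expect_equal(back_int$voxel_size, v_int$voxel_size, tolerance = 1e-9)
  expect_equal(dim(back_int$data), c(64L, 64L, 64L))

  # continuous data: within 2^-32 of the intensity range
  cont <- array(rnorm(64^3, 10, 30), c(64, 64, 64))
  v <- volume3d(cont, 0.35)
  write_stack(v, path)
  back <- read_stack(path)
  expect_lt(max(abs(back$data - cont)), diff(range(cont)) * 2^-30)

  # constant volume
  vc <- volume3d(array(7, c(8, 8, 8)), 0.2)
  write_stack(vc, path)
  bc <- read_stack(path)
  expect_equal(range(bc$data), c(7, 7))
})

test_that("mask stacks keep integer labels and roles through TIFF", {
  fg <- array(0L, c(8, 10, 12))
  fg[2:4, 2:4, 2:4] <- 1L
  fg[6:7, 6:8, 6:9] <- 2L
  m <- label_mask(fg, c(0.25, 0.35, 0.35), role = "clump")
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(m, path)
  back <- read_mask(path)
  expect_identical(back$data, m$data)
  expect_identical(back$role, "clump")
  expect_identical(sort(unique(as.vector(back$data))), c(0L, 1L, 2L))
})

test_that("read_stack refuses 2D pages and missing voxel sizes", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(64), 8, 8), path)
  expect_error(read_stack(path, voxel_size_override = 0.35),
               class = "nucmorph_shape_error")
  # multi-page but no sidecar and no override
  tiff::writeTIFF(lapply(1:8, function(i) matrix(runif(64), 8, 8)), path)
  file.remove(paste0(path, ".json")) |> suppressWarnings()
  expect_error(read_stack(path), class = "nucmorph_unit_error")
  expect_s3_class(read_stack(path, voxel_size_override = c(0.25, 0.35, 0.35)),
                  "volume3d")
})

test_that("feature tables round-trip CSV at full numeric precision", {
  tab <- feature_table(tibble::tibble(
    cell_id = c("c1", "c1", "c2"),
    condition = "dmso",
    feature = c("nuclear_volume", "nc_ratio", "nuclear_volume"),
    value = c(672.7, 0.65, 553.2 + 1e-10),
    unit = c("um3", "", "um3")
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$value, tab$value, tolerance = 1e-12)
  expect_identical(back$feature, tab$feature)

  # empty table round-trips as header-only
  empty <- tab[0, ]
  write_feature_table(empty, path)
  expect_equal(nrow(read_feature_table(path)), 0)

  # malformed header
  writeLines("id,cond,value", path)
  expect_error(read_feature_table(path), class = "nucmorph_format_error")

  # duplicate (condition, cell, feature) rows refused
  dup <- dplyr::bind_rows(tab, tab[1, ])
  expect_error(feature_table(dup), class = "nucmorph_format_error")
})
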