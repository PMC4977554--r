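# The four morphometric descriptors and the cohort runner.

test_that("nuclear volume is voxel count times voxel volume", {
  fg <- array(FALSE, c(12, 12, 12))
  fg[sample.int(12^3, 1000)] <- TRUE
  m <- label_mask(fg, 0.5, "nucleus")
  expect_equal(nuclear_volume(m), 1000 * 0.125)
  ball <- sphere_mask_um(5, 0.35)
  expect_equal(nuclear_volume(ball), 4 / 3 * pi * 125, tolerance = 0.03)
  rot <- label_mask(rot90_zyx(array(fg, dim(fg))), 0.5, "nucleus")
  expect_equal(nuclear_volume(rot), nuclear_volume(m))
  expect_error(nuclear_volume(label_mask(array(FALSE, c(8, 8, 8)), 1, "nucleus")),
               class = "nucmorph_empty_error")
})

test_that("NC ratio uses the cytoplasm-only denominator", {
  cell <- array(FALSE, c(20, 20, 20)); cell[2:17, 2:17, 2:17] <- TRUE # 4096
  nuc <- array(FALSE, c(20, 20, 20)); nuc[5:14, 5:14, 5:14] <- TRUE   # 1000
  cm <- label_mask(cell, 1, "cell"); nm <- label_mask(nuc, 1, "nucleus")
  expect_equal(nc_ratio(nm, cm), 1000 / 3096)
  half <- array(FALSE, c(20, 20, 20)); half[2:17, 2:17, 2:9] <- TRUE
  expect_equal(nc_ratio(label_mask(half, 1, "nucleus"), cm), 1)
  expect_error(nc_ratio(cm, cm), class = "nucmorph_value_error") # no cytoplasm
  expect_error(nc_ratio(cm, nm), class = "nucmorph_value_error") # not contained
})

test_that("concavity index matches the Qhull oracle on a bitten ball", {
  m <- bitten_ball(20, 10)
  expect_equal(concavity_index(m), oracle_hull_deficit(m), tolerance = 0.5)
  expect_lte(concavity_index(digital_ball(10)), 2)
})

test_that("concavity grows monotonically with invagination size and is
          rotation/translation invariant", {
  conc <- vapply(c(4, 6, 8), function(b) concavity_index(bitten_ball(12, b)),
                 numeric(1))
  expect_true(all(diff(conc) > 0))
  m <- bitten_ball(9, 5)
  rot <- label_mask(rot90_zyx(array(m$data, dim(m$data))), 1, "nucleus")
  expect_equal(concavity_index(rot), concavity_index(m), tolerance = 1e-9)
  # translation by whole voxels
  shifted <- array(0L, dim(m$data) + 2L)
  shifted[3:(dim(m$data)[1] + 2), 2:(dim(m$data)[2] + 1), 1:dim(m$data)[3]] <- m$data
  expect_equal(concavity_index(label_mask(shifted, 1, "nucleus")),
               concavity_index(m), tolerance = 1e-9)
})

test_that("dense clump counts recover the planted number", {
  for (k in c(0L, 5L, 6L)) {
    ph <- make_cell_phantom(cell_phantom_spec(n_clumps = k, noise_sd = 0.02,
                                              seed = 40 + k))
    expect_equal(count_dense_clumps(ph$volume, ph$nucleus_mask), k)
  }
  # sub-minimum-volume blobs are discarded
  ph <- make_cell_phantom(cell_phantom_spec(n_clumps = 4, noise_sd = 0.02, seed = 50))
  expect_equal(count_dense_clumps(ph$volume, ph$nucleus_mask,
                                  min_clump_volume_um3 = 50), 0L)
})

test_that("clump recovery holds across seeds at contrast 1.5 and 10% noise", {
  hits <- vapply(1:6, function(s) {
    ph <- make_cell_phantom(cell_phantom_spec(
      n_clumps = 4, clump_contrast = 1.5, noise_sd = 0.07, seed = 60 + s))
    count_dense_clumps(ph$volume, ph$nucleus_mask) == 4L
  }, logical(1))
  expect_true(all(hits))
})

test_that("run_morphometry processes a cohort directory and reports failures", {
  dir <- withr::local_tempdir()
  pop <- population_params(voxel_size_um = 0.6, grid_dim = c(40L, 40L, 40L))
  make_cohort(4, pop, seed = 12, out_dir = dir)
  # add one broken stack that cannot be segmented
  flat <- volume3d(array(1, c(8, 8, 8)), 0.6)
  write_stack(flat, file.path(dir, "cellbad_volume.tif"))
  res <- run_morphometry(dir, condition = "test")
  expect_equal(length(unique(res$features$cell_id)), 4)
  expect_equal(nrow(res$errors), 1)
  expect_match(res$errors$cell_id, "cellbad")
  # determinism: re-running the same directory reproduces the table
  res2 <- run_morphometry(dir, condition = "test")
  expect_identical(res$features, res2$features)
  # measured values sit close to the stored ground truth
  gt <- read_feature_table(file.path(dir, "ground_truth.csv"))
  joined <- dplyr::inner_join(res$features, gt,
                              by = c("cell_id", "feature"),
                              suffix = c("_m", "_t"))
  vol <- dplyr::filter(joined, feature == "nuclear_volume")
  expect_true(all(abs(vol$value_m - vol$value_t) / vol$value_t < 0.05))
})
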