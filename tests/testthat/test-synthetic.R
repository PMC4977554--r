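# Phantom generators: planted ground truth, determinism, feasibility errors.

test_that("cell phantom truth is computed from the emitted masks", {
  spec <- cell_phantom_spec(n_clumps = 5, n_invaginations = 0, seed = 3)
  ph <- make_cell_phantom(spec)
  vv <- voxel_volume(ph$nucleus_mask)
  expect_equal(ph$truth$nuclear_volume, sum(ph$nucleus_mask$data > 0) * vv)
  expect_equal(ph$truth$cell_volume, sum(ph$cell_mask$data > 0) * vv)
  expect_equal(ph$truth$clump_count, 5L)
  expect_equal(max(label_components(ph$clump_mask$data > 0, 26L)), 5L)
  # convex nucleus: concavity at the discretisation floor
  expect_lte(ph$truth$concavity_pct, 2)
  # spherical nucleus volume near the analytic value
  expect_equal(ph$truth$nuclear_volume, 4 / 3 * pi * 5^3, tolerance = 0.03)
  # intensity ordering: nucleus > cytoplasm > background
  cyto <- ph$cell_mask$data > 0 & ph$nucleus_mask$data == 0
  bg <- ph$cell_mask$data == 0
  expect_gt(mean(ph$volume$data[ph$nucleus_mask$data > 0]), mean(ph$volume$data[cyto]))
  expect_gt(mean(ph$volume$data[cyto]), mean(ph$volume$data[bg]))
})

test_that("phantom generation is bit-reproducible under a seed", {
  spec <- cell_phantom_spec(n_clumps = 3, n_invaginations = 1, seed = 77)
  a <- make_cell_phantom(spec)
  b <- make_cell_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth, b$truth)
})

test_that("infeasible clump placement raises a placement error", {
  spec <- cell_phantom_spec(cell_semiaxes_um = c(3, 3, 3),
                            nucleus_semiaxes_um = c(2, 2, 2),
                            n_clumps = 40, clump_radius_um = 0.6, seed = 1)
  expect_error(make_cell_phantom(spec), class = "nucmorph_placement_error")
})

test_that("invaginations produce hull-deficit concavity that grows with size", {
  conc <- vapply(c(1.5, 2.5, 3.5), function(r) {
    spec <- cell_phantom_spec(n_invaginations = 2, invagination_radius_um = r,
                              noise_sd = 0, seed = 5)
    make_cell_phantom(spec)$truth$concavity_pct
  }, numeric(1))
  expect_true(all(diff(conc) > 0))
  expect_gt(conc[1], 0.5)
})

test_that("FISH spots land at the requested radial positions", {
  ph <- make_fish_phantom(spot_rrds = c(0.1, 0.3, 0.5, 0.7, 0.9),
                          coloc_rho = 0.5, seed = 8)
  sdf <- nucmorph:::signed_distance(ph$nucleus_mask)
  re <- vapply(seq_len(nrow(ph$truth)), function(i) {
    rrd(c(ph$truth$z_um[i], ph$truth$y_um[i], ph$truth$x_um[i]),
        ph$nucleus_mask, sdf)
  }, numeric(1))
  expect_true(all(abs(re - ph$truth$requested_rrd) <= 0.05))
})

test_that("FISH extremes: rrd 1 at the centroid, rrd 0 at the boundary", {
  ph1 <- make_fish_phantom(spot_rrds = 1, seed = 2)
  cen <- nucmorph:::mask_centroid_um(ph1$nucleus_mask)
  pos <- unlist(ph1$truth[1, c("z_um", "y_um", "x_um")])
  expect_lt(sqrt(sum((pos - cen)^2)), max(ph1$nucleus_mask$voxel_size))
  ph0 <- make_fish_phantom(spot_rrds = 0, seed = 2)
  pos0 <- unlist(ph0$truth[1, c("z_um", "y_um", "x_um")])
  sdf <- nucmorph:::signed_distance(ph0$nucleus_mask)
  d_boundary <- nucmorph:::interp_trilinear(sdf, matrix(pos0 / ph0$nucleus_mask$voxel_size, 1))
  expect_lt(abs(d_boundary), max(ph0$nucleus_mask$voxel_size))
})

test_that("marker channel hits the requested colocalization", {
  for (rho in c(0, 0.5, 0.9)) {
    ph <- make_fish_phantom(spot_rrds = c(0.3, 0.7), coloc_rho = rho, seed = 21)
    r <- pearson_colocalization(ph$fish, ph$marker, ph$nucleus_mask)$pearson_r
    expect_equal(r, rho, tolerance = 0.05)
  }
  ph1 <- make_fish_phantom(spot_rrds = c(0.4), coloc_rho = 1, noise_sd = 0, seed = 3)
  r1 <- pearson_colocalization(ph1$fish, ph1$marker, ph1$nucleus_mask)$pearson_r
  expect_equal(r1, 1, tolerance = 1e-6)
})

test_that("cohorts are deterministic and recover the planted population mean", {
  pop <- population_params(voxel_size_um = 0.6, grid_dim = c(40L, 40L, 40L))
  a <- make_cohort(8, pop, seed = 5)
  b <- make_cohort(8, pop, seed = 5)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth), 8 * 4) # 4 features per cell

  # population scale: planted mean 672.7 um^3 with SEM(200) ~ 22.9
  big <- make_cohort(200, population_params(
    mean_nuclear_volume_um3 = 672.7, sd_nuclear_volume_um3 = 22.9 * sqrt(200),
    voxel_size_um = 0.6, grid_dim = c(40L, 40L, 40L)), seed = 31)
  vols <- big$truth_wide$nuclear_volume
  expect_lt(abs(mean(vols) - 672.7), 3 * 22.9)
})

test_that("viability tables follow the 4PL law with exact noiseless anchors", {
  tab <- make_viability_table(logic50 = 0.3, hill = -1, noise_sd = 0, n_reps = 6)
  expect_equal(nrow(tab), 60) # 10-dose series, 6 replicates each
  at_mid <- fourpl(0.3, 100, 0, 0.3, -1)
  expect_equal(at_mid, 50) # midpoint of the curve at X = LogIC50
  # low-dose limit with negative slope is the top asymptote,
  # high-dose limit the bottom
  expect_equal(fourpl(-12, 100, 0, 0.3, -1), 100, tolerance = 1e-9)
  expect_equal(fourpl(12, 100, 0, 0.3, -1), 0, tolerance = 1e-9)
  expect_error(make_viability_table(doses_um = c(-1, 1, 10, 100)),
               class = "nucmorph_domain_error")
})

test_that("qPCR tables invert the Pfaffl relation", {
  q1 <- make_qpcr_table(fold_change = 1, noise_sd = 0, seed = 1)
  p1 <- pfaffl_from_ct(q1)
  expect_equal(p1$dct_target, p1$dct_ref, tolerance = 1e-12)
  q12 <- make_qpcr_table(fold_change = 12, noise_sd = 0, seed = 1)
  p12 <- pfaffl_from_ct(q12)
  expect_equal(p12$dct_target - p12$dct_ref, log2(12), tolerance = 1e-9)
  a <- make_qpcr_table(fold_change = 5, seed = 9)
  b <- make_qpcr_table(fold_change = 5, seed = 9)
  expect_identical(a, b)
  expect_error(make_qpcr_table(e_target = 1), class = "nucmorph_domain_error")
})
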