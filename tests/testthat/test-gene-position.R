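# Spot detection, relative radial distance and colocalization.

test_that("rrd anchors: 1 at the nuclear centre, 0 at the periphery", {
  ball <- sphere_mask_um(5, 0.35)
  cen <- nucmorph:::mask_centroid_um(ball)
  expect_equal(rrd(cen, ball), 1)
  idx <- which(ball$data > 0, arr.ind = TRUE)
  zc <- round(cen[1] / 0.35) + 1
  yc <- round(cen[2] / 0.35) + 1
  x_out <- max(idx[idx[, 1] == zc & idx[, 2] == yc, 3])
  boundary_spot <- c(cen[1], cen[2], (x_out - 1) * 0.35)
  expect_lte(rrd(boundary_spot, ball), 0.35 / 5) # within one voxel / R
  expect_error(rrd(c(0, 0, 0), ball), class = "nucmorph_domain_error")
})

test_that("rrd is linear in radius on a sphere and monotone along rays", {
  ball <- sphere_mask_um(5, 0.35)
  cen <- nucmorph:::mask_centroid_um(ball)
  sdf <- nucmorph:::signed_distance(ball)
  dir <- c(1, 2, -1) / sqrt(6)
  rr <- vapply(seq(0.5, 4.5, by = 0.5), function(r) {
    rrd(cen + r * dir, ball, sdf)
  }, numeric(1))
  expect_true(all(diff(rr) < 0))
  expect_true(all(abs(rr - (1 - seq(0.5, 4.5, by = 0.5) / 5)) <= 0.05))
})

test_that("rrd is invariant under voxel translation and 90-degree rotation", {
  m <- sphere_mask_um(3.5, 0.35, pad = 8L)
  cen <- nucmorph:::mask_centroid_um(m)
  spot <- cen + c(0.7, -1.4, 1.05)
  r0 <- rrd(spot, m)
  shift <- c(2L, -1L, 3L)
  d <- dim(m$data)
  arr <- array(0L, d)
  arr[(1 + shift[1]):d[1], 1:(d[2] + shift[2]), (1 + shift[3]):d[3]] <-
    m$data[1:(d[1] - shift[1]), (1 - shift[2]):d[2], 1:(d[3] - shift[3])]
  mt <- label_mask(arr, 0.35, "nucleus")
  expect_equal(rrd(spot + shift * 0.35, mt), r0, tolerance = 1e-9)
  rot <- label_mask(rot90_zyx(array(m$data, d)), 0.35, "nucleus")
  # rotate the spot with the mask: (z, y, x) -> (z, x, n3 - 1 - y) in indices
  spot_idx <- spot / 0.35
  spot_rot <- c(spot_idx[1], d[3] - 1 - spot_idx[3], spot_idx[2]) * 0.35
  expect_equal(rrd(spot_rot, rot), r0, tolerance = 1e-9)
})

test_that("planted spots are detected within a voxel, including aneuploid cases", {
  for (rrds in list(c(0.4, 0.8), c(0.25, 0.5, 0.75))) {
    ph <- make_fish_phantom(spot_rrds = rrds, coloc_rho = 0.4, seed = 17)
    sp <- detect_spots(ph$fish, ph$nucleus_mask)
    expect_equal(nrow(sp), length(rrds))
    found <- as.matrix(sp[, c("z_um", "y_um", "x_um")])
    planted <- as.matrix(ph$truth[, c("z_um", "y_um", "x_um")])
    for (i in seq_len(nrow(planted))) {
      dmin <- min(sqrt(rowSums(sweep(found, 2, planted[i, ])^2)))
      expect_lt(dmin, 0.35)
    }
  }
})

test_that("an empty FISH channel yields an empty spot table with a warning", {
  ph <- make_fish_phantom(spot_rrds = numeric(), coloc_rho = 0, seed = 5)
  expect_warning(sp <- detect_spots(ph$fish, ph$nucleus_mask))
  expect_equal(nrow(sp), 0)
})

test_that("measured RRDs recover the requested values end to end", {
  ph <- make_fish_phantom(spot_rrds = c(0.2, 0.6), coloc_rho = 0.5, seed = 23)
  nm <- segment_nucleus_fluorescence(ph$dapi)
  sp <- measure_spot_positions(ph$fish, nm)
  expect_equal(nrow(sp), 2)
  expect_equal(sort(sp$rrd), sort(ph$truth$requested_rrd), tolerance = 0.06)
  expect_true(all(sp$rrd >= 0 & sp$rrd <= 1))
})

test_that("Pearson colocalization honours exact and null anchors", {
  ph <- make_fish_phantom(spot_rrds = c(0.5), coloc_rho = 0.5, seed = 3)
  m <- ph$nucleus_mask
  self <- pearson_colocalization(ph$fish, ph$fish, m)
  expect_equal(self$pearson_r, 1, tolerance = 1e-12)
  neg <- volume3d(-ph$fish$data, ph$fish$voxel_size, "fluorescence")
  expect_equal(pearson_colocalization(ph$fish, neg, m)$pearson_r, -1,
               tolerance = 1e-12)
  set.seed(31)
  d <- dim(m$data)
  n1 <- volume3d(array(rnorm(prod(d)), d), m$voxel_size, "fluorescence")
  n2 <- volume3d(array(rnorm(prod(d)), d), m$voxel_size, "fluorescence")
  expect_gt(sum(m$data > 0), 1e4)
  expect_lt(abs(pearson_colocalization(n1, n2, m)$pearson_r), 0.05)
})

test_that("colocalization is invariant to affine intensity rescaling", {
  ph <- make_fish_phantom(spot_rrds = c(0.3, 0.7), coloc_rho = 0.6, seed = 7)
  m <- ph$nucleus_mask
  r0 <- pearson_colocalization(ph$fish, ph$marker, m)$pearson_r
  scaled <- volume3d(3.7 * ph$marker$data - 11, m$voxel_size, "fluorescence")
  expect_equal(pearson_colocalization(ph$fish, scaled, m)$pearson_r, r0,
               tolerance = 1e-12)
  # agreement with a from-scratch Pearson formula
  fg <- m$data > 0
  expect_equal(r0, oracle_pearson(ph$fish$data[fg], ph$marker$data[fg]),
               tolerance = 1e-12)
  flat <- volume3d(array(2, dim(m$data)), m$voxel_size, "fluorescence")
  expect_error(pearson_colocalization(ph$fish, flat, m),
               class = "nucmorph_value_error")
})
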