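# FISH spot detection, relative radial distance (RRD) and colocalization.
#
# RRD convention: 0 = nuclear periphery, 1 = geometric nuclear centre. For a
# spot s and nucleus centroid c, a ray is cast from c through s; if b is the
# first boundary crossing beyond the spot, RRD = 1 - |s - c| / |b - c|.

# March along a ray from `origin_um` in direction `dir` (unit vector, um),
# sampling the mask's signed distance field at quarter-voxel steps starting
# at t_start, and return the distance (um) of the first boundary crossing,
# located by linear interpolation between the bracketing samples.
ray_boundary_distance <- function(sdf, voxel_size, origin_um, dir, t_start = 0) {
  step <- 0.25 * min(voxel_size)
  d <- dim(sdf)
  t_max <- sqrt(sum(((d - 1) * voxel_size)^2)) + step
  sample_sdf <- function(t) {
    p <- (origin_um + t * dir) / voxel_size
    interp_trilinear(sdf, p)
  }
  t_prev <- max(t_start, 0)
  v_prev <- sample_sdf(t_prev)
  if (v_prev <= 0) return(t_prev)
  t <- t_prev + step
  while (t <= t_max) {
    v <- sample_sdf(t)
    if (v <= 0) {
      return(t_prev + v_prev / (v_prev - v) * (t - t_prev))
    }
    t_prev <- t
    v_prev <- v
    t <- t + step
  }
  abort("ray never left the mask; is the mask degenerate?",
        class = "nucmorph_value_error")
}

#' Relative radial distance of a FISH spot
#'
#' Position of a locus relative to the nuclear periphery: 0 at the periphery,
#' 1 at the geometric nuclear centre. The centre is the centroid of the
#' nucleus mask; the boundary is the first crossing of the mask surface along
#' the ray from the centre through the spot, found by quarter-voxel marching
#' with sub-voxel linear interpolation of the signed distance field. A spot
#' within half a voxel of the centre returns 1 by convention.
#'
#' @param spot_centroid_um spot centroid, micrometres, (z, y, x) order
#'   (0-based voxel index times voxel size).
#' @param nucleus_mask a [label_mask()].
#' @param sdf optional precomputed signed distance field (from repeated calls
#'   on the same nucleus).
#' @return RRD value in `[0, 1]`.
#' @export
rrd <- function(spot_centroid_um, nucleus_mask, sdf = NULL) {
  vs <- nucleus_mask$voxel_size
  fg <- mask_fg(nucleus_mask)
  vox <- pmin(pmax(round(spot_centroid_um / vs), 0), dim(fg) - 1) + 1
  if (!fg[vox[1], vox[2], vox[3]]) {
    abort("spot centroid lies outside the nucleus mask",
          class = "nucmorph_domain_error")
  }
  centre <- mask_centroid_um(nucleus_mask)
  r <- sqrt(sum((spot_centroid_um - centre)^2))
  if (r < 0.5 * min(vs)) return(1)
  dir <- (spot_centroid_um - centre) / r
  if (is.null(sdf)) sdf <- signed_distance(nucleus_mask)
  rb <- ray_boundary_distance(sdf, vs, centre, dir, t_start = r)
  unname(min(max(1 - r / rb, 0), 1))
}

#' Detect FISH spots inside the nucleus
#'
#' Laplacian-of-Gaussian style blob enhancement (Gaussian smoothing at the
#' expected spot scale followed by a negative 3D Laplacian), thresholded at
#' `mean + k_sigma * sd` of the enhanced signal inside the nucleus;
#' 26-connected components above the minimum volume become spots, each
#' reported at its intensity-weighted centroid. Two or more spots per nucleus
#' are expected (allele pairs, or more under aneuploidy); zero spots yield an
#' empty table with a warning.
#'
#' @param fish_volume fluorescence-convention [volume3d()].
#' @param nucleus_mask a [label_mask()].
#' @param min_spot_volume_um3 minimum spot volume (default 0.05 um^3).
#' @param k_sigma threshold stringency (default 4).
#' @param spot_sigma_um blob enhancement scale (default 0.3 um).
#' @return Tibble with one row per spot: `allele`, `z_um`, `y_um`, `x_um`,
#'   `n_voxels`, ordered by decreasing integrated intensity.
#' @export
detect_spots <- function(fish_volume, nucleus_mask, min_spot_volume_um3 = 0.05,
                         k_sigma = 4, spot_sigma_um = 0.3) {
  if (fish_volume$convention != "fluorescence") {
    abort("spot detection expects a fluorescence-convention volume",
          class = "nucmorph_value_error")
  }
  fg <- mask_fg(nucleus_mask)
  vs <- fish_volume$voxel_size
  sm <- gaussian_smooth(fish_volume$data, spot_sigma_um, voxel_size = vs)
  enh <- -laplacian3d(sm, vs)
  vals <- enh[fg]
  thr <- mean(vals) + k_sigma * sd(vals)
  hot <- array(FALSE, dim(fg))
  hot[fg] <- enh[fg] > thr
  lab <- label_components(hot, 26L)
  empty <- tibble::tibble(allele = integer(), z_um = numeric(), y_um = numeric(),
                          x_um = numeric(), n_voxels = integer())
  if (max(lab) == 0L) {
    warn("no FISH spots detected in nucleus")
    return(empty)
  }
  min_vox <- min_spot_volume_um3 / prod(vs)
  raw <- fish_volume$data
  rows <- list()
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_vox) next
    w <- raw[idx]
    w <- pmax(w - min(w), 0) + 1e-12
    cen <- unname(colSums(sweep(idx - 1, 1, w, `*`)) / sum(w) * vs)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      z_um = cen[1], y_um = cen[2], x_um = cen[3],
      n_voxels = nrow(idx), intensity = sum(raw[idx]))
  }
  if (length(rows) == 0L) {
    warn("no FISH spots above the minimum volume")
    return(empty)
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$intensity)) |>
    dplyr::mutate(allele = dplyr::row_number()) |>
    dplyr::select(dplyr::all_of(c("allele", "z_um", "y_um", "x_um", "n_voxels")))
}

# discrete 3D Laplacian with physical spacings (6-neighbour stencil,
# replicated borders)
laplacian3d <- function(arr, voxel_size) {
  d <- dim(arr)
  out <- array(0, d)
  shift <- function(a, ax, by) {
    n <- d[ax]
    ix <- pmin(pmax(seq_len(n) + by, 1L), n)
    if (ax == 1) a[ix, , , drop = FALSE]
    else if (ax == 2) a[, ix, , drop = FALSE]
    else a[, , ix, drop = FALSE]
  }
  for (ax in 1:3) {
    out <- out + (shift(arr, ax, 1L) + shift(arr, ax, -1L) - 2 * arr) / voxel_size[ax]^2
  }
  out
}

#' Pearson colocalization of two channels inside the nucleus
#'
#' Sample Pearson correlation of the voxel intensities of two aligned
#' channels over all voxels of the nucleus mask — no intensity thresholding
#' and no Costes correction, matching the plain pixel-intensity definition.
#' The result is invariant to any affine intensity rescaling of either
#' channel.
#'
#' @param fish_volume,marker_volume aligned [volume3d()]s of identical shape
#'   (e.g. the FISH channel and an H3K9ac euchromatin stain).
#' @param nucleus_mask a [label_mask()]; needs >= 10 voxels.
#' @param cell_id optional identifier copied into the result.
#' @return One-row tibble: `cell_id`, `pearson_r`, `n_voxels`.
#' @export
pearson_colocalization <- function(fish_volume, marker_volume, nucleus_mask,
                                   cell_id = "cell") {
  fa <- as_volume_array(fish_volume)
  fb <- as_volume_array(marker_volume)
  if (!all(dim(fa) == dim(fb)) || !all(dim(fa) == dim(mask_fg(nucleus_mask)))) {
    abort("channel / mask shapes differ", class = "nucmorph_shape_error")
  }
  fg <- mask_fg(nucleus_mask)
  if (sum(fg) < 10L) {
    abort("nucleus mask has fewer than 10 voxels", class = "nucmorph_value_error")
  }
  a <- fa[fg]
  b <- fb[fg]
  if (sd(a) == 0 || sd(b) == 0) {
    abort("constant channel inside the nucleus; correlation undefined",
          class = "nucmorph_value_error")
  }
  tibble::tibble(cell_id = as.character(cell_id),
                 pearson_r = stats::cor(a, b),
                 n_voxels = sum(fg))
}

#' Measure RRD for every detected spot in a FISH stack
#'
#' Convenience wrapper: detect spots, compute each allele's RRD against the
#' nucleus, and return one row per allele.
#'
#' @inheritParams detect_spots
#' @param cell_id identifier copied into the result.
#' @return Tibble: `cell_id`, `allele`, `z_um`, `y_um`, `x_um`, `rrd`.
#' @export
measure_spot_positions <- function(fish_volume, nucleus_mask, cell_id = "cell",
                                   min_spot_volume_um3 = 0.05, k_sigma = 4,
                                   spot_sigma_um = 0.3) {
  spots <- detect_spots(fish_volume, nucleus_mask, min_spot_volume_um3,
                        k_sigma, spot_sigma_um)
  if (nrow(spots) == 0L) {
    return(tibble::tibble(cell_id = character(), allele = integer(),
                          z_um = numeric(), y_um = numeric(), x_um = numeric(),
                          rrd = numeric()))
  }
  sdf <- signed_distance(nucleus_mask)
  spots |>
    dplyr::mutate(
      cell_id = as.character(cell_id),
      rrd = purrr::pmap_dbl(list(.data$z_um, .data$y_um, .data$x_um),
                            function(z, y, x) rrd(c(z, y, x), nucleus_mask, sdf))
    ) |>
    dplyr::select(dplyr::all_of(c("cell_id", "allele", "z_um", "y_um", "x_um", "rrd")))
}
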