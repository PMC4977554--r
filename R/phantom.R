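# Synthetic single-cell phantoms with planted ground truth. Every truth
# value is computed from the generated voxel masks themselves (not from the
# analytic shape description), so the truth shares its discretisation with
# the pipeline under test.

#' Specification of a single-cell absorption phantom
#'
#' Describes one synthetic cell: an ellipsoidal cytoplasm containing an
#' ellipsoidal nucleus, optional dense intra-nuclear clumps (spheres of
#' elevated absorption) and optional surface invaginations (spherical bites
#' out of the nuclear surface producing measurable concavity). Intensities
#' follow the absorption convention: nucleus > cytoplasm > background.
#'
#' @param cell_semiaxes_um cell semi-axes (z, y, x), micrometres.
#' @param nucleus_semiaxes_um nucleus semi-axes (z, y, x), micrometres.
#' @param nucleus_offset_um nucleus centre offset from the cell centre.
#' @param n_clumps number of dense clumps (>= 0).
#' @param clump_radius_um clump radius.
#' @param clump_min_sep_um minimum clump centre-to-centre distance;
#'   defaults to two clump diameters, the separation at which threshold
#'   detection recovers the planted count exactly.
#' @param clump_contrast clump intensity as a multiplier (> 1) on the nuclear
#'   base intensity, applied before noise. The default 1.8 sits well above
#'   the default mean + 2 sd detection threshold.
#' @param n_invaginations number of spherical surface bites (>= 0).
#' @param invagination_radius_um radius of each bite.
#' @param intensities base intensities `c(background, cytoplasm, nucleus)`.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param voxel_size_um voxel size (scalar or (dz, dy, dx)), micrometres.
#' @param grid_dim grid size (Z, Y, X); `NULL` fits the cell plus a margin.
#' @param seed RNG seed for clump/invagination placement and noise.
#' @return A list of class `cell_phantom_spec`.
#' @export
cell_phantom_spec <- function(cell_semiaxes_um = c(7, 7, 7),
                              nucleus_semiaxes_um = c(5, 5, 5),
                              nucleus_offset_um = c(0, 0, 0),
                              n_clumps = 0L,
                              clump_radius_um = 0.75,
                              clump_min_sep_um = NULL,
                              clump_contrast = 1.8,
                              n_invaginations = 0L,
                              invagination_radius_um = 1.5,
                              intensities = c(background = 0.05,
                                              cytoplasm = 0.35,
                                              nucleus = 0.7),
                              noise_sd = 0.02,
                              voxel_size_um = 0.35,
                              grid_dim = NULL,
                              seed = 1L) {
  vs <- check_voxel_size(voxel_size_um)
  cell_semiaxes_um <- rep_len(cell_semiaxes_um, 3L)
  nucleus_semiaxes_um <- rep_len(nucleus_semiaxes_um, 3L)
  if (any(nucleus_semiaxes_um + abs(nucleus_offset_um) > cell_semiaxes_um)) {
    abort("nucleus (after offset) does not fit inside the cell",
          class = "nucmorph_value_error")
  }
  if (clump_contrast <= 1) {
    abort("clump_contrast must exceed 1", class = "nucmorph_value_error")
  }
  if (n_clumps > 0 && clump_radius_um >= min(nucleus_semiaxes_um) / 2) {
    abort("clumps too large for the nucleus", class = "nucmorph_value_error")
  }
  if (is.null(clump_min_sep_um)) clump_min_sep_um <- 4 * clump_radius_um
  if (clump_min_sep_um <= 2 * clump_radius_um) {
    abort("clump_min_sep_um must exceed one clump diameter (no merging)",
          class = "nucmorph_value_error")
  }
  structure(list(
    cell_semiaxes_um = cell_semiaxes_um,
    nucleus_semiaxes_um = nucleus_semiaxes_um,
    nucleus_offset_um = rep_len(nucleus_offset_um, 3L),
    n_clumps = as.integer(n_clumps),
    clump_radius_um = clump_radius_um,
    clump_min_sep_um = clump_min_sep_um,
    clump_contrast = clump_contrast,
    n_invaginations = as.integer(n_invaginations),
    invagination_radius_um = invagination_radius_um,
    intensities = intensities,
    noise_sd = noise_sd,
    voxel_size_um = vs,
    grid_dim = grid_dim,
    seed = as.integer(seed)
  ), class = "cell_phantom_spec")
}

# squared normalised ellipsoid radius field on the voxel grid (um coords)
ellipsoid_field <- function(dims, centre_um, semiaxes_um, voxel_size) {
  z <- ((seq_len(dims[1]) - 1) * voxel_size[1] - centre_um[1]) / semiaxes_um[1]
  y <- ((seq_len(dims[2]) - 1) * voxel_size[2] - centre_um[2]) / semiaxes_um[2]
  x <- ((seq_len(dims[3]) - 1) * voxel_size[3] - centre_um[3]) / semiaxes_um[3]
  outer(outer(z^2, y^2, `+`), x^2, `+`)
}

# ball mask on the voxel grid (evaluated only over the ball's bounding box)
ball_mask <- function(dims, centre_um, radius_um, voxel_size) {
  out <- array(FALSE, dims)
  lo <- pmax(floor((centre_um - radius_um) / voxel_size) + 1L, 1L)
  hi <- pmin(ceiling((centre_um + radius_um) / voxel_size) + 1L, dims)
  if (any(lo > hi)) return(out)
  rng <- lapply(1:3, function(ax) lo[ax]:hi[ax])
  z <- ((rng[[1]] - 1) * voxel_size[1] - centre_um[1])^2
  y <- ((rng[[2]] - 1) * voxel_size[2] - centre_um[2])^2
  x <- ((rng[[3]] - 1) * voxel_size[3] - centre_um[3])^2
  out[rng[[1]], rng[[2]], rng[[3]]] <-
    outer(outer(z, y, `+`), x, `+`) <= radius_um^2
  out
}

# uniform random unit vector
runit3 <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Generate a single-cell absorption phantom
#'
#' Renders the phantom described by a [cell_phantom_spec()] and returns the
#' noisy absorption volume, the true cell / nucleus / clump masks and a
#' ground-truth record computed from those masks (voxel count times voxel
#' volume for volumes; [concavity_index()] of the true nucleus mask for
#' concavity; connected-component count of the clump mask for clumps).
#'
#' Invaginated voxels are removed from the nucleus mask and rendered at
#' cytoplasm intensity. Clump centres are drawn uniformly inside the nucleus
#' with pairwise centre distance >= `clump_min_sep_um` (default two clump
#' diameters) and at least one radius clear of the nuclear border; placement
#' failing after bounded retries raises a placement error.
#'
#' @param spec a [cell_phantom_spec()].
#' @return List with `volume` ([volume3d()]), `cell_mask`, `nucleus_mask`,
#'   `clump_mask` ([label_mask()]s) and `truth` (one-row tibble).
#' @export
make_cell_phantom <- function(spec) {
  stopifnot(inherits(spec, "cell_phantom_spec"))
  set.seed(spec$seed)
  vs <- spec$voxel_size_um
  dims <- spec$grid_dim
  if (is.null(dims)) {
    dims <- ceiling(2 * spec$cell_semiaxes_um / vs) + 6L
  }
  dims <- pmax(as.integer(dims), 8L)
  centre <- (dims - 1) / 2 * vs
  n_centre <- centre + spec$nucleus_offset_um

  cell_fg <- ellipsoid_field(dims, centre, spec$cell_semiaxes_um, vs) <= 1
  nuc_fg <- ellipsoid_field(dims, n_centre, spec$nucleus_semiaxes_um, vs) <= 1

  # surface invaginations: balls centred on random points of the nuclear
  # surface, subtracted from the nucleus
  if (spec$n_invaginations > 0) {
    for (k in seq_len(spec$n_invaginations)) {
      u <- runit3()
      # point on the ellipsoid surface along direction u
      tt <- 1 / sqrt(sum((u / spec$nucleus_semiaxes_um)^2))
      surf <- n_centre + u * tt
      bite <- ball_mask(dims, surf, spec$invagination_radius_um, vs)
      nuc_fg <- nuc_fg & !bite
    }
  }

  # clump placement
  clump_lab <- array(0L, dims)
  clump_centres <- matrix(numeric(0), ncol = 3)
  if (spec$n_clumps > 0) {
    r <- spec$clump_radius_um
    placed <- 0L
    tries <- 0L
    max_tries <- 400L * spec$n_clumps
    inner <- spec$nucleus_semiaxes_um - r - max(vs)
    if (any(inner <= 0)) {
      abort("nucleus too small for requested clumps",
            class = "nucmorph_placement_error")
    }
    while (placed < spec$n_clumps) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort(sprintf("could not place %d clumps after %d tries",
                      spec$n_clumps, max_tries),
              class = "nucmorph_placement_error")
      }
      cand <- n_centre + runif(3, -1, 1) * inner
      if (sum(((cand - n_centre) / inner)^2) > 1) next
      if (nrow(clump_centres) > 0) {
        dmin <- min(sqrt(rowSums(sweep(clump_centres, 2, cand)^2)))
        if (dmin < spec$clump_min_sep_um) next
      }
      placed <- placed + 1L
      clump_centres <- rbind(clump_centres, cand)
      clump_lab[ball_mask(dims, cand, r, vs) & nuc_fg] <- placed
    }
  }

  ints <- spec$intensities
  vol <- array(ints[[1]], dims)
  vol[cell_fg] <- ints[[2]]
  vol[nuc_fg] <- ints[[3]]
  vol[clump_lab > 0L] <- spec$clump_contrast * ints[[3]]
  if (spec$noise_sd > 0) {
    vol <- vol + array(rnorm(prod(dims), 0, spec$noise_sd), dims)
  }

  volume <- volume3d(vol, vs, "absorption")
  cell_mask <- label_mask(cell_fg, vs, "cell")
  nucleus_mask <- label_mask(nuc_fg, vs, "nucleus")
  clump_mask <- label_mask(clump_lab, vs, "clump")

  vvol <- prod(vs)
  truth <- tibble::tibble(
    nuclear_volume = sum(nuc_fg) * vvol,
    cell_volume = sum(cell_fg) * vvol,
    nc_ratio = sum(nuc_fg) / (sum(cell_fg) - sum(nuc_fg)),
    concavity_pct = concavity_index(nucleus_mask),
    clump_count = max(clump_lab)
  )

  list(volume = volume, cell_mask = cell_mask, nucleus_mask = nucleus_mask,
       clump_mask = clump_mask, truth = truth, spec = spec)
}

#' Generate a multi-channel FISH phantom
#'
#' Builds a DAPI / FISH / euchromatin-marker (H3K9ac-like) channel triplet
#' over a spherical-to-ellipsoidal nucleus. Each requested spot is placed on
#' a random ray from the nucleus centroid at the fractional radial position
#' realising the requested RRD under the package's ray definition; the
#' marker channel is a mixture `rho * FISH + sqrt(1 - rho^2) * noise` of the
#' (standardised) FISH channel and an independent Gaussian field inside the
#' nucleus, so its whole-nucleus Pearson correlation with the FISH channel
#' targets `coloc_rho`.
#'
#' @param nucleus_semiaxes_um nucleus semi-axes, micrometres.
#' @param spot_rrds requested RRD per spot, each in `[0, 1]`; may be empty.
#' @param coloc_rho target FISH / marker Pearson correlation in `[-1, 1]`.
#' @param spot_sigma_um Gaussian spot width.
#' @param noise_sd additive channel noise (independent per channel).
#' @param voxel_size_um voxel size; use `c(0.25, dxy, dxy)` to mimic a
#'   confocal z-step of 0.25 um.
#' @param grid_dim optional grid size (Z, Y, X).
#' @param seed RNG seed.
#' @return List with `dapi`, `fish`, `marker` ([volume3d()]s),
#'   `nucleus_mask`, and `truth` (tibble of per-spot requested RRD, placed
#'   position and `coloc_rho`).
#' @export
make_fish_phantom <- function(nucleus_semiaxes_um = c(5, 5, 5),
                              spot_rrds = numeric(),
                              coloc_rho = 0.5,
                              spot_sigma_um = 0.3,
                              noise_sd = 0.01,
                              voxel_size_um = 0.35,
                              grid_dim = NULL,
                              seed = 1L) {
  if (length(spot_rrds) > 0 && (any(spot_rrds < 0) || any(spot_rrds > 1))) {
    abort("spot RRDs must lie in [0, 1]", class = "nucmorph_value_error")
  }
  if (abs(coloc_rho) > 1) {
    abort("coloc_rho must lie in [-1, 1]", class = "nucmorph_value_error")
  }
  set.seed(seed)
  vs <- check_voxel_size(voxel_size_um)
  nucleus_semiaxes_um <- rep_len(nucleus_semiaxes_um, 3L)
  dims <- grid_dim
  if (is.null(dims)) dims <- ceiling(2 * nucleus_semiaxes_um / vs) + 8L
  dims <- pmax(as.integer(dims), 8L)
  centre <- (dims - 1) / 2 * vs
  nuc_fg <- ellipsoid_field(dims, centre, nucleus_semiaxes_um, vs) <= 1
  nucleus_mask <- label_mask(nuc_fg, vs, "nucleus")

  # DAPI: bright nucleus on dark background
  dapi <- array(0.05, dims)
  dapi[nuc_fg] <- 1
  dapi <- gaussian_smooth(dapi, 0.2, voxel_size = vs)

  # spot placement at requested RRDs along random rays from the centroid
  cen <- mask_centroid_um(nucleus_mask)
  sdf <- signed_distance(nucleus_mask)
  fish <- array(0, dims)
  spots <- list()
  coords_um <- lapply(1:3, function(ax) (seq_len(dims[ax]) - 1) * vs[ax])
  for (i in seq_along(spot_rrds)) {
    u <- runit3()
    rb <- ray_boundary_distance(sdf, vs, cen, u, t_start = 0)
    pos <- unname(cen + (1 - spot_rrds[i]) * rb * u)
    dz2 <- (coords_um[[1]] - pos[1])^2
    dy2 <- (coords_um[[2]] - pos[2])^2
    dx2 <- (coords_um[[3]] - pos[3])^2
    blob <- exp(-outer(outer(dz2, dy2, `+`), dx2, `+`) / (2 * spot_sigma_um^2))
    fish <- fish + blob
    spots[[i]] <- tibble::tibble(
      spot = i, requested_rrd = spot_rrds[i],
      z_um = pos[1], y_um = pos[2], x_um = pos[3])
  }

  add_noise <- function(a) {
    if (noise_sd > 0) a + array(rnorm(prod(dims), 0, noise_sd), dims) else a
  }
  dapi <- add_noise(dapi)
  fish <- add_noise(fish)

  # marker channel with controlled in-nucleus Pearson correlation, mixed
  # from the noisy FISH channel so the realised correlation is not diluted
  n_in <- sum(nuc_fg)
  f_in <- fish[nuc_fg]
  marker <- array(0, dims)
  if (stats::sd(f_in) == 0) {
    marker[nuc_fg] <- rnorm(n_in)
  } else if (abs(coloc_rho) == 1 && noise_sd == 0) {
    marker[nuc_fg] <- sign(coloc_rho) * f_in
  } else {
    f_std <- (f_in - mean(f_in)) / stats::sd(f_in)
    g <- rnorm(n_in)
    g_std <- (g - mean(g)) / stats::sd(g)
    # remove the empirical correlation between g and f so the mixture hits rho
    g_std <- g_std - stats::cor(g_std, f_std) * f_std
    g_std <- g_std / stats::sd(g_std)
    marker[nuc_fg] <- coloc_rho * f_std + sqrt(1 - coloc_rho^2) * g_std
  }
  truth <- if (length(spots) > 0) dplyr::bind_rows(spots) else
    tibble::tibble(spot = integer(), requested_rrd = numeric(),
                   z_um = numeric(), y_um = numeric(), x_um = numeric())
  truth$coloc_rho <- if (nrow(truth) > 0) coloc_rho else numeric(0)

  list(
    dapi = volume3d(dapi, vs, "fluorescence"),
    fish = volume3d(fish, vs, "fluorescence"),
    marker = volume3d(marker, vs, "fluorescence"),
    nucleus_mask = nucleus_mask,
    truth = truth,
    coloc_rho = coloc_rho
  )
}
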