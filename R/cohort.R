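#' Population parameters for a phantom cohort
#'
#' Describes one experimental condition as a population of single-cell
#' phantoms: nuclear volumes are drawn from a Gaussian (truncated at +/- 2
#' sd so extreme draws still fit the imaging grid), the cell size follows
#' from the target NC ratio, clump counts are Poisson, and a fixed number of
#' surface invaginations of proportional size sets the concavity level.
#'
#' @param mean_nuclear_volume_um3 population mean nuclear volume.
#' @param sd_nuclear_volume_um3 population SD of nuclear volume.
#' @param nc_target population mean NC ratio (nucleus / cytoplasm-only
#'   volume).
#' @param nc_sd population SD of the per-cell NC ratio (truncated at +/- 2
#'   sd and bounded away from 0).
#' @param clump_mean mean clump count (Poisson).
#' @param n_invaginations invaginations per nucleus.
#' @param invagination_radius_frac bite radius as a fraction of the mean
#'   nuclear radius.
#' @param shape_jitter relative jitter of the nuclear semi-axes (volume
#'   preserving), giving mild ellipticity.
#' @param clump_radius_um,clump_contrast,noise_sd,voxel_size_um,grid_dim as
#'   in [cell_phantom_spec()].
#' @return A list of class `population_params`.
#' @export
population_params <- function(mean_nuclear_volume_um3 = 672.7,
                              sd_nuclear_volume_um3 = 323.9,
                              nc_target = 0.65,
                              nc_sd = 0.1,
                              clump_mean = 6.1,
                              n_invaginations = 1L,
                              invagination_radius_frac = 0.3,
                              shape_jitter = 0.08,
                              clump_radius_um = 0.75,
                              clump_contrast = 1.8,
                              noise_sd = 0.02,
                              voxel_size_um = 0.35,
                              grid_dim = c(64L, 64L, 64L)) {
  if (mean_nuclear_volume_um3 <= 0 || sd_nuclear_volume_um3 < 0 ||
      nc_target <= 0 || nc_sd < 0) {
    abort("population parameters out of range", class = "nucmorph_value_error")
  }
  structure(as.list(environment()), class = "population_params")
}

# draw one cell_phantom_spec from a population (uses the current RNG stream)
draw_phantom_spec <- function(pop, seed) {
  repeat {
    v <- rnorm(1, pop$mean_nuclear_volume_um3, pop$sd_nuclear_volume_um3)
    if (abs(v - pop$mean_nuclear_volume_um3) <= 2 * pop$sd_nuclear_volume_um3 &&
        v > 0.05 * pop$mean_nuclear_volume_um3) break
  }
  r_nuc <- (3 * v / (4 * pi))^(1 / 3)
  # volume-preserving semi-axis jitter
  f <- exp(rnorm(3, 0, pop$shape_jitter))
  f <- f / prod(f)^(1 / 3)
  nuc_ax <- r_nuc * f
  nc_i <- pop$nc_target
  if (pop$nc_sd > 0) {
    repeat {
      nc_i <- rnorm(1, pop$nc_target, pop$nc_sd)
      if (abs(nc_i - pop$nc_target) <= 2 * pop$nc_sd && nc_i > 0.05) break
    }
  }
  scale_cell <- ((1 + nc_i) / nc_i)^(1 / 3)
  cell_ax <- nuc_ax * scale_cell
  # keep the cell inside the grid with a 2-voxel margin
  vs <- check_voxel_size(pop$voxel_size_um)
  max_ax <- (pop$grid_dim - 5) / 2 * vs
  shrink <- min(1, min(max_ax / cell_ax))
  cell_ax <- cell_ax * shrink
  nuc_ax <- nuc_ax * shrink
  # clump count: Poisson, capped by what can be packed into this nucleus at
  # 1.5-diameter spacing (small nuclei carry fewer resolvable clumps)
  sep <- 3 * pop$clump_radius_um
  inner_ax <- pmax(nuc_ax - pop$clump_radius_um - max(vs), 0)
  v_inner <- 4 / 3 * pi * prod(inner_ax)
  n_cap <- floor(0.3 * v_inner / (4 / 3 * pi * (sep / 2)^3))
  n_clumps <- min(rpois(1, pop$clump_mean), n_cap)
  cell_phantom_spec(
    cell_semiaxes_um = cell_ax,
    nucleus_semiaxes_um = nuc_ax,
    n_clumps = n_clumps,
    clump_radius_um = pop$clump_radius_um,
    clump_min_sep_um = sep,
    clump_contrast = pop$clump_contrast,
    n_invaginations = pop$n_invaginations,
    invagination_radius_um = pop$invagination_radius_frac * r_nuc * shrink,
    noise_sd = pop$noise_sd,
    voxel_size_um = vs,
    grid_dim = pop$grid_dim,
    seed = seed
  )
}

#' Generate a phantom cohort for one condition
#'
#' Draws `n_cells` phantoms from a [population_params()] description,
#' computes each cell's mask-derived ground truth, and returns the truth as
#' a long-format feature table. Generation is fully deterministic under
#' `seed`. Volumes are either kept in memory (`keep_phantoms = TRUE`, for
#' small cohorts), written to `out_dir` as TIFF stacks, or streamed through
#' a `per_cell` callback (used by [run_study()] so big cohorts never occupy
#' memory all at once).
#'
#' @param n_cells number of cells (>= 1).
#' @param pop a [population_params()].
#' @param condition condition label stamped on the truth table.
#' @param seed RNG seed.
#' @param out_dir if non-`NULL`, write `<cell_id>_volume.tif` stacks here.
#' @param keep_phantoms keep full phantom objects in the returned list.
#' @param per_cell optional `function(phantom, cell_id)` called on each cell.
#' @return List with `truth` (feature table tibble, plus a wide `truth_wide`
#'   tibble) and, when requested, `phantoms`.
#' @export
make_cohort <- function(n_cells, pop = population_params(), condition = "cohort",
                        seed = 1L, out_dir = NULL, keep_phantoms = FALSE,
                        per_cell = NULL) {
  if (n_cells < 1) abort("n_cells must be >= 1", class = "nucmorph_value_error")
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max, n_cells)
  specs <- vector("list", n_cells)
  for (i in seq_len(n_cells)) specs[[i]] <- draw_phantom_spec(pop, cell_seeds[i])

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  truths <- vector("list", n_cells)
  phantoms <- if (keep_phantoms) vector("list", n_cells) else NULL
  for (i in seq_len(n_cells)) {
    cell_id <- sprintf("cell%04d", i)
    ph <- make_cell_phantom(specs[[i]])
    truths[[i]] <- dplyr::mutate(ph$truth, cell_id = cell_id, .before = 1)
    if (!is.null(out_dir)) {
      write_stack(ph$volume, file.path(out_dir, paste0(cell_id, "_volume.tif")))
    }
    if (!is.null(per_cell)) per_cell(ph, cell_id)
    if (keep_phantoms) phantoms[[i]] <- ph
  }
  truth_wide <- dplyr::bind_rows(truths)
  truth_long <- truth_wide |>
    dplyr::select(dplyr::all_of(c("cell_id", "nuclear_volume", "nc_ratio",
                                  "concavity_pct", "clump_count"))) |>
    records_to_feature_table(condition)
  out <- list(truth = truth_long, truth_wide = truth_wide, condition = condition,
              seed = seed, specs = specs)
  if (keep_phantoms) out$phantoms <- phantoms
  if (!is.null(out_dir)) {
    write_feature_table(truth_long, file.path(out_dir, "ground_truth.csv"))
    out$dir <- out_dir
  }
  out
}
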