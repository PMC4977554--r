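#' Nuclear volume in cubic micrometres
#'
#' Foreground voxel count times voxel volume.
#'
#' @param nucleus_mask a [label_mask()] of the nucleus.
#' @return Volume in um^3.
#' @export
nuclear_volume <- function(nucleus_mask) {
  n <- sum(mask_fg(nucleus_mask))
  if (n == 0L) abort("empty nucleus mask", class = "nucmorph_empty_error")
  n * voxel_volume(nucleus_mask)
}

#' Nuclear-to-cytoplasmic (NC) ratio
#'
#' The classical karyoplasmic ratio `V_nucleus / (V_cell - V_nucleus)`:
#' nuclear volume over cytoplasm-only volume.
#'
#' @param nucleus_mask,cell_mask [label_mask()] objects; the nucleus must be
#'   contained in the cell and the cell strictly larger.
#' @return Dimensionless ratio.
#' @export
nc_ratio <- function(nucleus_mask, cell_mask) {
  fn <- mask_fg(nucleus_mask)
  fc <- mask_fg(cell_mask)
  if (!all(dim(fn) == dim(fc))) {
    abort("mask shapes differ", class = "nucmorph_shape_error")
  }
  if (any(fn & !fc)) {
    abort("nucleus mask is not contained in the cell mask",
          class = "nucmorph_value_error")
  }
  vn <- sum(fn)
  vc <- sum(fc)
  if (vn == 0L || vc == 0L) abort("empty mask", class = "nucmorph_empty_error")
  if (vc <= vn) {
    abort("cell volume must exceed nuclear volume (no cytoplasm)",
          class = "nucmorph_value_error")
  }
  vn / (vc - vn)
}

#' Nuclear shape concavity index (percent)
#'
#' Hull volume deficit: `100 * (V_hull - V_mask) / V_hull`, with the hull
#' computed as the voxelised 3D convex hull of the mask
#' ([convex_hull_mask()]). Convex bodies score ~0; surface invaginations
#' increase the index monotonically.
#'
#' @param nucleus_mask a [label_mask()].
#' @return Concavity in percent, in `[0, 100)`.
#' @export
concavity_index <- function(nucleus_mask) {
  fg <- mask_fg(nucleus_mask)
  if (sum(fg) == 0L) abort("empty nucleus mask", class = "nucmorph_empty_error")
  hull <- convex_hull_mask(nucleus_mask)
  v_hull <- sum(mask_fg(hull))
  v_mask <- sum(fg)
  100 * (v_hull - v_mask) / v_hull
}

#' Count dense intra-nuclear clumps
#'
#' Chromatin-texture proxy: voxels inside the nucleus whose intensity exceeds
#' a per-nucleus adaptive threshold `mean + k_sigma * sd` are grouped into
#' 26-connected components; components smaller than `min_clump_volume_um3`
#' are discarded and the survivors counted. The threshold adapts to each
#' nucleus so per-cell staining intensity differences do not bias the count.
#'
#' @param volume absorption-convention [volume3d()].
#' @param nucleus_mask [label_mask()] of the nucleus.
#' @param k_sigma threshold stringency in nuclear-intensity SDs (default 2).
#' @param min_clump_volume_um3 minimum clump volume in um^3 (default 0.5).
#' @return Integer clump count (0 when nothing passes the threshold).
#' @export
count_dense_clumps <- function(volume, nucleus_mask, k_sigma = 2,
                               min_clump_volume_um3 = 0.5) {
  if (volume$convention != "absorption") {
    abort("clump counting expects an absorption-convention volume",
          class = "nucmorph_value_error")
  }
  fg <- mask_fg(nucleus_mask)
  if (sum(fg) == 0L) abort("empty nucleus mask", class = "nucmorph_empty_error")
  vals <- volume$data[fg]
  thr <- mean(vals) + k_sigma * sd(vals)
  hot <- array(FALSE, dim(fg))
  hot[fg] <- volume$data[fg] > thr
  lab <- label_components(hot, 26L)
  if (max(lab) == 0L) return(0L)
  sizes <- tabulate(lab[lab > 0L])
  min_vox <- min_clump_volume_um3 / voxel_volume(nucleus_mask)
  sum(sizes >= min_vox)
}

#' Per-cell morphometry record
#'
#' Computes the four morphometric descriptors for one segmented cell and
#' returns them as a one-row tibble.
#'
#' @param volume absorption [volume3d()].
#' @param cell_mask,nucleus_mask segmentation masks.
#' @param cell_id identifier copied into the record.
#' @param k_sigma,min_clump_volume_um3 passed to [count_dense_clumps()].
#' @return Tibble with columns `cell_id`, `nuclear_volume`, `nc_ratio`,
#'   `concavity_pct`, `clump_count`.
#' @export
morphometry_record <- function(volume, cell_mask, nucleus_mask, cell_id = "cell",
                               k_sigma = 2, min_clump_volume_um3 = 0.5) {
  tibble::tibble(
    cell_id = as.character(cell_id),
    nuclear_volume = nuclear_volume(nucleus_mask),
    nc_ratio = nc_ratio(nucleus_mask, cell_mask),
    concavity_pct = concavity_index(nucleus_mask),
    clump_count = count_dense_clumps(volume, nucleus_mask, k_sigma,
                                     min_clump_volume_um3)
  )
}

# long-format feature table from one or more morphometry records
records_to_feature_table <- function(records, condition) {
  records |>
    dplyr::mutate(condition = condition) |>
    tidyr::pivot_longer(c("nuclear_volume", "nc_ratio", "concavity_pct", "clump_count"),
                        names_to = "feature", values_to = "value") |>
    dplyr::mutate(unit = dplyr::case_when(
      feature == "nuclear_volume" ~ "um3",
      feature == "concavity_pct" ~ "percent",
      TRUE ~ ""
    )) |>
    dplyr::select(dplyr::all_of(feature_table_cols)) |>
    feature_table()
}

#' Run morphometry over a cohort directory
#'
#' Processes every volume TIFF in a directory (as written by
#' [write_cohort()]): segments cell and nucleus, computes the four
#' descriptors, and assembles a long-format feature table. Per-cell failures
#' are collected and reported, never silently dropped.
#'
#' @param cohort_dir directory containing `*_volume.tif` stacks (sidecar
#'   metadata as written by [write_stack()]).
#' @param condition condition label stamped on every record.
#' @param params a [segmentation_params()] list.
#' @param k_sigma,min_clump_volume_um3 clump detection settings.
#' @return A list with `features` (feature table tibble) and `errors`
#'   (tibble of cell_id, stage, message for any failures).
#' @export
run_morphometry <- function(cohort_dir, condition = "cohort",
                            params = segmentation_params(),
                            k_sigma = 2, min_clump_volume_um3 = 0.5) {
  paths <- sort(list.files(cohort_dir, pattern = "_volume\\.tif$", full.names = TRUE))
  if (length(paths) == 0L) {
    abort(paste0("no *_volume.tif stacks in ", cohort_dir),
          class = "nucmorph_io_error")
  }
  records <- list()
  errors <- list()
  for (p in paths) {
    cell_id <- sub("_volume\\.tif$", "", basename(p))
    res <- tryCatch({
      vol <- read_stack(p)
      seg <- segment_cell_nucleus(vol, params)
      morphometry_record(vol, seg$cell, seg$nucleus, cell_id, k_sigma,
                         min_clump_volume_um3)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- tibble::tibble(
        cell_id = cell_id, stage = "morphometry",
        message = conditionMessage(res))
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  features <- if (length(records) > 0) {
    records_to_feature_table(dplyr::bind_rows(records), condition)
  } else {
    feature_table(tibble::tibble(cell_id = character(), condition = character(),
                                 feature = character(), value = numeric(),
                                 unit = character()))
  }
  list(
    features = features,
    errors = if (length(errors) > 0) dplyr::bind_rows(errors) else
      tibble::tibble(cell_id = character(), stage = character(), message = character())
  )
}
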