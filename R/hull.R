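# Voxelised 3D convex hulls. The hull is computed exactly (quickhull on the
# surface voxels of the mask, in physical micrometre coordinates) and then
# rasterised back onto the voxel grid, so hull volumes share the mask's
# discretisation and no surface mesh ever enters a volume estimate.

# facet representation (outward normals + offsets) of the convex hull of a
# mask's foreground voxel centres
hull_facets <- function(mask) {
  fg <- mask_fg(mask)
  if (sum(fg) < 4L) {
    abort("mask has fewer than 4 foreground voxels; no 3D hull",
          class = "nucmorph_hull_error")
  }
  surf <- surface_voxels(fg)
  idx <- which(surf, arr.ind = TRUE) - 1 # 0-based (z, y, x)
  pts <- sweep(idx, 2, mask$voxel_size, `*`)
  tryCatch(
    .quickhull3d(pts),
    error = function(e) abort(paste0("convex hull failed: ", conditionMessage(e)),
                              class = "nucmorph_hull_error")
  )
}

#' Voxelised convex hull of a mask
#'
#' Rasterises the convex hull of the foreground voxel centres back onto the
#' voxel grid: a voxel belongs to the hull when its centre satisfies every
#' facet inequality (with a small tolerance so hull vertices themselves are
#' kept).
#'
#' @param mask a [label_mask()].
#' @return A `label_mask` of the filled hull (same voxel size, role kept).
#' @export
convex_hull_mask <- function(mask) {
  fg <- mask_fg(mask)
  facets <- hull_facets(mask)
  idx <- which(fg, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  gz <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gx <- lo[3]:hi[3]
  grid <- as.matrix(expand.grid(z = gz, y = gy, x = gx)) - 1
  pts <- sweep(grid, 2, mask$voxel_size, `*`)
  eps <- 1e-6 * max(mask$voxel_size)
  inside <- .points_in_hull(pts, facets$normals, facets$offsets, eps)
  hull <- array(FALSE, dim(fg))
  hull[grid[inside, , drop = FALSE] + 1] <- TRUE
  hull <- hull | fg # guard: every mask voxel is in its own hull
  label_mask(hull, mask$voxel_size, role = mask$role)
}
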