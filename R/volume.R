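#' 3D scalar volume with physical voxel size
#'
#' A `volume3d` wraps a 3D numeric array in axis order (Z, Y, X) together with
#' its per-axis voxel size in micrometres and an intensity convention.
#' Coordinates used throughout the package are 0-based voxel indices referring
#' to voxel centres; physical positions are `index * voxel_size` micrometres.
#'
#' @param data 3D numeric array, axis order (Z, Y, X); each axis must have at
#'   least 8 voxels.
#' @param voxel_size numeric length-3, micrometres per voxel along (z, y, x),
#'   or a single number for isotropic grids. All components must be > 0.
#' @param convention intensity convention: `"absorption"` (higher value =
#'   denser material, optical-CT / hematoxylin) or `"fluorescence"`.
#' @return An object of class `volume3d`.
#' @examples
#' v <- volume3d(array(rnorm(10 * 12 * 14), c(10, 12, 14)), 0.35)
#' voxel_volume(v)
#' @export
volume3d <- function(data, voxel_size, convention = c("absorption", "fluorescence")) {
  convention <- match.arg(convention)
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array (Z, Y, X)", class = "nucmorph_shape_error")
  }
  if (any(dim(data) < 8L)) {
    abort("each axis of `data` must have at least 8 voxels",
          class = "nucmorph_shape_error")
  }
  voxel_size <- check_voxel_size(voxel_size)
  structure(
    list(data = data, voxel_size = voxel_size, convention = convention),
    class = "volume3d"
  )
}

check_voxel_size <- function(voxel_size) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || !is.numeric(voxel_size) ||
      any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    abort("`voxel_size` must be 3 finite positive values (dz, dy, dx) in um",
          class = "nucmorph_unit_error")
  }
  as.numeric(voxel_size)
}

#' Voxel volume in cubic micrometres
#' @param x a `volume3d` or `label_mask`.
#' @return Scalar, dz * dy * dx in um^3.
#' @export
voxel_volume <- function(x) prod(x$voxel_size)

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d (Z,Y,X), voxel %s um, %s\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_size, 4), collapse = " x "),
              x$convention))
  invisible(x)
}

#' Integer label mask aligned to a volume
#'
#' A `label_mask` is a 3D integer array with the same shape (and voxel size)
#' as its parent [volume3d()]; 0 is background. The `role` records what the
#' labels delineate.
#'
#' @param data 3D array of non-negative integers (or logical, coerced to 0/1).
#' @param voxel_size as in [volume3d()].
#' @param role one of `"cell"`, `"nucleus"`, `"clump"`, `"spot"`.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(data, voxel_size, role = c("cell", "nucleus", "clump", "spot")) {
  role <- match.arg(role)
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("mask `data` must be a 3D array", class = "nucmorph_shape_error")
  }
  if (is.logical(data)) {
    # logical input is 0/1 by construction; skip the value scan
    data <- array(as.integer(data), dim(data))
  } else {
    if (any(data < 0) || any(data != round(data))) {
      abort("mask values must be non-negative integers", class = "nucmorph_value_error")
    }
    data <- array(as.integer(data), dim(data))
  }
  voxel_size <- check_voxel_size(voxel_size)
  structure(
    list(data = data, voxel_size = voxel_size, role = role),
    class = "label_mask"
  )
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_mask role=%s> %d x %d x %d, %d foreground voxels, %d labels\n",
              x$role, d[1], d[2], d[3], sum(x$data > 0),
              length(setdiff(unique(as.vector(x$data)), 0L))))
  invisible(x)
}

# logical foreground of a mask (array)
mask_fg <- function(mask) mask$data > 0L

# centre of mass of a mask foreground, 0-based voxel indices (z, y, x)
mask_centroid <- function(mask) {
  idx <- which(mask_fg(mask), arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("empty mask", class = "nucmorph_empty_error")
  colMeans(idx) - 1
}

# same, in micrometres
mask_centroid_um <- function(mask) mask_centroid(mask) * mask$voxel_size

as_volume_array <- function(x) {
  if (inherits(x, "volume3d") || inherits(x, "label_mask")) x$data else x
}
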