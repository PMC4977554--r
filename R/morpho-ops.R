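# Binary 3D morphology built on the C++ kernels. All functions operate on
# logical (Z, Y, X) arrays; physical radii are in micrometres and converted
# per axis through the voxel size, so structuring elements are Euclidean
# balls in physical space.

#' Label connected components of a binary 3D array
#'
#' @param fg logical 3D array.
#' @param connectivity 26 (default, used throughout the package) or 6.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(fg, connectivity = 26L) {
  stopifnot(is.logical(fg), length(dim(fg)) == 3L)
  .cc_label3d(as.vector(fg), dim(fg), as.integer(connectivity))
}

# keep only the largest connected component
largest_component <- function(fg, connectivity = 26L) {
  lab <- label_components(fg, connectivity)
  if (max(lab) == 0L) return(array(FALSE, dim(fg)))
  sizes <- tabulate(lab[lab > 0L])
  array(lab == which.max(sizes), dim(fg))
}

# fill internal cavities: background components (6-connected) not touching
# the array border become foreground
fill_holes <- function(fg) {
  lab <- label_components(!fg, connectivity = 6L)
  d <- dim(lab)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]
  ))
  border <- setdiff(border, 0L)
  fg | (lab > 0L & !(lab %in% border))
}

# Euclidean dilation / erosion by a ball of radius r_um (micrometres)
dilate_ball <- function(fg, r_um, voxel_size) {
  if (r_um <= 0) return(fg)
  # .edt3d_sq measures distance to the nearest FALSE voxel of its argument;
  # for dilation we need distance to the nearest TRUE voxel, hence !fg.
  d2 <- .edt3d_sq(as.vector(!fg), dim(fg), voxel_size)
  array(d2 <= r_um^2 + 1e-9, dim(fg))
}

erode_ball <- function(fg, r_um, voxel_size) {
  if (r_um <= 0) return(fg)
  d2 <- .edt3d_sq(as.vector(fg), dim(fg), voxel_size) # distance to background
  array(fg & d2 > r_um^2 + 1e-9, dim(fg))
}

# morphological closing with a Euclidean ball
close_ball <- function(fg, r_um, voxel_size) {
  if (r_um <= 0) return(fg)
  erode_ball(dilate_ball(fg, r_um, voxel_size), r_um, voxel_size)
}

# surface voxels (foreground with a 6-neighbour in the background); these are
# the only candidate vertices of the convex hull
surface_voxels <- function(fg) {
  er <- array(TRUE, dim(fg))
  d <- dim(fg)
  shift_and <- function(acc, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    src <- fg
    pad <- function(a, ax, by) {
      out <- array(FALSE, d)
      n <- d[ax]
      if (by == 1) {
        if (ax == 1) out[2:n, , ] <- a[1:(n - 1), , ]
        if (ax == 2) out[, 2:n, ] <- a[, 1:(n - 1), ]
        if (ax == 3) out[, , 2:n] <- a[, , 1:(n - 1)]
      } else {
        if (ax == 1) out[1:(n - 1), , ] <- a[2:n, , ]
        if (ax == 2) out[, 1:(n - 1), ] <- a[, 2:n, ]
        if (ax == 3) out[, , 1:(n - 1)] <- a[, , 2:n]
      }
      out
    }
    acc & pad(src, ax, by)
  }
  for (ax in 1:3) for (by in c(1, -1)) er <- shift_and(er, ax, by)
  fg & !er
}
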