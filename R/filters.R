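# Separable image filters and thresholding on (Z, Y, X) arrays.

# 1D Gaussian kernel, truncated at 3 sigma, renormalised.
gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve along one axis of a 3D array by band-matrix multiplication with
# edge renormalisation (kernel mass falling off the border is redistributed).
conv_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  band <- matrix(0, n, n)
  for (j in seq_len(n)) {
    lo <- max(1L, j - r)
    hi <- min(n, j + r)
    w <- kernel[(lo - j + r + 1L):(hi - j + r + 1L)]
    band[lo:hi, j] <- w / sum(w)
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  dm <- dim(a)
  a <- t(band) %*% matrix(a, nrow = dm[1])
  dim(a) <- dm
  aperm(a, order(perm))
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with the bandwidth given in micrometres, so the
#' effective smoothing is isotropic in physical space even on anisotropic
#' grids. Borders use renormalised (mass-preserving) truncation.
#'
#' @param volume a [volume3d()] (or bare 3D array plus `voxel_size`).
#' @param sigma_um standard deviation in micrometres (scalar).
#' @param voxel_size only needed when `volume` is a bare array.
#' @return Object of the same kind as the input with smoothed data.
#' @export
gaussian_smooth <- function(volume, sigma_um, voxel_size = NULL) {
  if (sigma_um < 0) abort("sigma must be >= 0", class = "nucmorph_value_error")
  vs <- if (inherits(volume, "volume3d")) volume$voxel_size else check_voxel_size(voxel_size)
  arr <- as_volume_array(volume)
  if (sigma_um > 0) {
    for (axis in 1:3) {
      arr <- conv_axis(arr, gauss_kernel(sigma_um / vs[axis]), axis)
    }
  }
  if (inherits(volume, "volume3d")) {
    volume$data <- arr
    volume
  } else {
    arr
  }
}

#' Otsu threshold of a numeric sample
#'
#' Global Otsu threshold (maximum between-class variance) computed on a
#' 256-bin histogram of the supplied intensities. Used for foreground /
#' background and cytoplasm / nucleus separation, where the intensity
#' distribution is essentially bimodal.
#'
#' @param x numeric vector of intensities.
#' @param nbins number of histogram bins.
#' @return The threshold value; voxels strictly above it are "high" class.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 1e-9 * max(abs(rng), 1)) {
    abort("cannot threshold a constant image", class = "nucmorph_segmentation_error")
  }
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Isodata (two-means) threshold refinement
#'
#' Iterates `t <- (mean(x[x <= t]) + mean(x[x > t])) / 2` from an Otsu
#' start until convergence (Ridler-Calvard). For a symmetric intensity
#' blend between two classes this places the threshold at the class-mean
#' midpoint, removing Otsu's class-size bias at smoothed boundaries.
#'
#' @param x numeric vector of intensities.
#' @param t0 starting threshold (defaults to [otsu_threshold()]).
#' @param max_iter,tol iteration controls.
#' @return Refined threshold value.
#' @export
isodata_threshold <- function(x, t0 = otsu_threshold(x), max_iter = 50L,
                              tol = 1e-8) {
  x <- x[is.finite(x)]
  t <- t0
  for (i in seq_len(max_iter)) {
    lo <- x[x <= t]
    hi <- x[x > t]
    if (length(lo) == 0 || length(hi) == 0) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < tol * max(abs(t), 1)) {
      t <- t_new
      break
    }
    t <- t_new
  }
  t
}

#' Three-class Otsu thresholds
#'
#' Exhaustive two-threshold Otsu (maximum between-class variance over all
#' bin pairs) for trimodal intensity histograms such as
#' background / cytoplasm / nucleus in absorption volumes.
#'
#' @param x numeric vector of intensities.
#' @param nbins number of histogram bins.
#' @return Length-2 numeric vector `c(lower, upper)` of thresholds.
#' @export
otsu_thresholds3 <- function(x, nbins = 128L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 1e-9 * max(abs(rng), 1)) {
    abort("cannot threshold a constant image", class = "nucmorph_segmentation_error")
  }
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  W <- c(0, cumsum(p))
  M <- c(0, cumsum(p * mids))
  class_term <- function(i, j) { # bins (i+1):j, i < j
    w <- W[j + 1] - W[i + 1]
    m <- M[j + 1] - M[i + 1]
    out <- ifelse(w > 0, m^2 / w, 0)
    out
  }
  best <- -Inf
  best_ij <- c(1L, 2L)
  for (i in seq_len(nbins - 2L)) {
    j <- (i + 1L):(nbins - 1L)
    v <- class_term(0L, i) + class_term(i, j) + class_term(j, nbins)
    k <- which.max(v)
    if (v[k] > best) {
      best <- v[k]
      best_ij <- c(i, j[k])
    }
  }
  mids[best_ij]
}

# Trilinear interpolation of a 3D array at fractional 0-based voxel
# coordinates (rows of `pts` = (z, y, x)). Out-of-grid queries clamp.
interp_trilinear <- function(arr, pts) {
  d <- dim(arr)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- pmin(pmax(pts[i, ], 0), d - 1)
    f <- floor(p)
    t <- p - f
    i0 <- as.integer(f) + 1L
    i1 <- pmin(i0 + 1L, d)
    c00 <- arr[i0[1], i0[2], i0[3]] * (1 - t[1]) + arr[i1[1], i0[2], i0[3]] * t[1]
    c10 <- arr[i0[1], i1[2], i0[3]] * (1 - t[1]) + arr[i1[1], i1[2], i0[3]] * t[1]
    c01 <- arr[i0[1], i0[2], i1[3]] * (1 - t[1]) + arr[i1[1], i0[2], i1[3]] * t[1]
    c11 <- arr[i0[1], i1[2], i1[3]] * (1 - t[1]) + arr[i1[1], i1[2], i1[3]] * t[1]
    c0 <- c00 * (1 - t[2]) + c10 * t[2]
    c1 <- c01 * (1 - t[2]) + c11 * t[2]
    out[i] <- c0 * (1 - t[3]) + c1 * t[3]
  }
  out
}

# Signed Euclidean distance field of a binary mask in micrometres:
# positive inside the foreground, negative outside, zero at the interface.
signed_distance <- function(mask) {
  fg <- mask_fg(mask)
  dims <- dim(fg)
  d_out <- sqrt(.edt3d_sq(as.vector(fg), dims, mask$voxel_size))   # dist to background
  d_in <- sqrt(.edt3d_sq(as.vector(!fg), dims, mask$voxel_size))   # dist to foreground
  sd <- array(0, dims)
  sd[fg] <- d_out[fg]
  sd[!fg] <- -d_in[!fg]
  sd
}
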