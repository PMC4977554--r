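# Shared fixture builders. Everything is generated in code at test time.

# digital ball mask: radius in voxels, isotropic voxel size vs_um
digital_ball <- function(r_vox, vs_um = 1, pad = 3L) {
  n <- as.integer(2 * ceiling(r_vox) + 1 + 2 * pad)
  dims <- c(n, n, n)
  c0 <- (n - 1) / 2
  z <- (seq_len(n) - 1 - c0)^2
  fg <- outer(outer(z, z, `+`), z, `+`) <= r_vox^2
  label_mask(fg, rep(vs_um, 3), role = "nucleus")
}

# ball minus a surface-centred bite, in voxel units
bitten_ball <- function(r_vox, bite_vox, vs_um = 1, pad = 3L) {
  ball <- digital_ball(r_vox, vs_um, pad)
  dims <- dim(ball$data)
  c0 <- (dims - 1) / 2
  bite_centre <- c0 + c(0, 0, r_vox) # on the +x surface
  z <- ((seq_len(dims[1]) - 1) - bite_centre[1])^2
  y <- ((seq_len(dims[2]) - 1) - bite_centre[2])^2
  x <- ((seq_len(dims[3]) - 1) - bite_centre[3])^2
  bite <- outer(outer(z, y, `+`), x, `+`) <= bite_vox^2
  label_mask(ball$data > 0 & !bite, rep(vs_um, 3), role = "nucleus")
}

# rotate a (Z, Y, X) array by 90 degrees about the z axis
rot90_zyx <- function(arr) aperm(arr[, , dim(arr)[3]:1, drop = FALSE], c(1, 3, 2))

# spherical nucleus mask with physical radius (um) and voxel size (um)
sphere_mask_um <- function(radius_um, voxel_um, pad = 4L) {
  r_vox <- radius_um / voxel_um
  n <- as.integer(2 * ceiling(r_vox) + 1 + 2 * pad)
  c0 <- (n - 1) / 2 * voxel_um
  z <- ((seq_len(n) - 1) * voxel_um - c0)^2
  fg <- outer(outer(z, z, `+`), z, `+`) <= radius_um^2
  label_mask(fg, rep(voxel_um, 3), role = "nucleus")
}
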