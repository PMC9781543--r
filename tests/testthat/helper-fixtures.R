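# Shared fixtures: small synthetic regions and designs sized so the whole
# suite runs in a few minutes on one core.

sphere_region <- function(r_um, name = "toy") {
  make_region(name, list(type = "ellipsoid", semi_axes_um = rep(r_um, 3)))
}

# ellipsoid with the aspect ratio of the dolphin central nucleus, scaled to
# a given volume; long axis along z (the cutting axis)
cn_shaped_region <- function(volume_mm3, name = "CN") {
  base <- c(9000, 5500, 13740)
  s <- (volume_mm3 * 1e9 / (4 / 3 * pi * prod(base)))^(1 / 3)
  make_region(name, list(type = "ellipsoid", semi_axes_um = base * s))
}

# design with every sampling fraction equal to 1 on 50 um sections: an
# exhaustive census
census_design <- function(cell_um = 500) {
  sampling_design(
    section_period = 1L, cut_thickness_um = 50, mounted_thickness_um = 50,
    grid_um = c(cell_um, cell_um), frame_um = c(cell_um, cell_um),
    disector_height_um = 50, guard_um = 0
  )
}

# independent scalar oracle for segment-sphere surface crossings: solves
# the quadratic with polyroot() per segment and filters roots explicitly
oracle_sphere_crossings <- function(p1, p2, center, r, slab = NULL) {
  d <- p2 - p1
  q <- p1 - center
  coefs <- c(sum(q^2) - r^2, 2 * sum(q * d), sum(d^2))
  if (coefs[3] == 0) return(0L)
  roots <- polyroot(coefs)
  real <- Re(roots)[abs(Im(roots)) < 1e-9]
  if (length(real) < 2 || abs(real[1] - real[2]) < 1e-12) return(0L)
  n <- 0L
  for (t in real) {
    if (t >= 0 && t <= 1) {
      z <- p1[3] + d[3] * t
      if (is.null(slab) || (z >= slab[1] && z < slab[2])) n <- n + 1L
    }
  }
  n
}

# voxel-count volume oracle for an origin-centred ellipsoid: counts voxel
# centres inside, slice by slice (vectorised over y within each z slice)
voxel_volume_ellipsoid <- function(semi_axes, voxel) {
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  centers <- function(hw) {
    n <- ceiling(hw / voxel)
    (seq(-n, n) + 0.5) * voxel
  }
  zs <- centers(cc); ys <- centers(b)
  total <- 0
  for (z in zs) {
    f <- 1 - (z / cc)^2
    if (f <= 0) next
    w <- a * sqrt(pmax(f - (ys / b)^2, 0))  # half-width in x per y row
    pos <- w > 0
    # count of voxel centres (k + 0.5) * voxel with |x| <= w
    nhalf <- floor(w[pos] / voxel + 0.5)
    total <- total + sum(2 * nhalf)
  }
  total * voxel^3
}
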