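# Serial sectioning of simulated tissue: assignment of points and fibers to
# half-open z slabs, z-collapse of cut thickness to mounted thickness,
# in-plane shrinkage, and optional caudal truncation.

#' Histological processing (shrinkage) model
#'
#' @param xy_linear_factor In-plane linear shrinkage factor, in (0, 1].
#' @param z_collapse_factor Ratio of mounted to cut section thickness, in
#'   (0, 1]. Mounted thickness = cut thickness x `z_collapse_factor`.
#' @param truncation_fraction Fraction of sections removed from the caudal
#'   end of the stack, in \[0, 1) (models macroscopically damaged tissue
#'   that could not be sectioned).
#' @return An object of class `"shrinkage_model"`.
#' @examples
#' shrinkage_model()                      # identity processing
#' shrinkage_model(0.9, 0.4, 1 / 3)       # 50 um cut -> 20 um mounted
#' @export
shrinkage_model <- function(xy_linear_factor = 1, z_collapse_factor = 1,
                            truncation_fraction = 0) {
  if (xy_linear_factor <= 0 || xy_linear_factor > 1 ||
      z_collapse_factor <= 0 || z_collapse_factor > 1) {
    stop_sf("bad_shrinkage", "shrinkage factors must lie in (0, 1]")
  }
  if (truncation_fraction < 0 || truncation_fraction >= 1) {
    stop_sf("bad_shrinkage", "truncation_fraction must lie in [0, 1)")
  }
  structure(
    list(
      xy_linear_factor = xy_linear_factor,
      z_collapse_factor = z_collapse_factor,
      truncation_fraction = truncation_fraction
    ),
    class = "shrinkage_model"
  )
}

#' Cut simulated tissue into a stack of serial sections
#'
#' Cuts the region (with its point and fiber content) into consecutive
#' sections of equal cut thickness along z, rostral to caudal, using
#' half-open intervals `[z0, z0 + t)` so that every point lands in exactly
#' one section. Within each section, local z is rescaled by the z-collapse
#' factor (cut -> mounted thickness) and x, y are scaled by the in-plane
#' shrinkage factor. Truncation then removes the last
#' `ceiling(truncation_fraction * n)` sections.
#'
#' @param region A [make_region()] object (defines the z extent).
#' @param points Optional marker-point data.frame (see
#'   [simulate_neuron_field()]).
#' @param fibers Optional fiber-segment data.frame (see
#'   [simulate_fiber_field()]); segments spanning several sections are split
#'   at section faces before the local transform.
#' @param cut_thickness_um Cut section thickness (> 0), micrometres.
#' @param shrinkage A [shrinkage_model()].
#' @return An object of class `"section_stack"`: fields `n_sections`
#'   (after truncation), `n_sections_cut` (before), `z0_um` (rostral face
#'   of section 0), `cut_thickness_um`, `mounted_thickness_um`,
#'   `shrinkage`, `region`, and data.frames `points` / `fibers` carrying a
#'   0-based `section_index` plus section-local, processed coordinates.
#' @export
section_stack <- function(region, points = NULL, fibers = NULL,
                          cut_thickness_um = 50,
                          shrinkage = shrinkage_model()) {
  if (cut_thickness_um <= 0) stop_sf("bad_thickness", "cut_thickness_um must be > 0")
  stopifnot(inherits(shrinkage, "shrinkage_model"))
  t_cut <- cut_thickness_um
  zc <- shrinkage$z_collapse_factor
  xyf <- shrinkage$xy_linear_factor
  z0 <- region$bbox_um[3, 1]
  extent <- region$bbox_um[3, 2] - z0
  n_cut <- max(1L, as.integer(ceiling(extent / t_cut - 1e-12)))
  n_drop <- as.integer(ceiling(shrinkage$truncation_fraction * n_cut))
  n_keep <- n_cut - n_drop

  pts <- NULL
  if (!is.null(points) && nrow(points) > 0) {
    idx <- pmin(pmax(floor((points$z_um - z0) / t_cut), 0), n_cut - 1)
    local_z <- (points$z_um - (z0 + idx * t_cut)) * zc
    pts <- points
    pts$section_index <- as.integer(idx)
    pts$x_um <- points$x_um * xyf
    pts$y_um <- points$y_um * xyf
    pts$z_um <- local_z
    pts <- pts[pts$section_index < n_keep, , drop = FALSE]
    rownames(pts) <- NULL
  } else if (!is.null(points)) {
    pts <- cbind(points, section_index = integer(0))
  }

  fib <- NULL
  if (!is.null(fibers) && nrow(fibers) > 0) {
    fib <- split_fibers_into_sections(fibers, z0, t_cut, n_cut)
    fib <- fib[fib$section_index < n_keep, , drop = FALSE]
    # local transform
    fz0 <- z0 + fib$section_index * t_cut
    fib$x1_um <- fib$x1_um * xyf; fib$x2_um <- fib$x2_um * xyf
    fib$y1_um <- fib$y1_um * xyf; fib$y2_um <- fib$y2_um * xyf
    fib$z1_um <- (fib$z1_um - fz0) * zc
    fib$z2_um <- (fib$z2_um - fz0) * zc
    fib$length_um <- sqrt((fib$x2_um - fib$x1_um)^2 +
                          (fib$y2_um - fib$y1_um)^2 +
                          (fib$z2_um - fib$z1_um)^2)
    rownames(fib) <- NULL
  } else if (!is.null(fibers)) {
    fib <- cbind(fibers, section_index = integer(0))
  }

  structure(
    list(
      n_sections = n_keep, n_sections_cut = n_cut, z0_um = z0,
      cut_thickness_um = t_cut,
      mounted_thickness_um = t_cut * zc,
      shrinkage = shrinkage, region = region,
      points = pts, fibers = fib
    ),
    class = "section_stack"
  )
}

# Split segments at section faces; returns global coordinates plus a
# 0-based section_index per sub-segment.
split_fibers_into_sections <- function(fibers, z0, t_cut, n_cut) {
  za <- pmin(fibers$z1_um, fibers$z2_um)
  zb <- pmax(fibers$z1_um, fibers$z2_um)
  i0 <- pmin(pmax(floor((za - z0) / t_cut), 0), n_cut - 1)
  i1 <- pmin(pmax(floor((zb - z0) / t_cut - 1e-12), i0), n_cut - 1)
  n_pieces <- as.integer(i1 - i0 + 1)
  seg <- rep(seq_len(nrow(fibers)), n_pieces)
  sec <- unlist(lapply(seq_len(nrow(fibers)), function(i) i0[i]:i1[i]),
                use.names = FALSE)
  p1 <- cbind(fibers$x1_um, fibers$y1_um, fibers$z1_um)[seg, , drop = FALSE]
  p2 <- cbind(fibers$x2_um, fibers$y2_um, fibers$z2_um)[seg, , drop = FALSE]
  dz <- p2[, 3] - p1[, 3]
  zlo <- z0 + sec * t_cut
  zhi <- zlo + t_cut
  # parametric clip of each piece to [zlo, zhi)
  t0 <- rep(0, length(seg)); t1 <- rep(1, length(seg))
  nz <- abs(dz) > 1e-12
  ta <- (zlo[nz] - p1[nz, 3]) / dz[nz]
  tb <- (zhi[nz] - p1[nz, 3]) / dz[nz]
  t0[nz] <- pmax(pmin(ta, tb), 0)
  t1[nz] <- pmin(pmax(ta, tb), 1)
  keep <- t1 > t0
  d <- p2 - p1
  e1 <- p1[keep, , drop = FALSE] + d[keep, , drop = FALSE] * t0[keep]
  e2 <- p1[keep, , drop = FALSE] + d[keep, , drop = FALSE] * t1[keep]
  data.frame(
    section_index = as.integer(sec[keep]),
    x1_um = e1[, 1], y1_um = e1[, 2], z1_um = e1[, 3],
    x2_um = e2[, 1], y2_um = e2[, 2], z2_um = e2[, 3],
    length_um = sqrt(rowSums((e2 - e1)^2))
  )
}

#' @export
print.section_stack <- function(x, ...) {
  cat(sprintf(
    "<section_stack> %d sections (%d cut, %d truncated), %g um cut / %g um mounted, %d points, %d fiber pieces\n",
    x$n_sections, x$n_sections_cut, x$n_sections_cut - x$n_sections,
    x$cut_thickness_um, x$mounted_thickness_um,
    if (is.null(x$points)) 0L else nrow(x$points),
    if (is.null(x$fibers)) 0L else nrow(x$fibers)
  ))
  invisible(x)
}

#' Contour of one mounted section
#'
#' Cross-section of the stack's region at the mid-plane of the given
#' section, with the stack's in-plane shrinkage applied -- the polygon a
#' microscopist would trace around the structure on that slide.
#'
#' @param stack A [section_stack()].
#' @param section_index 0-based section index.
#' @param n_vertices Number of polygon vertices.
#' @return A two-column matrix, or `NULL` if the plane misses the region.
#' @export
section_polygon <- function(stack, section_index, n_vertices = 180) {
  z_mid <- stack$z0_um + (section_index + 0.5) * stack$cut_thickness_um
  region_cross_section(stack$region, z_mid, n_vertices,
                       xy_factor = stack$shrinkage$xy_linear_factor)
}
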