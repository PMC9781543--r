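#' Create a 3D region with known true volume
#'
#' A region is the simulator-side ground truth: a bounded 3D shape (an
#' analytic ellipsoid or a voxel mask) whose true volume is known by
#' construction. Estimator tests sample synthetic cell and fiber fields
#' inside a region and check that the probes recover the known quantities.
#'
#' @param name Text label, e.g. `"IC-CN"`, `"IC-EC"`, `"VCN"`.
#' @param shape_spec A list describing the geometry. Either
#'   `list(type = "ellipsoid", semi_axes_um = c(a, b, c), center_um = c(x, y, z))`
#'   (center defaults to the origin; the third semi-axis runs along z, the
#'   cutting axis) or
#'   `list(type = "mask", mask = <logical 3D array>, voxel_size_um = s)`.
#'
#' @return An object of class `"region"` with fields `name`, `type`,
#'   `true_volume_um3`, `bbox_um` (a 3x2 matrix of axis ranges) and the
#'   geometry parameters.
#'
#' @details For an ellipsoid the true volume is \eqn{\frac{4}{3}\pi abc};
#'   for a mask it is the voxel count times the voxel volume.
#'
#' @examples
#' r <- make_region("toy", list(type = "ellipsoid", semi_axes_um = c(100, 100, 100)))
#' r$true_volume_um3 / (4 / 3 * pi * 100^3)  # 1
#' @export
make_region <- function(name, shape_spec) {
  type <- shape_spec$type
  if (is.null(type) || !type %in% c("ellipsoid", "mask")) {
    stop_sf("bad_shape", "shape_spec$type must be 'ellipsoid' or 'mask'")
  }
  if (type == "ellipsoid") {
    ax <- as.numeric(shape_spec$semi_axes_um)
    if (length(ax) != 3 || any(!is.finite(ax)) || any(ax <= 0)) {
      stop_sf("bad_shape", "ellipsoid semi-axes must be three positive numbers")
    }
    ctr <- shape_spec$center_um
    if (is.null(ctr)) ctr <- c(0, 0, 0)
    ctr <- as.numeric(ctr)
    bbox <- rbind(ctr - ax, ctr + ax)
    reg <- list(
      name = name, type = "ellipsoid",
      semi_axes_um = ax, center_um = ctr,
      true_volume_um3 = 4 / 3 * pi * prod(ax),
      bbox_um = t(bbox)
    )
  } else {
    mask <- shape_spec$mask
    vs <- shape_spec$voxel_size_um
    if (is.null(mask) || length(dim(mask)) != 3 || sum(mask) == 0) {
      stop_sf("bad_shape", "mask must be a non-empty 3D logical array")
    }
    if (is.null(vs) || vs <= 0) stop_sf("bad_shape", "voxel_size_um must be > 0")
    dm <- dim(mask)
    reg <- list(
      name = name, type = "mask",
      mask = (mask != 0), voxel_size_um = vs,
      true_volume_um3 = sum(mask != 0) * vs^3,
      bbox_um = rbind(c(0, dm[1] * vs), c(0, dm[2] * vs), c(0, dm[3] * vs))
    )
  }
  dimnames(reg$bbox_um) <- list(c("x", "y", "z"), c("min", "max"))
  class(reg) <- "region"
  reg
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf(
    "<region '%s'> %s, true volume %.4g mm^3\n",
    x$name, x$type, um3_to_mm3(x$true_volume_um3)
  ))
  invisible(x)
}

#' Test whether points lie inside a region
#'
#' @param region A [make_region()] object.
#' @param xyz Numeric matrix with columns x, y, z (micrometres).
#' @return Logical vector, one entry per row of `xyz`.
#' @export
point_in_region <- function(region, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (region$type == "ellipsoid") {
    u <- sweep(xyz, 2, region$center_um)
    u <- sweep(u, 2, region$semi_axes_um, "/")
    rowSums(u^2) <= 1
  } else {
    vs <- region$voxel_size_um
    dm <- dim(region$mask)
    i <- floor(xyz[, 1] / vs) + 1
    j <- floor(xyz[, 2] / vs) + 1
    k <- floor(xyz[, 3] / vs) + 1
    ok <- i >= 1 & i <= dm[1] & j >= 1 & j <= dm[2] & k >= 1 & k <= dm[3]
    out <- rep(FALSE, nrow(xyz))
    out[ok] <- region$mask[cbind(i[ok], j[ok], k[ok])]
    out
  }
}

#' Planar cross-section contour of a region
#'
#' Returns the closed polygon where the plane at height `z_um` cuts the
#' region, optionally scaled in-plane by a linear shrinkage factor. Only
#' ellipsoid regions have analytic contours; the cross-section of an
#' ellipsoid is an ellipse, discretised to `n_vertices` vertices.
#'
#' @param region A [make_region()] object of type `"ellipsoid"`.
#' @param z_um Height of the cutting plane, micrometres.
#' @param n_vertices Number of polygon vertices.
#' @param xy_factor In-plane linear scaling applied about the section
#'   centroid's position (models xy shrinkage of a mounted section).
#' @return An `n_vertices` x 2 matrix (open polygon; the last vertex is not
#'   repeated), or `NULL` when the plane misses the region.
#' @export
region_cross_section <- function(region, z_um, n_vertices = 180, xy_factor = 1) {
  if (region$type != "ellipsoid") {
    stop_sf("bad_shape", "cross-section contours are only defined for ellipsoid regions")
  }
  ax <- region$semi_axes_um
  ctr <- region$center_um
  f <- 1 - ((z_um - ctr[3]) / ax[3])^2
  if (f <= 0) return(NULL)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  cbind(
    x = (ctr[1] + ax[1] * sqrt(f) * cos(th)) * xy_factor,
    y = (ctr[2] + ax[2] * sqrt(f) * sin(th)) * xy_factor
  )
}

#' Polygon area by the shoelace formula
#'
#' @param polygon Matrix with two columns (x, y); the polygon is closed
#'   implicitly.
#' @return Absolute enclosed area in the square of the coordinate unit.
#' @export
polygon_area <- function(polygon) {
  p <- as.matrix(polygon)
  if (is.null(p) || nrow(p) < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

# Area-weighted centroid of a simple polygon (falls back to the vertex mean
# for degenerate polygons).
polygon_centroid <- function(polygon) {
  p <- as.matrix(polygon)
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * max(1, sum(abs(cr)))) {
    return(colMeans(p))
  }
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}
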