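# Marker-distribution maps: average region contours across serial sections
# and kernel-smoothed 2D density grids of marker coordinates projected onto
# the coronal (x-y) plane.

#' Average a contour across serial sections
#'
#' Resamples each per-section polygon to a fixed number of vertices by arc
#' length (counter-clockwise, starting at the boundary point right of the
#' centroid), aligns the polygons on their centroids, and takes the
#' vertex-wise mean, re-centred on the mean centroid. Two congruent
#' translated contours average to the same shape at the mean position;
#' concentric circles of radii 1 and 3 average to a circle of radius 2.
#'
#' @param per_section_polygons List of two-column vertex matrices (>= 1).
#' @param n_vertices Number of vertices of the averaged polygon.
#' @return A `n_vertices` x 2 matrix.
#' @export
average_contour <- function(per_section_polygons, n_vertices = 200) {
  if (length(per_section_polygons) == 0) {
    stop_sf("bad_counts", "no polygons to average")
  }
  res <- lapply(per_section_polygons, resample_polygon, n = n_vertices)
  ctrs <- t(vapply(res, polygon_centroid, numeric(2)))
  centered <- Map(function(p, i) sweep(p, 2, ctrs[i, ]), res, seq_along(res))
  avg <- Reduce(`+`, centered) / length(centered)
  sweep(avg, 2, colMeans(ctrs), `+`)
}

#' Resample a polygon to n vertices by arc length
#'
#' Vertices are placed at equal arc-length steps along the boundary,
#' traversed counter-clockwise starting from the boundary point where the
#' ray from the centroid along +x crosses it, so that resampled polygons
#' of similar shapes are in vertex-wise correspondence.
#'
#' @param polygon Two-column vertex matrix (closed implicitly).
#' @param n Number of output vertices.
#' @return An `n` x 2 matrix.
#' @export
resample_polygon <- function(polygon, n = 200) {
  p <- as.matrix(polygon)
  if (nrow(p) < 3) stop_sf("bad_shape", "polygon needs at least 3 vertices")
  # enforce counter-clockwise orientation
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  if (sum(x * y2 - x2 * y) < 0) p <- p[nrow(p):1, , drop = FALSE]
  ctr <- polygon_centroid(p)
  # start at the boundary crossing of the +x ray from the centroid
  q <- sweep(p, 2, ctr)
  ang <- atan2(q[, 2], q[, 1])
  start <- which.min(abs(ang))
  p <- p[c(start:nrow(p), seq_len(start - 1)), , drop = FALSE]
  closed <- rbind(p, p[1, ])
  seglen <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  if (total == 0) stop_sf("bad_shape", "polygon has zero perimeter")
  s <- seq(0, total, length.out = n + 1)[seq_len(n)]
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(closed) - 1)
  frac <- (s - cum[idx]) / pmax(seglen[idx], .Machine$double.eps)
  closed[idx, , drop = FALSE] +
    (closed[idx + 1, , drop = FALSE] - closed[idx, , drop = FALSE]) * frac
}

#' Kernel-smoothed marker density heatmap
#'
#' Projects marker coordinates onto the coronal (x, y) plane (sections are
#' pooled), bins them into square pixels, and smooths the counts with a
#' normalized isotropic Gaussian kernel using reflecting boundaries, so
#' that the total smoothed mass equals the point count. The stored
#' intensity is max-normalized to 1 (all zero for empty input); lighter
#' values mark higher marker density.
#'
#' @param points Marker-point data.frame with `x_um`, `y_um` (z and
#'   section index are ignored: the map pools all sections), or a matrix
#'   whose first two columns are x and y.
#' @param pixel_size_um Pixel edge length, micrometres.
#' @param bandwidth_um Gaussian kernel standard deviation, micrometres.
#' @param bbox Optional 2x2 matrix `rbind(c(xmin, xmax), c(ymin, ymax))`;
#'   grown as needed so the grid always covers all points. Required when
#'   `points` is empty.
#' @param contours Optional list of overlay polygons (e.g. from
#'   [average_contour()]), stored with the grid.
#' @return An object of class `"heatmap_grid"`: `intensity` (nx x ny
#'   matrix, max 1), `mass` (unnormalized smoothed counts), `pixel_size_um`,
#'   `x_centers`, `y_centers`, `bbox`, `contours`, `points`.
#' @export
marker_heatmap <- function(points, pixel_size_um, bandwidth_um,
                           bbox = NULL, contours = NULL) {
  if (pixel_size_um <= 0 || bandwidth_um <= 0) {
    stop_sf("bad_design", "pixel size and bandwidth must be > 0")
  }
  if (is.data.frame(points)) {
    xy <- cbind(points$x_um, points$y_um)
  } else {
    xy <- matrix(as.numeric(points), ncol = max(2, ncol(points)))[, 1:2, drop = FALSE]
  }
  if (nrow(xy) == 0 && is.null(bbox)) {
    stop_sf("bad_counts", "empty input needs an explicit bbox")
  }
  px <- pixel_size_um
  lims <- if (is.null(bbox)) {
    rbind(range(xy[, 1]), range(xy[, 2]))
  } else {
    b <- as.matrix(bbox)
    if (nrow(xy) > 0) {
      rbind(range(b[1, ], xy[, 1]), range(b[2, ], xy[, 2]))
    } else {
      b
    }
  }
  x0 <- floor(lims[1, 1] / px) * px
  y0 <- floor(lims[2, 1] / px) * px
  nx <- max(1L, ceiling((lims[1, 2] - x0) / px + 1e-9))
  ny <- max(1L, ceiling((lims[2, 2] - y0) / px + 1e-9))
  counts <- matrix(0, nx, ny)
  if (nrow(xy) > 0) {
    i <- pmin(pmax(floor((xy[, 1] - x0) / px) + 1, 1), nx)
    j <- pmin(pmax(floor((xy[, 2] - y0) / px) + 1, 1), ny)
    tab <- table(factor(i, levels = seq_len(nx)), factor(j, levels = seq_len(ny)))
    counts <- matrix(as.numeric(tab), nx, ny)
  }
  kern <- gaussian_kernel_1d(bandwidth_um / px)
  kr <- (length(kern) - 1L) / 2L
  if (kr >= nx || kr >= ny) {
    stop_sf("bad_design", "bandwidth too large for the grid extent")
  }
  mass <- reflect_convolve_cols(t(reflect_convolve_cols(t(counts), kern)), kern)
  mx <- max(mass)
  structure(
    list(
      intensity = if (mx > 0) mass / mx else mass,
      mass = mass, pixel_size_um = px,
      x_centers = x0 + (seq_len(nx) - 0.5) * px,
      y_centers = y0 + (seq_len(ny) - 0.5) * px,
      bbox = rbind(c(x0, x0 + nx * px), c(y0, y0 + ny * px)),
      contours = contours,
      points = if (is.data.frame(points)) points else NULL
    ),
    class = "heatmap_grid"
  )
}

# normalized 1D Gaussian kernel, truncated at 4 sd (odd length)
gaussian_kernel_1d <- function(sd_px) {
  kr <- max(1L, ceiling(4 * sd_px))
  k <- stats::dnorm(seq(-kr, kr), sd = sd_px)
  k / sum(k)
}

# column-wise 1D convolution with reflecting boundaries (mass-preserving
# for a normalized kernel)
reflect_convolve_cols <- function(M, kern) {
  kr <- (length(kern) - 1L) / 2L
  if (kr == 0L) return(M * kern)
  n <- nrow(M)
  pad <- rbind(
    M[kr:1, , drop = FALSE],
    M,
    M[n:(n - kr + 1), , drop = FALSE]
  )
  sm <- stats::filter(pad, kern, sides = 2)
  matrix(sm[(kr + 1):(kr + n), ], n, ncol(M))
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat(sprintf(
    "<heatmap_grid> %d x %d pixels of %g um, total mass %.4g\n",
    length(x$x_centers), length(x$y_centers), x$pixel_size_um, sum(x$mass)
  ))
  invisible(x)
}

#' Plot a marker heatmap
#'
#' Renders the normalized intensity grid with lighter colors for higher
#' marker density, plus any stored contour overlays and point overlays
#' colored by immunoreactivity compartment.
#'
#' @param x A [marker_heatmap()] grid.
#' @param show_points Overlay the raw points.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.heatmap_grid <- function(x, show_points = FALSE, ...) {
  graphics::image(
    x$x_centers, x$y_centers, x$intensity,
    col = grDevices::hcl.colors(64, "inferno"),
    xlab = "x (um)", ylab = "y (um)", asp = 1, useRaster = TRUE, ...
  )
  for (ct in x$contours %||% list()) {
    graphics::lines(rbind(ct, ct[1, ]), col = "white", lwd = 1.5)
  }
  if (show_points && !is.null(x$points)) {
    comp <- factor(x$points$compartment %||% "none", levels = COMPARTMENTS)
    graphics::points(x$points$x_um, x$points$y_um, pch = 16, cex = 0.3,
                     col = grDevices::adjustcolor(
                       c("cyan", "green3", "orange", "grey70")[as.integer(comp)],
                       alpha.f = 0.6
                     ))
  }
  invisible(x)
}

#' Export a heatmap grid as TSV
#'
#' Writes the normalized intensity matrix with pixel-center coordinates in
#' the header comment, one row per pixel row.
#'
#' @param grid A [marker_heatmap()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_heatmap_tsv <- function(grid, path) {
  df <- data.frame(
    x_um = rep(grid$x_centers, times = length(grid$y_centers)),
    y_um = rep(grid$y_centers, each = length(grid$x_centers)),
    intensity = as.vector(grid$intensity)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
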