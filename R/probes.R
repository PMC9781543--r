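# Geometric probe kernels and probe runners: systematic random sampling
# (SRS) site placement, unbiased counting frames with optical disectors,
# Cavalieri point counting on section contours, and sphere-surface
# (Spaceball) intersection counting for fibers.

#' Place a systematic random sampling grid over a section contour
#'
#' Translates a regular grid by a single uniform random offset in
#' `[0, gx) x [0, gy)` and keeps the grid points relevant to the contour.
#' Under the default rule a grid point is a site when it falls inside the
#' polygon, so the expected site count equals the contour area divided by
#' the grid-cell area (the property Cavalieri point counting relies on).
#' `rule = "frame"` instead keeps grid points whose counting frame
#' intersects the contour, which adds boundary sites.
#'
#' @param section_polygon Two-column matrix of contour vertices (closed
#'   implicitly). Degenerate contours (fewer than 3 vertices or zero area)
#'   yield an empty site list.
#' @param grid_um Grid step `c(gx, gy)`, micrometres.
#' @param seed Integer seed for the random offset (deterministic per seed).
#' @param offset Optional explicit offset `c(ox, oy)`; overrides `seed`.
#' @param rule `"origin"` (default) or `"frame"`; see Details.
#' @param frame_um Counting frame size, required for `rule = "frame"`.
#' @return A matrix of site origins (columns x, y), possibly with 0 rows,
#'   with the offset used stored in `attr(, "offset")`.
#' @export
place_srs_grid <- function(section_polygon, grid_um, seed = NULL,
                           offset = NULL, rule = c("origin", "frame"),
                           frame_um = NULL) {
  rule <- match.arg(rule)
  gx <- grid_um[1]; gy <- grid_um[2]
  if (!is.null(seed)) set.seed(seed)
  if (is.null(offset)) offset <- c(stats::runif(1, 0, gx), stats::runif(1, 0, gy))
  empty <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
  attr(empty, "offset") <- offset
  if (is.null(section_polygon) || nrow(section_polygon) < 3 ||
      polygon_area(section_polygon) == 0) {
    return(empty)
  }
  poly <- close_polygon(section_polygon)
  pad <- if (rule == "frame") {
    if (is.null(frame_um)) stop_sf("bad_design", "rule = 'frame' requires frame_um")
    c(frame_um[1], frame_um[2])
  } else {
    c(0, 0)
  }
  rx <- range(section_polygon[, 1]); ry <- range(section_polygon[, 2])
  xs <- grid_coords(rx[1] - pad[1], rx[2], gx, offset[1])
  ys <- grid_coords(ry[1] - pad[2], ry[2], gy, offset[2])
  if (length(xs) == 0 || length(ys) == 0) return(empty)
  cand <- cbind(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
  keep <- if (rule == "origin") {
    mgcv::in.out(poly, cand)
  } else {
    frame_hits_polygon(cand, frame_um, poly, section_polygon)
  }
  out <- cand[keep, , drop = FALSE]
  attr(out, "offset") <- offset
  out
}

close_polygon <- function(p) {
  p <- as.matrix(p)
  if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ])
  p
}

grid_coords <- function(lo, hi, step, offset) {
  i0 <- ceiling((lo - offset) / step)
  i1 <- floor((hi - offset) / step)
  if (i1 < i0) return(numeric(0))
  offset + (i0:i1) * step
}

# Approximate frame/polygon intersection test: a frame with its origin at a
# candidate grid point hits the contour when one of its corners lies inside
# the polygon or a polygon vertex lies inside the frame. Edge-through-edge
# crossings without contained vertices are not detected; at the frame sizes
# used (frame much smaller than a contour edge) this is negligible.
frame_hits_polygon <- function(cand, frame_um, poly_closed, poly_open) {
  fw <- frame_um[1]; fh <- frame_um[2]
  hit <- rep(FALSE, nrow(cand))
  for (dx in c(0, fw)) {
    for (dy in c(0, fh)) {
      hit <- hit | mgcv::in.out(poly_closed, cbind(cand[, 1] + dx, cand[, 2] + dy))
    }
  }
  todo <- which(!hit)
  for (i in todo) {
    inside <- poly_open[, 1] >= cand[i, 1] & poly_open[, 1] < cand[i, 1] + fw &
      poly_open[, 2] >= cand[i, 2] & poly_open[, 2] < cand[i, 2] + fh
    if (any(inside)) hit[i] <- TRUE
  }
  hit
}

#' Count points in an unbiased counting frame with an optical disector
#'
#' Applies the counting rule for point-like items: half-open intervals on
#' all three axes, `x in [x0, x0 + fw)`, `y in [y0, y0 + fh)`,
#' `z in [z1, z2)`. For items reduced to a single point this is exactly the
#' classical inclusion/exclusion-line rule (items on the inclusion lines
#' count, items on the forbidden lines do not), and tiling a section with
#' frames counts every point exactly once.
#'
#' @param points Marker-point data.frame with `x_um`, `y_um`, `z_um`
#'   (section-local coordinates), or a 3-column matrix.
#' @param frame_origin Frame origin `c(x0, y0)`, micrometres.
#' @param frame_size Frame size `c(fw, fh)`, micrometres.
#' @param z_window Disector window `c(z1, z2)` in section-local z,
#'   micrometres (typically `c(guard, guard + h)`).
#' @return Integer count Q.
#' @export
count_in_frame <- function(points, frame_origin, frame_size, z_window) {
  if (is.data.frame(points)) {
    x <- points$x_um; y <- points$y_um; z <- points$z_um
  } else {
    x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  }
  sum(
    x >= frame_origin[1] & x < frame_origin[1] + frame_size[1] &
    y >= frame_origin[2] & y < frame_origin[2] + frame_size[2] &
    z >= z_window[1] & z < z_window[2]
  )
}

#' Cavalieri point count on one section contour
#'
#' Counts the points of a randomly offset square grid that fall inside the
#' contour. The expected count is the contour area divided by the squared
#' spacing, which is what makes `d x a(p) x sum(P)` an unbiased volume
#' estimator.
#'
#' @param section_polygon Two-column matrix of contour vertices; degenerate
#'   contours give 0.
#' @param point_grid_spacing_um Grid spacing (> 0), micrometres.
#' @param seed Integer seed for the random offset.
#' @param offset Optional explicit offset `c(ox, oy)` in
#'   `[0, spacing)^2`; overrides `seed`.
#' @return Integer point count P.
#' @export
point_count_section <- function(section_polygon, point_grid_spacing_um,
                                seed = NULL, offset = NULL) {
  if (point_grid_spacing_um <= 0) stop_sf("bad_design", "spacing must be > 0")
  sites <- place_srs_grid(
    section_polygon, c(point_grid_spacing_um, point_grid_spacing_um),
    seed = seed, offset = offset, rule = "origin"
  )
  nrow(sites)
}

#' Count transversal crossings of fiber segments with a sphere surface
#'
#' Solves the quadratic for the intersection of each segment with the
#' sphere of radius `r` about `center` and counts parameter roots in
#' `[0, 1]` whose crossing point has z inside the half-open `slab` (the
#' optical-disector window the Spaceball surface is truncated to).
#' Tangencies (double roots) count zero; a segment entirely inside the
#' sphere crosses nowhere.
#'
#' @param p1,p2 Segment endpoints: numeric length-3 vectors or n x 3
#'   matrices (micrometres).
#' @param center Sphere center, length-3.
#' @param r Sphere radius, micrometres.
#' @param slab Optional `c(zlo, zhi)`: crossings are only counted where
#'   `zlo <= z < zhi`. `NULL` keeps the full sphere.
#' @return Integer vector of crossing counts, one per segment.
#' @export
intersect_fiber_sphere <- function(p1, p2, center, r, slab = NULL) {
  p1 <- matrix(as.numeric(p1), ncol = 3)
  p2 <- matrix(as.numeric(p2), ncol = 3)
  d <- p2 - p1
  q <- sweep(p1, 2, as.numeric(center))
  a <- rowSums(d^2)
  b <- 2 * rowSums(q * d)
  cc <- rowSums(q^2) - r^2
  disc <- b^2 - 4 * a * cc
  n <- nrow(p1)
  counts <- integer(n)
  ok <- which(disc > 0 & a > 0)
  if (length(ok) == 0) return(counts)
  sq <- sqrt(disc[ok])
  for (sgn in c(-1, 1)) {
    t_root <- (-b[ok] + sgn * sq) / (2 * a[ok])
    inside <- t_root >= 0 & t_root <= 1
    if (!is.null(slab)) {
      zc <- p1[ok, 3] + d[ok, 3] * t_root
      inside <- inside & zc >= slab[1] & zc < slab[2]
    }
    counts[ok] <- counts[ok] + as.integer(inside)
  }
  counts
}

#' Run a stereological probe over a sectioned stack
#'
#' Selects every k-th section starting at a random (or given) offset,
#' places an SRS grid on each sampled section, and applies the probe at
#' every site: disector counting frames for `probe = "fractionator"`,
#' Spaceball sphere surfaces for `probe = "spaceballs"`.
#'
#' For the fractionator the tally is computed with the counting frame
#' applied at every grid translate (items are assigned to frames by the
#' modulo rule), which is exactly the half-open frame rule of
#' [count_in_frame()] tiled over the plane; a design with all sampling
#' fractions equal to 1 therefore returns the exact census. Site counts per
#' section are still recorded from the contour for reporting.
#'
#' @param stack A [section_stack()].
#' @param design A [sampling_design()].
#' @param item_filter Optional named list over `cell_class`, `marker`,
#'   `compartment`; points must match every given field. Ignored for the
#'   Spaceball probe (fibers carry no labels).
#' @param probe `"fractionator"` or `"spaceballs"`.
#' @param seed Integer seed controlling the section offset and all site
#'   offsets.
#' @param section_offset Optional integer in `[0, k)`: index of the first
#'   sampled section. Drawn uniformly when `NULL`.
#' @param n_vertices Vertices used for section contours.
#' @return A `section_counts` data.frame with one row per sampled section:
#'   `section_index`, `n_sites`, `tally`; attributes `probe`,
#'   `section_offset` and `design`.
#' @export
run_probe <- function(stack, design, item_filter = NULL,
                      probe = c("fractionator", "spaceballs"),
                      seed = NULL, section_offset = NULL, n_vertices = 180) {
  probe <- match.arg(probe)
  stopifnot(inherits(stack, "section_stack"), inherits(design, "sampling_design"))
  if (stack$n_sections < 1) stop_sf("empty_stack", "the stack has no sections")
  if (abs(stack$mounted_thickness_um - design$mounted_thickness_um) > 1e-6) {
    stop_sf("bad_design", sprintf(
      "design mounted thickness (%g um) does not match the stack (%g um)",
      design$mounted_thickness_um, stack$mounted_thickness_um
    ))
  }
  if (!is.null(seed)) set.seed(seed)
  k <- design$section_period
  if (is.null(section_offset)) section_offset <- sample.int(k, 1) - 1L
  sampled <- seq.int(section_offset, stack$n_sections - 1L, by = k)

  guard <- design$guard_um
  h <- design$disector_height_um
  z_win <- c(guard, guard + h)

  pts <- NULL
  if (probe == "fractionator") {
    pts <- stack$points
    if (is.null(pts)) pts <- data.frame(section_index = integer(0),
                                        x_um = numeric(0), y_um = numeric(0),
                                        z_um = numeric(0))
    pts <- filter_items(pts, item_filter)
  }

  res <- lapply(sampled, function(s) {
    off <- c(stats::runif(1, 0, design$grid_um[1]),
             stats::runif(1, 0, design$grid_um[2]))
    poly <- section_polygon(stack, s, n_vertices)
    sites <- place_srs_grid(poly, design$grid_um, offset = off)
    if (probe == "fractionator") {
      p <- pts[pts$section_index == s, , drop = FALSE]
      tally <- sum(
        ((p$x_um - off[1]) %% design$grid_um[1]) < design$frame_um[1] &
        ((p$y_um - off[2]) %% design$grid_um[2]) < design$frame_um[2] &
        p$z_um >= z_win[1] & p$z_um < z_win[2]
      )
    } else {
      tally <- spaceball_section_tally(stack, s, sites, design, z_win)
    }
    c(n_sites = nrow(sites), tally = tally)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    section_index = as.integer(sampled),
    n_sites = as.integer(res[, "n_sites"]),
    tally = as.integer(res[, "tally"])
  )
  attr(out, "probe") <- probe
  attr(out, "section_offset") <- as.integer(section_offset)
  attr(out, "design") <- design
  class(out) <- c("section_counts", class(out))
  out
}

filter_items <- function(points, item_filter) {
  if (is.null(item_filter) || nrow(points) == 0) return(points)
  keep <- rep(TRUE, nrow(points))
  for (field in c("cell_class", "marker", "compartment")) {
    if (!is.null(item_filter[[field]])) {
      keep <- keep & points[[field]] %in% item_filter[[field]]
    }
  }
  points[keep, , drop = FALSE]
}

spaceball_section_tally <- function(stack, s, sites, design, z_win) {
  fib <- stack$fibers
  if (is.null(fib) || nrow(sites) == 0) return(0L)
  fib <- fib[fib$section_index == s, , drop = FALSE]
  if (nrow(fib) == 0) return(0L)
  r <- design$ball_radius_um
  zc_site <- design$guard_um + design$disector_height_um / 2
  xlo <- pmin(fib$x1_um, fib$x2_um); xhi <- pmax(fib$x1_um, fib$x2_um)
  ylo <- pmin(fib$y1_um, fib$y2_um); yhi <- pmax(fib$y1_um, fib$y2_um)
  zlo <- pmin(fib$z1_um, fib$z2_um); zhi <- pmax(fib$z1_um, fib$z2_um)
  p1 <- cbind(fib$x1_um, fib$y1_um, fib$z1_um)
  p2 <- cbind(fib$x2_um, fib$y2_um, fib$z2_um)
  total <- 0L
  for (i in seq_len(nrow(sites))) {
    cx <- sites[i, 1]; cy <- sites[i, 2]
    near <- xhi >= cx - r & xlo <= cx + r &
            yhi >= cy - r & ylo <= cy + r &
            zhi >= z_win[1] & zlo < z_win[2]
    if (!any(near)) next
    total <- total + sum(intersect_fiber_sphere(
      p1[near, , drop = FALSE], p2[near, , drop = FALSE],
      c(cx, cy, zc_site), r, slab = z_win
    ))
  }
  total
}

#' Run the Cavalieri probe over a sectioned stack
#'
#' Samples every k-th section (random or given first section), point-counts
#' each sampled contour with an independently offset square grid, and
#' returns the volume estimate `d x a(p) x sum(P)` with its
#' Gundersen-Jensen coefficient of error, where `d = k x cut thickness`
#' and `a(p)` is the squared point spacing.
#'
#' @inheritParams run_probe
#' @param nugget Passed to [gundersen_ce()]; off by default for planimetric
#'   point counts.
#' @return An [estimate][new_estimate] of kind `"volume"` (um^3); the
#'   per-section counts are attached as `attr(, "counts")`.
#' @export
run_cavalieri <- function(stack, design, seed = NULL, section_offset = NULL,
                          n_vertices = 180, nugget = FALSE) {
  stopifnot(inherits(stack, "section_stack"), inherits(design, "sampling_design"))
  if (!is.null(seed)) set.seed(seed)
  k <- design$section_period
  if (is.null(section_offset)) section_offset <- sample.int(k, 1) - 1L
  sampled <- seq.int(section_offset, stack$n_sections - 1L, by = k)
  sp <- design$cavalieri_spacing_um
  counts <- vapply(sampled, function(s) {
    poly <- section_polygon(stack, s, n_vertices)
    point_count_section(poly, sp, offset = stats::runif(2, 0, sp))
  }, integer(1))
  est <- cavalieri_volume(
    counts,
    inter_section_distance_um = k * stack$cut_thickness_um,
    area_per_point_um2 = sp^2,
    nugget = nugget
  )
  attr(est, "counts") <- data.frame(section_index = as.integer(sampled), P = counts)
  attr(est, "section_offset") <- as.integer(section_offset)
  est
}
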