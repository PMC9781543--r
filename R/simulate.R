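# Synthetic tissue fields: homogeneous Poisson point processes for cell
# somata (with Bernoulli immunoreactivity-compartment labels) and isotropic
# line-segment processes for axonal fibers. Each simulated cell is reduced
# to a single representative point (the counting item); whether real counts
# target somata or nucleoli is a study-design question the simulator does
# not model.

COMPARTMENTS <- c("nuclear", "cytoplasmic", "both", "none")
CELL_CLASSES <- c("neuron", "astrocyte", "microglia")
MARKERS <- c("Abeta", "FN", "TDP43", "pNFP", "Iba1", "GFAP")

# n points uniform inside a region, by rejection from the bounding box.
uniform_points_in_region <- function(region, n) {
  bb <- region$bbox_um
  out <- matrix(numeric(0), ncol = 3)
  while (nrow(out) < n) {
    need <- n - nrow(out)
    # inflate by the box/region volume ratio to keep the loop short
    m <- ceiling(need * prod(bb[, 2] - bb[, 1]) / region$true_volume_um3 * 1.2) + 16
    cand <- cbind(
      stats::runif(m, bb[1, 1], bb[1, 2]),
      stats::runif(m, bb[2, 1], bb[2, 2]),
      stats::runif(m, bb[3, 1], bb[3, 2])
    )
    cand <- cand[point_in_region(region, cand), , drop = FALSE]
    out <- rbind(out, cand)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate a homogeneous Poisson neuron field with compartment labels
#'
#' Draws a homogeneous Poisson point process of the given intensity inside
#' the region and assigns each neuron an immunoreactivity compartment
#' (nuclear / cytoplasmic / both / none) i.i.d. from `label_probs`.
#'
#' @param region A [make_region()] object.
#' @param density_per_mm3 Expected number of neurons per mm^3 (>= 0).
#' @param label_probs Named numeric vector of probabilities over the four
#'   compartments; must sum to 1 (tolerance 1e-9). Missing names default
#'   to 0.
#' @param seed Integer seed; the draw is deterministic per seed.
#' @param marker Marker label recorded on the points (default `"Abeta"`).
#' @return A data.frame of marker points with columns `x_um`, `y_um`,
#'   `z_um`, `cell_class`, `marker`, `compartment`.
#' @examples
#' r <- make_region("toy", list(type = "ellipsoid", semi_axes_um = c(500, 400, 300)))
#' pts <- simulate_neuron_field(r, 5e4, c(nuclear = 0.7, none = 0.3), seed = 1)
#' @export
simulate_neuron_field <- function(region, density_per_mm3,
                                  label_probs = c(none = 1),
                                  seed = NULL, marker = "Abeta") {
  probs <- normalise_label_probs(label_probs)
  simulate_point_field(region, density_per_mm3, "neuron", marker, probs, seed)
}

#' Simulate a homogeneous Poisson glial field
#'
#' As [simulate_neuron_field()], but glial cells only carry cytoplasmic
#' immunoreactivity: the compartment is fixed to `"cytoplasmic"`.
#'
#' @inheritParams simulate_neuron_field
#' @param cell_class `"astrocyte"` or `"microglia"`.
#' @param marker Marker label; defaults to GFAP for astrocytes, Iba1 for
#'   microglia.
#' @return A marker-point data.frame (see [simulate_neuron_field()]).
#' @export
simulate_glia_field <- function(region, density_per_mm3,
                                cell_class = c("astrocyte", "microglia"),
                                seed = NULL, marker = NULL) {
  cell_class <- match.arg(cell_class)
  marker <- marker %||% switch(cell_class, astrocyte = "GFAP", microglia = "Iba1")
  simulate_point_field(
    region, density_per_mm3, cell_class, marker,
    c(nuclear = 0, cytoplasmic = 1, both = 0, none = 0), seed
  )
}

simulate_point_field <- function(region, density_per_mm3, cell_class, marker,
                                 probs, seed) {
  if (!is.numeric(density_per_mm3) || density_per_mm3 < 0) {
    stop_sf("bad_density", "density_per_mm3 must be >= 0")
  }
  if (!is.null(seed)) set.seed(seed)
  lambda_um3 <- density_per_mm3 / 1e9
  bb <- region$bbox_um
  n_cand <- stats::rpois(1, lambda_um3 * prod(bb[, 2] - bb[, 1]))
  xyz <- if (n_cand > 0) {
    cand <- cbind(
      stats::runif(n_cand, bb[1, 1], bb[1, 2]),
      stats::runif(n_cand, bb[2, 1], bb[2, 2]),
      stats::runif(n_cand, bb[3, 1], bb[3, 2])
    )
    cand[point_in_region(region, cand), , drop = FALSE]
  } else {
    matrix(numeric(0), ncol = 3)
  }
  n <- nrow(xyz)
  comp <- if (n > 0) {
    sample(COMPARTMENTS, n, replace = TRUE, prob = probs[COMPARTMENTS])
  } else {
    character(0)
  }
  data.frame(
    x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
    cell_class = rep(cell_class, n), marker = rep(marker, n),
    compartment = comp, stringsAsFactors = FALSE
  )
}

normalise_label_probs <- function(label_probs) {
  if (is.null(names(label_probs)) || !all(names(label_probs) %in% COMPARTMENTS)) {
    stop_sf("bad_enum", paste(
      "label_probs must be named with compartments:",
      paste(COMPARTMENTS, collapse = ", ")
    ))
  }
  probs <- stats::setNames(rep(0, 4), COMPARTMENTS)
  probs[names(label_probs)] <- as.numeric(label_probs)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    stop_sf("bad_probs", "label_probs must be non-negative and sum to 1 (tolerance 1e-9)")
  }
  probs
}

#' Simulate an isotropic fiber field of known length density
#'
#' Generates a stationary, isotropic line-segment process: segment
#' midpoints follow a homogeneous Poisson process with intensity
#' `Lv / segment_length_um`, orientations are uniform on the sphere, and
#' segments have constant length `segment_length_um`. Midpoints are drawn
#' in the region's bounding box dilated by half a segment length on every
#' axis, and each segment is clipped to the region, so the expected
#' in-region length per unit volume equals the target density with no edge
#' bias at the boundary.
#'
#' @param region A [make_region()] object of type `"ellipsoid"` (clipping
#'   uses the convexity of the ellipsoid).
#' @param length_density_m_per_mm3 Target length density, m/mm^3 (>= 0).
#' @param segment_length_um Constant segment length in micrometres (> 0).
#' @param seed Integer seed.
#' @param z_window Optional numeric length-2 vector: restricts generation to
#'   segments whose midpoint lies within `z_window` dilated by half a
#'   segment length. Because segments cannot reach further than half their
#'   length from their midpoint, the fiber material with z inside
#'   `z_window` has exactly the distribution of the full-region process --
#'   this is a computational marginalisation used when only a few sampled
#'   sections of a large region are probed.
#' @param dilate_um Enlarges the clip ellipsoid's semi-axes by this amount
#'   (micrometres). The default 0 clips segments to the region itself, so
#'   the total in-region length is the ground truth for the stated density.
#'   A positive dilation emulates a structure embedded in continuous
#'   fiber-bearing tissue: probes whose surface reaches past the traced
#'   contour (e.g. Spaceballs at boundary sites) then see a stationary
#'   field, as they would in a real section. Set it to at least the probe
#'   radius in that case.
#' @return A data.frame of fiber segments with columns `x1_um` ... `z2_um`
#'   and `length_um` (clipped length).
#' @export
simulate_fiber_field <- function(region, length_density_m_per_mm3,
                                 segment_length_um, seed = NULL,
                                 z_window = NULL, dilate_um = 0) {
  if (!is.numeric(length_density_m_per_mm3) || length_density_m_per_mm3 < 0) {
    stop_sf("bad_density", "length_density_m_per_mm3 must be >= 0")
  }
  if (!is.numeric(segment_length_um) || segment_length_um <= 0) {
    stop_sf("bad_length", "segment_length_um must be > 0")
  }
  if (region$type != "ellipsoid") {
    stop_sf("bad_shape", "fiber simulation requires an ellipsoid region")
  }
  if (!is.null(seed)) set.seed(seed)
  len <- segment_length_um
  lv_um2 <- length_density_m_per_mm3 / 1e3           # um / um^3
  lambda_mid <- lv_um2 / len                         # midpoints per um^3
  ax <- region$semi_axes_um + dilate_um
  ctr <- region$center_um
  bb <- cbind(ctr - ax, ctr + ax)
  lo <- bb[, 1] - len / 2
  hi <- bb[, 2] + len / 2
  if (!is.null(z_window)) {
    lo[3] <- max(lo[3], z_window[1] - len / 2)
    hi[3] <- min(hi[3], z_window[2] + len / 2)
    if (hi[3] <= lo[3]) {
      return(empty_fibers())
    }
  }
  n <- stats::rpois(1, lambda_mid * prod(hi - lo))
  if (n == 0) return(empty_fibers())
  mid <- cbind(
    stats::runif(n, lo[1], hi[1]),
    stats::runif(n, lo[2], hi[2]),
    stats::runif(n, lo[3], hi[3])
  )
  # isotropic directions: cos(theta) uniform on [-1, 1]
  u <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  d <- cbind(s * cos(phi), s * sin(phi), u)
  p1 <- mid - d * (len / 2)
  # clip [p1, p1 + len * d] to the (possibly dilated) ellipsoid -- a single
  # parameter interval by convexity
  q <- sweep(p1, 2, ctr)
  qs <- sweep(q, 2, ax, "/")
  ds <- sweep(d * len, 2, ax, "/")
  a <- rowSums(ds^2)
  b <- 2 * rowSums(qs * ds)
  cc <- rowSums(qs^2) - 1
  disc <- b^2 - 4 * a * cc
  keep <- disc > 0
  if (!any(keep)) return(empty_fibers())
  sq <- sqrt(disc[keep])
  t0 <- pmax((-b[keep] - sq) / (2 * a[keep]), 0)
  t1 <- pmin((-b[keep] + sq) / (2 * a[keep]), 1)
  ok <- t1 > t0
  t0 <- t0[ok]; t1 <- t1[ok]
  p1k <- p1[keep, , drop = FALSE][ok, , drop = FALSE]
  dk <- d[keep, , drop = FALSE][ok, , drop = FALSE] * len
  e1 <- p1k + dk * t0
  e2 <- p1k + dk * t1
  data.frame(
    x1_um = e1[, 1], y1_um = e1[, 2], z1_um = e1[, 3],
    x2_um = e2[, 1], y2_um = e2[, 2], z2_um = e2[, 3],
    length_um = sqrt(rowSums((e2 - e1)^2))
  )
}

empty_fibers <- function() {
  data.frame(
    x1_um = numeric(0), y1_um = numeric(0), z1_um = numeric(0),
    x2_um = numeric(0), y2_um = numeric(0), z2_um = numeric(0),
    length_um = numeric(0)
  )
}
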