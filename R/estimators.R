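# The scalar estimators: Gundersen-Jensen CE, Cavalieri volume, optical
# fractionator and Spaceballs length. Each returns an `estimate` object
# whose value is reproducible from its components by one multiplication.

#' Construct a stereological estimate
#'
#' An estimate carries its value, its coefficient of error, and the named
#' multiplicative components it was assembled from; the value is defined as
#' `prod(components)`, so it is always reproducible from the record by one
#' multiplication chain.
#'
#' @param components Named numeric vector whose product is the value.
#' @param ce Coefficient of error (relative standard error), or `NA` when
#'   undefined (zero total).
#' @param kind `"volume"`, `"number"` or `"length"`.
#' @param units Unit string of the value (e.g. `"um^3"`).
#' @return An object of class `"estimate"` with fields `value`, `ce`,
#'   `components`, `kind`, `units`.
#' @export
new_estimate <- function(components, ce, kind, units) {
  stopifnot(is.numeric(components), !is.null(names(components)))
  structure(
    list(
      value = prod(components), ce = ce,
      components = components, kind = kind, units = units
    ),
    class = "estimate"
  )
}

#' @export
print.estimate <- function(x, ...) {
  cat(sprintf(
    "<estimate: %s> %.6g %s (CE %s)\n  components: %s\n",
    x$kind, x$value, x$units,
    if (is.na(x$ce)) "undefined" else sprintf("%.4f", x$ce),
    paste(sprintf("%s = %.6g", names(x$components), x$components), collapse = ", ")
  ))
  invisible(x)
}

#' Gundersen-Jensen coefficient of error for systematic samples
#'
#' Computes the coefficient of error (relative standard error) of a total
#' obtained from systematically spaced per-section counts
#' \eqn{c_1, \dots, c_n}, from the covariogram terms
#' \eqn{A = \sum c_i^2}, \eqn{B = \sum c_i c_{i+1}},
#' \eqn{C = \sum c_i c_{i+2}}:
#' \deqn{Var_{SRS} = \frac{3(A - \nu) - 4B + C}{240}}
#' for smoothness class m = 1 (divisor 12 for m = 0), with the nugget
#' \eqn{\nu = \sum c_i} subtracted from A and added back to the variance
#' when `nugget = TRUE` (local Poisson counting noise, appropriate for
#' disector counts), and \eqn{\nu = 0} otherwise (planimetric point
#' counts). The CE is
#' \eqn{\sqrt{Var_{SRS} + \nu} / \sum c_i}.
#'
#' @param counts Non-negative per-section tallies in section order.
#' @param smoothness_m Smoothness class of the measurement function: 1
#'   (default, divisor 240) or 0 (divisor 12).
#' @param nugget Include the Poisson nugget term.
#' @return The coefficient of error (dimensionless).
#' @examples
#' gundersen_ce(c(10, 10, 10, 10))                 # 0.0228
#' gundersen_ce(c(10, 10, 10, 10), nugget = TRUE)  # 0.1588
#' @export
gundersen_ce <- function(counts, smoothness_m = 1, nugget = FALSE) {
  counts <- as.numeric(counts)
  if (length(counts) < 1) stop_sf("bad_counts", "counts must have length >= 1")
  if (any(counts < 0)) stop_sf("bad_counts", "counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop_sf("zero_total", "CE is undefined for an all-zero tally")
  A <- sum(counts^2)
  B <- if (length(counts) >= 2) sum(counts[-length(counts)] * counts[-1]) else 0
  C <- if (length(counts) >= 3) {
    n <- length(counts)
    sum(counts[1:(n - 2)] * counts[3:n])
  } else 0
  nu <- if (nugget) total else 0
  divisor <- if (smoothness_m == 1) 240 else 12
  var_srs <- (3 * (A - nu) - 4 * B + C) / divisor
  sqrt(max(var_srs, 0) + nu) / total
}

#' Cavalieri volume estimate from section point counts
#'
#' `V = d x a(p) x sum(P)`: inter-section distance times the area
#' associated with one grid point times the total number of grid points
#' hitting the structure across the systematically spaced sections.
#'
#' @param section_point_counts Per-section point counts P_i, in order.
#' @param inter_section_distance_um Distance d between sampled sections
#'   (section period x cut thickness), micrometres.
#' @param area_per_point_um2 Area per grid point a(p) (squared spacing),
#'   square micrometres.
#' @param nugget Passed to [gundersen_ce()] (off by default for
#'   planimetric counts).
#' @return An [estimate][new_estimate] of kind `"volume"` in um^3. An
#'   all-zero tally gives volume 0 with an undefined (`NA`) CE.
#' @examples
#' e <- cavalieri_volume(rep(38, 6), 1500, 4e6)
#' um3_to_mm3(e$value)
#' @export
cavalieri_volume <- function(section_point_counts, inter_section_distance_um,
                             area_per_point_um2, nugget = FALSE) {
  if (length(section_point_counts) == 0) {
    stop_sf("bad_counts", "section_point_counts must not be empty")
  }
  if (inter_section_distance_um <= 0 || area_per_point_um2 <= 0) {
    stop_sf("bad_design", "d and a(p) must be > 0")
  }
  total <- sum(section_point_counts)
  ce <- if (total > 0) {
    gundersen_ce(section_point_counts, smoothness_m = 1, nugget = nugget)
  } else {
    NA_real_
  }
  new_estimate(
    c(sum_P = total, d_um = inter_section_distance_um,
      area_per_point_um2 = area_per_point_um2),
    ce = ce, kind = "volume", units = "um^3"
  )
}

#' Optical fractionator estimate of total particle number
#'
#' `N = sum(Q) x (1/ssf) x (1/asf) x (1/tsf)`: the disector counts scaled
#' by the inverse section, area and thickness sampling fractions. The
#' thickness sampling fraction uses the mounted (post-processing)
#' thickness, the slab the disector actually sits in.
#'
#' @param section_Q_counts Per-section disector counts Q_i in section
#'   order, or a `section_counts` object from [run_probe()].
#' @param design A [sampling_design()].
#' @return An [estimate][new_estimate] of kind `"number"` (dimensionless).
#'   The CE is Gundersen-Jensen with the Poisson nugget; a zero total
#'   gives value 0 with `NA` CE.
#' @examples
#' optical_fractionator(rep(58, 14), ic_design())
#' @export
optical_fractionator <- function(section_Q_counts, design) {
  counts <- section_tallies(section_Q_counts)
  stopifnot(inherits(design, "sampling_design"))
  total <- sum(counts)
  ce <- if (total > 0) gundersen_ce(counts, smoothness_m = 1, nugget = TRUE) else NA_real_
  new_estimate(
    c(sum_Q = total, inv_ssf = 1 / design$ssf, inv_asf = 1 / design$asf,
      inv_tsf = 1 / design$tsf),
    ce = ce, kind = "number", units = "particles"
  )
}

#' Spaceballs estimate of total fiber length
#'
#' From the total number of transversal fiber crossings `sum(I)` over
#' `n_sites` sphere probes, the length density is
#' \eqn{L_v = 2 \Sigma I / (n \cdot S)} where `S` is the probe surface
#' per site: the sphere of radius r truncated to the optical-disector
#' slab, a spherical zone of area `2 pi r min(h, 2r)` (Archimedes'
#' hat-box). The total length is `Lv x reference volume`.
#'
#' @param section_I_counts Per-section crossing counts, or a
#'   `section_counts` object from [run_probe()].
#' @param design A [sampling_design()] (supplies r and h).
#' @param n_sites Total number of probe sites across the sampled sections
#'   (> 0); taken from the counts object when omitted.
#' @param reference_volume_um3 Reference volume the density is scaled by
#'   (um^3), typically the Cavalieri volume of the structure.
#' @return An [estimate][new_estimate] of kind `"length"` in um. The
#'   length density in m/mm^3 is retrievable as
#'   `lv_um2_to_m_per_mm3(prod(e$components[c("sum_I", "lv_factor")]))`.
#' @export
spaceballs_length <- function(section_I_counts, design, n_sites = NULL,
                              reference_volume_um3) {
  counts <- section_tallies(section_I_counts)
  stopifnot(inherits(design, "sampling_design"))
  if (is.null(n_sites) && inherits(section_I_counts, "section_counts")) {
    n_sites <- sum(section_I_counts$n_sites)
  }
  if (is.null(n_sites) || n_sites <= 0) {
    stop_sf("bad_design", "n_sites must be a positive count of probe sites")
  }
  if (reference_volume_um3 <= 0) {
    stop_sf("bad_design", "reference_volume_um3 must be > 0")
  }
  r <- design$ball_radius_um
  h <- design$disector_height_um
  S <- 2 * pi * r * min(h, 2 * r)
  total <- sum(counts)
  ce <- if (total > 0) gundersen_ce(counts, smoothness_m = 1, nugget = TRUE) else NA_real_
  new_estimate(
    c(sum_I = total, lv_factor = 2 / (n_sites * S),
      reference_volume_um3 = reference_volume_um3),
    ce = ce, kind = "length", units = "um"
  )
}

section_tallies <- function(x) {
  counts <- if (inherits(x, "section_counts")) x$tally else as.numeric(x)
  if (length(counts) == 0) stop_sf("bad_counts", "no per-section counts given")
  if (any(counts < 0)) stop_sf("bad_counts", "counts must be non-negative")
  counts
}
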