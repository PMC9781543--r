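# Turning estimates into reported quantities: densities, averaged
# multi-probe totals, immunoreactivity-compartment profiles, weighted and
# unweighted percentage summaries, shrinkage ratios and cross-specimen
# comparison tables.

#' Number (or length) density
#'
#' @param total Total count (or length in the unit of interest).
#' @param volume_mm3 Reference volume in mm^3 (> 0).
#' @return `total / volume_mm3`.
#' @examples
#' number_density(2299.47, 1362)  # 1.688 m/mm^3
#' @export
number_density <- function(total, volume_mm3) {
  if (!is.numeric(volume_mm3) || any(volume_mm3 <= 0)) {
    stop_sf("bad_volume", "volume_mm3 must be > 0")
  }
  total / volume_mm3
}

#' Average independent probe totals
#'
#' When several probes count the same population independently (e.g.
#' neuron probes for different markers that all tally non-immunoreactive
#' neurons too), their totals are averaged.
#'
#' @param estimates Numeric vector of totals, or a list of
#'   [estimate][new_estimate] objects.
#' @return A list with `mean`, `sd` (sample SD; `NA` for a single input)
#'   and `n`.
#' @export
combine_probe_totals <- function(estimates) {
  vals <- if (is.list(estimates)) {
    vapply(estimates, function(e) if (inherits(e, "estimate")) e$value else as.numeric(e),
           numeric(1))
  } else {
    as.numeric(estimates)
  }
  if (length(vals) == 0) stop_sf("bad_counts", "no estimates to combine")
  list(mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
       n = length(vals))
}

#' Immunoreactivity-compartment profile
#'
#' Empirical fractions of counted cells per immunoreactivity compartment
#' (nuclear / cytoplasmic / both / none).
#'
#' @param counted_markers Marker-point data.frame with a `compartment`
#'   column, or a character vector of compartment labels.
#' @return An object of class `"ir_profile"`: named `fractions` summing to
#'   1 and `n_counted`.
#' @export
ir_profile <- function(counted_markers) {
  comp <- if (is.data.frame(counted_markers)) {
    counted_markers$compartment
  } else {
    as.character(counted_markers)
  }
  if (length(comp) == 0) stop_sf("bad_counts", "no counted cells")
  bad <- setdiff(unique(comp), COMPARTMENTS)
  if (length(bad) > 0) {
    stop_sf("bad_enum", paste("unknown compartment label:", paste(bad, collapse = ", ")))
  }
  tab <- table(factor(comp, levels = COMPARTMENTS))
  fractions <- stats::setNames(as.numeric(tab) / length(comp), COMPARTMENTS)
  structure(
    list(fractions = fractions, n_counted = length(comp)),
    class = "ir_profile"
  )
}

#' @export
print.ir_profile <- function(x, ...) {
  cat(sprintf(
    "<ir_profile> n = %d: %s\n", x$n_counted,
    paste(sprintf("%s %.1f%%", names(x$fractions), 100 * x$fractions), collapse = ", ")
  ))
  invisible(x)
}

#' Population-weighted percentage
#'
#' Combines per-region percentages into a whole-structure percentage,
#' weighting by the regions' population sizes:
#' `sum(f_i w_i) / sum(w_i)`.
#'
#' @param fractions Per-region percentages (or fractions; any common scale).
#' @param weights Positive weights of equal length (population totals).
#' @param round Round half-up to the nearest integer (printed-style
#'   percentage); set `FALSE` for the raw value.
#' @return The combined percentage.
#' @examples
#' weighted_fraction(c(37, 30), c(4.85e6, 1.28e6))  # 36
#' @export
weighted_fraction <- function(fractions, weights, round = TRUE) {
  if (length(fractions) != length(weights)) {
    stop_sf("bad_counts", "fractions and weights must have equal length")
  }
  if (any(weights <= 0)) stop_sf("bad_counts", "weights must be positive")
  out <- sum(fractions * weights) / sum(weights)
  if (round) round_half_up(out) else out
}

#' Unweighted mean percentage
#'
#' @param fractions Per-region percentages.
#' @param round Round half-up to the nearest integer.
#' @return The mean percentage.
#' @examples
#' mean_fraction(c(67, 53, 55))  # 58
#' @export
mean_fraction <- function(fractions, round = TRUE) {
  if (length(fractions) == 0) stop_sf("bad_counts", "fractions must not be empty")
  out <- mean(fractions)
  if (round) round_half_up(out) else out
}

#' Shrinkage ratio of a processed volume to its in-situ reference
#'
#' Reports `100 x cavalieri / reference` percent, always in the direction
#' processed over reference (a fully preserved structure gives 100%), so
#' e.g. a Cavalieri estimate of 1362 mm^3 against an MRI volume of
#' 1775 mm^3 is 77%, not 130%.
#'
#' @param cavalieri_mm3 Volume estimated from processed sections (> 0).
#' @param reference_mm3 In-situ (e.g. MRI-derived) volume (> 0).
#' @param round Round half-up to the nearest integer percent.
#' @return Percentage.
#' @export
shrinkage_ratio <- function(cavalieri_mm3, reference_mm3, round = TRUE) {
  if (cavalieri_mm3 <= 0 || reference_mm3 <= 0) {
    stop_sf("bad_volume", "volumes must be > 0")
  }
  out <- 100 * cavalieri_mm3 / reference_mm3
  if (round) round_half_up(out) else out
}

#' Assemble a per-region report
#'
#' Gathers the estimates for one region into a single record; the density
#' is derived from the total and volume so that
#' `density x volume = total` holds exactly.
#'
#' @param name Region name.
#' @param total Estimated total cell number.
#' @param volume_mm3 Cavalieri (processed) volume, mm^3.
#' @param reference_volume_mm3 Optional in-situ (MRI) volume, mm^3.
#' @param ir_profiles Optional named list of [ir_profile()]s per marker.
#' @param length_m Optional total fiber length, metres.
#' @param ce Optional named numeric vector of CEs per estimate.
#' @param processing Tissue processing label (e.g. `"DPX"`,
#'   `"celloidin"`); comparisons across differing processing are flagged.
#' @param notes Character vector of caveats recorded with the report (e.g.
#'   source-value discrepancies), kept as metadata rather than silently
#'   resolved.
#' @return An object of class `"subnucleus_report"`.
#' @export
subnucleus_report <- function(name, total, volume_mm3,
                              reference_volume_mm3 = NA_real_,
                              ir_profiles = list(), length_m = NA_real_,
                              ce = numeric(0), processing = "DPX",
                              notes = character()) {
  if (volume_mm3 <= 0) stop_sf("bad_volume", "volume_mm3 must be > 0")
  structure(
    list(
      name = name, total = total, volume_mm3 = volume_mm3,
      reference_volume_mm3 = reference_volume_mm3,
      density_per_mm3 = number_density(total, volume_mm3),
      length_m = length_m,
      length_density_m_per_mm3 = if (is.na(length_m)) NA_real_ else
        number_density(length_m, volume_mm3),
      shrinkage_percent = if (is.na(reference_volume_mm3)) NA_real_ else
        shrinkage_ratio(volume_mm3, reference_volume_mm3, round = FALSE),
      ir_profiles = ir_profiles, ce = ce, processing = processing,
      notes = notes
    ),
    class = "subnucleus_report"
  )
}

#' @export
print.subnucleus_report <- function(x, ...) {
  cat(sprintf(
    "<subnucleus_report '%s'> total %.4g, volume %.4g mm^3, density %.4g /mm^3%s\n",
    x$name, x$total, x$volume_mm3, x$density_per_mm3,
    if (is.na(x$shrinkage_percent)) "" else
      sprintf(", %.0f%% of reference volume", x$shrinkage_percent)
  ))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Cross-specimen / cross-region comparison table
#'
#' Pairwise percentage ratios of totals, volumes and densities between
#' region reports, with a flag for pairs whose tissue processing differs
#' (e.g. DPX versus celloidin embedding), where ratios confound biology
#' with differential shrinkage.
#'
#' @param reports List of [subnucleus_report()]s (>= 2).
#' @return A data.frame with one row per ordered pair: `a`, `b`,
#'   `total_ratio_pct` (100 x total_a / total_b), `volume_ratio_pct`,
#'   `density_ratio_pct`, `processing_differs`.
#' @export
comparison_table <- function(reports) {
  stopifnot(length(reports) >= 2, all(vapply(reports, inherits, TRUE, "subnucleus_report")))
  pairs <- expand.grid(i = seq_along(reports), j = seq_along(reports))
  pairs <- pairs[pairs$i != pairs$j, ]
  rows <- lapply(seq_len(nrow(pairs)), function(p) {
    a <- reports[[pairs$i[p]]]; b <- reports[[pairs$j[p]]]
    data.frame(
      a = a$name, b = b$name,
      total_ratio_pct = 100 * a$total / b$total,
      volume_ratio_pct = 100 * a$volume_mm3 / b$volume_mm3,
      density_ratio_pct = 100 * a$density_per_mm3 / b$density_per_mm3,
      processing_differs = !identical(a$processing, b$processing)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
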