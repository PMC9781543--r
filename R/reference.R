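#' Reported reference values from the dolphin auditory-nuclei study
#'
#' The published quantitative results the package's defaults and worked
#' examples are checked against: MRI and Cavalieri volumes per specimen and
#' nucleus, neuron/glia totals and densities, axonal lengths and length
#' densities, and the immunoreactivity-compartment percentages per marker
#' and region, for the bottlenose dolphin inferior colliculus (central
#' nucleus CN and external cortex EC) and ventral cochlear nucleus (VCN).
#'
#' Two reported values are mutually inconsistent: the VCN neuron total
#' appears both as 3.16 million and as 316.38 thousand, and only the
#' latter is consistent with the reported VCN density (2455/mm^3) at the
#' reported Cavalieri volume (129 mm^3). The table carries 316.38 thousand
#' as the consistent value, with the discrepancy recorded in the `note`
#' column rather than silently dropped.
#'
#' @return A data.frame with columns `specimen`, `region`, `quantity`,
#'   `value`, `units`, `note`.
#' @examples
#' ref <- dolphin_reference_values()
#' subset(ref, quantity == "volume_cavalieri_mm3")
#' @export
dolphin_reference_values <- function() {
  row <- function(specimen, region, quantity, value, units, note = "") {
    data.frame(specimen = specimen, region = region, quantity = quantity,
               value = value, units = units, note = note)
  }
  out <- rbind(
    # volumes (MRI in situ vs Cavalieri from processed serial sections)
    row("Marine0142", "LIC", "volume_mri_mm3", 1775, "mm^3"),
    row("Marine0142", "LIC", "volume_cavalieri_mm3", 1362, "mm^3"),
    row("Marine0142", "LVCN", "volume_mri_mm3", 435, "mm^3"),
    row("Marine0142", "LVCN", "volume_cavalieri_mm3", 129, "mm^3",
        "intact rostral two-thirds only; caudal third missing"),
    row("Marine0116", "LIC", "volume_mri_mm3", 1345, "mm^3"),
    row("Marine0116", "LVCN", "volume_mri_mm3", 387, "mm^3"),
    row("Marine0116", "RIC", "volume_mri_mm3", 1451, "mm^3"),
    row("Marine0116", "RIC", "volume_cavalieri_mm3", 921, "mm^3"),
    row("Marine0116", "RVCN", "volume_mri_mm3", 378, "mm^3"),
    row("Marine0116", "RVCN", "volume_cavalieri_mm3", 285, "mm^3"),
    row("Dolphin2", "RIC", "volume_cavalieri_mm3", 571, "mm^3", "celloidin-embedded"),
    row("Dolphin2", "LVCN", "volume_cavalieri_mm3", 199, "mm^3", "celloidin-embedded"),
    # neuron totals and densities (averaged over the three neuron probes)
    row("Marine0142", "IC", "neurons_total", 6.13e6, "cells"),
    row("Marine0142", "IC", "neuron_density_per_mm3", 3313, "cells/mm^3"),
    row("Marine0142", "CN", "neurons_total", 4.85e6, "cells"),
    row("Marine0142", "CN", "neurons_total_sd", 754.58e3, "cells"),
    row("Marine0142", "CN", "neuron_density_per_mm3", 3561, "cells/mm^3"),
    row("Marine0142", "EC", "neurons_total", 1.28e6, "cells"),
    row("Marine0142", "EC", "neurons_total_sd", 159.71e3, "cells"),
    row("Marine0142", "EC", "neuron_density_per_mm3", 2621, "cells/mm^3"),
    row("Marine0142", "VCN", "neurons_total", 316.38e3, "cells",
        "also reported as 3.16 million; 316.38 thousand is consistent with density x volume"),
    row("Marine0142", "VCN", "neurons_total_sd", 102.19e3, "cells"),
    row("Marine0142", "VCN", "neuron_density_per_mm3", 2455, "cells/mm^3",
        "316380/129 = 2452.6 at printed precision"),
    row("Dolphin2", "CN", "neurons_total", 8.30e6, "cells", "celloidin-embedded"),
    row("Dolphin2", "EC", "neurons_total", 1.76e6, "cells", "celloidin-embedded"),
    row("Dolphin2", "VCN", "neurons_total", 2.15e6, "cells", "celloidin-embedded"),
    row("Human", "VCN", "neurons_total", 91.47e3, "cells", "healthy adult reference"),
    # amyloid-beta immunoreactivity percentages
    row("Marine0142", "CN", "Abeta_nuclear_pct", 71, "%"),
    row("Marine0142", "EC", "Abeta_nuclear_pct", 7, "%"),
    row("Marine0142", "IC", "Abeta_nuclear_pct", 56, "%"),
    row("Marine0142", "IC", "Abeta_both_pct", 14, "%"),
    row("Marine0142", "IC", "Abeta_cytoplasmic_pct", 0.9, "%"),
    row("Marine0142", "VCN", "Abeta_nuclear_pct", 18, "%"),
    row("Marine0142", "VCN", "Abeta_both_pct", 26, "%"),
    row("Marine0142", "VCN", "Abeta_cytoplasmic_pct", 4, "%"),
    # fibronectin percentages
    row("Marine0142", "CN", "FN_cytoplasmic_pct", 23, "%"),
    row("Marine0142", "EC", "FN_cytoplasmic_pct", 17, "%"),
    row("Marine0142", "VCN", "FN_cytoplasmic_pct", 18, "%"),
    row("Marine0142", "CN", "FN_both_pct", 14, "%"),
    row("Marine0142", "EC", "FN_both_pct", 13, "%"),
    row("Marine0142", "VCN", "FN_both_pct", 14, "%"),
    row("Marine0142", "IC", "FN_any_pct", 36, "%"),
    row("Marine0142", "VCN", "FN_any_pct", 32, "%"),
    # TDP-43 percentages
    row("Marine0142", "CN", "TDP43_nuclear_pct", 67, "%"),
    row("Marine0142", "EC", "TDP43_nuclear_pct", 53, "%"),
    row("Marine0142", "VCN", "TDP43_nuclear_pct", 55, "%"),
    row("Marine0142", "CN", "TDP43_both_pct", 17, "%"),
    row("Marine0142", "EC", "TDP43_both_pct", 26, "%"),
    row("Marine0142", "VCN", "TDP43_both_pct", 19, "%"),
    row("Marine0142", "CN", "TDP43_cytoplasmic_pct", 7, "%"),
    row("Marine0142", "EC", "TDP43_cytoplasmic_pct", 7, "%"),
    row("Marine0142", "VCN", "TDP43_cytoplasmic_pct", 8, "%"),
    row("Marine0142", "all", "TDP43_nuclear_pct", 58, "%", "mean over CN, EC, VCN"),
    row("Marine0142", "all", "TDP43_both_pct", 21, "%", "mean over CN, EC, VCN"),
    row("Marine0142", "all", "TDP43_cytoplasmic_pct", 7, "%", "mean over CN, EC, VCN"),
    # axonal length (pNFP, Spaceballs)
    row("Marine0142", "CN", "axon_length_m", 2299.47, "m"),
    row("Marine0142", "EC", "axon_length_m", 1058.09, "m"),
    row("Marine0142", "VCN", "axon_length_m", 195.31, "m"),
    row("Marine0142", "CN", "axon_length_density_m_per_mm3", 1.69, "m/mm^3"),
    row("Marine0142", "EC", "axon_length_density_m_per_mm3", 2.17, "m/mm^3"),
    row("Marine0142", "VCN", "axon_length_density_m_per_mm3", 1.52, "m/mm^3",
        "195.31/129 = 1.514 at printed precision"),
    # glia
    row("Marine0142", "CN", "microglia_total", 405.63e6, "cells"),
    row("Marine0142", "EC", "microglia_total", 316.30e6, "cells"),
    row("Marine0142", "VCN", "microglia_total", 39.36e6, "cells"),
    row("Marine0142", "CN", "microglia_density_per_mm3", 297.85e3, "cells/mm^3"),
    row("Marine0142", "EC", "microglia_density_per_mm3", 648.62e3, "cells/mm^3"),
    row("Marine0142", "VCN", "microglia_density_per_mm3", 305.44e3, "cells/mm^3"),
    row("Marine0142", "CN", "astrocyte_total", 717.04e6, "cells"),
    row("Marine0142", "EC", "astrocyte_total", 394.37e6, "cells"),
    row("Marine0142", "VCN", "astrocyte_total", 77.23e6, "cells"),
    row("Marine0142", "CN", "astrocyte_density_per_mm3", 526.51e3, "cells/mm^3"),
    row("Marine0142", "EC", "astrocyte_density_per_mm3", 808.72e3, "cells/mm^3"),
    row("Marine0142", "VCN", "astrocyte_density_per_mm3", 599.39e3, "cells/mm^3"),
    # shrinkage ratios (Cavalieri / MRI)
    row("Marine0142", "LIC", "cavalieri_over_mri_pct", 77, "%"),
    row("Marine0142", "LVCN", "cavalieri_over_mri_pct", 30, "%"),
    row("Marine0116", "RIC", "cavalieri_over_mri_pct", 84, "%",
        "not derivable from the tabulated volumes (921/1451 = 63.5%)"),
    row("Marine0116", "RVCN", "cavalieri_over_mri_pct", 75, "%")
  )
  rownames(out) <- NULL
  out
}

#' Look up one reference value
#'
#' @param region Region label in [dolphin_reference_values()].
#' @param quantity Quantity label.
#' @param specimen Specimen label (default `"Marine0142"`).
#' @return A single numeric value.
#' @export
reference_value <- function(region, quantity, specimen = "Marine0142") {
  ref <- dolphin_reference_values()
  hit <- ref$value[ref$specimen == specimen & ref$region == region &
                     ref$quantity == quantity]
  if (length(hit) != 1) {
    stop_sf("bad_enum", sprintf("no unique reference value for %s / %s / %s",
                                specimen, region, quantity))
  }
  hit
}
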