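#' Stereological sampling design
#'
#' Bundles every parameter of the sampling scheme: the section period (every
#' k-th section), cut and mounted thickness, the systematic random sampling
#' (SRS) grid, the counting frame, the optical-disector height and guard
#' zones, the Spaceball radius, and the Cavalieri point spacing.
#'
#' @param section_period Every k-th serial section is sampled (integer >= 1).
#' @param cut_thickness_um Cut section thickness, micrometres.
#' @param mounted_thickness_um Post-processing (mounted) thickness; the
#'   denominator of the thickness sampling fraction. Must accommodate the
#'   disector plus both guard zones.
#' @param grid_um SRS grid step `c(gx, gy)`, micrometres.
#' @param frame_um Counting frame `c(width, height)`, micrometres; must not
#'   exceed the grid componentwise.
#' @param disector_height_um Optical disector height h, micrometres.
#' @param guard_um Guard-zone thickness at top and bottom, micrometres.
#' @param ball_radius_um Spaceball radius, micrometres.
#' @param cavalieri_spacing_um Cavalieri point-grid spacing, micrometres.
#' @return An object of class `"sampling_design"` with derived sampling
#'   fractions `ssf` (1/k), `asf` (frame area / grid-cell area) and `tsf`
#'   (h / mounted thickness).
#' @seealso [ic_design()], [vcn_design()] for the designs used on the
#'   dolphin inferior colliculus and ventral cochlear nucleus.
#' @export
sampling_design <- function(section_period,
                            cut_thickness_um = 50,
                            mounted_thickness_um = 20,
                            grid_um = c(2000, 2000),
                            frame_um = c(150, 150),
                            disector_height_um = 18,
                            guard_um = 1,
                            ball_radius_um = 18,
                            cavalieri_spacing_um = 2000) {
  section_period <- as.integer(section_period)
  lens <- c(cut_thickness_um, mounted_thickness_um, grid_um, frame_um,
            disector_height_um, ball_radius_um, cavalieri_spacing_um)
  if (section_period < 1L) stop_sf("bad_design", "section_period must be >= 1")
  if (any(!is.finite(lens)) || any(lens <= 0) || guard_um < 0) {
    stop_sf("bad_design", "all design lengths must be positive (guard >= 0)")
  }
  if (disector_height_um + 2 * guard_um > mounted_thickness_um + 1e-9) {
    stop_sf("bad_design",
            "disector height plus both guard zones must fit in the mounted thickness")
  }
  if (any(frame_um > grid_um + 1e-9)) {
    stop_sf("bad_design", "counting frame must not exceed the grid componentwise")
  }
  structure(
    list(
      section_period = section_period,
      cut_thickness_um = cut_thickness_um,
      mounted_thickness_um = mounted_thickness_um,
      grid_um = as.numeric(grid_um),
      frame_um = as.numeric(frame_um),
      disector_height_um = disector_height_um,
      guard_um = guard_um,
      ball_radius_um = ball_radius_um,
      cavalieri_spacing_um = cavalieri_spacing_um,
      ssf = 1 / section_period,
      asf = prod(frame_um) / prod(grid_um),
      tsf = disector_height_um / mounted_thickness_um
    ),
    class = "sampling_design"
  )
}

#' @export
print.sampling_design <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<sampling_design> every %d-th section (%g um cut, %g um mounted)\n",
      "  grid %g x %g um, frame %g x %g um, disector %g um + %g um guards, ball r = %g um\n",
      "  ssf = %.4g, asf = %.4g, tsf = %.4g (overall fraction %.4g)\n"
    ),
    x$section_period, x$cut_thickness_um, x$mounted_thickness_um,
    x$grid_um[1], x$grid_um[2], x$frame_um[1], x$frame_um[2],
    x$disector_height_um, x$guard_um, x$ball_radius_um,
    x$ssf, x$asf, x$tsf, x$ssf * x$asf * x$tsf
  ))
  invisible(x)
}

#' Inferior colliculus sampling design
#'
#' Every 30th 50-um section (1500 um apart), 2000 x 2000 um SRS grid,
#' 18 um disector with 1 um guards in a 20 um mounted section, 18 um
#' Spaceball radius, 2000 um Cavalieri spacing. The neuron probes use a
#' 150 x 150 um counting frame, the glial probes 30 x 30 um.
#'
#' @param frame_um Counting frame, `c(150, 150)` by default.
#' @return A [sampling_design()].
#' @export
ic_design <- function(frame_um = c(150, 150)) {
  sampling_design(
    section_period = 30L, grid_um = c(2000, 2000), frame_um = frame_um,
    cavalieri_spacing_um = 2000
  )
}

#' Ventral cochlear nucleus sampling design
#'
#' Every 20th 50-um section (1000 um apart), 1000 x 1000 um SRS grid,
#' otherwise as [ic_design()]. The Cavalieri spacing is halved to keep the
#' total point count in the 150-250 range on this smaller structure.
#'
#' @param frame_um Counting frame, `c(150, 150)` by default.
#' @return A [sampling_design()].
#' @export
vcn_design <- function(frame_um = c(150, 150)) {
  sampling_design(
    section_period = 20L, grid_um = c(1000, 1000), frame_um = frame_um,
    cavalieri_spacing_um = 1000
  )
}
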