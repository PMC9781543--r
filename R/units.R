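# Unit conversions. Everything inside the package is micrometres; mm^3 and
# metres appear only at the reporting boundary, through these helpers.

#' Unit conversions between internal (micrometre) and reported units
#'
#' Internally every coordinate, length and volume is in micrometres (um,
#' um^2, um^3); reports use mm^3 for volumes, metres for fiber length and
#' m/mm^3 for length density. A length density of 1 um/um^3 (= um^-2)
#' equals 1000 m/mm^3.
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
um3_to_mm3 <- function(x) x / 1e9

#' @rdname units
#' @export
mm3_to_um3 <- function(x) x * 1e9

#' @rdname units
#' @export
um_to_m <- function(x) x / 1e6

#' @rdname units
#' @export
lv_um2_to_m_per_mm3 <- function(x) x * 1e3

#' Round half away from zero
#'
#' Printed-style percentages and densities use conventional half-up
#' rounding (2.5 -> 3), not R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(c(0.5, 1.5, 35.54))  # 1 2 36
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Signal a classed error so callers can distinguish failure modes.
# class_suffix becomes "stereofract_error_<suffix>".
stop_sf <- function(class_suffix, message, call = sys.call(-1)) {
  stop(errorCondition(
    message,
    class = c(paste0("stereofract_error_", class_suffix), "stereofract_error")
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
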