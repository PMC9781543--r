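# File formats: marker and fiber CSV (lossless round-trip at 1e-6 um),
# region-contour JSON, study configuration YAML, probe-result TSV and
# estimate JSON. Readers validate and raise classed errors naming the
# offending column, value or key.

MARKER_COLUMNS <- c("specimen", "region", "section_index",
                    "x_um", "y_um", "z_um", "cell_class", "marker", "compartment")
FIBER_COLUMNS <- c("section_index", "x1_um", "y1_um", "z1_um",
                   "x2_um", "y2_um", "z2_um")

#' Read and write marker-point CSV
#'
#' One row per counted cell: `specimen`, `region`, `section_index`,
#' `x_um`, `y_um`, `z_um`, `cell_class`, `marker`, `compartment`. Columns
#' are addressed by name, so any column order is accepted. Coordinates
#' round-trip losslessly to 1e-6 um. Missing columns, non-numeric
#' coordinates and unknown enum labels raise classed errors
#' (`stereofract_error_missing_column`, `stereofract_error_bad_coordinate`,
#' `stereofract_error_bad_enum`).
#'
#' @param path CSV file path.
#' @param points Marker-point data.frame (e.g. from
#'   [simulate_neuron_field()]); `specimen`, `region` and `section_index`
#'   are filled with defaults when absent.
#' @param specimen,region Defaults used by the writer when the data.frame
#'   lacks those columns.
#' @return `read_markers()`: a validated marker data.frame.
#'   `write_markers()`: `path`, invisibly.
#' @export
read_markers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MARKER_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop_sf("missing_column",
            paste("marker CSV is missing column(s):", paste(missing, collapse = ", ")))
  }
  for (col in c("x_um", "y_um", "z_um")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) && !all(is.na(df[[col]]))) {
      stop_sf("bad_coordinate", paste("non-numeric values in column", col))
    }
    if (anyNA(v)) stop_sf("bad_coordinate", paste("non-numeric values in column", col))
    df[[col]] <- v
  }
  check_enum(df$cell_class, CELL_CLASSES, "cell_class")
  check_enum(df$marker, MARKERS, "marker")
  check_enum(df$compartment, COMPARTMENTS, "compartment")
  df[, MARKER_COLUMNS]
}

check_enum <- function(values, allowed, field) {
  bad <- setdiff(unique(values), allowed)
  if (length(bad) > 0) {
    stop_sf("bad_enum", sprintf(
      "unknown %s value(s): %s (allowed: %s)",
      field, paste(bad, collapse = ", "), paste(allowed, collapse = ", ")
    ))
  }
  invisible(values)
}

#' @rdname read_markers
#' @export
write_markers <- function(points, path, specimen = "synthetic", region = "region") {
  df <- points
  if (is.null(df$specimen)) df$specimen <- specimen
  if (is.null(df$region)) df$region <- region
  if (is.null(df$section_index)) df$section_index <- NA_integer_
  df <- df[, MARKER_COLUMNS]
  utils::write.csv(format_coords(df, c("x_um", "y_um", "z_um")), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# print coordinates with enough significant digits for 1e-6 um round-trips
format_coords <- function(df, cols) {
  for (col in cols) df[[col]] <- formatC(df[[col]], format = "g", digits = 15)
  df
}

#' Read and write fiber-segment CSV
#'
#' One row per segment: `section_index` (NA for unsectioned fields) and
#' the two endpoints `x1_um` ... `z2_um`. Round-trips losslessly at
#' 1e-6 um.
#'
#' @param path CSV file path.
#' @param fibers Fiber data.frame (e.g. from [simulate_fiber_field()]).
#' @return `read_fibers()`: a fiber data.frame with a recomputed
#'   `length_um`; `write_fibers()`: `path`, invisibly.
#' @export
read_fibers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(FIBER_COLUMNS, "section_index"), names(df))
  if (length(missing) > 0) {
    stop_sf("missing_column",
            paste("fiber CSV is missing column(s):", paste(missing, collapse = ", ")))
  }
  for (col in setdiff(FIBER_COLUMNS, "section_index")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stop_sf("bad_coordinate", paste("non-numeric values in column", col))
    df[[col]] <- v
  }
  if (is.null(df$section_index)) df$section_index <- NA_integer_
  df$length_um <- sqrt((df$x2_um - df$x1_um)^2 + (df$y2_um - df$y1_um)^2 +
                       (df$z2_um - df$z1_um)^2)
  df[, c(FIBER_COLUMNS, "length_um")]
}

#' @rdname read_fibers
#' @export
write_fibers <- function(fibers, path) {
  df <- fibers
  if (is.null(df$section_index)) df$section_index <- NA_integer_
  df <- df[, FIBER_COLUMNS]
  utils::write.csv(format_coords(df, setdiff(FIBER_COLUMNS, "section_index")),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write region-contour JSON
#'
#' The contour file is a JSON object
#' `{"region": <name>, "units": "um", "sections": [...]}` where each
#' section holds `section_index`, `z_um` and `polygon` (an N x 2 array of
#' vertices in micrometres). Round-trips losslessly at 1e-6 um.
#'
#' @param path JSON file path.
#' @param contours A list with fields `region` and `sections` (list of
#'   lists with `section_index`, `z_um`, `polygon`).
#' @return `read_contours()`: the contour list with polygons as matrices;
#'   `write_contours()`: `path`, invisibly.
#' @export
read_contours <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$sections)) {
    stop_sf("missing_column", "contour JSON has no 'sections' field")
  }
  secs <- obj$sections
  if (is.data.frame(secs)) {
    secs <- lapply(seq_len(nrow(secs)), function(i) {
      list(section_index = secs$section_index[i], z_um = secs$z_um[i],
           polygon = matrix(unlist(secs$polygon[i]), ncol = 2))
    })
  } else {
    secs <- lapply(secs, function(s) {
      s$polygon <- matrix(unlist(s$polygon), ncol = 2)
      s
    })
  }
  list(region = obj$region, units = obj$units %||% "um", sections = secs)
}

#' @rdname read_contours
#' @export
write_contours <- function(contours, path) {
  obj <- list(
    region = contours$region %||% "region",
    units = "um",
    sections = lapply(contours$sections, function(s) {
      list(
        section_index = s$section_index, z_um = s$z_um,
        polygon = unname(as.matrix(s$polygon))
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a study configuration
#'
#' The YAML configuration gathers specimen metadata (`specimen: {id,
#' processing}`), one sampling design per region (`regions: <name>:
#' {design: {...}, reference_volume_mm3}`), shrinkage parameters and a
#' seed. Designs are instantiated through [sampling_design()], so
#' invalid probe geometry fails validation here. A missing required key
#' raises a `stereofract_error_config` error naming the key.
#'
#' @param path YAML file path.
#' @return A list with `specimen`, `regions` (each with a
#'   `sampling_design` and reference volume), `shrinkage` (a
#'   [shrinkage_model()]) and `seed`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("specimen", "regions")) {
    if (is.null(cfg[[key]])) {
      stop_sf("config", paste("study config is missing required key:", key))
    }
  }
  if (is.null(cfg$specimen$id)) {
    stop_sf("config", "study config is missing required key: specimen$id")
  }
  regions <- lapply(names(cfg$regions), function(nm) {
    rg <- cfg$regions[[nm]]
    if (is.null(rg$design)) {
      stop_sf("config", paste0("study config is missing required key: regions$", nm, "$design"))
    }
    if (is.null(rg$design$section_period)) {
      stop_sf("config", paste0("study config is missing required key: regions$",
                               nm, "$design$section_period"))
    }
    des <- do.call(sampling_design, rg$design)
    vol <- rg$reference_volume_mm3
    if (!is.null(vol) && vol <= 0) {
      stop_sf("config", paste0("regions$", nm, "$reference_volume_mm3 must be > 0"))
    }
    list(name = nm, design = des, reference_volume_mm3 = vol)
  })
  names(regions) <- names(cfg$regions)
  shr <- cfg$shrinkage %||% list()
  list(
    specimen = list(id = cfg$specimen$id,
                    processing = cfg$specimen$processing %||% "DPX"),
    regions = regions,
    shrinkage = shrinkage_model(
      xy_linear_factor = shr$xy_linear_factor %||% 1,
      z_collapse_factor = shr$z_collapse_factor %||% 1,
      truncation_fraction = shr$truncation_fraction %||% 0
    ),
    seed = as.integer(cfg$seed %||% 1L)
  )
}

#' Write probe counts as TSV and an estimate as JSON
#'
#' `write_section_counts()` writes the per-section tallies
#' (`section_index`, `n_sites`, `tally`); `write_estimate()` writes the
#' estimate record (`value`, `ce`, `kind`, `units`, `components`) so the
#' value is reproducible from the file by multiplying the components.
#'
#' @param counts A `section_counts` data.frame from [run_probe()].
#' @param estimate An [estimate][new_estimate].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_section_counts <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_section_counts
#' @export
write_estimate <- function(estimate, path) {
  jsonlite::write_json(
    list(
      value = estimate$value, ce = estimate$ce, kind = estimate$kind,
      units = estimate$units, components = as.list(estimate$components)
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Write the deterministic worked-example fixtures
#'
#' Generates the small fixtures the worked examples and tests run on: a
#' 1 mm^3 toy region holding exactly 1000 neurons with the central-nucleus
#' amyloid-beta label mix (`toy_markers.csv`), an isotropic fiber field at
#' 1.69 m/mm^3 in the same region (`toy_fibers.csv`), the published
#' reference-value table (`reference_values.tsv`) and an example study
#' configuration (`study_config.yaml`). All outputs are deterministic.
#'
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
make_fixtures <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_sf("io", paste("cannot create directory", out_dir))
  }
  r_um <- (3 / (4 * pi) * 1e9)^(1 / 3)  # sphere of exactly 1 mm^3
  region <- make_region("toy", list(type = "ellipsoid",
                                    semi_axes_um = rep(r_um, 3)))
  set.seed(20220692)
  xyz <- uniform_points_in_region(region, 1000)
  comp <- sample(COMPARTMENTS, 1000, replace = TRUE,
                 prob = c(0.71, 0.009, 0.14, 0.141))
  pts <- data.frame(
    x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
    cell_class = "neuron", marker = "Abeta", compartment = comp
  )
  fib <- simulate_fiber_field(region, 1.69, segment_length_um = 250,
                              seed = 20220693)
  files <- c(
    markers = file.path(out_dir, "toy_markers.csv"),
    fibers = file.path(out_dir, "toy_fibers.csv"),
    reference = file.path(out_dir, "reference_values.tsv"),
    config = file.path(out_dir, "study_config.yaml")
  )
  write_markers(pts, files[["markers"]], specimen = "synthetic", region = "toy")
  write_fibers(fib, files[["fibers"]])
  utils::write.table(dolphin_reference_values(), files[["reference"]],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(example_config_yaml(), files[["config"]])
  files
}

example_config_yaml <- function() {
  c(
    "specimen:",
    "  id: Marine0142",
    "  processing: DPX",
    "regions:",
    "  CN:",
    "    design:",
    "      section_period: 30",
    "      grid_um: [2000, 2000]",
    "      frame_um: [150, 150]",
    "      cavalieri_spacing_um: 2000",
    "    reference_volume_mm3: 1362",
    "  VCN:",
    "    design:",
    "      section_period: 20",
    "      grid_um: [1000, 1000]",
    "      frame_um: [150, 150]",
    "      cavalieri_spacing_um: 1000",
    "    reference_volume_mm3: 129",
    "shrinkage:",
    "  xy_linear_factor: 1.0",
    "  z_collapse_factor: 0.4",
    "  truncation_fraction: 0.0",
    "seed: 1"
  )
}
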