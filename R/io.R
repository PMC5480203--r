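# NIfTI-1 series I/O, configuration files, provenance.

#' Write a dynamic series to NIfTI-1
#'
#' Stores the image stack as a 4D NIfTI volume (row x col x 1 slice x time)
#' with the pixel spacing and frame interval in `pixdim`. Voxel data round-trip
#' bit-exactly (FLOAT64 storage).
#'
#' @param ds A `dynamic_series`, or a plain row x col x frame array (then
#'   `pixel_mm` and `tr_s` must be given).
#' @param path Output file (`.nii`).
#' @param pixel_mm,tr_s Spacing overrides for plain arrays.
#' @return `path`, invisibly.
#' @export
write_series <- function(ds, path, pixel_mm = NULL, tr_s = NULL) {
  if (inherits(ds, "dynamic_series")) {
    arr <- ds$series
    pixel_mm <- pixel_mm %||% ds$config$geometry$pixel_mm
    tr_s <- tr_s %||% ds$tr_s
  } else {
    arr <- ds
    if (is.null(pixel_mm) || is.null(tr_s)) {
      abort("pixel_mm and tr_s are required for plain arrays",
            class = "vsperf_invalid_input")
    }
  }
  stopifnot(length(dim(arr)) == 3)
  d <- dim(arr)
  vol <- array(arr, dim = c(d[1], d[2], 1, d[3]))
  img <- RNifti::asNifti(
    vol,
    reference = list(pixdim = c(-1, pixel_mm, pixel_mm, 1, tr_s, 0, 0, 0)),
    datatype = "double", internal = FALSE
  )
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a dynamic series from NIfTI-1
#'
#' @param path NIfTI file with a 2D+time or 3D(single-slice)+time image.
#' @return List: `series` (row x col x frame array), `pixel_mm`, `tr_s`.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "vsperf_io_error")
  }
  img <- tryCatch(RNifti::readNifti(path), error = function(e) {
    abort(paste0("malformed NIfTI file: ", path), class = "vsperf_io_error")
  })
  d <- dim(img)
  pd <- RNifti::pixdim(img)
  if (length(d) == 4 && d[3] == 1) {
    arr <- array(as.vector(img), dim = d[c(1, 2, 4)])
    tr <- pd[4]
  } else if (length(d) == 3) {
    # ambiguous 3D: treat third axis as time only if pixdim marks it temporal
    abort(paste0("expected a 4D (2D + time) image, got 3D: ", path),
          class = "vsperf_io_error")
  } else {
    abort(paste0("unsupported NIfTI dimensionality in ", path),
          class = "vsperf_io_error")
  }
  list(series = arr, pixel_mm = pd[1], tr_s = tr)
}

#' Write / read a label map as NIfTI-1
#'
#' @param labels Integer matrix.
#' @param path File path.
#' @return `path` invisibly / integer label matrix.
#' @export
write_labels <- function(labels, path) {
  img <- RNifti::asNifti(array(as.integer(labels), dim = c(dim(labels), 1)),
                         datatype = "int16")
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_labels
#' @param strict Error (rather than warn and round) on non-integer labels.
#' @export
read_labels <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "vsperf_io_error")
  }
  img <- RNifti::readNifti(path)
  m <- as.vector(img)
  if (any(m != round(m))) {
    if (strict) abort("label map contains non-integer values", class = "vsperf_io_error")
    warn("label map contains non-integer values; rounding")
    m <- round(m)
  }
  d <- dim(img)
  matrix(as.integer(m), d[1], d[2])
}

# ---- configuration ----------------------------------------------------------

config_schema <- function() {
  list(
    seed = "integer",
    output_dir = "character",
    protocol = c("mode", "flip_deg", "venc_cm_s", "n_frames", "noise_sigma",
                 "psf_fwhm_px", "coil_plane", "defect_sector",
                 "defect_flow_factor", "t2star_ms", "base_te_ms",
                 "rf_gap_overhead_ms"),
    geometry = c("matrix_size", "pixel_mm", "lv_radius_mm", "myo_inner_mm",
                 "myo_outer_mm", "rv_thickness_mm", "rv_span_deg", "insertion_deg"),
    flow = c("heart_rate_bpm", "lv_mean_cm_s", "lv_sd_cm_s", "myo_mean_cm_s",
             "myo_sd_cm_s", "rv_mean_cm_s", "rv_sd_cm_s", "trigger"),
    kinetics = c("a", "b", "c", "delay_s", "rv_lead_s", "mbf_ml_g_min",
                 "lambda_ml_g", "injection_delay_beats"),
    relaxation = c("t1_blood_s", "polarization"),
    analysis = c("modality", "prebolus_frames"),
    boundary_layer_frac = "numeric"
  )
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' Unknown keys are rejected before any computation. All fields are optional;
#' missing ones take package defaults. Units are embedded in key names
#' (e.g. `venc_cm_s`, `t1_blood_s`).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A validated nested list (class `run_config`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "vsperf_io_error")
  }
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  schema <- config_schema()
  bad_top <- setdiff(names(cfg), names(schema))
  if (length(bad_top)) {
    abort(paste0("unknown config keys: ", paste(bad_top, collapse = ", ")),
          class = "vsperf_config_error")
  }
  for (blk in intersect(names(cfg), names(schema))) {
    allowed <- schema[[blk]]
    if (is.list(cfg[[blk]])) {
      bad <- setdiff(names(cfg[[blk]]), allowed)
      if (length(bad)) {
        abort(paste0("unknown keys in config block '", blk, "': ",
                     paste(bad, collapse = ", ")),
              class = "vsperf_config_error")
      }
    }
  }
  structure(cfg, class = "run_config")
}

#' Assemble a phantom configuration from a run config
#'
#' @param cfg A `run_config` (or plain nested list).
#' @return A [phantom_config()].
#' @export
build_phantom_config <- function(cfg = list()) {
  call_with <- function(fn, args) do.call(fn, args %||% list())
  proto_args <- cfg$protocol %||% list()
  if (!is.null(cfg$seed)) proto_args$seed <- cfg$seed
  phantom_config(
    geometry = call_with(phantom_geometry, cfg$geometry),
    flow = call_with(flow_waveform, cfg$flow),
    kinetics = call_with(bolus_kinetics, cfg$kinetics),
    relaxation = call_with(relaxation_model, cfg$relaxation),
    protocol = call_with(acquisition_protocol, proto_args),
    boundary_layer_frac = cfg$boundary_layer_frac %||% 0.15
  )
}

#' Provenance record for a run
#'
#' @param config The configuration used (list).
#' @param seed The run seed.
#' @param files Named character vector of output paths; digests (md5) are
#'   recorded for those that exist.
#' @return A list (class `provenance_record`).
#' @export
provenance_record <- function(config, seed, files = character(0)) {
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  digests <- if (length(files)) {
    ex <- files[file.exists(files)]
    as.list(tools::md5sum(ex))
  } else list()
  structure(
    list(
      tool = "vsperf",
      version = as.character(utils::packageVersion("vsperf")),
      config_md5 = unname(tools::md5sum(cfg_file)),
      seed = seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      file_md5 = digests
    ),
    class = "provenance_record"
  )
}

write_provenance <- function(prov, path) {
  jsonlite::write_json(unclass(prov), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write sector curves to CSV
#'
#' One row per frame, one column per compartment, units in the header.
#'
#' @param curves A `sector_curves` tibble.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  wide <- tidyr::pivot_wider(as_tibble(curves), names_from = "compartment",
                             values_from = "signal")
  names(wide)[names(wide) == "time_s"] <- "time_s"
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Write perfusion metrics to JSON
#'
#' @param metrics A `perfusion_metrics` object.
#' @param path Output JSON.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  payload <- list(
    modality = metrics$modality,
    noise_sd = metrics$noise_sd,
    per_sector = metrics$per_sector,
    cov = metrics$cov,
    window_frames = range(metrics$window)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
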