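# Geometry and velocity sampling for the dynamic short-axis cardiac phantom.
#
# Label convention: 0 background, 1 LV blood pool, 2 RV blood pool,
# 3..8 myocardial AHA sectors 1..6. Sectors span 60 degrees each, starting at
# the anterior RV insertion, counterclockwise. Image arrays are row x column
# (row-major thinking, 0-based angles from the insertion).

LABEL_BG <- 0L
LABEL_LV <- 1L
LABEL_RV <- 2L
LABEL_SECTOR0 <- 2L   # sector k has label LABEL_SECTOR0 + k, k = 1..6

#' Short-axis phantom geometry
#'
#' A mid-ventricular short-axis slice: circular LV cavity, annular myocardium
#' divided into six sectors, and an RV crescent abutting the anterior/inferior
#' septum. Defaults emulate a porcine heart on a 110 x 110 mm field of view.
#'
#' @param matrix_size Image matrix (pixels per side).
#' @param pixel_mm Pixel spacing (mm).
#' @param lv_radius_mm LV cavity radius (mm).
#' @param myo_inner_mm,myo_outer_mm Myocardial annulus radii (mm);
#'   inner < outer.
#' @param rv_thickness_mm Radial thickness of the RV crescent (mm).
#' @param rv_span_deg Angular span of the RV crescent (degrees).
#' @param insertion_deg Anterior RV insertion angle (degrees, counterclockwise
#'   from the +x image axis).
#' @return A `phantom_geometry` list.
#' @export
phantom_geometry <- function(matrix_size = 64, pixel_mm = 110 / 64,
                             lv_radius_mm = 12, myo_inner_mm = 13,
                             myo_outer_mm = 22, rv_thickness_mm = 7,
                             rv_span_deg = 150, insertion_deg = 120) {
  if (myo_inner_mm >= myo_outer_mm) {
    abort("myocardial inner radius must be < outer radius", class = "vsperf_invalid_input")
  }
  fov_half <- matrix_size * pixel_mm / 2
  if (myo_outer_mm + rv_thickness_mm >= fov_half) {
    abort("geometry does not fit inside the image matrix", class = "vsperf_invalid_input")
  }
  structure(
    list(matrix_size = as.integer(matrix_size), pixel_mm = pixel_mm,
         lv_radius_mm = lv_radius_mm, myo_inner_mm = myo_inner_mm,
         myo_outer_mm = myo_outer_mm, rv_thickness_mm = rv_thickness_mm,
         rv_span_deg = rv_span_deg, insertion_deg = insertion_deg),
    class = "phantom_geometry"
  )
}

#' Build the compartment label map
#'
#' @param geometry A [phantom_geometry()].
#' @return Integer matrix (`matrix_size` square): 0 background, 1 LV, 2 RV,
#'   3-8 the six myocardial sectors of equal 60-degree extent starting at the
#'   anterior RV insertion, counterclockwise.
#' @export
#' @examples
#' labels <- build_label_map(phantom_geometry())
#' table(labels)
build_label_map <- function(geometry = phantom_geometry()) {
  g <- geometry
  if (g$myo_outer_mm - g$myo_inner_mm <= g$pixel_mm / 2) {
    abort("myocardial wall is too thin to rasterize any sector pixels",
          class = "vsperf_invalid_input")
  }
  n <- g$matrix_size
  ctr <- (n + 1) / 2
  ix <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  iy <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  x <- (ix - ctr) * g$pixel_mm
  y <- (ctr - iy) * g$pixel_mm                    # image row down = -y
  r <- sqrt(x^2 + y^2)
  theta <- (atan2(y, x) * 180 / pi) %% 360

  labels <- matrix(LABEL_BG, n, n)
  labels[r <= g$lv_radius_mm] <- LABEL_LV

  myo <- r >= g$myo_inner_mm & r <= g$myo_outer_mm
  rel <- (theta - g$insertion_deg) %% 360
  sector <- pmin(floor(rel / 60), 5) + 1L
  labels[myo] <- LABEL_SECTOR0 + sector[myo]

  # RV crescent: annulus hugging the epicardium over the septal span,
  # centered on the insertion going clockwise (toward the free wall)
  rv_r <- r >= g$myo_outer_mm + 0.5 & r <= g$myo_outer_mm + 0.5 + g$rv_thickness_mm
  rel_rv <- (g$insertion_deg - theta) %% 360
  labels[rv_r & rel_rv <= g$rv_span_deg & labels == LABEL_BG] <- LABEL_RV
  storage.mode(labels) <- "integer"
  labels
}

#' Per-compartment through-plane flow statistics
#'
#' Velocity statistics of the trigger phase. Defaults are early-systolic
#' values under dobutamine stress: LV 33.4 +/- 6.2 cm/s, myocardium
#' -0.82 +/- 5.2 cm/s; the RV distribution is a free parameter (not measured
#' in the source data) defaulting to 25 +/- 8 cm/s.
#'
#' @param heart_rate_bpm Heart rate (beats per minute).
#' @param lv_mean_cm_s,lv_sd_cm_s LV blood-pool velocity statistics (cm/s).
#' @param myo_mean_cm_s,myo_sd_cm_s Myocardial velocity statistics (cm/s);
#'   `|myo_mean|` should stay <= 7 cm/s.
#' @param rv_mean_cm_s,rv_sd_cm_s RV blood-pool velocity statistics (cm/s).
#' @param trigger `"early_systole"` or `"early_diastole"` (labels the phase;
#'   supply the matching statistics).
#' @return A `flow_waveform` list.
#' @export
flow_waveform <- function(heart_rate_bpm = 120,
                          lv_mean_cm_s = 33.4, lv_sd_cm_s = 6.2,
                          myo_mean_cm_s = -0.82, myo_sd_cm_s = 5.2,
                          rv_mean_cm_s = 25, rv_sd_cm_s = 8,
                          trigger = c("early_systole", "early_diastole")) {
  trigger <- match.arg(trigger)
  if (abs(myo_mean_cm_s) > 7) {
    warn("myocardial mean velocity beyond the +/- 7 cm/s range seen in vivo")
  }
  structure(
    list(heart_rate_bpm = heart_rate_bpm,
         lv_mean_cm_s = lv_mean_cm_s, lv_sd_cm_s = lv_sd_cm_s,
         myo_mean_cm_s = myo_mean_cm_s, myo_sd_cm_s = myo_sd_cm_s,
         rv_mean_cm_s = rv_mean_cm_s, rv_sd_cm_s = rv_sd_cm_s,
         trigger = trigger),
    class = "flow_waveform"
  )
}

#' Sample a per-pixel through-plane velocity map
#'
#' Draws pixelwise Gaussian velocities per compartment at the trigger phase,
#' with an optional laminar boundary layer tapering the LV velocity toward
#' zero at the endocardial wall (emulating slow trabecular flow).
#'
#' @param labels Label map from [build_label_map()].
#' @param waveform A [flow_waveform()].
#' @param seed Integer seed; fixed seed gives bit-identical maps.
#' @param geometry The geometry used for `labels` (needed for the boundary
#'   layer radius).
#' @param boundary_layer_frac Fraction of the LV cavity radius over which the
#'   mean LV velocity tapers linearly to zero at the wall; 0 disables.
#' @return Numeric matrix of velocities (cm/s), 0 in the background.
#' @export
sample_velocity_field <- function(labels, waveform = flow_waveform(), seed = 1L,
                                  geometry = phantom_geometry(),
                                  boundary_layer_frac = 0.15) {
  set.seed(as.integer(seed))
  n <- nrow(labels)
  v <- matrix(0, n, n)
  draw <- function(mask, mean, sd) {
    k <- sum(mask)
    if (k > 0) v[mask] <<- rnorm(k, mean, sd)
  }
  draw(labels == LABEL_LV, waveform$lv_mean_cm_s, waveform$lv_sd_cm_s)
  draw(labels == LABEL_RV, waveform$rv_mean_cm_s, waveform$rv_sd_cm_s)
  draw(labels >= LABEL_SECTOR0 + 1L, waveform$myo_mean_cm_s, waveform$myo_sd_cm_s)

  if (boundary_layer_frac > 0) {
    ctr <- (n + 1) / 2
    ix <- matrix(rep(seq_len(n), each = n), n, n)
    iy <- matrix(rep(seq_len(n), times = n), n, n)
    r <- sqrt(((ix - ctr))^2 + ((iy - ctr))^2) * geometry$pixel_mm
    lv <- labels == LABEL_LV
    edge <- geometry$lv_radius_mm
    taper <- pmin(1, pmax(0, (edge - r) / (edge * boundary_layer_frac)))
    v[lv] <- v[lv] * taper[lv]
  }
  v
}
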