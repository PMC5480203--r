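# Dynamic hyperpolarized image-series simulation.

#' Acquisition protocol
#'
#' @param mode `"velocity_selective"` (1-1 binomial tip-back, 2 x `flip_deg`)
#'   or `"conventional"` (single pulse of `2 * flip_deg`).
#' @param flip_deg Per-pulse flip angle for the binomial pair (degrees);
#'   conventional mode uses the equivalent single pulse `2 * flip_deg`.
#' @param venc_cm_s Encoding velocity (cm/s); ignored in conventional mode.
#' @param n_frames Number of frames (>= 20); one frame per heartbeat.
#' @param noise_sigma Rician noise level as a fraction of the peak noiseless
#'   conventional-mode LV signal (cross-mode comparable).
#' @param seed Integer seed; fixed seed gives bit-identical series.
#' @param psf_fwhm_px In-plane Gaussian point-spread FWHM (pixels) emulating
#'   the single-shot readout resolution; source of blood-pool spillover into
#'   adjacent myocardium. 0 disables.
#' @param coil_plane Optional length-3 numeric `c(intercept, slope_x, slope_y)`
#'   of a linear coil-sensitivity plane (per-pixel multiplier,
#'   `intercept + slope_x * col + slope_y * row`, indices centered); `NULL`
#'   for a flat coil.
#' @param defect_sector Optional sector index 1-6 with reduced flow.
#' @param defect_flow_factor Multiplier on MBF in the defect sector.
#' @param t2star_ms Effective T2* (ms) converting echo-time differences into
#'   attenuation.
#' @param base_te_ms,rf_gap_overhead_ms Echo-time model, see [te_penalty()].
#' @param limits [gradient_limits()] for the bipolar design.
#' @return An `acquisition_protocol` list.
#' @export
acquisition_protocol <- function(mode = c("velocity_selective", "conventional"),
                                 flip_deg = 30, venc_cm_s = 33.4, n_frames = 60,
                                 noise_sigma = 0.002, seed = 1L, psf_fwhm_px = 2,
                                 coil_plane = NULL, defect_sector = NULL,
                                 defect_flow_factor = 0.3, t2star_ms = 25,
                                 base_te_ms = 10.2, rf_gap_overhead_ms = 3.1,
                                 limits = gradient_limits()) {
  mode <- match.arg(mode)
  if (n_frames < 20) abort("n_frames must be >= 20", class = "vsperf_invalid_input")
  structure(
    list(mode = mode, flip_deg = flip_deg, venc_cm_s = venc_cm_s,
         n_frames = as.integer(n_frames), noise_sigma = noise_sigma,
         seed = as.integer(seed), psf_fwhm_px = psf_fwhm_px,
         coil_plane = coil_plane, defect_sector = defect_sector,
         defect_flow_factor = defect_flow_factor, t2star_ms = t2star_ms,
         base_te_ms = base_te_ms, rf_gap_overhead_ms = rf_gap_overhead_ms,
         limits = limits),
    class = "acquisition_protocol"
  )
}

#' Relaxation and polarization model
#'
#' @param t1_blood_s T1 of hyperpolarized urea in blood (s).
#' @param polarization Polarization at time of injection (fraction).
#' @return A `relaxation_model` list.
#' @export
relaxation_model <- function(t1_blood_s = 34, polarization = 0.29) {
  if (t1_blood_s <= 0) abort("T1 must be > 0", class = "vsperf_invalid_input")
  structure(list(t1_blood_s = t1_blood_s, polarization = polarization),
            class = "relaxation_model")
}

#' Full phantom configuration
#'
#' Bundles geometry, flow, kinetics, relaxation and the acquisition protocol.
#'
#' @param geometry [phantom_geometry()].
#' @param flow [flow_waveform()].
#' @param kinetics [bolus_kinetics()].
#' @param relaxation [relaxation_model()].
#' @param protocol [acquisition_protocol()].
#' @param boundary_layer_frac Trabecular boundary-layer fraction for
#'   [sample_velocity_field()].
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(geometry = phantom_geometry(), flow = flow_waveform(),
                           kinetics = bolus_kinetics(),
                           relaxation = relaxation_model(),
                           protocol = acquisition_protocol(),
                           boundary_layer_frac = 0.15) {
  structure(
    list(geometry = geometry, flow = flow, kinetics = kinetics,
         relaxation = relaxation, protocol = protocol,
         boundary_layer_frac = boundary_layer_frac),
    class = "phantom_config"
  )
}

# separable Gaussian blur, reflecting borders; fwhm in pixels
gaussian_blur <- function(img, fwhm_px) {
  if (fwhm_px <= 0) return(img)
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_idx <- function(i, n) pmin(pmax(i, 1L), n)
  n <- nrow(img)
  m <- ncol(img)
  conv1 <- function(x, along_rows) {
    out <- matrix(0, n, m)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      if (along_rows) {
        out <- out + k[j] * img[pad_idx(seq_len(n) + off, n), , drop = FALSE]
      } else {
        out <- out + k[j] * img[, pad_idx(seq_len(m) + off, m), drop = FALSE]
      }
    }
    out
  }
  img <- conv1(img, TRUE)
  n2 <- img
  out <- matrix(0, n, m)
  for (j in seq_along(k)) {
    off <- j - half - 1L
    out <- out + k[j] * n2[, pad_idx(seq_len(m) + off, m), drop = FALSE]
  }
  out
}

# per-pixel excitation amplitude (fraction of M0 -> transverse) and
# longitudinal survival factor for one shot, given pixel velocities
shot_factors <- function(v, protocol) {
  if (protocol$mode == "conventional") {
    a <- 2 * protocol$flip_deg * pi / 180
    list(transverse = matrix(sin(a), nrow(v), ncol(v)),
         survival = matrix(cos(a), nrow(v), ncol(v)))
  } else {
    list(transverse = bloch_transverse_v(v, protocol$venc_cm_s, protocol$flip_deg),
         survival = abs(bloch_longitudinal_v(v, protocol$venc_cm_s, protocol$flip_deg)))
  }
}

#' Simulate a dynamic first-pass image series
#'
#' Per frame n at time `t_n = (n - 1) * TR` from the start of imaging (itself
#' `injection_delay_beats` after injection): blood pixels carry the bolus
#' concentration times T1 decay, tissue pixels carry the one-compartment
#' tissue magnetization whose residue loses the per-shot longitudinal
#' survival factor each frame (fresh inflow enters undepleted; blood is fully
#' replaced in-slice between beats and accrues no depletion). Each pixel is
#' excited with its velocity's transverse amplitude, attenuated by
#' `exp(-TE / T2*)`, blurred by the readout point spread, optionally shaded by
#' a linear coil plane, and finally complex Gaussian noise is added before
#' taking the magnitude.
#'
#' @param config A [phantom_config()].
#' @return A `dynamic_series` list: `series` (row x col x frame array),
#'   `times_s`, `tr_s`, `labels`, `velocity`, `truth` (tibble of noiseless
#'   compartment mean curves: frame, time_s, compartment, signal), `config`.
#' @export
#' @examples
#' ser <- simulate_series(phantom_config(protocol = acquisition_protocol(n_frames = 20)))
#' dim(ser$series)
simulate_series <- function(config = phantom_config()) {
  g <- config$geometry
  pr <- config$protocol
  kin <- config$kinetics
  rel <- config$relaxation
  tr_s <- 60 / config$flow$heart_rate_bpm
  nfr <- pr$n_frames
  times <- (seq_len(nfr) - 1) * tr_s
  t_since_inj <- times + kin$injection_delay_beats * tr_s

  labels <- build_label_map(g)
  vel <- sample_velocity_field(labels, config$flow, seed = pr$seed, geometry = g,
                               boundary_layer_frac = config$boundary_layer_frac)
  sf <- shot_factors(vel, pr)
  te_ms <- if (pr$mode == "conventional") pr$base_te_ms else {
    te_penalty(pr$venc_cm_s, pr$limits, pr$base_te_ms, pr$rf_gap_overhead_ms)
  }
  te_fac <- exp(-te_ms / pr$t2star_ms)
  t1_fac <- exp(-t_since_inj / rel$t1_blood_s)

  # compartment concentration curves (no T1 / RF; those factor in below)
  aif_lv <- aif_concentration(times, kin)
  aif_rv <- aif_concentration(times, kin, delay_s = kin$delay_s - kin$rv_lead_s)
  mbf <- kin$mbf_ml_g_min
  if (!is.null(pr$defect_sector)) {
    mbf[pr$defect_sector] <- mbf[pr$defect_sector] * pr$defect_flow_factor
  }

  n <- g$matrix_size
  lv_mask <- labels == LABEL_LV
  rv_mask <- labels == LABEL_RV

  # tissue recursion per pixel: residue keeps washout x per-shot survival
  dt <- tr_s
  sector_of <- labels - LABEL_SECTOR0
  myo_mask <- sector_of >= 1 & sector_of <= 6
  mbf_px <- matrix(0, n, n)
  mbf_px[myo_mask] <- mbf[sector_of[myo_mask]] / 60   # 1/s
  wash_px <- exp(-mbf_px / kin$lambda_ml_g * dt)

  coil <- NULL
  if (!is.null(pr$coil_plane)) {
    ctr <- (n + 1) / 2
    ix <- matrix(rep(seq_len(n), each = n), n, n)
    iy <- matrix(rep(seq_len(n), times = n), n, n)
    coil <- pr$coil_plane[1] + pr$coil_plane[2] * (ix - ctr) + pr$coil_plane[3] * (iy - ctr)
  }

  set.seed(pr$seed + 1L)
  series <- array(0, dim = c(n, n, nfr))
  truth_rows <- vector("list", nfr)
  tissue_mag <- matrix(0, n, n)

  # noise scale: fraction of the peak noiseless conventional-mode LV signal
  conv_amp <- sin(2 * pr$flip_deg * pi / 180)
  conv_te_fac <- exp(-pr$base_te_ms / pr$t2star_ms)
  lv_peak_conv <- max(aif_lv * t1_fac) * rel$polarization * conv_amp * conv_te_fac
  sigma_abs <- pr$noise_sigma * lv_peak_conv

  for (i in seq_len(nfr)) {
    tissue_mag <- tissue_mag * wash_px * sf$survival + mbf_px * aif_lv[i] * dt
    mag <- matrix(0, n, n)
    mag[lv_mask] <- aif_lv[i]
    mag[rv_mask] <- aif_rv[i]
    mag[myo_mask] <- tissue_mag[myo_mask]
    img <- mag * rel$polarization * t1_fac[i] * sf$transverse * te_fac
    if (!is.null(coil)) img <- img * coil
    img <- gaussian_blur(img, pr$psf_fwhm_px)
    truth_rows[[i]] <- tibble(
      frame = i, time_s = times[i],
      compartment = c("lv", "rv", paste0("sector", 1:6)),
      signal = c(mean(img[lv_mask]), mean(img[rv_mask]),
                 vapply(1:6, function(s) mean(img[sector_of == s]), numeric(1)))
    )
    if (sigma_abs > 0) {
      re <- img + rnorm(n * n, 0, sigma_abs)
      im <- rnorm(n * n, 0, sigma_abs)
      img <- sqrt(re^2 + matrix(im, n, n)^2)
    }
    series[, , i] <- img
  }

  structure(
    list(series = series, times_s = times, tr_s = tr_s, labels = labels,
         velocity = vel, truth = bind_rows(truth_rows), config = config),
    class = "dynamic_series"
  )
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$series)
  cat(sprintf("dynamic_series: %d x %d pixels, %d frames (TR %.3f s), mode %s\n",
              d[1], d[2], d[3], x$tr_s, x$config$protocol$mode))
  invisible(x)
}

#' Simulate the flow-tube validation phantom
#'
#' A water tube in static gel: averages the relative excitation amplitude
#' over the tube cross-section (plug or parabolic profile with a boundary
#' layer tapering to zero at the wall) for each encoding velocity, weighted by
#' the echo-time-dependent T2* attenuation relative to conventional
#' excitation.
#'
#' @param mean_velocity_cm_s Mean tube velocity (cm/s), > 0.
#' @param venc_cm_s Encoding velocities to evaluate (cm/s).
#' @param profile `"plug"` or `"parabolic"`.
#' @param boundary_layer_frac Fraction of the tube radius over which a plug
#'   profile tapers linearly to zero at the wall.
#' @param t2star_ms,base_te_ms,rf_gap_overhead_ms,limits Echo-time model.
#' @param n_radial Radial integration points.
#' @return Tibble: `venc_cm_s`, `flow_signal_rel`, `static_signal_rel`
#'   (relative to conventional excitation of the same compartment).
#' @export
#' @examples
#' simulate_flow_phantom(48, venc_cm_s = c(24, 48))
simulate_flow_phantom <- function(mean_velocity_cm_s, venc_cm_s,
                                  profile = c("plug", "parabolic"),
                                  boundary_layer_frac = 0.1,
                                  t2star_ms = 25, base_te_ms = 10.2,
                                  rf_gap_overhead_ms = 3.1,
                                  limits = gradient_limits(), n_radial = 4000) {
  profile <- match.arg(profile)
  if (mean_velocity_cm_s <= 0) {
    abort("mean velocity must be > 0", class = "vsperf_invalid_input")
  }
  r <- (seq_len(n_radial) - 0.5) / n_radial   # normalized radius
  v <- if (profile == "plug") {
    core <- mean_velocity_cm_s
    ifelse(r <= 1 - boundary_layer_frac, core,
           core * (1 - r) / boundary_layer_frac)
  } else {
    # parabolic: peak 2 x mean at center
    2 * mean_velocity_cm_s * (1 - r^2)
  }
  purrr::map_dfr(venc_cm_s, function(ve) {
    te <- te_penalty(ve, limits, base_te_ms, rf_gap_overhead_ms)
    w <- exp(-(te - base_te_ms) / t2star_ms)
    s <- excitation_amplitude(v, ve)
    tibble(
      venc_cm_s = ve,
      flow_signal_rel = sum(s * r) / sum(r) * w,
      static_signal_rel = excitation_amplitude(0, ve) * w
    )
  })
}
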