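# Corrections and sector curve extraction.

#' Coil-sensitivity correction by plane fit
#'
#' Fits a least-squares plane to the myocardial signal of a reference frame
#' (prior to bolus passage for contrast data, after it for hyperpolarized
#' data) and divides the whole series by the plane, normalized to unit mean
#' over the mask, removing linear receive-coil shading.
#'
#' @param series Row x col x frame numeric array.
#' @param mask Logical matrix of myocardial pixels.
#' @param reference_frame Frame index used for the fit.
#' @return Corrected series array.
#' @export
plane_fit_correction <- function(series, mask, reference_frame) {
  stopifnot(length(dim(series)) == 3)
  if (sum(mask) < 3) {
    abort("mask must contain at least 3 pixels", class = "vsperf_fit_error")
  }
  n <- nrow(mask)
  m <- ncol(mask)
  ix <- matrix(rep(seq_len(m), each = n), n, m)
  iy <- matrix(rep(seq_len(n), times = m), n, m)
  df <- data.frame(z = series[, , reference_frame][mask], x = ix[mask], y = iy[mask])
  if (all(df$z == 0)) {
    abort("reference frame has zero myocardial signal", class = "vsperf_fit_error")
  }
  fit <- lm(z ~ x + y, data = df)
  if (any(is.na(coef(fit)))) {
    abort("degenerate mask: collinear pixels", class = "vsperf_fit_error")
  }
  plane <- coef(fit)[1] + coef(fit)[2] * ix + coef(fit)[3] * iy
  plane <- plane / mean(plane[mask])
  if (any(plane <= 0)) {
    abort("fitted sensitivity plane is not positive over the image",
          class = "vsperf_fit_error")
  }
  sweep(series, c(1, 2), plane, "/")
}

#' Extract per-sector and LV signal-time curves
#'
#' Means over each myocardial sector mask and the LV blood-pool mask per
#' frame, with a global magnitude-offset correction: for hyperpolarized data
#' the mean over the last 10 frames (post-bolus, noise only) is subtracted
#' per curve; for contrast data the mean over the pre-bolus frames is used.
#'
#' @param series Row x col x frame array.
#' @param labels Label map (see [build_label_map()]).
#' @param modality `"hyperpolarized"`, `"contrast"`, or `"none"` (no baseline
#'   subtraction).
#' @param prebolus_frames Frames counted as pre-bolus baseline for contrast
#'   data.
#' @param times_s Frame times (s); defaults to 0, 1, 2, ...
#' @return A tibble of class `sector_curves`: `frame`, `time_s`,
#'   `compartment` (`lv`, `sector1`..`sector6`), `signal`, plus attributes
#'   `modality` and `baseline` (the per-compartment subtracted offsets).
#' @export
extract_curves <- function(series, labels,
                           modality = c("hyperpolarized", "contrast", "none"),
                           prebolus_frames = 2,
                           times_s = seq_len(dim(series)[3]) - 1) {
  modality <- match.arg(modality)
  nfr <- dim(series)[3]
  if (modality == "hyperpolarized" && nfr < 10) {
    abort("need >= 10 trailing frames for the hyperpolarized baseline window",
          class = "vsperf_invalid_input")
  }
  if (modality == "contrast" && nfr < prebolus_frames) {
    abort("fewer frames than the pre-bolus baseline window",
          class = "vsperf_invalid_input")
  }
  stopifnot(length(times_s) == nfr, all(diff(times_s) > 0))
  comps <- c(lv = LABEL_LV, setNames(LABEL_SECTOR0 + 1:6, paste0("sector", 1:6)))
  masks <- lapply(comps, function(l) labels == l)
  if (any(vapply(masks, sum, integer(1)) == 0)) {
    abort("empty compartment mask", class = "vsperf_invalid_input")
  }
  raw <- vapply(masks, function(m) {
    vapply(seq_len(nfr), function(i) mean(series[, , i][m]), numeric(1))
  }, numeric(nfr))
  base_idx <- switch(modality,
    hyperpolarized = (nfr - 9):nfr,
    contrast = seq_len(prebolus_frames),
    none = integer(0)
  )
  baseline <- if (length(base_idx)) colMeans(raw[base_idx, , drop = FALSE]) else {
    setNames(rep(0, length(comps)), names(comps))
  }
  corr <- sweep(raw, 2, baseline, "-")
  out <- tibble(
    frame = rep(seq_len(nfr), times = length(comps)),
    time_s = rep(times_s, times = length(comps)),
    compartment = rep(names(comps), each = nfr),
    signal = as.vector(corr)
  )
  attr(out, "modality") <- modality
  attr(out, "baseline") <- baseline
  class(out) <- c("sector_curves", class(out))
  out
}
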