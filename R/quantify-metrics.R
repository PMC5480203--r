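# Semi-quantitative perfusion measures and cross-mode statistics.

#' Semi-quantitative perfusion measures from a fitted curve
#'
#' From a converged gamma-variate (or polynomial) fit: AUC (closed form
#' `a * c^(b+1) * Gamma(b+1)` for a gamma-variate covering the full pass,
#' numeric quadrature otherwise), pCNR (fitted peak / noise SD), and upslope
#' (maximum first derivative of the fitted curve between bolus arrival and the
#' peak).
#'
#' @param fit A `gamma_fit` or `poly_fit`.
#' @param noise_sd Noise standard deviation for pCNR (see [snr_series()]).
#' @param full_pass For gamma fits, use the closed-form full-pass AUC
#'   (default); otherwise integrate numerically over the window.
#' @return Tibble with `auc`, `pcnr`, `upslope`, `peak_value`,
#'   `peak_time_s`, `converged`.
#' @export
semi_quant_metrics <- function(fit, noise_sd = 1, full_pass = TRUE) {
  if (inherits(fit, "gamma_fit")) {
    if (!isTRUE(fit$converged)) {
      return(tibble(auc = NA_real_, pcnr = NA_real_, upslope = NA_real_,
                    peak_value = NA_real_, peak_time_s = NA_real_, converged = FALSE))
    }
    peak_t <- fit$t0_s + fit$b * fit$c
    peak_v <- fit$a * (fit$b * fit$c)^fit$b * exp(-fit$b)
    auc <- if (full_pass) gamma_auc(fit) else {
      w <- range(fit$times_s[fit$window])
      integrate(function(t) predict_gamma(fit, t), w[1], w[2],
                rel.tol = 1e-9)$value
    }
    tg <- seq(fit$t0_s, peak_t, length.out = 512)[-1]
    ts <- tg - fit$t0_s
    deriv <- fit$a * ts^(fit$b - 1) * exp(-ts / fit$c) * (fit$b - ts / fit$c)
    upslope <- max(deriv)
  } else if (inherits(fit, "poly_fit")) {
    w <- fit$times_s[fit$window]
    tg <- seq(min(w), max(w), length.out = 1024)
    yv <- predict_poly(fit, tg)
    ipk <- which.max(yv)
    peak_t <- tg[ipk]
    peak_v <- yv[ipk]
    auc <- pracma::trapz(tg, yv)
    cf <- fit$coefficients
    dy <- as.vector(outer(tg[seq_len(ipk)], 0:3, `^`) %*% (cf[2:5] * (1:4)))
    upslope <- max(dy)
  } else {
    abort("fit must be a gamma_fit or poly_fit", class = "vsperf_invalid_input")
  }
  tibble(auc = auc, pcnr = peak_v / noise_sd, upslope = upslope,
         peak_value = peak_v, peak_time_s = peak_t, converged = TRUE)
}

#' SNR by the difference-image method
#'
#' Mean signal over the mask divided by the noise SD estimated from the
#' difference of two signal-free frames: `sd(diff over mask) / sqrt(2)`
#' (the difference of two independent noise realizations carries twice the
#' noise variance).
#'
#' @param series Row x col x frame array.
#' @param mask Logical matrix of signal pixels.
#' @param signal_frames Frames whose mask mean forms the signal estimate.
#' @param noise_frames Length-2 frame indices of the noise pair (post-bolus
#'   for hyperpolarized data, pre-bolus for contrast).
#' @return List: `snr` (per signal frame), `noise_sd`.
#' @export
snr_series <- function(series, mask, signal_frames = seq_len(dim(series)[3]),
                       noise_frames = dim(series)[3] - c(1, 0)) {
  stopifnot(length(noise_frames) == 2)
  dimg <- series[, , noise_frames[1]] - series[, , noise_frames[2]]
  noise_sd <- sd(dimg[mask]) / sqrt(2)
  if (noise_sd == 0) abort("zero noise variance", class = "vsperf_invalid_input")
  snr <- vapply(signal_frames, function(i) mean(series[, , i][mask]), numeric(1)) / noise_sd
  list(snr = snr, noise_sd = noise_sd)
}

#' CNR from an SNR time curve
#'
#' Peak contrast-enhanced SNR minus the mean baseline SNR.
#'
#' @param snr_t SNR time curve.
#' @param baseline_frames Indices of baseline frames.
#' @return CNR (scalar).
#' @export
cnr <- function(snr_t, baseline_frames) {
  max(snr_t) - mean(snr_t[baseline_frames])
}

#' Cross-sector coefficient of variance
#'
#' Sample standard deviation divided by the mean, the homogeneity measure
#' over the six myocardial sectors.
#'
#' @param x Per-sector values.
#' @return CoV (fraction).
#' @export
#' @examples
#' sector_cov(c(1, 1, 1, 1, 1, 2))
sector_cov <- function(x) {
  m <- mean(x)
  if (m == 0) abort("zero mean: CoV undefined", class = "vsperf_invalid_input")
  sd(x) / m
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Exact two-sided paired Wilcoxon signed-rank test (exact distribution for
#' n <= 25 without ties). All-zero differences return p = 1 with a warning.
#'
#' @param a,b Equal-length paired samples, n >= 2.
#' @param alpha Significance level for the flag.
#' @return Tibble: `statistic`, `p_value`, `significant`, `n`.
#' @export
#' @examples
#' paired_compare(1:6, (1:6) + 1)   # p = 0.03125
paired_compare <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (all(d == 0)) {
    warn("all paired differences are zero; p = 1")
    return(tibble(statistic = NA_real_, p_value = 1, significant = FALSE,
                  n = length(a)))
  }
  ex <- length(a) <= 25 && !any(d == 0) && !any(duplicated(abs(d)))
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = ex))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         significant = wt$p.value < alpha, n = length(a))
}

#' Full semi-quantitative perfusion analysis of a sector curve set
#'
#' Fits each myocardial sector curve (gamma-variate for hyperpolarized data,
#' degree-4 polynomial for contrast data) over the first-pass window derived
#' from the LV curve and extracts AUC, pCNR and upslope, plus per-sector SNR
#' and CNR from the series and cross-sector CoV per metric.
#'
#' @param ds A `dynamic_series` (from [simulate_series()] or assembled from
#'   [read_series()] plus a label map), or `NULL` when `curves` is given
#'   directly.
#' @param curves A `sector_curves` tibble; extracted from `ds` when missing.
#' @param modality `"hyperpolarized"` (gamma-variate fits) or `"contrast"`
#'   (polynomial fits).
#' @param noise_frames Two frame indices used for the noise estimate;
#'   defaults to the last two frames (hyperpolarized) or first two
#'   (contrast).
#' @return A `perfusion_metrics` list: `per_sector` tibble (sector, auc,
#'   pcnr, upslope, peak_value, peak_time_s, snr_peak, cnr, converged),
#'   `cov` tibble (metric, cov), `noise_sd`, `window`, `fits`, `lv_fit`.
#' @export
perfusion_metrics <- function(ds = NULL, curves = NULL,
                              modality = c("hyperpolarized", "contrast"),
                              noise_frames = NULL) {
  modality <- match.arg(modality)
  if (is.null(curves)) {
    stopifnot(inherits(ds, "dynamic_series"))
    curves <- extract_curves(ds$series, ds$labels, modality = modality,
                             times_s = ds$times_s)
  }
  times <- curves$time_s[curves$compartment == "lv"]
  nfr <- length(times)
  lv <- curves$signal[curves$compartment == "lv"]
  if (is.null(noise_frames)) {
    noise_frames <- if (modality == "hyperpolarized") nfr - c(1, 0) else c(1, 2)
  }

  noise_sd <- NA_real_
  snr_peak <- rep(NA_real_, 6)
  cnr_val <- rep(NA_real_, 6)
  if (!is.null(ds)) {
    baseline_frames <- if (modality == "hyperpolarized") (nfr - 9):nfr else
      seq_len(max(2, noise_frames[2]))
    for (s in 1:6) {
      msk <- ds$labels == LABEL_SECTOR0 + s
      sn <- snr_series(ds$series, msk, noise_frames = noise_frames)
      snr_peak[s] <- max(sn$snr)
      cnr_val[s] <- cnr(sn$snr, baseline_frames)
      if (s == 1) noise_sd <- sn$noise_sd
    }
  } else {
    # noise SD from the trailing/leading baseline of the sector curves
    base_idx <- if (modality == "hyperpolarized") (nfr - 9):nfr else seq_len(2)
    noise_sd <- curves |>
      filter(.data$compartment != "lv", .data$frame %in% base_idx) |>
      dplyr::pull(.data$signal) |> sd()
  }

  window <- first_pass_window(lv, times)
  lv_fit <- if (modality == "hyperpolarized") {
    fit_gamma_variate(lv, times, window)
  } else NULL

  fits <- vector("list", 6)
  rows <- vector("list", 6)
  for (s in 1:6) {
    y <- curves$signal[curves$compartment == paste0("sector", s)]
    # extend the window end for the (later) myocardial pass
    myo_win0 <- first_pass_window(lv, times)
    f0 <- if (modality == "hyperpolarized") {
      fit_gamma_variate(y, times, myo_win0)
    } else NULL
    win <- first_pass_window(lv, times, myo_fit = f0)
    fit <- if (modality == "hyperpolarized") {
      fit_gamma_variate(y, times, win)
    } else {
      fit_polynomial4(y, times, win)
    }
    fits[[s]] <- fit
    m <- semi_quant_metrics(fit, noise_sd = noise_sd)
    rows[[s]] <- mutate(m, sector = s, snr_peak = snr_peak[s], cnr = cnr_val[s],
                        .before = 1)
  }
  per_sector <- bind_rows(rows)
  ok <- per_sector$converged
  cov_tbl <- tibble(
    metric = c("auc", "pcnr", "upslope"),
    cov = c(
      if (sum(ok) >= 2) sector_cov(per_sector$auc[ok]) else NA_real_,
      if (sum(ok) >= 2) sector_cov(per_sector$pcnr[ok]) else NA_real_,
      if (sum(ok) >= 2) sector_cov(per_sector$upslope[ok]) else NA_real_
    )
  )
  structure(
    list(per_sector = per_sector, cov = cov_tbl, noise_sd = noise_sd,
         window = window, fits = fits, lv_fit = lv_fit, modality = modality),
    class = "perfusion_metrics"
  )
}

#' @export
print.perfusion_metrics <- function(x, ...) {
  cat(sprintf("perfusion_metrics (%s): 6 sectors, noise SD %.4g\n", x$modality, x$noise_sd))
  print(x$per_sector, ...)
  cat("cross-sector CoV:\n")
  print(x$cov, ...)
  invisible(x)
}

#' @export
tidy.perfusion_metrics <- function(x, ...) x$per_sector

#' @export
glance.perfusion_metrics <- function(x, ...) {
  tidyr::pivot_wider(x$cov, names_from = "metric", values_from = "cov",
                     names_prefix = "cov_") |>
    mutate(noise_sd = x$noise_sd, n_converged = sum(x$per_sector$converged))
}
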