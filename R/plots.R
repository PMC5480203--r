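# ggplot2 quick-look methods.

#' @export
autoplot.excitation_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$velocity_cm_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$s_rel, colour = "excited (s)")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mz_rel, colour = "preserved (Mz)"),
                       linetype = "dashed") +
    ggplot2::facet_wrap(~venc_cm_s, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "through-plane velocity (cm/s)", y = "relative amplitude",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sector_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$signal,
                                       colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "signal (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dynamic_series <- function(object, frames = NULL, ...) {
  nfr <- dim(object$series)[3]
  if (is.null(frames)) frames <- unique(round(seq(1, nfr, length.out = 6)))
  df <- purrr::map_dfr(frames, function(i) {
    tibble(
      frame = i,
      row = rep(seq_len(nrow(object$series)), times = ncol(object$series)),
      col = rep(seq_len(ncol(object$series)), each = nrow(object$series)),
      value = as.vector(object$series[, , i])
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~frame, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "signal") +
    ggplot2::theme_void()
}

#' Plot fitted sector curves over the data
#'
#' @param metrics A `perfusion_metrics` object.
#' @param curves The `sector_curves` the metrics were computed from.
#' @return A ggplot.
#' @export
plot_sector_fits <- function(metrics, curves) {
  myo <- filter(as_tibble(curves), .data$compartment != "lv")
  fitted_df <- purrr::imap_dfr(metrics$fits, function(f, s) {
    tg <- seq(min(f$times_s), max(f$times_s), length.out = 200)
    yv <- if (inherits(f, "gamma_fit")) {
      if (!f$converged) return(NULL)
      predict_gamma(f, tg)
    } else predict_poly(f, tg)
    tibble(compartment = paste0("sector", s), time_s = tg, signal = yv)
  })
  ggplot2::ggplot(myo, ggplot2::aes(.data$time_s, .data$signal)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = fitted_df, colour = "red") +
    ggplot2::facet_wrap(~compartment) +
    ggplot2::labs(x = "time (s)", y = "signal (a.u.)") +
    ggplot2::theme_minimal()
}
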