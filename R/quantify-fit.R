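# Curve fitting: gamma-variate (hyperpolarized) and degree-4 polynomial
# (contrast) models of the first-pass signal.

#' Fit a three-parameter gamma-variate to a first-pass curve
#'
#' Nonlinear least squares of `s(t) = a * t^b * exp(-t/c)` (time measured from
#' `t0_s`) on the window, by Levenberg-Marquardt with positivity bounds
#' (`b <= 10`) and initialization from the log-linearization
#' `log s = log a + b log t - t/c`. Non-convergence is flagged, not thrown.
#'
#' @param curve Signal values.
#' @param times_s Times (s), same length.
#' @param window Integer indices of the first-pass window (default: all
#'   points); needs >= 6 points.
#' @param t0_s Bolus-arrival time origin (s); default the time of the last
#'   point at or below 5% of the window peak before the peak, falling back to
#'   the first window point.
#' @return A `gamma_fit` list: `a`, `b`, `c`, `t0_s`, `converged`, `residual`
#'   (RMS), `fitted` (on the window), `window`, `times_s`, `curve`.
#'   `peak_time_s = t0 + b*c` and `peak_value` are precomputed.
#' @export
#' @examples
#' t <- seq(0.25, 15, by = 0.25)
#' y <- 5 * t^3 * exp(-t / 0.8)
#' f <- fit_gamma_variate(y, t)
#' tidy(f)
fit_gamma_variate <- function(curve, times_s, window = seq_along(curve), t0_s = NULL) {
  stopifnot(length(curve) == length(times_s))
  if (length(window) < 6) {
    abort("first-pass window needs >= 6 points", class = "vsperf_invalid_input")
  }
  y <- curve[window]
  t <- times_s[window]
  failed <- function() {
    structure(list(a = NA_real_, b = NA_real_, c = NA_real_, t0_s = t0_s %||% t[1],
                   converged = FALSE, residual = NA_real_, fitted = rep(NA_real_, length(t)),
                   window = window, times_s = times_s, curve = curve),
              class = "gamma_fit")
  }
  if (max(y) <= 0 || all(y == y[1])) return(failed())
  if (is.null(t0_s)) {
    ipk <- which.max(y)
    low <- which(y[seq_len(ipk)] <= 0.05 * y[ipk])
    t0_s <- if (length(low)) t[max(low)] else t[1] - (t[2] - t[1])
  }
  tt <- t - t0_s
  pos <- tt > 0 & y > 0
  if (sum(pos) < 4) return(failed())
  init <- tryCatch({
    lf <- lm(log(y[pos]) ~ log(tt[pos]) + tt[pos])
    b0 <- max(min(unname(coef(lf)[2]), 9), 0.1)
    c0 <- if (coef(lf)[3] < 0) -1 / unname(coef(lf)[3]) else max(tt) / 3
    a0 <- exp(unname(coef(lf)[1]))
    c(a = a0, b = b0, c = c0)
  }, error = function(e) NULL)
  if (is.null(init) || any(!is.finite(init))) return(failed())
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * ifelse(tt > 0, tt, 0)^b * exp(-ifelse(tt > 0, tt, 0) / c),
      start = as.list(init),
      lower = c(a = 1e-12, b = 1e-3, c = 1e-6),
      upper = c(a = Inf, b = 10, c = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-8, ptol = 1e-8)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed())
  p <- coef(fit)
  structure(
    list(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["c"]), t0_s = t0_s,
         converged = TRUE,
         residual = sqrt(mean(residuals(fit)^2)),
         fitted = fitted(fit), window = window, times_s = times_s, curve = curve),
    class = "gamma_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a fitted gamma-variate
#'
#' @param fit A `gamma_fit`.
#' @param t_s Times (s).
#' @return Fitted signal values (0 before `t0_s`).
#' @export
predict_gamma <- function(fit, t_s) {
  tt <- t_s - fit$t0_s
  ifelse(tt > 0, fit$a * tt^fit$b * exp(-tt / fit$c), 0)
}

#' @export
tidy.gamma_fit <- function(x, ...) {
  tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c))
}

#' @export
glance.gamma_fit <- function(x, ...) {
  tibble(
    converged = x$converged, residual_rms = x$residual, t0_s = x$t0_s,
    peak_time_s = x$t0_s + x$b * x$c,
    peak_value = x$a * (x$b * x$c)^x$b * exp(-x$b),
    auc = gamma_auc(x)
  )
}

#' @export
print.gamma_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("gamma-variate fit: a = %.4g, b = %.4g, c = %.4g s (t0 = %.3g s), RMS %.3g\n",
                x$a, x$b, x$c, x$t0_s, x$residual))
  } else {
    cat("gamma-variate fit: did not converge\n")
  }
  invisible(x)
}

# closed-form area under the full gamma-variate pass
gamma_auc <- function(fit) fit$a * fit$c^(fit$b + 1) * gamma(fit$b + 1)

#' Fit a fourth-order polynomial to a first-pass curve
#'
#' Least-squares degree-4 polynomial over the window, the conventional model
#' for gadolinium contrast-enhancement curves.
#'
#' @inheritParams fit_gamma_variate
#' @return A `poly_fit` list: `coefficients` (increasing powers, intercept
#'   first), `fitted`, `window`, `times_s`, `curve`.
#' @export
fit_polynomial4 <- function(curve, times_s, window = seq_along(curve)) {
  stopifnot(length(curve) == length(times_s))
  if (length(window) < 5) {
    abort("need >= 5 points for a degree-4 fit", class = "vsperf_invalid_input")
  }
  t <- times_s[window]
  y <- curve[window]
  X <- outer(t, 0:4, `^`)
  qrX <- qr(X)
  if (qrX$rank < 5) {
    abort("rank-deficient design (degenerate time grid)", class = "vsperf_fit_error")
  }
  beta <- qr.coef(qrX, y)
  structure(
    list(coefficients = unname(beta), fitted = as.vector(X %*% beta),
         window = window, times_s = times_s, curve = curve),
    class = "poly_fit"
  )
}

#' @export
tidy.poly_fit <- function(x, ...) {
  tibble(term = paste0("t^", 0:4), estimate = x$coefficients)
}

#' Evaluate a fitted polynomial
#'
#' @param fit A `poly_fit`.
#' @param t_s Times (s).
#' @return Fitted values.
#' @export
predict_poly <- function(fit, t_s) {
  as.vector(outer(t_s, 0:4, `^`) %*% fit$coefficients)
}

#' First-pass analysis window
#'
#' Bolus arrival is the first frame where the LV curve exceeds 5 x its
#' baseline noise SD; the window ends at the later of the fitted myocardial
#' peak plus three time constants or the LV curve falling below 10% of its
#' peak.
#'
#' @param lv_curve LV blood-pool curve (baseline-corrected).
#' @param times_s Frame times (s).
#' @param baseline_sd Noise SD of the LV baseline; default estimated from the
#'   last 10 frames.
#' @param myo_fit Optional `gamma_fit` of a myocardial curve to extend the
#'   window end.
#' @return Integer vector of frame indices.
#' @export
first_pass_window <- function(lv_curve, times_s, baseline_sd = NULL, myo_fit = NULL) {
  n <- length(lv_curve)
  if (is.null(baseline_sd)) baseline_sd <- sd(tail(lv_curve, 10))
  thresh <- 5 * baseline_sd
  start <- which(lv_curve > thresh)[1]
  if (is.na(start)) start <- 1L
  ipk <- which.max(lv_curve)
  after <- which(lv_curve < 0.1 * lv_curve[ipk] & seq_len(n) > ipk)[1]
  end_lv <- if (is.na(after)) n else after
  end <- end_lv
  if (!is.null(myo_fit) && isTRUE(myo_fit$converged)) {
    t_end <- myo_fit$t0_s + myo_fit$b * myo_fit$c + 3 * myo_fit$c
    end <- max(end, which(times_s <= t_end) |> max())
  }
  seq.int(start, min(end, n))
}
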