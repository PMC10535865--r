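# Inversion of the uptake assay: from the three fluorescence levels
# (F_0 at drug addition, F_n at steady state, F_N after membrane
# permeabilization) to nuclear/cytosolic concentrations and the passive
# and active transport coefficients.

# net (background-subtracted) intensity at the drug-addition sample
f0_from_trace <- function(trace, conditions) {
  t0 <- trace$events$drug_added
  if (is.null(t0)) stop("event `drug_added` is missing from the trace")
  i0 <- which.min(abs(trace$times - t0))
  f0 <- trace$intensities[i0] - conditions$background
  if (f0 <= 0) stop("F0 (intensity at drug addition minus background) must be > 0")
  f0
}

window_mean <- function(trace, window) {
  sel <- trace$times >= window[1] & trace$times <= window[2]
  if (!any(sel)) stop("window [", window[1], ", ", window[2],
                      "] s lies outside the trace")
  mean(trace$intensities[sel])
}

# Plateau of the pre-permeabilization decay by fitting
# F = a + b*exp(-(t - t1)/tau) over the tail of the record. Falls back to
# the plain window mean when the fit fails or disagrees grossly with it
# (flat traces make the exponential unidentifiable).
plateau_extrapolate <- function(trace, t0, t_end_pre, window, f0,
                                floor_gross = -Inf) {
  mean_w <- window_mean(trace, window)
  t_start <- t0 + 0.4 * (t_end_pre - t0)
  sel <- trace$times >= t_start & trace$times <= t_end_pre
  tt <- trace$times[sel]
  ff <- trace$intensities[sel]
  if (length(tt) < 10) return(mean_w)
  a0 <- min(ff)
  b0 <- max(ff[1] - a0, 1e-6 * f0)
  tau0 <- (t_end_pre - t0) / 4
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    ff ~ a + b * exp(-(tt - t1) / tau),
    start = list(a = a0, b = b0, tau = tau0),
    data = list(tt = tt, ff = ff, t1 = tt[1]),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )), silent = TRUE)
  if (inherits(fit, "try-error")) return(mean_w)
  cf <- stats::coef(fit)
  a <- cf[["a"]]
  # a valid plateau of a decaying trace sits at or just below the
  # window mean and not below the fully-permeabilized level
  # (C_n <= C_N); anything else means the exponential was not
  # identified
  ok <- is.finite(a) && cf[["b"]] > 0 && cf[["tau"]] > 0 &&
    a <= mean_w + 0.005 * f0 && a >= max(floor_gross, 0)
  if (!ok) return(mean_w)
  a
}

#' Concentrations from the characteristic fluorescence levels
#'
#' Reads F_0, F_n and F_N off a trace and converts them to the
#' nuclear-bound drug concentration at steady state,
#' `C_n = C_T (F_0 - F_n)/F_0`, and after membrane permeabilization,
#' `C_N = C_T (F_0 - F_N)/F_0`. All intensities are background-subtracted.
#'
#' F_n is by default obtained by extrapolating the tail of the
#' pre-permeabilization decay to its plateau, which removes the residual
#' equilibration transient still present at the detergent step;
#' `method = "mean"` uses the plain mean over the steady-state window.
#' F_N is the mean over the post-permeabilization window (the last 90% of
#' the record after the detergent step). Concentrations are clamped to
#' `[0, C_T]` with a warning.
#'
#' @param trace a [fluorescence_trace()] with events `drug_added` and
#'   `steady_state_window` (and `permeabilization` for C_N).
#' @param conditions an [assay_conditions()] object.
#' @param method plateau estimator for F_n: `"extrapolate"` (default) or
#'   `"mean"`.
#' @return an object of class `kinetic_estimates`: list with `F0`, `Fn`,
#'   `FN`, `C_n`, `C_N` (NA when no permeabilization step) and `C_T`.
#' @export
concentrations_from_trace <- function(trace, conditions,
                                      method = c("extrapolate", "mean")) {
  stopifnot(inherits(trace, "fluorescence_trace"),
            inherits(conditions, "assay_conditions"))
  method <- match.arg(method)
  ev <- trace$events
  if (is.null(ev$drug_added)) stop("event `drug_added` is missing from the trace")
  if (is.null(ev$steady_state_window)) {
    stop("event `steady_state_window` is missing from the trace")
  }
  c_t <- conditions$total_drug
  bg <- conditions$background
  f0 <- f0_from_trace(trace, conditions)

  fN <- NA_real_
  if (!is.null(ev$permeabilization)) {
    tp <- ev$permeabilization
    t_max <- max(trace$times)
    if (t_max > tp) {
      wN <- c(tp + 0.1 * (t_max - tp), t_max)
      fN <- window_mean(trace, wN) - bg
    }
  }

  t_end_pre <- if (!is.null(ev$permeabilization)) ev$permeabilization else
    max(trace$times)
  fn_gross <- if (method == "extrapolate") {
    plateau_extrapolate(trace, ev$drug_added, t_end_pre,
                        ev$steady_state_window, f0,
                        floor_gross = if (is.na(fN)) -Inf else fN + bg)
  } else {
    window_mean(trace, ev$steady_state_window)
  }
  fn <- fn_gross - bg

  clamp <- function(x, what) {
    if (is.na(x)) return(x)
    if (x < 0 || x > c_t) {
      warning(sprintf("%s = %.4g nM outside [0, C_T]; clamped", what, x))
      x <- min(max(x, 0), c_t)
    }
    x
  }
  c_n <- clamp(c_t * (f0 - fn) / f0, "C_n")
  c_N <- clamp(c_t * (f0 - fN) / f0, "C_N")

  structure(list(F0 = f0, Fn = fn, FN = fN, C_n = c_n, C_N = c_N,
                 C_T = c_t),
            class = "kinetic_estimates")
}

#' @export
print.kinetic_estimates <- function(x, ...) {
  cat("<kinetic_estimates>\n")
  flds <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(flds)) {
    if (is.numeric(flds[[nm]])) {
      cat(sprintf("  %-8s %s\n", nm, format(signif(flds[[nm]], 4))))
    }
  }
  invisible(x)
}

#' Initial passive influx rate and permeation coefficient
#'
#' The initial uptake rate is read from the steepest decline of the
#' fluorescence after drug addition, `V_+ = (C_T/F_0) * max(-dF/dt)`;
#' the per-cell passive permeation coefficient is
#' `k_+ = V_+ / (C_T * rho)` with `rho` the cell density.
#'
#' Two estimators of the initial derivative are available.
#' `"exponential"` (default) fits `F = a + b exp(-(t - t0)/tau)` over
#' the influx window and evaluates the slope at drug addition,
#' `b/tau`; because the early decay of the transport model is
#' exponential to high accuracy, this uses every sample in the window
#' and is unbiased by noise. `"sliding"` is the classical steepest
#' sliding-window regression slope (sub-windows of `sub_window`
#' seconds); it needs no model but, being a maximum over noisy slope
#' estimates, is upward-biased and considerably noisier on sampled
#' data. The exponential fit falls back to the sliding estimator when
#' it cannot converge (e.g. a flat trace).
#'
#' @param trace a [fluorescence_trace()].
#' @param conditions an [assay_conditions()] object.
#' @param window influx window after drug addition (s).
#' @param sub_window width of the sliding regression sub-window (s).
#' @param method `"exponential"` or `"sliding"` (see Details).
#' @return list with `V_plus` (nM/s) and `k_plus` (L/cell/s).
#' @export
estimate_initial_influx <- function(trace, conditions, window = 300,
                                    sub_window = 20,
                                    method = c("exponential", "sliding")) {
  stopifnot(inherits(trace, "fluorescence_trace"),
            inherits(conditions, "assay_conditions"))
  method <- match.arg(method)
  if (window < sub_window) stop("`window` must be at least `sub_window`")
  t0 <- trace$events$drug_added
  if (is.null(t0)) stop("event `drug_added` is missing from the trace")
  sel <- trace$times >= t0 & trace$times <= t0 + window
  if (sum(sel) < 5) stop("fewer than 5 samples in the influx window")
  tt <- trace$times[sel]
  ff <- trace$intensities[sel]

  f0 <- f0_from_trace(trace, conditions)
  c_t <- conditions$total_drug

  steepest <- NA_real_
  if (method == "exponential") {
    span <- ff[1] - min(ff)
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      ff ~ a + b * exp(-(tt - t0) / tau),
      start = list(a = min(ff), b = max(span, 1e-6 * f0),
                   tau = (max(tt) - t0) / 3),
      data = list(tt = tt, ff = ff, t0 = t0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      cf <- stats::coef(fit)
      if (is.finite(cf[["tau"]]) && cf[["tau"]] > 0) {
        steepest <- cf[["b"]] / cf[["tau"]]
      }
    }
  }
  if (!is.finite(steepest)) {
    starts <- which(tt <= max(tt) - sub_window)
    if (!length(starts)) starts <- 1L
    slopes <- vapply(starts, function(i) {
      j <- which(tt >= tt[i] & tt <= tt[i] + sub_window)
      if (length(j) < 3) return(NA_real_)
      ls_slope(tt[j], ff[j])
    }, numeric(1))
    slopes <- slopes[is.finite(slopes)]
    if (!length(slopes)) stop("no usable regression sub-window in the trace")
    steepest <- max(-slopes)
  }

  if (steepest <= 1e-12 * f0) {
    warning("trace is flat over the influx window; V_plus = 0")
    steepest <- 0
  }
  v_plus <- (c_t / f0) * steepest
  list(V_plus = v_plus,
       k_plus = v_plus / (c_t * conditions$cell_density))
}

#' Active efflux rate and coefficient from steady-state levels
#'
#' Closes the estimation using the three measured fluorescence levels.
#' The cytosolic free concentration follows a linear intercalation
#' isotherm (bound/free ratio at steady state equals the bound/free
#' ratio after permeabilization): `C_i = C_n (C_T - C_N)/C_N`. The
#' extracellular free concentration is what is neither nuclear-bound nor
#' cytosolic, `C_e_ss = C_T - C_n - C_i`. At steady state net passive
#' influx balances the pump, so `V_a = k_+ rho (C_e_ss - C_i)` and
#' `k_a = V_a / (C_i rho)`.
#'
#' @param est a `kinetic_estimates` object from
#'   [concentrations_from_trace()] (needs `C_n`, `C_N`, `C_T`).
#' @param conditions an [assay_conditions()] object.
#' @param k_plus passive permeation coefficient (L/cell/s), e.g. from
#'   [estimate_initial_influx()].
#' @return the input estimates extended with `C_i`, `C_e_ss` (nM),
#'   `V_a` (nM/s), `k_a` (L/cell/s) and `k_plus`.
#' @export
estimate_active_efflux <- function(est, conditions, k_plus) {
  stopifnot(inherits(est, "kinetic_estimates"),
            inherits(conditions, "assay_conditions"))
  check_finite(k_plus, "k_plus")
  if (is.na(est$C_N) || is.null(est$C_N)) {
    stop("C_N unavailable (no permeabilization step); ",
         "active-efflux estimation is impossible")
  }
  if (est$C_N <= 0) {
    stop("C_N must be > 0 for active-efflux estimation")
  }
  rho <- conditions$cell_density
  c_t <- est$C_T
  c_i <- est$C_n * (c_t - est$C_N) / est$C_N
  c_e <- c_t - est$C_n - c_i
  v_a <- k_plus * rho * (c_e - c_i)
  if (c_i <= 0) {
    if (v_a > 1e-8 * c_t) {
      stop("degenerate trace: C_i = 0 with V_a > 0")
    }
    k_a <- 0
  } else {
    k_a <- v_a / (c_i * rho)
  }
  est$C_i <- c_i
  est$C_e_ss <- c_e
  est$V_a <- v_a
  est$k_a <- k_a
  est$k_plus <- k_plus
  est
}

#' P-gp inhibition ratio
#'
#' Ratio `r = k_a(inhibited) / k_a(control)` of the active efflux
#' coefficients with and without the modulator: 1 means no inhibition of
#' active efflux, 0 means the pump is completely blocked.
#'
#' @param k_a_inhibited active efflux coefficient under the inhibitor
#'   (L/cell/s).
#' @param k_a_control control active efflux coefficient (> 0).
#' @return an object of class `inhibition_result` with fields
#'   `k_a_control`, `k_a_inhibited`, `ratio`.
#' @examples
#' inhibition_ratio(1.06e-9, 2.9e-9)$ratio  # ~0.366
#' @export
inhibition_ratio <- function(k_a_inhibited, k_a_control) {
  check_finite(k_a_inhibited, "k_a_inhibited")
  check_finite(k_a_control, "k_a_control")
  if (k_a_control <= 0) stop("`k_a_control` must be > 0")
  structure(list(k_a_control = k_a_control,
                 k_a_inhibited = k_a_inhibited,
                 ratio = k_a_inhibited / k_a_control),
            class = "inhibition_result")
}

#' @export
print.inhibition_result <- function(x, ...) {
  cat(sprintf("<inhibition_result> r = k_a(i)/k_a(0) = %.4g\n", x$ratio))
  invisible(x)
}

#' Full kinetic analysis of one uptake trace
#'
#' Convenience wrapper chaining [concentrations_from_trace()],
#' [estimate_initial_influx()] and [estimate_active_efflux()].
#'
#' @inheritParams concentrations_from_trace
#' @inheritParams estimate_initial_influx
#' @return a complete `kinetic_estimates` object.
#' @export
fit_efflux_kinetics <- function(trace, conditions, window = 300,
                                sub_window = 20,
                                method = c("extrapolate", "mean")) {
  est <- concentrations_from_trace(trace, conditions, method = method)
  infl <- estimate_initial_influx(trace, conditions, window = window,
                                  sub_window = sub_window)
  est$V_plus <- infl$V_plus
  estimate_active_efflux(est, conditions, k_plus = infl$k_plus)
}
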