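# Forward model of pirarubicin (THP) uptake in a stirred cell suspension,
# observed through quenching of THP fluorescence on DNA intercalation.
#
# Three solution-volume-referred pools (nM): extracellular free drug C_e,
# cytosolic free drug C_c and nuclear-intercalated drug C_n.
#   dC_e/dt = -k_plus*rho*(C_e - C_c) + k_act*rho*C_c
#   dC_c/dt =  k_plus*rho*(C_e - C_c) - k_act*rho*C_c
#              - k_on*C_c*(B_max - C_n) + k_off*C_n
#   dC_n/dt =  k_on*C_c*(B_max - C_n) - k_off*C_n
# Passive permeation is symmetric, the pump acts on cytosolic free drug,
# and nuclear intercalation is a saturable (Langmuir) binding site.
# Fluorescence tracks total unquenched drug: F = bg + s*(C_T - C_n)/C_T.
#
# The detergent (permeabilization) step removes the membrane barrier:
# from then on the free drug forms a single well-stirred pool C_f =
# C_e + C_c that equilibrates with the nuclear binding site (no pump).

#' Conditions of a fluorescence uptake assay
#'
#' Describes one spectrofluorometric transport experiment: total drug in
#' the cuvette, cell load, and the inhibitor applied (if any). Defaults
#' follow the standard protocol for K562/ADR cells: 1 uM THP added to
#' 2e6 cells in 2 mL.
#'
#' @param total_drug total drug concentration C_T in nM (> 0).
#' @param n_cells number of cells in the cuvette (> 0).
#' @param solution_volume cuvette volume in litres (> 0).
#' @param background instrument background fluorescence (arbitrary units).
#' @param inhibitor label of the efflux modulator ("none" for control).
#' @param inhibitor_conc modulator concentration in ug/mL (0 = control).
#' @return an object of class `assay_conditions`; `cell_density` (cells/L)
#'   is derived as `n_cells / solution_volume`.
#' @export
assay_conditions <- function(total_drug = 1000, n_cells = 2e6,
                             solution_volume = 2e-3, background = 5,
                             inhibitor = "none", inhibitor_conc = 0) {
  check_finite(total_drug, "total_drug")
  check_finite(n_cells, "n_cells")
  check_finite(solution_volume, "solution_volume")
  check_finite(background, "background")
  if (total_drug <= 0) stop("`total_drug` must be > 0")
  if (n_cells <= 0) stop("`n_cells` must be > 0")
  if (solution_volume <= 0) stop("`solution_volume` must be > 0")
  structure(list(
    total_drug = total_drug,
    n_cells = n_cells,
    solution_volume = solution_volume,
    cell_density = n_cells / solution_volume,
    background = background,
    inhibitor = inhibitor,
    inhibitor_conc = inhibitor_conc
  ), class = "assay_conditions")
}

#' Ground-truth transport parameters of the uptake model
#'
#' Per-cell permeation and efflux coefficients plus the nuclear binding
#' site. Defaults place the system in the regime of the published assay:
#' rate constants `k * cell_density` of a few 1e-3 per second (steady
#' state reached by ~1600 s), an active/passive ratio of ~2, and a
#' near-linear intercalation isotherm (B_max >> steady-state C_n).
#'
#' @param k_plus passive permeation coefficient, L/cell/s (>= 0).
#' @param k_act active P-gp efflux coefficient, L/cell/s (>= 0).
#' @param k_on nuclear binding on-rate, 1/(nM s) (>= 0).
#' @param k_off nuclear unbinding rate, 1/s (>= 0).
#' @param b_max nuclear binding capacity, nM referred to solution
#'   volume (> 0).
#' @return an object of class `transport_params`.
#' @export
transport_params <- function(k_plus = 3e-12, k_act = 6e-12,
                             k_on = 1e-3, k_off = 0.6, b_max = 3e4) {
  for (nm in c("k_plus", "k_act", "k_on", "k_off", "b_max")) {
    check_finite(get(nm), nm)
  }
  if (k_plus < 0 || k_act < 0 || k_on < 0 || k_off < 0) {
    stop("rates must be >= 0")
  }
  if (b_max <= 0) stop("`b_max` must be > 0")
  structure(list(k_plus = k_plus, k_act = k_act, k_on = k_on,
                 k_off = k_off, b_max = b_max),
            class = "transport_params")
}

#' Construct a fluorescence-time trace
#'
#' @param times sample times in seconds, strictly increasing.
#' @param intensities fluorescence intensities (arbitrary units, >= 0).
#' @param events named list of assay markers: `drug_added` (s),
#'   `steady_state_window` (length-2 interval, s) and optionally
#'   `permeabilization` (s).
#' @return an object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(times, intensities, events = list()) {
  check_finite(times, "times")
  check_finite(intensities, "intensities")
  if (length(times) != length(intensities)) {
    stop("`times` and `intensities` must have equal length")
  }
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(intensities < 0)) stop("`intensities` must be >= 0")
  if (!is.null(events$drug_added) && !is.null(events$steady_state_window)) {
    if (events$drug_added >= events$steady_state_window[1]) {
      stop("`drug_added` must precede the steady-state window")
    }
  }
  if (!is.null(events$permeabilization) &&
      !is.null(events$steady_state_window)) {
    if (events$steady_state_window[2] > events$permeabilization) {
      stop("steady-state window must end at or before permeabilization")
    }
  }
  structure(list(times = times, intensities = intensities, events = events),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> %d samples, t = [%g, %g] s\n",
              length(x$times), min(x$times), max(x$times)))
  if (length(x$events)) {
    ev <- vapply(x$events, function(e) paste(signif(e, 6), collapse = "-"),
                 character(1))
    cat("  events:", paste(names(ev), ev, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulate a THP uptake assay
#'
#' Integrates the three-pool transport model from drug addition
#' (`C_e = C_T`, `C_c = C_n = 0`) and returns the noise-free
#' fluorescence trace. At `permeabilization_time` the membrane barrier is
#' removed (detergent step): the permeation rate constant is raised to
#' `perm_rate` and active efflux is switched off, so the drug
#' re-equilibrates with the nuclear binding site and the fluorescence
#' decreases further.
#'
#' @param params a [transport_params()] object.
#' @param conditions an [assay_conditions()] object.
#' @param times output time grid (s), starting at drug addition (t = 0),
#'   strictly increasing.
#' @param permeabilization_time time of the detergent step (s), or `NULL`
#'   to skip it. After this time the membrane barrier is gone: the
#'   extracellular and cytosolic free pools merge into one pool that
#'   equilibrates with the nuclear binding site, and active efflux
#'   stops.
#' @param f0_scale fluorescence span: F(t) = background +
#'   `f0_scale` * (C_T - C_n)/C_T, so the net intensity at t = 0 is
#'   `f0_scale`.
#' @return a [fluorescence_trace()] with events populated; the underlying
#'   pool concentrations are attached as attribute `"concentrations"`
#'   (data.frame time/C_e/C_c/C_n) and the parameters as `"params"`.
#' @examples
#' tr <- simulate_uptake(transport_params(), assay_conditions())
#' head(attr(tr, "concentrations"))
#' @export
simulate_uptake <- function(params, conditions,
                            times = seq(0, 2000, by = 1),
                            permeabilization_time = 1600,
                            f0_scale = 100) {
  stopifnot(inherits(params, "transport_params"),
            inherits(conditions, "assay_conditions"))
  check_finite(times, "times")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")

  c_t <- conditions$total_drug
  rho <- conditions$cell_density
  y0 <- c(C_e = c_t, C_c = 0, C_n = 0)

  deriv <- function(t, y, p) {
    perm <- p$kp_rho * (y[1] - y[2])
    pump <- p$ka_rho * y[2]
    bind <- p$k_on * y[2] * (p$b_max - y[3]) - p$k_off * y[3]
    list(c(-perm + pump, perm - pump - bind, bind))
  }
  run <- function(tt, y, p) {
    out <- try(deSolve::lsoda(y, tt, deriv, p, rtol = 1e-10,
                              atol = 1e-8), silent = TRUE)
    if (inherits(out, "try-error") ||
        nrow(out) < length(tt) || anyNA(out)) {
      stop("ODE integration of the uptake model failed", call. = FALSE)
    }
    out
  }

  p_live <- list(kp_rho = params$k_plus * rho, ka_rho = params$k_act * rho,
                 k_on = params$k_on, k_off = params$k_off,
                 b_max = params$b_max)
  t_perm <- permeabilization_time
  if (!is.null(t_perm) && (t_perm <= times[1] || t_perm > max(times))) {
    stop("`permeabilization_time` must lie inside the time grid")
  }

  # after membrane removal: one free pool C_f exchanging with the
  # nuclear site
  deriv_perm <- function(t, y, p) {
    bind <- p$k_on * y[1] * (p$b_max - y[2]) - p$k_off * y[2]
    list(c(-bind, bind))
  }
  run_perm <- function(tt, y, p) {
    out <- try(deSolve::lsoda(y, tt, deriv_perm, p, rtol = 1e-10,
                              atol = 1e-8), silent = TRUE)
    if (inherits(out, "try-error") ||
        nrow(out) < length(tt) || anyNA(out)) {
      stop("ODE integration of the uptake model failed", call. = FALSE)
    }
    out
  }

  if (is.null(t_perm)) {
    sol <- run(times, y0, p_live)[, -1, drop = FALSE]
  } else {
    t1 <- times[times <= t_perm]
    t1g <- unique(c(t1, t_perm))
    s1 <- run(t1g, y0, p_live)
    y1 <- s1[nrow(s1), -1]
    t2 <- times[times > t_perm]
    sol <- s1[seq_along(t1), -1, drop = FALSE]
    if (length(t2)) {
      yf <- c(C_f = unname(y1[1] + y1[2]), C_n = unname(y1[3]))
      s2 <- run_perm(c(t_perm, t2), yf, p_live)
      # report the merged free pool as extracellular; the cytosol no
      # longer exists as a compartment
      s2m <- cbind(s2[-1, 2], 0, s2[-1, 3])
      sol <- rbind(sol, s2m)
    }
  }

  conc <- data.frame(time = times, C_e = sol[, 1], C_c = sol[, 2],
                     C_n = sol[, 3])
  f <- conditions$background + f0_scale * (c_t - conc$C_n) / c_t

  ssw <- if (is.null(t_perm)) {
    c(times[1] + 0.9 * (max(times) - times[1]), max(times))
  } else {
    c(times[1] + 0.8 * (t_perm - times[1]), t_perm)
  }
  events <- list(drug_added = times[1], steady_state_window = ssw)
  if (!is.null(t_perm)) events$permeabilization <- t_perm

  tr <- fluorescence_trace(times, f, events)
  attr(tr, "concentrations") <- conc
  attr(tr, "params") <- params
  attr(tr, "f0_scale") <- f0_scale
  tr
}
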