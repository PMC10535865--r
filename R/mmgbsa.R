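# End-state (MM-GBSA) free-energy bookkeeping:
#   dG_bind = dH + (-TdS),  dH = dE_MM + dG_sol,
#   dE_MM = dE_vdw + dE_elect,  dG_sol = dG_polar + dG_nonpolar,
# with the entropic penalty -TdS from the interaction-entropy method.
# Per-frame component energies are *inputs* (complex-minus-parts
# differences from an end-state engine); no force field is evaluated
# here.

#' Aggregate MM-GBSA components into a binding free energy
#'
#' @param e_vdw,e_elect mean van der Waals and electrostatic interaction
#'   energies (kcal/mol).
#' @param g_polar,g_nonpolar mean polar (GB) and non-polar (SASA)
#'   solvation free energies (kcal/mol).
#' @param minus_tds entropic penalty -TdS (kcal/mol), reported as the
#'   additive non-negative term.
#' @return an object of class `gbsa_summary` with the components,
#'   `e_mm`, `g_sol`, `dH` and `dG_bind`.
#' @examples
#' mmgbsa_total(-57.36, -9.45, 31.87, -8.21, 9.28)$dG_bind  # -33.87
#' @export
mmgbsa_total <- function(e_vdw, e_elect, g_polar, g_nonpolar, minus_tds) {
  for (nm in c("e_vdw", "e_elect", "g_polar", "g_nonpolar", "minus_tds")) {
    check_finite(get(nm), nm)
  }
  if (minus_tds < 0) {
    warning("-TdS is negative; the interaction-entropy penalty should be >= 0")
  }
  e_mm <- e_vdw + e_elect
  g_sol <- g_polar + g_nonpolar
  dh <- e_mm + g_sol
  structure(list(e_vdw = e_vdw, e_elect = e_elect, g_polar = g_polar,
                 g_nonpolar = g_nonpolar, minus_tds = minus_tds,
                 e_mm = e_mm, g_sol = g_sol, dH = dh,
                 dG_bind = dh + minus_tds),
            class = "gbsa_summary")
}

#' @export
print.gbsa_summary <- function(x, ...) {
  cat("<gbsa_summary> (kcal/mol)\n")
  cat(sprintf("  dE_vdw %8.2f  dE_elect %8.2f  dG_polar %8.2f  dG_nonpolar %8.2f\n",
              x$e_vdw, x$e_elect, x$g_polar, x$g_nonpolar))
  cat(sprintf("  dH %12.2f  -TdS %11.2f  dG_bind %9.2f\n",
              x$dH, x$minus_tds, x$dG_bind))
  invisible(x)
}

#' Interaction entropy from per-frame interaction energies
#'
#' Entropic penalty of binding estimated from the fluctuation of the
#' gas-phase protein-ligand interaction energy E_int over trajectory
#' frames:
#' `-TdS = (1/beta) * log( mean( exp(beta * (E_int - mean(E_int))) ) )`
#' with `beta = 1/(kB T)`. Computed with log-sum-exp, so arbitrarily
#' large fluctuations do not overflow; it is non-negative by Jensen's
#' inequality and zero only for a constant series. A warning of class
#' `pgptools_ie_unstable` is raised when the average is dominated by a
#' single frame (fluctuations >> kB T), where the estimator is known to
#' converge poorly.
#'
#' @param e_int numeric vector of per-frame interaction energies
#'   (kcal/mol), at least 2 frames.
#' @param temperature simulation temperature in K.
#' @return `-TdS` in kcal/mol (>= 0).
#' @examples
#' interaction_entropy(c(-50, -52, -51, -49), temperature = 310)
#' @export
interaction_entropy <- function(e_int, temperature = 310) {
  check_finite(e_int, "e_int")
  check_finite(temperature, "temperature")
  if (length(e_int) < 2) stop("at least 2 frames are required")
  if (temperature <= 0) stop("`temperature` must be > 0")
  beta <- 1 / (.kB * temperature)
  d <- beta * (e_int - mean(e_int))
  if (max(d) - log(length(d)) > 25) {
    warning(structure(
      class = c("pgptools_ie_unstable", "warning", "condition"),
      list(message = paste("interaction-entropy average dominated by a",
                           "single frame; estimate is unreliable"),
           call = sys.call(-1))))
  }
  (log_sum_exp(d) - log(length(d))) / beta
}

#' Mean and standard error over replica simulations
#'
#' @param x numeric vector of per-replica values (e.g. dG_bind of each
#'   replica copy).
#' @return list with `mean` and `sem` (sample SD / sqrt(n)); a single
#'   replica returns `sem = 0` with a warning.
#' @examples
#' replica_summary(c(-33, -34, -35))  # mean -34, sem 0.577
#' @export
replica_summary <- function(x) {
  check_finite(x, "x")
  if (length(x) < 1) stop("empty input")
  if (length(x) == 1) {
    warning("single replica: SEM reported as 0")
    return(list(mean = x, sem = 0))
  }
  list(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)))
}

#' Filter a per-residue energy decomposition
#'
#' Keeps the residues whose decomposed binding energy is strictly below
#' `threshold` (i.e. the favourable contributors named in decomposition
#' plots), sorted by increasing energy.
#'
#' @param decomp data.frame with columns `residue` (unique labels) and
#'   `energy` (kcal/mol).
#' @param threshold cut-off in kcal/mol; strictly-less-than rule, so a
#'   residue at exactly the threshold is excluded.
#' @return the filtered, sorted data.frame.
#' @examples
#' d <- data.frame(residue = c("F343", "F728", "X1"),
#'                 energy = c(-3.66, -3.49, -0.4))
#' decompose_filter(d)$residue  # "F343" "F728"
#' @export
decompose_filter <- function(decomp, threshold = -0.5) {
  if (!is.data.frame(decomp) ||
      !all(c("residue", "energy") %in% names(decomp))) {
    stop("`decomp` must be a data.frame with columns `residue` and `energy`")
  }
  if (nrow(decomp) == 0) return(decomp)
  if (anyDuplicated(decomp$residue)) stop("residue labels must be unique")
  check_finite(decomp$energy, "energy")
  out <- decomp[decomp$energy < threshold, , drop = FALSE]
  out <- out[order(out$energy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize per-frame MM-GBSA tables across replicas
#'
#' For each replica: component means over frames, the gas-phase
#' interaction energy series `E_int = E_vdw + E_elect`, its
#' interaction-entropy penalty, and the replica total via
#' [mmgbsa_total()]. Components and totals are then averaged across
#' replicas with [replica_summary()].
#'
#' @param frames data.frame with columns `replica`, `frame`, `e_vdw`,
#'   `e_elect`, `g_polar`, `g_nonpolar` (kcal/mol per frame).
#' @param temperature temperature (K) for the interaction entropy.
#' @return list with `per_replica` (data.frame, one row per replica) and
#'   `summary` (data.frame with mean and SEM per term).
#' @export
mmgbsa_summarize <- function(frames, temperature = 310) {
  req <- c("replica", "frame", "e_vdw", "e_elect", "g_polar", "g_nonpolar")
  if (!is.data.frame(frames) || !all(req %in% names(frames))) {
    stop("`frames` must contain columns ", paste(req, collapse = ", "))
  }
  if (any(tapply(frames$frame, frames$replica, anyDuplicated) > 0)) {
    stop("frame indices must be unique within each replica")
  }
  reps <- split(frames, frames$replica)
  per <- do.call(rbind, lapply(names(reps), function(r) {
    fr <- reps[[r]]
    e_int <- fr$e_vdw + fr$e_elect
    mtds <- interaction_entropy(e_int, temperature)
    tot <- mmgbsa_total(mean(fr$e_vdw), mean(fr$e_elect),
                        mean(fr$g_polar), mean(fr$g_nonpolar), mtds)
    data.frame(replica = r, n_frames = nrow(fr), e_vdw = tot$e_vdw,
               e_elect = tot$e_elect, g_polar = tot$g_polar,
               g_nonpolar = tot$g_nonpolar, minus_tds = mtds,
               dH = tot$dH, dG_bind = tot$dG_bind)
  }))
  terms <- c("e_vdw", "e_elect", "g_polar", "g_nonpolar", "minus_tds",
             "dH", "dG_bind")
  summ <- do.call(rbind, lapply(terms, function(tm) {
    s <- suppressWarnings(replica_summary(per[[tm]]))
    data.frame(term = tm, mean = s$mean, sem = s$sem)
  }))
  rownames(summ) <- NULL
  list(per_replica = per, summary = summ)
}
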