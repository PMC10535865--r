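# Dose-response fitting and the resistance / reversal bookkeeping used
# to quantify chemosensitization of resistant cell lines.

#' Fit a Hill (4-parameter logistic) dose-response curve
#'
#' Least-squares fit of viability
#' `v(c) = bottom + (top - bottom) / (1 + (c/ic50)^h)` to
#' percent-of-control viabilities. The zero dose anchors the top of the
#' curve. The IC50 is parameterized on the log scale so it stays
#' positive.
#'
#' When no dose reduces mean viability below 50%, the IC50 is not
#' identifiable from the data; the fit is flagged `converged = FALSE`
#' and `ic50` reports the maximum tested dose as a lower bound
#' (`ic50_is_bound = TRUE`).
#'
#' @param data data.frame with columns `dose` (>= 0, including 0) and
#'   `viability` (percent of untreated control); replicates are extra
#'   rows at the same dose. Alternatively give `dose` and `viability`
#'   vectors via `data = data.frame(dose=, viability=)`.
#' @param fix_top_bottom if `TRUE`, constrain top = 100 and bottom = 0.
#' @return an object of class `hill_fit`: `ic50`, `hill`, `top`,
#'   `bottom`, `rss`, `converged`, `ic50_is_bound`.
#' @export
fit_dose_response <- function(data, fix_top_bottom = FALSE) {
  if (!is.data.frame(data) || !all(c("dose", "viability") %in% names(data))) {
    stop("`data` must be a data.frame with columns `dose` and `viability`")
  }
  dose <- data$dose
  viab <- data$viability
  check_finite(dose, "dose")
  check_finite(viab, "viability")
  if (any(dose < 0)) stop("doses must be >= 0")
  if (length(unique(dose)) < 4) stop("at least 4 distinct doses are required")
  if (!any(dose == 0)) stop("dose 0 (normalization anchor) must be present")
  if (diff(range(viab)) < .Machine$double.eps^0.5) {
    stop("all viabilities are equal; dose-response is non-identifiable")
  }

  vbar <- tapply(viab, dose, mean)
  dbar <- as.numeric(names(vbar))
  crossed <- any(vbar < 50)

  # model with (c/ic50)^h evaluated as 0 at c = 0 (h > 0 limit)
  hillv <- function(c, lic50, h, top, bottom) {
    q <- ifelse(c == 0, 0, exp(h * (log(pmax(c, 1e-300)) - lic50)))
    bottom + (top - bottom) / (1 + q)
  }
  d50 <- dbar[which.min(abs(vbar - 50))]
  lic0 <- log(max(d50, min(dose[dose > 0])))
  st <- if (fix_top_bottom) list(lic50 = lic0, h = 1) else
    list(lic50 = lic0, h = 1, top = max(vbar), bottom = min(vbar))
  form <- if (fix_top_bottom) {
    viability ~ hillv(dose, lic50, h, 100, 0)
  } else {
    viability ~ hillv(dose, lic50, h, top, bottom)
  }
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    form, data = data.frame(dose = dose, viability = viab), start = st,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )), silent = TRUE)

  if (inherits(fit, "try-error")) {
    if (!crossed) {
      return(structure(list(ic50 = max(dose), hill = NA_real_,
                            top = if (fix_top_bottom) 100 else max(vbar),
                            bottom = if (fix_top_bottom) 0 else min(vbar),
                            rss = NA_real_, converged = FALSE,
                            ic50_is_bound = TRUE),
                       class = "hill_fit"))
    }
    stop("dose-response fit failed to converge")
  }
  cf <- stats::coef(fit)
  top <- if (fix_top_bottom) 100 else cf[["top"]]
  bottom <- if (fix_top_bottom) 0 else cf[["bottom"]]
  ic50 <- exp(cf[["lic50"]])
  h <- cf[["h"]]
  rss <- sum(stats::residuals(fit)^2)
  converged <- crossed && is.finite(ic50) && h > 0 && bottom < top
  if (!crossed) {
    ic50 <- max(dose)
  }
  structure(list(ic50 = ic50, hill = h, top = top, bottom = bottom,
                 rss = rss, converged = converged,
                 ic50_is_bound = !crossed),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> IC50 = %.4g%s, hill = %.3g, top = %.3g, bottom = %.3g (%s)\n",
    x$ic50, if (x$ic50_is_bound) " (bound)" else "", x$hill, x$top,
    x$bottom, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Inhibitory concentration at a given level
#'
#' Dose producing `level`% inhibition across the fitted span:
#' `c = ic50 * (level/(100 - level))^(1/h)`. With top = 100 and
#' bottom = 0 this is the dose at which viability equals `100 - level`;
#' in general `level` is the percent drop across the fitted
#' top-to-bottom span, so `ic_level(fit, 50)` is the IC50 for any fit.
#'
#' @param fit a converged [fit_dose_response()] result.
#' @param level percent inhibition in (0, 100).
#' @return concentration in the dose units of the fit.
#' @examples
#' # h = 1: IC20 sits at one quarter of the IC50
#' f <- structure(list(ic50 = 1, hill = 1, top = 100, bottom = 0,
#'                     converged = TRUE), class = "hill_fit")
#' ic_level(f, 20)  # 0.25
#' @export
ic_level <- function(fit, level) {
  stopifnot(inherits(fit, "hill_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge; IC levels undefined")
  check_finite(level, "level")
  if (level <= 0 || level >= 100) stop("`level` must lie in (0, 100)")
  fit$ic50 * (level / (100 - level))^(1 / fit$hill)
}

#' Resistance index
#'
#' IC50 of the resistant line (with or without modulator) divided by the
#' IC50 of the sensitive line without modulator, rounded half-up.
#'
#' @param ic50_resistant IC50 of the resistant line.
#' @param ic50_sensitive_no_mod IC50 of the sensitive line without
#'   modulator (same units).
#' @param decimals decimals kept (round-half-up); ignored when
#'   `exact = TRUE`.
#' @param exact return the unrounded quotient.
#' @return dimensionless index.
#' @examples
#' resistance_index(4.54, 0.64)  # 7.1
#' @export
resistance_index <- function(ic50_resistant, ic50_sensitive_no_mod,
                             decimals = 1, exact = FALSE) {
  check_finite(ic50_resistant, "ic50_resistant")
  check_finite(ic50_sensitive_no_mod, "ic50_sensitive_no_mod")
  if (ic50_resistant <= 0 || ic50_sensitive_no_mod <= 0) {
    stop("IC50 values must be > 0")
  }
  q <- ic50_resistant / ic50_sensitive_no_mod
  if (exact) q else round_half_up(q, decimals)
}

#' Reversal index
#'
#' Resistance index without the modulator divided by the resistance
#' index with the modulator; the no-modulator row is 1 by definition.
#' By default the quotient is taken on the *rounded* resistance indices
#' (the convention under which the published tables are internally
#' consistent); `exact = TRUE` divides the unrounded values.
#'
#' @param ri_without_mod resistance index without modulator.
#' @param ri_with_mod resistance index with modulator.
#' @inheritParams resistance_index
#' @return dimensionless index.
#' @examples
#' reversal_index(7.1, 0.3)  # 23.7
#' @export
reversal_index <- function(ri_without_mod, ri_with_mod, decimals = 1,
                           exact = FALSE) {
  check_finite(ri_without_mod, "ri_without_mod")
  check_finite(ri_with_mod, "ri_with_mod")
  if (ri_without_mod <= 0 || ri_with_mod <= 0) {
    stop("resistance indices must be > 0")
  }
  q <- ri_without_mod / ri_with_mod
  if (exact) q else round_half_up(q, decimals)
}

#' Resistance/reversal table from IC50 values
#'
#' Builds the full modulator table: one row per treatment with the
#' resistance index (vs the sensitive line without modulator) and the
#' reversal index (vs the no-modulator resistance index).
#'
#' @param ic50_sensitive_no_mod IC50 of the sensitive line, no modulator.
#' @param ic50_resistant named numeric vector of resistant-line IC50s;
#'   the first element must be the no-modulator condition.
#' @param ic50_sensitive optional IC50s of the sensitive line under the
#'   modulator (reported, not used in the indices).
#' @inheritParams resistance_index
#' @return data.frame with columns `treatment`, `ic50_sensitive`,
#'   `ic50_resistant`, `resistance_index`, `reversal_index`.
#' @export
resistance_table <- function(ic50_sensitive_no_mod, ic50_resistant,
                             ic50_sensitive = NULL, decimals = 1,
                             exact = FALSE) {
  if (is.null(names(ic50_resistant))) {
    names(ic50_resistant) <- paste0("treatment", seq_along(ic50_resistant))
  }
  ri <- vapply(ic50_resistant, resistance_index,
               numeric(1), ic50_sensitive_no_mod = ic50_sensitive_no_mod,
               decimals = decimals, exact = exact)
  rev <- vapply(ri, function(x) {
    reversal_index(ri[[1]], x, decimals = decimals, exact = exact)
  }, numeric(1))
  data.frame(
    treatment = names(ic50_resistant),
    ic50_sensitive = if (is.null(ic50_sensitive)) NA_real_ else
      as.numeric(ic50_sensitive),
    ic50_resistant = as.numeric(ic50_resistant),
    resistance_index = as.numeric(ri),
    reversal_index = as.numeric(rev),
    row.names = NULL
  )
}

#' Relative gene expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target - Ct_reference)[treated] -
#' (Ct_target - Ct_reference)[control]`; the fold change is
#' `2^(-ddCt)`.
#'
#' @param ct_target_treated,ct_ref_treated Ct of the target and the
#'   reference (housekeeping) gene in the treated condition.
#' @param ct_target_control,ct_ref_control same for the control
#'   condition.
#' @return fold change (dimensionless, > 0).
#' @examples
#' ddct_expression(25, 20, 24, 20)  # ddCt = 1 -> 0.5
#' @export
ddct_expression <- function(ct_target_treated, ct_ref_treated,
                            ct_target_control, ct_ref_control) {
  for (x in list(ct_target_treated, ct_ref_treated, ct_target_control,
                 ct_ref_control)) check_finite(x, "Ct")
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control,
           ct_ref_control)
  if (any(cts <= 0 | cts >= 45)) {
    warning("Ct values outside the usual (0, 45) cycle range")
  }
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Intracellular drug accumulation fold
#'
#' Background-subtracted ratio of treated to control fluorescence
#' intensities from a drug-accumulation assay.
#'
#' @param intensity_treated,intensity_control intensities (a.u.).
#' @param background instrument background (a.u.).
#' @return fold change (>= 0).
#' @export
accumulation_fold <- function(intensity_treated, intensity_control,
                              background = 0) {
  check_finite(intensity_treated, "intensity_treated")
  check_finite(intensity_control, "intensity_control")
  ctrl <- intensity_control - background
  if (ctrl <= 0) stop("background-subtracted control intensity must be > 0")
  max(intensity_treated - background, 0) / ctrl
}
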