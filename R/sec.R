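# Analytical size-exclusion chromatography: partition coefficients, the
# linear Kav-vs-log10(MW) calibration, apparent-MW estimation, and a
# three-way oligomer-state classification against the theoretical monomer
# mass.

#' Partition coefficient of an SEC peak
#'
#' `Kav = (Ve - V0) / (Vc - V0)`.  Values slightly outside [0, 1] occur for
#' peaks at the column limits; values outside [-0.05, 1.05] trigger a
#' warning.
#'
#' @param ve Elution volume (mL).
#' @param v0 Column void volume (mL).
#' @param vc Total column volume (mL), `vc > v0`.
#' @return Dimensionless Kav (vectorized over `ve`).
#' @export
compute_kav <- function(ve, v0, vc) {
  if (!is.numeric(vc) || !is.numeric(v0) || vc <= v0)
    nd_stop("nmrdomain_value_error", "vc must exceed v0")
  kav <- (ve - v0) / (vc - v0)
  if (any(kav < -0.05 | kav > 1.05))
    nd_warn("Kav outside [-0.05, 1.05] for %d value(s)",
            sum(kav < -0.05 | kav > 1.05))
  kav
}

#' Fit the Kav vs log10(MW) calibration line
#'
#' Ordinary least squares of the standards' partition coefficients on the
#' decadic log of their molecular weights.
#'
#' @param standards Data frame with columns `name`, `mw_kda`, `ve_ml`
#'   (at least 2 distinct molecular weights).
#' @param v0,vc Column void and total volumes (mL).
#' @return A `sec_calibration` list: `v0`, `vc`, `slope`, `intercept`,
#'   `r_squared`, and `standards` augmented with their `kav`.
#' @export
fit_calibration <- function(standards, v0, vc) {
  missing <- setdiff(c("mw_kda", "ve_ml"), names(standards))
  if (length(missing) > 0L)
    nd_stop("nmrdomain_value_error", "standards lack column(s): %s",
            paste(missing, collapse = ", "))
  if (length(unique(standards$mw_kda)) < 2L)
    nd_stop("nmrdomain_value_error",
            "need >= 2 standards with distinct molecular weights")
  if (any(standards$mw_kda <= 0))
    nd_stop("nmrdomain_value_error", "standard MWs must be positive")
  standards$kav <- compute_kav(standards$ve_ml, v0, vc)
  fit <- stats::lm(kav ~ log10(mw_kda), data = standards)
  structure(list(v0 = v0, vc = vc,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 standards = standards),
            class = "sec_calibration")
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf("SEC calibration (V0 %.2f mL, Vc %.2f mL, %d standards):\n",
              x$v0, x$vc, nrow(x$standards)))
  cat(sprintf("  Kav = %.4f * log10(MW) + %.4f   (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
plot.sec_calibration <- function(x, ...) {
  graphics::plot(log10(x$standards$mw_kda), x$standards$kav, pch = 16,
                 xlab = "log10(MW / kDa)", ylab = "Kav", ...)
  graphics::abline(a = x$intercept, b = x$slope, col = "firebrick")
  invisible(x)
}

#' Apparent molecular weight from a partition coefficient
#'
#' Inverts the calibration line: `MW = 10^((Kav - intercept) / slope)`.
#' Kav values outside the standards' range are extrapolations and trigger a
#' warning.
#'
#' @param kav Partition coefficient(s).
#' @param cal A [fit_calibration()] result.
#' @return Apparent molecular weight(s) in kDa.
#' @export
estimate_mw <- function(kav, cal) {
  stopifnot(inherits(cal, "sec_calibration"))
  if (cal$slope == 0)
    nd_stop("nmrdomain_value_error", "calibration slope is zero")
  rng <- range(cal$standards$kav)
  if (any(kav < rng[1] | kav > rng[2]))
    nd_warn("Kav outside the calibrated range [%.3f, %.3f]: extrapolating",
            rng[1], rng[2])
  10^((kav - cal$intercept) / cal$slope)
}

#' Classify oligomeric state from apparent vs monomer mass
#'
#' The ratio apparent/monomer is cut at `monomer_max` (default 1.4) and
#' `dimer_min` (default 1.75): below the first is a monomer, at or above
#' the second a dimer or larger, in between an exchange-averaged
#' monomer-dimer intermediate.  The three classes partition (0, Inf).
#'
#' @param apparent_mw Apparent molecular weight (kDa), > 0.
#' @param monomer_mw Theoretical monomer mass (kDa), > 0.
#' @param monomer_max,dimer_min Class boundaries on the mass ratio.
#' @return A list: `ratio`, `state` (one of `"monomer"`,
#'   `"monomer_dimer_intermediate"`, `"dimer_or_larger"`).
#' @export
classify_oligomer <- function(apparent_mw, monomer_mw,
                              monomer_max = 1.4, dimer_min = 1.75) {
  if (!is.numeric(apparent_mw) || !is.numeric(monomer_mw) ||
      apparent_mw <= 0 || monomer_mw <= 0)
    nd_stop("nmrdomain_value_error", "masses must be positive")
  if (!(monomer_max < dimer_min))
    nd_stop("nmrdomain_value_error", "monomer_max must be below dimer_min")
  ratio <- apparent_mw / monomer_mw
  state <- if (ratio < monomer_max) "monomer"
    else if (ratio >= dimer_min) "dimer_or_larger"
    else "monomer_dimer_intermediate"
  list(ratio = ratio, state = state)
}
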