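# Core portal-systemic difference estimators: FaFg, BA, Fh.

#' Apparent absorbed fraction FaFg from the portal-systemic AUC difference
#'
#' The excess of portal over systemic exposure after an oral dose, converted
#' to blood with Rb and scaled by portal blood flow, recovers the amount of
#' drug delivered into the portal vein:
#' `FaFg = Qpv * Rb * (AUC_pv - AUC_sys) / Dose`,
#' with Qpv in L/h/kg and the dose in nmol/kg. Fa (fraction absorbed) and
#' Fg (gut availability) are not separately identifiable; only their product
#' is returned.
#'
#' Values above 1 can legitimately arise from assay and sampling noise when
#' true absorption is near-complete; they are returned as computed with a
#' `supra_unity` flag, never clamped. A portal AUC below the systemic AUC
#' yields a negative value with a `nonphysical` flag rather than an error,
#' since it usually indicates an arm or assay mismatch worth inspecting.
#'
#' @param auc_pv,auc_sys Oral-route AUCs to infinity at the portal and
#'   systemic sites, nmol/L x h.
#' @param rb Blood/plasma concentration ratio, > 0.
#' @param qpv Portal blood flow in mL/min/kg (default 106.6).
#' @param dose_oral Oral dose in nmol/kg, > 0.
#' @return A list with `fafg` (fraction, unclamped) and `flags`
#'   (character vector, possibly empty).
#' @export
#' @examples
#' # ciprofloxacin, wild-type arm:
#' fafg(489, 306, rb = 1.20, qpv = 106.6,
#'      dose_oral = dose_to_nmol_per_kg(1, 331.34))$fafg # ~0.465
fafg <- function(auc_pv, auc_sys, rb, qpv = 106.6, dose_oral) {
  if (!is.finite(dose_oral) || dose_oral <= 0)
    stop("dose_oral must be > 0", call. = FALSE)
  if (!is.finite(rb) || rb <= 0) stop("rb must be > 0", call. = FALSE)
  value <- qpv_to_L_per_h_per_kg(qpv) * rb * (auc_pv - auc_sys) / dose_oral
  flags <- character(0)
  if (value < 0) flags <- c(flags, "nonphysical")
  if (value > 1) flags <- c(flags, "supra_unity")
  list(fafg = value, flags = flags)
}

#' FaFg from a paired portal/systemic oral profile
#'
#' Profile-level estimator of the portal-systemic difference integral. The
#' estimand is `Int (Cpv - Csys) dt`; under first-order absorption the
#' difference curve is a single decaying exponential, so it is integrated
#' directly as a paired curve rather than as a subtraction of two
#' separately integrated AUCs (whose independent trapezoid errors do not
#' cancel on a sparse schedule). The difference is anchored at a
#' back-extrapolated value at time zero, integrated with the
#' linear-up/log-down rule, and the tail beyond the last point is
#' extrapolated with the portal terminal slope when the last difference is
#' positive.
#'
#' @param portal,systemic Oral-route [conc_profile()]s on a common
#'   schedule.
#' @param rb Blood/plasma ratio.
#' @param qpv Portal blood flow, mL/min/kg.
#' @param dose_oral Oral dose in nmol/kg.
#' @param lambda_tail Terminal rate constant for the tail of the
#'   difference; default `NULL` uses [lambda_z()] of the portal profile.
#' @return As [fafg()]: list with `fafg`, `flags`, plus `auc_diff`.
#' @export
fafg_profiles <- function(portal, systemic, rb, qpv = 106.6, dose_oral,
                          lambda_tail = NULL) {
  stopifnot(inherits(portal, "conc_profile"),
            inherits(systemic, "conc_profile"))
  if (!isTRUE(all.equal(portal$times, systemic$times)))
    stop("portal and systemic profiles must share a schedule", call. = FALSE)
  t <- portal$times
  d <- portal$concs - systemic$concs
  # anchor: log-linear back-extrapolation through the first two positive
  # differences (the absorption stream starts at its maximum at t = 0+)
  if (t[1] > 0) {
    pos <- which(d > 0)
    d0 <- if (length(pos) >= 2) {
      i <- pos[1:2]
      slope <- (log(d[i[2]]) - log(d[i[1]])) / (t[i[2]] - t[i[1]])
      exp(log(d[i[1]]) - slope * t[i[1]])
    } else if (length(pos) == 1) d[pos] else 0
    t <- c(0, t)
    d <- c(d0, d)
  }
  auc_diff <- trapezoid_segments(t, d, "linlog")$auc
  d_last <- d[length(d)]
  if (d_last > 0) {
    if (is.null(lambda_tail))
      lambda_tail <- tryCatch(lambda_z(portal)$lambda_z,
                              error = function(e) NULL)
    if (!is.null(lambda_tail) && is.finite(lambda_tail) && lambda_tail > 0)
      auc_diff <- auc_diff + d_last / lambda_tail
  }
  value <- qpv_to_L_per_h_per_kg(qpv) * rb * auc_diff / dose_oral
  flags <- character(0)
  if (value < 0) flags <- c(flags, "nonphysical")
  if (value > 1) flags <- c(flags, "supra_unity")
  list(fafg = value, flags = flags, auc_diff = auc_diff)
}

#' Oral bioavailability from dose-normalized exposures
#'
#' `BA = (AUC_oral / AUC_iv) * (Dose_iv / Dose_oral)`, systemic site on both
#' routes. Returned as a fraction; multiply by 100 only at the reporting
#' layer. Doses may be in any common unit (the ratio cancels units).
#'
#' @param auc_oral_sys,auc_iv_sys Systemic AUCs to infinity, > 0.
#' @param dose_iv,dose_oral Doses per route (same unit), > 0.
#' @return Bioavailability as a fraction.
#' @export
#' @examples
#' bioavailability(306, 886, 1, 1) # ciprofloxacin WT, ~0.345
bioavailability <- function(auc_oral_sys, auc_iv_sys, dose_iv, dose_oral) {
  v <- c(auc_oral_sys, auc_iv_sys, dose_iv, dose_oral)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all inputs must be > 0", call. = FALSE)
  (auc_oral_sys / auc_iv_sys) * (dose_iv / dose_oral)
}

#' Hepatic availability
#'
#' `Fh = BA / FaFg`: the fraction of portally delivered drug that escapes
#' hepatic first-pass extraction. By this definition `BA = FaFg * Fh`
#' exactly.
#'
#' @param ba Bioavailability as a fraction, >= 0.
#' @param fafg Apparent absorbed fraction, > 0.
#' @return Hepatic availability as a fraction, or `NA` with a warning when
#'   `fafg` is not positive.
#' @export
hepatic_availability <- function(ba, fafg) {
  if (!is.finite(ba) || ba < 0) stop("ba must be >= 0", call. = FALSE)
  if (!is.finite(fafg) || fafg <= 0) {
    warning("Fh undefined: FaFg must be > 0", call. = FALSE)
    return(NA_real_)
  }
  ba / fafg
}
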