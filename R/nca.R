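# Non-compartmental analysis of a single profile.

#' Terminal elimination rate constant (lambda_z)
#'
#' Log-linear least-squares regression of ln(concentration) on time over the
#' last `n_terminal` sampling points. Points with non-positive concentration
#' cannot enter the log fit; the window shrinks toward the minimum of 2
#' trailing positive points before failing.
#'
#' @param profile A [conc_profile()].
#' @param n_terminal Number of terminal points to use (default 3, minimum 2).
#' @return A list with `lambda_z` (1/h, > 0), `intercept` (ln nmol/L),
#'   `r_squared`, `n_points`, and `t_half` (h).
#' @export
lambda_z <- function(profile, n_terminal = 3) {
  stopifnot(inherits(profile, "conc_profile"))
  if (n_terminal < 2) stop("n_terminal must be >= 2", call. = FALSE)
  pos <- which(profile$concs > 0)
  if (length(pos) < 2)
    stop("lambda_z estimation error: fewer than 2 positive concentrations",
         call. = FALSE)
  idx <- utils::tail(pos, n_terminal)
  t <- profile$times[idx]
  y <- log(profile$concs[idx])
  fit <- stats::lm.fit(cbind(1, t), y)
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= -1e-10)
    stop("lambda_z estimation error: no terminal decay", call. = FALSE)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  lz <- -unname(slope)
  list(lambda_z = lz, intercept = unname(fit$coefficients[1]),
       r_squared = r2, n_points = length(idx), t_half = half_life(lz))
}

#' Elimination half-life
#'
#' @param lambda_z Terminal rate constant in 1/h, > 0.
#' @return `log(2) / lambda_z`, in hours.
#' @export
half_life <- function(lambda_z) {
  if (any(!is.finite(lambda_z)) || any(lambda_z <= 0))
    stop("lambda_z must be > 0", call. = FALSE)
  log(2) / lambda_z
}

# Segment-wise AUC and AUMC over observed nodes. "linlog" applies the
# mono-exponential (log) rule on strictly declining positive segments and
# the linear chord elsewhere; "linear" is the chord everywhere.
trapezoid_segments <- function(t, c, method = "linear") {
  auc <- 0
  aumc <- 0
  for (i in seq_len(length(t) - 1)) {
    t1 <- t[i]; t2 <- t[i + 1]; c1 <- c[i]; c2 <- c[i + 1]
    dt <- t2 - t1
    if (method == "linlog" && c1 > c2 && c2 > 0) {
      k <- log(c1 / c2) / dt
      auc <- auc + (c1 - c2) / k
      aumc <- aumc + (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
    } else {
      auc <- auc + dt * (c1 + c2) / 2
      aumc <- aumc + dt * (t1 * c1 + t2 * c2) / 2
    }
  }
  list(auc = auc, aumc = aumc)
}

# Back-extrapolated C(0) for an iv bolus: exp of the intercept of a
# log-linear fit through the first two positive observations.
c0_backextrapolate <- function(profile) {
  pos <- which(profile$concs > 0)
  if (length(pos) < 2) return(if (length(pos) == 1) profile$concs[pos] else 0)
  i <- pos[1:2]
  t <- profile$times[i]
  y <- log(profile$concs[i])
  slope <- (y[2] - y[1]) / (t[2] - t[1])
  exp(y[1] - slope * t[1])
}

#' AUC and AUMC from time zero to infinity
#'
#' Linear trapezoidal rule over the observed points, anchored at time zero,
#' with terminal extrapolation beyond the last positive concentration:
#' `AUC tail = C_last / lambda_z` and
#' `AUMC tail = C_last * t_last / lambda_z + C_last / lambda_z^2`.
#'
#' @param profile A [conc_profile()].
#' @param lambda_z Terminal rate constant (1/h). Required whenever the last
#'   concentration is positive; may be `NULL` for an all-zero tail.
#' @param c0 Concentration at time zero (used only when the profile does not
#'   already start at t = 0). Default `NULL` picks the anchor by profile
#'   kind: 0 for an oral systemic profile (first-order absorption starts the
#'   systemic curve at zero), and the log-linear back-extrapolate through
#'   the first two positive points for an iv bolus or an oral portal
#'   profile (both begin at a positive concentration at t = 0+: the bolus
#'   by instantaneous mixing, the portal stream at the peak of its
#'   first-order input).
#' @param method `"linear"` (default) for the plain linear trapezoid on all
#'   segments, or `"linlog"` for linear-up/log-down: segments where the
#'   concentration declines between two positive values are integrated
#'   under a mono-exponential assumption, which is exact for first-order
#'   decay and removes the systematic overestimation of the linear chord on
#'   wide sampling intervals.
#' @return A list with `auc_inf` (nmol/L x h), `aumc_inf` (nmol/L x h^2),
#'   `auc_last`, `aumc_last`, and `c0`.
#' @export
auc_aumc_inf <- function(profile, lambda_z = NULL, c0 = NULL,
                         method = c("linear", "linlog")) {
  stopifnot(inherits(profile, "conc_profile"))
  method <- match.arg(method)
  t <- profile$times
  c <- profile$concs
  if (t[1] > 0) {
    if (is.null(c0)) {
      backex <- profile$route == "iv" ||
        (profile$route == "oral" && profile$site == "portal")
      c0 <- if (backex) c0_backextrapolate(profile) else 0
    }
    t <- c(0, t)
    c <- c(c0, c)
  } else {
    c0 <- c[1]
  }
  seg <- trapezoid_segments(t, c, method)
  auc_last <- seg$auc
  aumc_last <- seg$aumc
  c_last <- c[length(c)]
  t_last <- t[length(t)]
  if (c_last > 0) {
    if (is.null(lambda_z) || !is.finite(lambda_z) || lambda_z <= 0)
      stop("positive terminal concentration requires lambda_z > 0",
           call. = FALSE)
    auc_tail <- c_last / lambda_z
    aumc_tail <- c_last * t_last / lambda_z + c_last / lambda_z^2
  } else {
    auc_tail <- 0
    aumc_tail <- 0
  }
  list(auc_inf = auc_last + auc_tail, aumc_inf = aumc_last + aumc_tail,
       auc_last = auc_last, aumc_last = aumc_last, c0 = c0)
}

#' Total body clearance from an iv profile
#'
#' @param dose Dose in nmol/kg, > 0 (see [dose_to_nmol_per_kg()]).
#' @param auc_iv AUC to infinity after iv dosing, nmol/L x h, > 0.
#' @return Clearance in L/h/kg: `dose / auc_iv`.
#' @export
cl_tot <- function(dose, auc_iv) {
  if (any(!is.finite(dose)) || any(dose <= 0) ||
      any(!is.finite(auc_iv)) || any(auc_iv <= 0))
    stop("dose and auc_iv must be > 0", call. = FALSE)
  dose / auc_iv
}

#' Steady-state volume of distribution
#'
#' @param aumc_iv,auc_iv First-moment and zeroth-moment iv exposures, > 0.
#' @param cl Total clearance in L/h/kg, > 0.
#' @return `(aumc_iv / auc_iv) * cl`, in L/kg (i.e. MRT x CL).
#' @export
vd_ss <- function(aumc_iv, auc_iv, cl) {
  if (any(!is.finite(c(aumc_iv, auc_iv, cl))) ||
      any(c(aumc_iv, auc_iv, cl) <= 0))
    stop("aumc_iv, auc_iv and cl must be > 0", call. = FALSE)
  (aumc_iv / auc_iv) * cl
}

#' Mean absorption time
#'
#' Defined as `MRT_oral - MRT_iv`. A negative value is returned as computed
#' (it signals inconsistent arms), with a warning.
#'
#' @param mrt_oral,mrt_iv Mean residence times in hours, >= 0.
#' @return MAT in hours.
#' @export
mat <- function(mrt_oral, mrt_iv) {
  if (any(!is.finite(c(mrt_oral, mrt_iv))) || any(c(mrt_oral, mrt_iv) < 0))
    stop("mean residence times must be >= 0", call. = FALSE)
  out <- mrt_oral - mrt_iv
  if (out < 0) warning("negative MAT: MRT_oral < MRT_iv", call. = FALSE)
  out
}

#' Non-compartmental analysis of one profile
#'
#' Convenience wrapper chaining [lambda_z()] and [auc_aumc_inf()] and the
#' derived parameters. Clearance, Vdss and C0 are only defined for iv
#' profiles and require `dose_nmol_per_kg`.
#'
#' @param profile A [conc_profile()].
#' @param dose_nmol_per_kg Molar dose; needed for clearance (iv only).
#' @param n_terminal Terminal window size for [lambda_z()].
#' @param lloq Lower limit of quantification in nmol/L; observations strictly
#'   below it are dropped before analysis. The default 0 keeps everything.
#' @return A one-row data frame of class `nca_result` with columns
#'   `cmax, tmax, lambda_z, r_squared, t_half, auc_inf, aumc_inf, mrt,
#'   cltot, vdss, c0` (the iv-only columns are `NA` for oral profiles).
#' @export
nca <- function(profile, dose_nmol_per_kg = NULL, n_terminal = 3, lloq = 0) {
  stopifnot(inherits(profile, "conc_profile"))
  if (lloq > 0) {
    keep <- profile$concs >= lloq
    if (sum(keep) < 3)
      stop("fewer than 3 observations remain above the LLOQ", call. = FALSE)
    profile <- conc_profile(profile$compound, profile$genotype,
                            profile$route, profile$site,
                            profile$times[keep], profile$concs[keep],
                            profile$dose_mg_per_kg)
  }
  lz <- lambda_z(profile, n_terminal = n_terminal)
  area <- auc_aumc_inf(profile, lambda_z = lz$lambda_z)
  i_max <- which.max(profile$concs)
  mrt <- area$aumc_inf / area$auc_inf
  is_iv <- profile$route == "iv"
  cl <- vd <- NA_real_
  if (is_iv && !is.null(dose_nmol_per_kg)) {
    cl <- cl_tot(dose_nmol_per_kg, area$auc_inf)
    vd <- vd_ss(area$aumc_inf, area$auc_inf, cl)
  }
  out <- data.frame(
    compound = profile$compound, genotype = profile$genotype,
    route = profile$route, site = profile$site,
    cmax = profile$concs[i_max], tmax = profile$times[i_max],
    lambda_z = lz$lambda_z, r_squared = lz$r_squared, t_half = lz$t_half,
    auc_inf = area$auc_inf, aumc_inf = area$aumc_inf, mrt = mrt,
    cltot = cl, vdss = vd, c0 = if (is_iv) area$c0 else NA_real_
  )
  class(out) <- c("nca_result", "data.frame")
  out
}
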