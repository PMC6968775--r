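# Domain types and IO for concentration-time studies.
# Internal units are fixed: time in hours, plasma concentration in nmol/L,
# dose in mg/kg at the boundary (converted to nmol/kg for all mass balance).

GENOTYPES <- c("WT", "BcrpKO", "Mdr1a1bKO")
ROUTES <- c("iv", "oral")
SITES <- c("systemic", "portal")

#' Default portal-vein sampling schedule (hours)
#'
#' The sparse 7-point schedule used in the mouse studies this package
#' analyses: 5 and 10 minutes, then 0.5, 1, 2, 4 and 8 hours.
#'
#' @return Numeric vector of sampling times in hours.
#' @export
default_schedule <- function() c(0.083, 0.17, 0.5, 1, 2, 4, 8)

#' Construct a concentration-time profile
#'
#' The atomic observation unit: one concentration-time series for one
#' compound, genotype arm, route and sampling site.
#'
#' @param compound Compound identifier (character scalar).
#' @param genotype One of `"WT"`, `"BcrpKO"`, `"Mdr1a1bKO"`.
#' @param route `"iv"` or `"oral"`.
#' @param site `"systemic"` or `"portal"`. A portal site is only physically
#'   meaningful after oral dosing; an iv/portal profile is accepted but
#'   flagged in the object (`$flag_iv_portal`).
#' @param times Strictly increasing sampling times in hours, at least 3.
#' @param concs Non-negative plasma concentrations in nmol/L, same length.
#' @param dose_mg_per_kg Administered dose in mg/kg, > 0.
#'
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(compound, genotype, route, site, times, concs,
                         dose_mg_per_kg) {
  genotype <- match_enum(genotype, GENOTYPES, "genotype")
  route <- match_enum(route, ROUTES, "route")
  site <- match_enum(site, SITES, "site")
  times <- as.numeric(times)
  concs <- as.numeric(concs)
  if (length(times) != length(concs))
    stop("times and concs must have equal length", call. = FALSE)
  if (length(times) < 3)
    stop("a profile needs at least 3 time points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(concs)) || any(concs < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  if (!is.finite(dose_mg_per_kg) || dose_mg_per_kg <= 0)
    stop("dose_mg_per_kg must be > 0", call. = FALSE)
  structure(
    list(compound = as.character(compound), genotype = genotype,
         route = route, site = site, times = times, concs = concs,
         dose_mg_per_kg = as.numeric(dose_mg_per_kg),
         flag_iv_portal = (route == "iv" && site == "portal")),
    class = "conc_profile"
  )
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> %s | %s | %s | %s | %d points | dose %g mg/kg\n",
              x$compound, x$genotype, x$route, x$site, length(x$times),
              x$dose_mg_per_kg))
  print(data.frame(time_h = x$times, conc_nM = x$concs))
  invisible(x)
}

match_enum <- function(value, levels, what) {
  value <- as.character(value)
  if (length(value) != 1 || !(value %in% levels))
    stop(sprintf("unknown %s '%s'; expected one of: %s",
                 what, paste(value, collapse = ","),
                 paste(levels, collapse = ", ")), call. = FALSE)
  value
}

#' Compound constants
#'
#' Per-compound constants consumed by the availability estimators.
#' `mw_dosed` is the molar mass of the chemical form actually dosed (a salt
#' if a salt was weighed out): the dose-to-moles conversion must use it for
#' the AUC-based clearances and FaFg to come out on the right scale.
#'
#' @param name Compound identifier.
#' @param mw_dosed Molar mass of the dosed form, g/mol.
#' @param rb Blood/plasma concentration ratio (dimensionless), > 0.
#'   Treated as genotype-independent.
#' @param dose_iv,dose_oral Doses per route, mg/kg.
#'
#' @return An object of class `compound_spec`.
#' @export
compound_spec <- function(name, mw_dosed, rb, dose_iv, dose_oral) {
  for (v in c(mw_dosed = mw_dosed, rb = rb, dose_iv = dose_iv,
              dose_oral = dose_oral)) {
    if (!is.finite(v) || v <= 0)
      stop("all compound constants must be finite and > 0", call. = FALSE)
  }
  structure(list(name = as.character(name), mw_dosed = mw_dosed, rb = rb,
                 dose_iv = dose_iv, dose_oral = dose_oral),
            class = "compound_spec")
}

#' Physiology constants
#'
#' @param qpv Portal venous blood flow in mL/min/kg. The default 106.6 is the
#'   literature value for mouse used throughout the package.
#' @param schedule Sampling schedule in hours; defaults to
#'   [default_schedule()].
#'
#' @return An object of class `physiology_config`.
#' @export
physiology_config <- function(qpv = 106.6, schedule = default_schedule()) {
  if (!is.finite(qpv) || qpv <= 0) stop("qpv must be > 0", call. = FALSE)
  schedule <- as.numeric(schedule)
  if (any(diff(schedule) <= 0))
    stop("schedule must be strictly increasing", call. = FALSE)
  structure(list(qpv = qpv, schedule = schedule),
            class = "physiology_config")
}

STUDY_COLUMNS <- c("compound", "genotype", "route", "site", "time_h",
                   "conc_nM", "dose_mg_per_kg")

#' Read a concentration-time study from CSV
#'
#' Reads a long-format table (columns `compound, genotype, route, site,
#' time_h, conc_nM, dose_mg_per_kg`) and returns one [conc_profile()] per
#' (compound, genotype, route, site) group, sorted by time. Replicate rows at
#' the same time within a group (e.g. several animals) are arithmetically
#' averaged before analysis, matching the mean-profile convention of sparse
#' destructive-sampling designs.
#'
#' @param path Path to a CSV file (comma separator, dot decimal, header).
#' @param config A [physiology_config()]; carried along for downstream
#'   stages (unused during reading itself).
#'
#' @return A named list of `conc_profile` objects (class `conc_study`);
#'   names are `compound.genotype.route.site`.
#' @export
read_study <- function(path, config = physiology_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  profiles_from_table(df)
}

#' Build profiles from a long-format study table
#'
#' The in-memory equivalent of [read_study()]: validates the schema, averages
#' replicates and splits the table into per-arm profiles.
#'
#' @param df Data frame with the study columns (see [read_study()]).
#' @return A `conc_study` list of [conc_profile()] objects.
#' @export
profiles_from_table <- function(df) {
  missing_cols <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("study table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("genotype", "route", "site")) {
    levels <- switch(col, genotype = GENOTYPES, route = ROUTES, site = SITES)
    bad <- setdiff(unique(df[[col]]), levels)
    if (length(bad) > 0)
      stop(sprintf("unknown %s '%s'; expected one of: %s", col, bad[1],
                   paste(levels, collapse = ", ")), call. = FALSE)
  }
  key <- interaction(df$compound, df$genotype, df$route, df$site, drop = TRUE)
  profiles <- lapply(split(df, key), function(g) {
    agg <- stats::aggregate(conc_nM ~ time_h, data = g, FUN = mean)
    agg <- agg[order(agg$time_h), ]
    if (anyDuplicated(agg$time_h))
      stop("duplicate times remain after replicate averaging", call. = FALSE)
    conc_profile(g$compound[1], g$genotype[1], g$route[1], g$site[1],
                 agg$time_h, agg$conc_nM, g$dose_mg_per_kg[1])
  })
  structure(profiles, class = "conc_study")
}

#' Write a study (or profile list) back to long-format CSV
#'
#' Inverse of [read_study()] for already-averaged profiles: every
#' (time, conc) pair is written to full precision so that
#' `read_study(write_study(x))` round-trips exactly.
#'
#' @param study A `conc_study` list, a single `conc_profile`, or a
#'   long-format data frame already in the study schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  df <- study_table(study)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flatten profiles to the long-format study schema
#'
#' @param study As for [write_study()].
#' @return A data frame with the study columns.
#' @export
study_table <- function(study) {
  if (is.data.frame(study)) {
    stopifnot(all(STUDY_COLUMNS %in% names(study)))
    return(study[STUDY_COLUMNS])
  }
  if (inherits(study, "conc_profile")) study <- list(study)
  rows <- lapply(study, function(p) {
    data.frame(compound = p$compound, genotype = p$genotype, route = p$route,
               site = p$site, time_h = p$times, conc_nM = p$concs,
               dose_mg_per_kg = p$dose_mg_per_kg)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Convert a mg/kg dose to nmol/kg
#'
#' All AUC-based quantities in this package are molar (nmol/L x h), so doses
#' must enter mass balance in nmol/kg, converted with the molar mass of the
#' dosed chemical form.
#'
#' @param dose Dose in mg/kg, > 0.
#' @param mw_dosed Molar mass of the dosed form in g/mol, > 0.
#' @return Dose in nmol/kg: `dose * 1e6 / mw_dosed`.
#' @export
#' @examples
#' dose_to_nmol_per_kg(1, 331.34) # ciprofloxacin, ~3018 nmol/kg
dose_to_nmol_per_kg <- function(dose, mw_dosed) {
  if (any(!is.finite(dose)) || any(dose <= 0))
    stop("dose must be > 0", call. = FALSE)
  if (any(!is.finite(mw_dosed)) || any(mw_dosed <= 0))
    stop("mw_dosed must be > 0", call. = FALSE)
  dose * 1e6 / mw_dosed
}

#' Convert portal blood flow from mL/min/kg to L/h/kg
#'
#' @param qpv Portal blood flow in mL/min/kg, > 0.
#' @return Flow in L/h/kg: `qpv * 60 / 1000`.
#' @export
#' @examples
#' qpv_to_L_per_h_per_kg(106.6) # 6.396
qpv_to_L_per_h_per_kg <- function(qpv) {
  if (any(!is.finite(qpv)) || any(qpv <= 0))
    stop("qpv must be > 0", call. = FALSE)
  qpv * 60 / 1000
}
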