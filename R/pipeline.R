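# Full-study pipeline: NCA -> FaFg/BA/Fh -> ka -> AQ/R -> quadrants.

#' Analyze a complete knockout study
#'
#' Chains every stage of the portal-systemic difference analysis for one
#' compound across genotype arms:
#' \enumerate{
#'   \item NCA of the iv systemic profile (terminal slope, CLtot, Vdss, C0).
#'   \item NCA of the oral systemic and portal profiles (AUCs to infinity).
#'   \item FaFg from the portal-systemic difference integral
#'     ([fafg_profiles()], paired-difference integration; or [fafg()] on
#'     the two separately integrated AUCs with
#'     `fafg_method = "separate"`), BA from dose-normalized systemic AUCs,
#'     Fh = BA / FaFg.
#'   \item ka by Bateman least squares with ke fixed at the iv terminal
#'     slope; MAT as MRT_oral - MRT_iv.
#'   \item AQ and R scores from the genotype triplets (when all three arms
#'     are present).
#' }
#'
#' @param study A `conc_study` from [read_study()]/[profiles_from_table()],
#'   or a long-format study data frame.
#' @param compound_specs Named list of [compound_spec()] (or a single spec)
#'   keyed by compound name.
#' @param physio A [physiology_config()].
#' @param n_terminal Terminal window for [lambda_z()].
#' @param weighting Passed to [fit_ka()].
#' @param fafg_method `"difference"` (default) integrates the paired
#'   portal-systemic difference curve; `"separate"` subtracts the two
#'   per-site AUCs, mirroring how summary tables are assembled.
#' @return A list of class `psdiff_analysis` with elements `nca`
#'   (per-profile NCA table), `absorption` (one row per compound x genotype:
#'   fafg, ba, fh, ka, mat plus flags), and `contribution` (AQ/R per
#'   compound, `NULL` when a full triplet is unavailable).
#' @export
analyze_study <- function(study, compound_specs,
                          physio = physiology_config(),
                          n_terminal = 3,
                          weighting = "uniform",
                          fafg_method = c("difference", "separate")) {
  fafg_method <- match.arg(fafg_method)
  if (is.data.frame(study)) study <- profiles_from_table(study)
  if (inherits(compound_specs, "compound_spec"))
    compound_specs <- stats::setNames(list(compound_specs),
                                      compound_specs$name)
  find_profile <- function(cmp, g, route, site) {
    hit <- Filter(function(p) p$compound == cmp && p$genotype == g &&
                    p$route == route && p$site == site, study)
    if (length(hit) == 0) NULL else hit[[1]]
  }

  nca_rows <- list()
  abs_rows <- list()
  compounds <- unique(vapply(study, `[[`, character(1), "compound"))
  for (cmp in compounds) {
    spec <- compound_specs[[cmp]]
    if (is.null(spec))
      stop("no compound_spec provided for '", cmp, "'", call. = FALSE)
    dose_iv_nmol <- dose_to_nmol_per_kg(spec$dose_iv, spec$mw_dosed)
    dose_oral_nmol <- dose_to_nmol_per_kg(spec$dose_oral, spec$mw_dosed)
    genotypes <- unique(vapply(
      Filter(function(p) p$compound == cmp, study), `[[`, character(1),
      "genotype"))
    for (g in genotypes) {
      p_iv <- find_profile(cmp, g, "iv", "systemic")
      p_sys <- find_profile(cmp, g, "oral", "systemic")
      p_pv <- find_profile(cmp, g, "oral", "portal")

      nca_iv <- nca_sys <- nca_pv <- NULL
      if (!is.null(p_iv)) {
        nca_iv <- nca(p_iv, dose_nmol_per_kg = dose_iv_nmol,
                      n_terminal = n_terminal)
        nca_rows[[length(nca_rows) + 1]] <- nca_iv
      }
      if (!is.null(p_sys)) {
        nca_sys <- nca(p_sys, n_terminal = n_terminal)
        nca_rows[[length(nca_rows) + 1]] <- nca_sys
      }
      if (!is.null(p_pv)) {
        nca_pv <- nca(p_pv, n_terminal = n_terminal)
        nca_rows[[length(nca_rows) + 1]] <- nca_pv
      }

      fafg_val <- ba_val <- fh_val <- ka_val <- mat_val <- NA_real_
      flags <- character(0)
      if (!is.null(nca_pv) && !is.null(nca_sys)) {
        fa <- if (fafg_method == "difference") {
          fafg_profiles(p_pv, p_sys, rb = spec$rb, qpv = physio$qpv,
                        dose_oral = dose_oral_nmol)
        } else {
          fafg(nca_pv$auc_inf, nca_sys$auc_inf, rb = spec$rb,
               qpv = physio$qpv, dose_oral = dose_oral_nmol)
        }
        fafg_val <- fa$fafg
        flags <- c(flags, fa$flags)
      }
      if (!is.null(nca_sys) && !is.null(nca_iv)) {
        ba_val <- bioavailability(nca_sys$auc_inf, nca_iv$auc_inf,
                                  spec$dose_iv, spec$dose_oral)
        mat_val <- nca_sys$mrt - nca_iv$mrt
      }
      if (is.finite(ba_val) && is.finite(fafg_val) && fafg_val > 0)
        fh_val <- hepatic_availability(ba_val, fafg_val)
      if (!is.null(p_sys) && !is.null(nca_iv)) {
        fit <- try(fit_ka(p_sys, ke = nca_iv$lambda_z,
                          weighting = weighting), silent = TRUE)
        if (!inherits(fit, "try-error")) {
          ka_val <- fit$ka
          if (fit$at_bound) flags <- c(flags, "ka_at_bound")
        } else {
          flags <- c(flags, "ka_fit_failed")
        }
      }
      abs_rows[[length(abs_rows) + 1]] <- data.frame(
        compound = cmp, genotype = g, fafg = fafg_val, ba = ba_val,
        fh = fh_val, ka = ka_val, mat = mat_val,
        flags = paste(flags, collapse = ";"))
    }
  }
  absorption <- do.call(rbind, c(abs_rows, list(make.row.names = FALSE)))

  contribution <- NULL
  trip <- function(df, col) {
    if (!all(GENOTYPES %in% df$genotype)) return(NULL)
    v <- stats::setNames(df[[col]], df$genotype)[GENOTYPES]
    if (any(!is.finite(v))) return(NULL)
    unname(v)
  }
  contrib_rows <- lapply(unique(absorption$compound), function(cmp) {
    df <- absorption[absorption$compound == cmp, ]
    ka_t <- trip(df, "ka")
    fa_t <- trip(df, "fafg")
    if (is.null(ka_t) && is.null(fa_t)) return(NULL)
    aq <- if (!is.null(ka_t) && all(ka_t > 0)) aq_in_vivo(ka_t) else NULL
    rr <- if (!is.null(fa_t) && all(fa_t >= 0)) r_contribution(fa_t) else NULL
    data.frame(
      compound = cmp,
      aq_bcrp = if (is.null(aq)) NA_real_ else aq$aq_bcrp,
      aq_pgp = if (is.null(aq)) NA_real_ else aq$aq_pgp,
      aq_estimable = if (is.null(aq)) FALSE else aq$estimable,
      r_bcrp = if (is.null(rr)) NA_real_ else rr$r_bcrp,
      r_pgp = if (is.null(rr)) NA_real_ else rr$r_pgp,
      r_estimable = if (is.null(rr)) FALSE else rr$estimable)
  })
  contrib_rows <- Filter(Negate(is.null), contrib_rows)
  if (length(contrib_rows) > 0)
    contribution <- do.call(rbind, c(contrib_rows,
                                     list(make.row.names = FALSE)))

  structure(list(nca = do.call(rbind, c(nca_rows,
                                        list(make.row.names = FALSE))),
                 absorption = absorption, contribution = contribution),
            class = "psdiff_analysis")
}

#' @export
print.psdiff_analysis <- function(x, ...) {
  cat("<psdiff_analysis>\n-- absorption summary --\n")
  print(x$absorption)
  if (!is.null(x$contribution)) {
    cat("-- transporter contribution --\n")
    print(x$contribution)
  }
  invisible(x)
}

#' Write report tables for an analysis
#'
#' Emits per-stage CSVs mirroring the standard report layout: the NCA
#' parameter table (3 significant figures), the absorption summary
#' (fractions rendered as percent), the AQ/R contribution table (2
#' decimals, dashes for not-estimable cells) and, when in vitro scores are
#' supplied, the quadrant table.
#'
#' @param analysis A `psdiff_analysis` from [analyze_study()].
#' @param dir Output directory (created if missing).
#' @param invitro Optional data frame `compound, aq_bcrp, aq_pgp` of
#'   in vitro scores for [ivivc_table()].
#' @param threshold Quadrant criterion.
#' @return Invisibly, the vector of file paths written.
#' @export
write_report_tables <- function(analysis, dir, invitro = NULL,
                                threshold = 0.4) {
  stopifnot(inherits(analysis, "psdiff_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  nca_tab <- analysis$nca
  num <- vapply(nca_tab, is.numeric, logical(1))
  nca_tab[num] <- lapply(nca_tab[num], signif, digits = 3)
  wr(nca_tab, "nca_parameters.csv")
  abs_tab <- analysis$absorption
  for (col in c("fafg", "ba", "fh")) {
    abs_tab[[paste0(col, "_pct")]] <- round(100 * abs_tab[[col]], 1)
  }
  wr(abs_tab, "absorption_summary.csv")
  if (!is.null(analysis$contribution)) {
    ct <- analysis$contribution
    ct[c("aq_bcrp", "aq_pgp", "r_bcrp", "r_pgp")] <-
      lapply(ct[c("aq_bcrp", "aq_pgp", "r_bcrp", "r_pgp")], round, 2)
    wr(ct, "contribution_scores.csv")
    if (!is.null(invitro)) {
      invivo <- analysis$contribution[c("compound", "r_bcrp", "r_pgp")]
      wr(ivivc_table(invitro, invivo, threshold), "ivivc_quadrants.csv")
    }
  }
  invisible(paths)
}

#' Path to a packaged example table
#'
#' The package ships small plain-text summary tables (printed AUC, ka,
#' FaFg and in vitro AQ values for four reference compounds) used by the
#' regression tests and examples.
#'
#' @param name File name under `extdata/`; with no argument, lists the
#'   available files.
#' @return A file path (or a vector of file names).
#' @export
#' @examples
#' psdiff_example()
#' utils::read.csv(psdiff_example("fafg_triplets.csv"))
psdiff_example <- function(name = NULL) {
  if (is.null(name))
    return(dir(system.file("extdata", package = "psdiff")))
  path <- system.file("extdata", name, package = "psdiff")
  if (path == "") stop("no packaged file called '", name, "'", call. = FALSE)
  path
}
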