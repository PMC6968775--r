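# Transporter-contribution scores and the in vitro / in vivo quadrant.

#' Genotype triplet
#'
#' Holds one value per genotype arm (wild-type, Bcrp knockout, Mdr1a/1b
#' knockout) of either an absorption rate constant (`kind = "ka"`) or an
#' apparent absorbed fraction (`kind = "fafg"`).
#'
#' @param wt,bcrp_ko,pgp_ko Finite values; must be > 0 for `kind = "ka"`,
#'   >= 0 for `kind = "fafg"`.
#' @param kind `"ka"` or `"fafg"`.
#' @return An object of class `genotype_triplet`.
#' @export
genotype_triplet <- function(wt, bcrp_ko, pgp_ko, kind = c("ka", "fafg")) {
  kind <- match.arg(kind)
  v <- c(wt = wt, bcrp_ko = bcrp_ko, pgp_ko = pgp_ko)
  if (any(!is.finite(v)))
    stop("triplet values must be finite", call. = FALSE)
  if (kind == "ka" && any(v <= 0))
    stop("ka triplet values must be > 0", call. = FALSE)
  if (kind == "fafg" && any(v < 0))
    stop("fafg triplet values must be >= 0", call. = FALSE)
  structure(list(wt = wt, bcrp_ko = bcrp_ko, pgp_ko = pgp_ko, kind = kind),
            class = "genotype_triplet")
}

# Shared normalized-delta algebra behind AQ and R:
#   delta_b = x_bcrp - x_wt; delta_p = x_pgp - x_wt
#   D = x_wt + delta_b + delta_p
#   score_b = delta_b / D; score_p = delta_p / D
# A negative delta means the knockout LOWERED the quantity, which the score
# cannot attribute to loss of efflux; the raw quotient is still reported but
# flagged not estimable (rendered "-" in reports).
normalized_delta_scores <- function(wt, bcrp_ko, pgp_ko) {
  delta_b <- bcrp_ko - wt
  delta_p <- pgp_ko - wt
  denom <- wt + delta_b + delta_p
  flags <- character(0)
  if (delta_b < 0) flags <- c(flags, "negative_delta_bcrp")
  if (delta_p < 0) flags <- c(flags, "negative_delta_pgp")
  if (denom <= 0) {
    flags <- c(flags, "zero_denominator", "not_estimable")
    return(list(bcrp = NA_real_, pgp = NA_real_, denom = denom,
                estimable = FALSE, flags = flags))
  }
  if (length(flags) > 0) flags <- c(flags, "not_estimable")
  list(bcrp = delta_b / denom, pgp = delta_p / denom, denom = denom,
       estimable = length(flags) == 0, flags = flags)
}

#' In vivo absorptive quotient (AQ) from a ka triplet
#'
#' The normalized increase in the absorption rate constant upon knockout of
#' each efflux transporter:
#' `AQ_bcrp = (ka_bcrp - ka_wt) / (ka_wt + (ka_bcrp - ka_wt) + (ka_pgp - ka_wt))`
#' and symmetrically for P-gp. When either knockout lowers ka the score loses
#' its interpretation as an attributable fraction; the raw quotient is still
#' returned with a `not_estimable` flag.
#'
#' @param ka A [genotype_triplet()] of kind `"ka"`, or a numeric vector
#'   `c(wt, bcrp_ko, pgp_ko)`.
#' @return A list with `aq_bcrp`, `aq_pgp`, `denominator`, `estimable`,
#'   `flags`.
#' @export
#' @examples
#' aq_in_vivo(c(3.18, 5.18, 3.68)) # topotecan: AQ_bcrp ~0.35
aq_in_vivo <- function(ka) {
  ka <- as_triplet(ka, "ka")
  s <- normalized_delta_scores(ka$wt, ka$bcrp_ko, ka$pgp_ko)
  list(aq_bcrp = s$bcrp, aq_pgp = s$pgp, denominator = s$denom,
       estimable = s$estimable, flags = s$flags)
}

#' Rate of contribution (R) from a FaFg triplet
#'
#' The same normalized-delta algebra as [aq_in_vivo()] applied to the
#' apparent absorbed fractions across genotypes:
#' `R_bcrp = (FaFg_bcrp - FaFg_wt) / (FaFg_wt + (FaFg_bcrp - FaFg_wt) + (FaFg_pgp - FaFg_wt))`.
#' When both deltas are non-negative the scores and `FaFg_wt / D` partition
#' unity exactly.
#'
#' @param fafg A [genotype_triplet()] of kind `"fafg"`, or a numeric vector
#'   `c(wt, bcrp_ko, pgp_ko)`.
#' @return A list with `r_bcrp`, `r_pgp`, `denominator`, `estimable`,
#'   `flags`.
#' @export
#' @examples
#' r_contribution(c(0.16, 1.30, 0.30)) # sulfasalazine: R_bcrp ~0.79
r_contribution <- function(fafg) {
  fafg <- as_triplet(fafg, "fafg")
  s <- normalized_delta_scores(fafg$wt, fafg$bcrp_ko, fafg$pgp_ko)
  list(r_bcrp = s$bcrp, r_pgp = s$pgp, denominator = s$denom,
       estimable = s$estimable, flags = s$flags)
}

as_triplet <- function(x, kind) {
  if (inherits(x, "genotype_triplet")) {
    if (x$kind != kind)
      stop(sprintf("expected a %s-kind triplet", kind), call. = FALSE)
    return(x)
  }
  if (is.numeric(x) && length(x) == 3)
    return(genotype_triplet(x[[1]], x[[2]], x[[3]], kind = kind))
  stop("expected a genotype_triplet or a numeric vector of length 3",
       call. = FALSE)
}

#' Quadrant classification of in vitro vs in vivo transporter scores
#'
#' Places a compound x transporter pair in the true/false positive/negative
#' scheme by comparing the in vitro absorptive quotient (Caco-2) and the
#' in vivo rate of contribution against a common criterion (default 0.4,
#' applied as a closed bound: values equal to the threshold count as
#' positive).
#'
#' @param aq_in_vitro In vitro AQ score (input, from a Caco-2 assay).
#' @param r_in_vivo In vivo R score.
#' @param threshold Decision criterion in (0, 1); default 0.4.
#' @return One of `"T_pos"`, `"T_neg"`, `"F_pos"`, `"F_neg"`:
#'   `T_pos` when both axes are at/above the threshold, `T_neg` when both
#'   are below, `F_pos` when only the in vitro score is at/above, `F_neg`
#'   when only the in vivo score is.
#' @export
classify_quadrant <- function(aq_in_vitro, r_in_vivo, threshold = 0.4) {
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  if (!is.finite(aq_in_vitro) || !is.finite(r_in_vivo))
    stop("classification refused: score not estimable", call. = FALSE)
  vitro_pos <- aq_in_vitro >= threshold
  vivo_pos <- r_in_vivo >= threshold
  if (vitro_pos && vivo_pos) "T_pos"
  else if (!vitro_pos && !vivo_pos) "T_neg"
  else if (vitro_pos) "F_pos"
  else "F_neg"
}

#' Contribution summary table for a set of compounds
#'
#' Applies [aq_in_vivo()] and [r_contribution()] row-wise and returns a
#' report-shaped data frame (full precision plus 2-decimal rendering, the
#' not-estimable cells rendered as `"-"`).
#'
#' @param ka_triplets Data frame with columns `compound, wt, bcrp_ko,
#'   pgp_ko` of ka values (1/h); may be `NULL` to skip AQ.
#' @param fafg_triplets Data frame with the same columns of FaFg fractions;
#'   may be `NULL` to skip R.
#' @return A data frame keyed by compound with `aq_bcrp, aq_pgp, r_bcrp,
#'   r_pgp` numeric columns and `aq_display_*`, `r_display_*` rendered
#'   columns.
#' @export
contribution_table <- function(ka_triplets = NULL, fafg_triplets = NULL) {
  if (is.null(ka_triplets) && is.null(fafg_triplets))
    stop("need at least one of ka_triplets, fafg_triplets", call. = FALSE)
  compounds <- unique(c(ka_triplets$compound, fafg_triplets$compound))
  render <- function(x, ok) ifelse(ok, sprintf("%.2f", x), "-")
  out <- data.frame(compound = compounds)
  if (!is.null(ka_triplets)) {
    aq <- lapply(compounds, function(cmp) {
      row <- ka_triplets[ka_triplets$compound == cmp, ]
      if (nrow(row) == 0) return(list(aq_bcrp = NA, aq_pgp = NA,
                                      estimable = FALSE))
      aq_in_vivo(c(row$wt, row$bcrp_ko, row$pgp_ko))
    })
    out$aq_bcrp <- vapply(aq, `[[`, numeric(1), "aq_bcrp")
    out$aq_pgp <- vapply(aq, `[[`, numeric(1), "aq_pgp")
    ok <- vapply(aq, `[[`, logical(1), "estimable")
    out$aq_display_bcrp <- render(out$aq_bcrp, ok)
    out$aq_display_pgp <- render(out$aq_pgp, ok)
  }
  if (!is.null(fafg_triplets)) {
    rr <- lapply(compounds, function(cmp) {
      row <- fafg_triplets[fafg_triplets$compound == cmp, ]
      if (nrow(row) == 0) return(list(r_bcrp = NA, r_pgp = NA,
                                      estimable = FALSE))
      r_contribution(c(row$wt, row$bcrp_ko, row$pgp_ko))
    })
    out$r_bcrp <- vapply(rr, `[[`, numeric(1), "r_bcrp")
    out$r_pgp <- vapply(rr, `[[`, numeric(1), "r_pgp")
    ok <- vapply(rr, `[[`, logical(1), "estimable")
    out$r_display_bcrp <- render(out$r_bcrp, ok)
    out$r_display_pgp <- render(out$r_pgp, ok)
  }
  out
}

#' In vitro / in vivo correlation table
#'
#' Joins in vitro AQ scores (assay inputs) with in vivo R scores and
#' classifies every compound x transporter pair into its quadrant.
#'
#' @param invitro Data frame with columns `compound, aq_bcrp, aq_pgp`
#'   (Caco-2 scores).
#' @param invivo Data frame with columns `compound, r_bcrp, r_pgp`.
#' @param threshold Criterion passed to [classify_quadrant()].
#' @return A long data frame with one row per compound x transporter:
#'   `compound, transporter, aq_in_vitro, r_in_vivo, quadrant`.
#' @export
ivivc_table <- function(invitro, invivo, threshold = 0.4) {
  merged <- merge(invitro, invivo, by = "compound")
  rows <- lapply(seq_len(nrow(merged)), function(i) {
    m <- merged[i, ]
    data.frame(
      compound = rep(m$compound, 2),
      transporter = c("BCRP", "Pgp"),
      aq_in_vitro = c(m$aq_bcrp, m$aq_pgp),
      r_in_vivo = c(m$r_bcrp, m$r_pgp),
      quadrant = c(classify_quadrant(m$aq_bcrp, m$r_bcrp, threshold),
                   classify_quadrant(m$aq_pgp, m$r_pgp, threshold))
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
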