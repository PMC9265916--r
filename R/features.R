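# Stable-isotope delta notation and fatty-acid feature engineering.

# International reference ratios for the two elements handled here.
# 13C/12C of Vienna Pee Dee Belemnite; 15N/14N of atmospheric N2.
.REFERENCE_RATIOS <- c("VPDB" = 0.0111802, "air-N2" = 0.0036765)

#' Reference isotope ratio of a measurement standard
#'
#' @param reference `"VPDB"` (carbon) or `"air-N2"` (nitrogen).
#' @return the heavy/light abundance ratio of the standard.
#' @export
reference_ratio <- function(reference = c("VPDB", "air-N2")) {
  reference <- match.arg(reference)
  unname(.REFERENCE_RATIOS[reference])
}

#' Convert an isotope abundance ratio to delta notation
#'
#' delta = (R_sample / R_standard - 1) * 1000, in per mil. Carbon ratios
#' are reported against VPDB, nitrogen against atmospheric N2.
#'
#' @param r_sample heavy/light abundance ratio of the sample (> 0).
#' @param r_standard heavy/light abundance ratio of the reference standard
#'   (> 0); defaults to VPDB. May also be `"VPDB"` or `"air-N2"`.
#' @return delta values in per mil (permille).
#' @seealso [ratio_from_delta()] for the inverse.
#' @examples
#' delta_from_ratio(0.0109, "VPDB")
#' @export
delta_from_ratio <- function(r_sample, r_standard = "VPDB") {
  if (is.character(r_standard)) r_standard <- reference_ratio(r_standard)
  if (any(!is.finite(r_sample)) || any(r_sample <= 0)) {
    stopf("isotope ratios must be finite and positive")
  }
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stopf("the standard ratio must be finite and positive")
  }
  (r_sample / r_standard - 1) * 1000
}

#' Recover an abundance ratio from a delta value
#'
#' Algebraic inverse of [delta_from_ratio()]:
#' R_sample = R_standard * (1 + delta/1000). Deltas at or below -1000 permil
#' would imply a nonpositive ratio and are rejected.
#'
#' @param delta delta values in per mil; must exceed -1000.
#' @param r_standard reference ratio (numeric > 0, or `"VPDB"` / `"air-N2"`).
#' @return heavy/light abundance ratios.
#' @export
ratio_from_delta <- function(delta, r_standard = "VPDB") {
  if (is.character(r_standard)) r_standard <- reference_ratio(r_standard)
  if (any(!is.finite(delta)) || any(delta <= -1000)) {
    stopf("delta must be finite and > -1000 permil (nonphysical ratio)")
  }
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stopf("the standard ratio must be finite and positive")
  }
  r_standard * (1 + delta / 1000)
}

# ---- fatty-acid naming and classes ---------------------------------------

# The fixed 15-FA panel: five saturated, five monounsaturated, five
# polyunsaturated fatty acids. 14:0 completes the saturated five; the other
# fourteen identities are those named for this assay panel.
.FA_NAMES <- c(
  "14:0", "15:0", "16:0", "17:0", "18:0",
  "16:1n-7", "18:1n-7", "18:1n-9", "20:1n-7", "20:1n-9",
  "18:2n-6", "18:3n-3", "20:4n-6", "20:5n-3", "22:6n-3"
)
.FA_CLASS <- stats::setNames(
  rep(c("SFA", "MUFA", "PUFA"), each = 5L), .FA_NAMES
)

# Diet-source biomarker pairs: diatoms, flagellates, bacteria.
.BIOMARKERS <- list(
  diatom     = c("20:5n-3", "16:1n-7"),
  flagellate = c("18:1n-9", "22:6n-3"),
  bacteria   = c("17:0", "18:1n-7")
)

#' The 15 fatty acids of the profiling panel
#' @return character vector of FA shorthand names, SFAs first, then MUFAs,
#'   then PUFAs.
#' @export
fa_names <- function() .FA_NAMES

#' Saturation class of each panel fatty acid
#' @return named character vector mapping FA name to
#'   `"SFA"`/`"MUFA"`/`"PUFA"`.
#' @export
fa_class_map <- function() .FA_CLASS

#' Relative fatty-acid composition
#'
#' Normalizes raw FA quantities (peak areas, concentrations) to percent of
#' total identified FAs. The result is scale-invariant: multiplying the
#' input by any positive constant leaves it unchanged.
#'
#' @param raw named nonnegative numeric vector of FA quantities; at least
#'   one entry must be positive.
#' @return an object of class `fa_profile`: a list with `abundances`
#'   (named percentages summing to 100) and `class_map` (saturation class
#'   of each named FA, `NA` for names outside the panel).
#' @examples
#' relative_composition(c("16:0" = 1, "18:0" = 1, "22:6n-3" = 2))
#' @export
relative_composition <- function(raw) {
  if (is.null(names(raw)) || any(!nzchar(names(raw)))) {
    stopf("'raw' must be a fully named numeric vector of FA quantities")
  }
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stopf("FA quantities must be finite and nonnegative")
  }
  total <- sum(raw)
  if (total <= 0) stopf("all FA quantities are zero; composition undefined")
  structure(
    list(
      abundances = 100 * raw / total,
      class_map = .FA_CLASS[names(raw)]
    ),
    class = "fa_profile"
  )
}

#' @export
print.fa_profile <- function(x, ...) {
  cat("Fatty-acid profile (% of total identified FAs)\n")
  print(round(x$abundances, 2))
  cls <- x$class_map[!is.na(x$class_map)]
  if (length(cls)) {
    tot <- tapply(x$abundances[names(cls)], cls, sum)
    cat("Class totals:",
        paste(names(tot), sprintf("%.1f%%", tot), collapse = ", "), "\n")
  }
  invisible(x)
}

# Coerce a named percent vector or fa_profile to percent abundances.
as_fa_percent <- function(profile) {
  if (inherits(profile, "fa_profile")) return(profile$abundances)
  if (is.numeric(profile) && !is.null(names(profile))) return(profile)
  stopf("'profile' must be an fa_profile or a named numeric vector")
}

#' Diet-source biomarker summary of a fatty-acid profile
#'
#' Computes the biomarker sums and ratios used to interpret clam diet:
#' diatom signal (20:5n-3 + 16:1n-7), flagellate signal (18:1n-9 +
#' 22:6n-3), bacterial signal (17:0 + 18:1n-7), the DHA/EPA ratio
#' (22:6n-3 / 20:5n-3, > 1 under dinoflagellate-dominated diets), and the
#' PUFA/SFA ratio.
#'
#' @param profile an [fa_profile][relative_composition] or named percent
#'   vector containing at least the six biomarker FAs.
#' @return named numeric vector with elements `diatom_pct`,
#'   `flagellate_pct`, `bacteria_pct`, `dha_epa_ratio`, `pufa_sfa_ratio`.
#'   Ratios with a zero denominator are reported as `NA` rather than
#'   raising an error.
#' @export
biomarker_summary <- function(profile) {
  pct <- as_fa_percent(profile)
  needed <- unique(unlist(.BIOMARKERS))
  missing <- setdiff(needed, names(pct))
  if (length(missing)) {
    stopf("profile is missing biomarker FA(s): %s",
          paste(missing, collapse = ", "))
  }
  cls <- .FA_CLASS[names(pct)]
  sfa <- sum(pct[!is.na(cls) & cls == "SFA"])
  pufa <- sum(pct[!is.na(cls) & cls == "PUFA"])
  epa <- unname(pct[["20:5n-3"]])
  dha <- unname(pct[["22:6n-3"]])
  c(
    diatom_pct = sum(pct[.BIOMARKERS$diatom]),
    flagellate_pct = sum(pct[.BIOMARKERS$flagellate]),
    bacteria_pct = sum(pct[.BIOMARKERS$bacteria]),
    dha_epa_ratio = if (epa > 0) dha / epa else NA_real_,
    pufa_sfa_ratio = if (sfa > 0) pufa / sfa else NA_real_
  )
}

#' Append biomarker summary columns to a sample table
#'
#' Computes [biomarker_summary()] for every row of a wide sample table
#' (as produced by [generate_samples()]) and appends the five summary
#' columns.
#'
#' @param samples data frame with the 15 FA percentage columns.
#' @return `samples` with columns `diatom_pct`, `flagellate_pct`,
#'   `bacteria_pct`, `dha_epa_ratio`, `pufa_sfa_ratio` appended.
#' @export
add_biomarkers <- function(samples) {
  fa_cols <- intersect(.FA_NAMES, names(samples))
  needed <- unique(unlist(.BIOMARKERS))
  missing <- setdiff(needed, fa_cols)
  if (length(missing)) {
    stopf("sample table is missing biomarker FA column(s): %s",
          paste(missing, collapse = ", "))
  }
  summ <- t(vapply(
    seq_len(nrow(samples)),
    function(i) {
      v <- as.numeric(samples[i, fa_cols])
      names(v) <- fa_cols
      biomarker_summary(v)
    },
    numeric(5)
  ))
  cbind(samples, as.data.frame(summ))
}
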