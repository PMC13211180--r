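# Deterministic conversions from raw assay readouts to the units used
# downstream. Only conversions whose constants are fixed by the assay
# chemistry are provided: cell-viability counts, GST activity via the
# CDNB extinction coefficient, and SOD units from the fractional
# inhibition of pyrogallol autoxidation. GPx and MDA enter the
# pipeline as already-computed values.

#' Assay constants
#'
#' The fixed constants behind the unit conversions: the CDNB-conjugate
#' extinction coefficient at 340 nm (9.6 per mM per cm) and the
#' fractional inhibition of autoxidation defining one SOD unit (0.5).
#'
#' @return A named list with `epsilon_cdnb` and `sod_unit_inhibition`.
#' @export
assay_constants <- function() {
  list(epsilon_cdnb = 9.6, sod_unit_inhibition = 0.5)
}

#' Cell viability from live/total counts
#'
#' `100 * viable_count / total_count`, the percent of cells unstained
#' by Trypan Blue or retaining Neutral Red.
#'
#' @param viable_count Nonnegative integer count(s) of viable cells.
#' @param total_count Positive integer total cell count(s).
#' @return Percent viability in \[0, 100\].
#' @export
#' @examples
#' cell_viability(171, 200) # 85.5
cell_viability <- function(viable_count, total_count) {
  if (!is.numeric(viable_count) || !is.numeric(total_count) ||
      any(!is.finite(viable_count)) || any(!is.finite(total_count)) ||
      any(viable_count != round(viable_count)) ||
      any(total_count != round(total_count))) {
    stop("counts must be finite integers", call. = FALSE)
  }
  if (any(total_count <= 0)) stop("total_count must be positive", call. = FALSE)
  if (any(viable_count < 0)) stop("viable_count must be nonnegative", call. = FALSE)
  if (any(viable_count > total_count)) {
    stop("viable_count cannot exceed total_count", call. = FALSE)
  }
  100 * viable_count / total_count
}

#' GST activity from the CDNB kinetic slope
#'
#' Converts an absorbance slope at 340 nm into protein-normalized GST
#' activity. The slope in absorbance per minute is divided by
#' `epsilon * path` (Beer-Lambert) to give mM of conjugate formed per
#' minute, scaled to nmol per mL per minute, and divided by the
#' protein concentration. A negative slope (photobleaching or blank
#' drift) is clamped to zero with a warning.
#'
#' @param delta_A340_per_min Absorbance change per minute.
#' @param path_cm Optical path length in cm (positive).
#' @param protein_ug_per_ml Protein concentration in ug per mL
#'   (positive).
#' @return Activity in nmol per (ug protein x min).
#' @export
#' @examples
#' gst_activity(0.096, path_cm = 1, protein_ug_per_ml = 100) # 0.1
gst_activity <- function(delta_A340_per_min, path_cm = 1, protein_ug_per_ml) {
  if (any(!is.finite(delta_A340_per_min))) {
    stop("delta_A340_per_min must be finite", call. = FALSE)
  }
  if (any(!is.finite(path_cm)) || any(path_cm <= 0)) {
    stop("path_cm must be positive", call. = FALSE)
  }
  if (any(!is.finite(protein_ug_per_ml)) || any(protein_ug_per_ml <= 0)) {
    stop("protein_ug_per_ml must be positive", call. = FALSE)
  }
  if (any(delta_A340_per_min < 0)) {
    warning("negative absorbance slope clamped to zero")
    delta_A340_per_min <- pmax(delta_A340_per_min, 0)
  }
  rate_mM_per_min <- delta_A340_per_min / (assay_constants()$epsilon_cdnb * path_cm)
  (rate_mM_per_min * 1000) / protein_ug_per_ml # 1 mM = 1000 nmol / mL
}

#' SOD units from fractional inhibition of autoxidation
#'
#' One unit of SOD is the amount inhibiting autoxidation by 50%; the
#' conversion interpolates linearly through (0 -> 0 U, 0.5 -> 1 U),
#' the standard pyrogallol-assay convention. Complete inhibition is
#' outside the linear range and rejected.
#'
#' @param inhibition_fraction Fraction of autoxidation inhibited, in
#'   \[0, 1).
#' @return Activity in U per mL; per-mg-protein normalization is the
#'   caller's responsibility.
#' @export
#' @examples
#' sod_units(0.5) # 1
sod_units <- function(inhibition_fraction) {
  if (any(!is.finite(inhibition_fraction)) || any(inhibition_fraction < 0)) {
    stop("inhibition_fraction must be in [0, 1)", call. = FALSE)
  }
  if (any(inhibition_fraction >= 1)) {
    stop("complete inhibition (fraction >= 1) is outside the linear convention",
         call. = FALSE)
  }
  inhibition_fraction / assay_constants()$sod_unit_inhibition
}
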