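## Serology-derived quantities: arbitrary units, percentile cutoffs,
## net optical density, antiphospholipid positivity.

#' Anti-protein antibody level in arbitrary units
#'
#' Expresses a sample's ELISA signal as a percentage of a high-titer
#' positive reference serum run on the same plate: `100 * sample /
#' reference`.
#'
#' @param sampleSignal numeric sample signal(s) (e.g. optical density).
#' @param referenceSignal positive-reference signal (> 0).
#' @return arbitrary units (AU), same length as `sampleSignal`.
#' @examples
#' antiCrpAU(0.35, 2.0)  # 17.5
#' @export
antiCrpAU <- function(sampleSignal, referenceSignal) {
  if (!is.numeric(referenceSignal) || length(referenceSignal) != 1L ||
      !is.finite(referenceSignal) || referenceSignal <= 0)
    stop("calibration error: reference signal must be a positive scalar")
  100 * sampleSignal / referenceSignal
}

#' Empirical percentile cutoff (nearest rank)
#'
#' Positivity cutoffs derived from a healthy-donor panel, e.g. the 95th
#' percentile of 100 healthy blood donors. Uses the nearest-rank
#' convention: the `ceiling(pct/100 * n)`-th order statistic (no
#' interpolation). Positivity downstream is strict (`value > cutoff`).
#'
#' @param values numeric vector (at least 2 values).
#' @param pct percentile in (0, 100] (default 95).
#' @return the cutoff value.
#' @examples
#' percentileCutoff(1:100, 95)  # 95
#' @export
percentileCutoff <- function(values, pct = 95) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("data error: no values to take a percentile of")
  if (length(values) < 2L)
    warning("percentile cutoff from fewer than 2 values")
  stopifnot(pct > 0, pct <= 100)
  sort(values)[ceiling(pct / 100 * length(values))]
}

#' Net optical density with zero flooring
#'
#' Background-corrected ELISA signal: coated-well OD minus the OD of the
#' matching non-coated well, floored at zero (negative net values are set
#' to 0).
#'
#' @param coated,uncoated numeric OD vectors (recycled).
#' @return non-negative netOD vector.
#' @examples
#' netOD(0.8, 0.3)  # 0.5
#' netOD(0.2, 0.4)  # 0
#' @export
netOD <- function(coated, uncoated) {
  stopifnot(is.numeric(coated), is.numeric(uncoated),
            all(is.finite(coated)), all(is.finite(uncoated)))
  pmax(coated - uncoated, 0)
}

#' Default antiphospholipid kit cutoffs
#'
#' Reads the packaged JSON config of assay cutoffs (U/ml) for
#' anticardiolipin (aCL) and anti-beta-2-glycoprotein-I IgG/IgM. Values are
#' in the range kit manufacturers recommend; supply your own file to
#' override.
#'
#' @param path JSON file with fields `acl_igg`, `acl_igm`, `b2gpi_igg`,
#'   `b2gpi_igm`.
#' @return named numeric vector of cutoffs.
#' @export
aplCutoffs <- function(path = system.file("extdata", "apl_cutoffs.json",
                                          package = "epitiler")) {
  cfg <- read_json(path, simplifyVector = TRUE)
  need <- c("acl_igg", "acl_igm", "b2gpi_igg", "b2gpi_igm")
  stopifnot(all(need %in% names(cfg)))
  unlist(cfg[need])
}

#' Antiphospholipid antibody positivity
#'
#' Positive when any of the four assays (aCL IgG/IgM, anti-beta-2GPI
#' IgG/IgM) strictly exceeds its kit cutoff.
#'
#' @param aclIgg,aclIgm,b2gpiIgg,b2gpiIgm numeric assay values in U/ml
#'   (vectors recycled to common length).
#' @param cutoffs named cutoffs as returned by [aplCutoffs()].
#' @return logical vector.
#' @export
aplPositive <- function(aclIgg, aclIgm, b2gpiIgg, b2gpiIgm,
                        cutoffs = aplCutoffs()) {
  aclIgg > cutoffs[["acl_igg"]] | aclIgm > cutoffs[["acl_igm"]] |
    b2gpiIgg > cutoffs[["b2gpi_igg"]] | b2gpiIgm > cutoffs[["b2gpi_igm"]]
}

#' Derive serology and activity flags for a subject table
#'
#' Adds (or recomputes) the derived columns of a clinical/serology table:
#' `anti_crp_positive` (AU strictly above the healthy-donor percentile
#' cutoff), `apl_positive` ([aplPositive()] over the four assays) and
#' `active` (disease-activity score of at least 5).
#'
#' @param records data.frame with one row per subject; must contain
#'   `anti_crp_au`, the four aPL assay columns and `sledai2k`.
#' @param antiCrpCutoff AU cutoff (e.g. [percentileCutoff()] of a
#'   healthy-donor panel).
#' @param cutoffs aPL kit cutoffs, see [aplCutoffs()].
#' @return the table with the three derived columns set.
#' @export
deriveSerologyFlags <- function(records, antiCrpCutoff,
                                cutoffs = aplCutoffs()) {
  need <- c("anti_crp_au", "acl_igg", "acl_igm", "b2gpi_igg", "b2gpi_igm",
            "sledai2k")
  stopifnot(all(need %in% names(records)))
  records$anti_crp_positive <- records$anti_crp_au > antiCrpCutoff
  records$apl_positive <- aplPositive(records$acl_igg, records$acl_igm,
                                      records$b2gpi_igg, records$b2gpi_igm,
                                      cutoffs = cutoffs)
  records$active <- records$sledai2k >= 5
  records
}

#' Validate subject-record invariants
#'
#' Checks the internal consistency of a clinical/serology table:
#' `active == (sledai2k >= 5)`, `apl_positive` consistent with the four
#' assay values, and non-negative arbitrary units.
#'
#' @inheritParams deriveSerologyFlags
#' @return `TRUE` invisibly; stops with an informative error otherwise.
#' @export
validateSubjectRecords <- function(records, cutoffs = aplCutoffs()) {
  if (!all(records$active == (records$sledai2k >= 5)))
    stop("invariant violated: active must equal sledai2k >= 5")
  expect <- aplPositive(records$acl_igg, records$acl_igm,
                        records$b2gpi_igg, records$b2gpi_igm,
                        cutoffs = cutoffs)
  if (!all(records$apl_positive == expect))
    stop("invariant violated: apl_positive inconsistent with assay values")
  if (any(records$anti_crp_au < 0))
    stop("invariant violated: arbitrary units must be >= 0")
  invisible(TRUE)
}
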