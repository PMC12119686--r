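## S4 classes for the tiling library, the array container and the cohort matrix.

AA_ALPHABET1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' PeptideTiling: an overlapping-peptide library over a protein monomer
#'
#' Represents the physical peptide library printed on a tiling microarray:
#' the mature protein sequence, the neutral flank appended on both sides,
#' and one row per printed tile. Tile coordinates exist in two systems:
#' positions on the flanked sequence (internal) and 1-based inclusive spans
#' on the mature monomer, clipped to `[1, L]`. Tiles lying wholly inside a
#' flank carry `NA` mature spans; they exist on the physical array but can
#' never support an epitope.
#'
#' @slot proteinId single character label of the antigen.
#' @slot protein the mature amino-acid sequence (one string).
#' @slot flank the flank sequence added before and after the protein.
#' @slot tileLength number of residues per printed peptide.
#' @slot overlap number of shared residues between consecutive tiles.
#' @slot flankedStart integer vector, 1-based start of each tile on the
#'   flanked sequence.
#' @slot matureStart,matureEnd integer vectors, clipped 1-based span of each
#'   tile on the mature sequence (`NA` for flank-only tiles).
#'
#' @seealso [tileSequence()], [tilingTable()], [tileSequences()]
#' @export
setClass("PeptideTiling", slots = c(
  proteinId   = "character",
  protein     = "character",
  flank       = "character",
  tileLength  = "integer",
  overlap     = "integer",
  flankedStart = "integer",
  matureStart = "integer",
  matureEnd   = "integer"
))

setValidity("PeptideTiling", function(object) {
  msg <- character()
  L <- nchar(object@protein)
  step <- object@tileLength - object@overlap
  if (object@overlap < 0L || object@overlap >= object@tileLength)
    msg <- c(msg, "overlap must satisfy 0 <= overlap < tileLength")
  if (!all(grepl(sprintf("^[%s]+$", paste(AA_ALPHABET1, collapse = "")),
                 c(object@protein, if (nzchar(object@flank)) object@flank))))
    msg <- c(msg, "protein and flank must use the 20-letter amino-acid alphabet")
  n <- length(object@flankedStart)
  if (n > 1L && !all(diff(object@flankedStart) == step))
    msg <- c(msg, "consecutive tile starts must differ by tileLength - overlap")
  if (length(object@matureStart) != n || length(object@matureEnd) != n)
    msg <- c(msg, "mature span vectors must match the number of tiles")
  ok <- !is.na(object@matureStart)
  if (any(object@matureStart[ok] < 1L) || any(object@matureEnd[ok] > L))
    msg <- c(msg, "mature spans must lie within [1, protein length]")
  covered <- rep(FALSE, L)
  for (i in which(ok)) covered[object@matureStart[i]:object@matureEnd[i]] <- TRUE
  if (n > 0L && !all(covered))
    msg <- c(msg, "tiles must cover every mature residue")
  if (length(msg)) msg else TRUE
})

#' @describeIn PeptideTiling number of tiles in the library.
#' @param x a `PeptideTiling`.
#' @export
setMethod("length", "PeptideTiling", function(x) length(x@flankedStart))

setMethod("show", "PeptideTiling", function(object) {
  cat(sprintf(
    "PeptideTiling of %s (%d aa): %d tiles of %d aa, %d aa overlap, flank '%s'\n",
    object@proteinId, nchar(object@protein), length(object),
    object@tileLength, object@overlap, object@flank))
})

#' PeptideArrayExperiment: per-subject peptide-array scans
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one row per tile and
#' one column per subject, holding two assays: `intensity` (serum scan) and
#' `background` (pre-serum scan), both in arbitrary fluorescence units.
#' Column data carry `subject_id`, `group` and `control` (a
#' [S4Vectors::NumericList] of control-spot intensities, the antigen grid
#' framing the print area). The tiling library travels in
#' `metadata(x)$tiling`.
#'
#' @seealso [readArrayTable()], [backgroundLevel()], [callPositiveTiles()]
#' @export
setClass("PeptideArrayExperiment", contains = "SummarizedExperiment")

setValidity("PeptideArrayExperiment", function(object) {
  msg <- character()
  if (!all(c("intensity", "background") %in% names(assays(object))))
    msg <- c(msg, "assays must include 'intensity' and 'background'")
  else {
    if (any(assay(object, "intensity") < 0, na.rm = TRUE) ||
        any(assay(object, "background") < 0, na.rm = TRUE))
      msg <- c(msg, "fluorescence values must be >= 0")
  }
  if (!all(c("subject_id", "group", "control") %in% names(colData(object))))
    msg <- c(msg, "colData must have subject_id, group and control")
  tl <- metadata(object)$tiling
  if (!is(tl, "PeptideTiling"))
    msg <- c(msg, "metadata(x)$tiling must be a PeptideTiling")
  else if (length(tl) != nrow(object))
    msg <- c(msg, "row count must equal the number of tiles in the library")
  if (length(msg)) msg else TRUE
})

#' EpitopeMatrix: cohort-harmonized subject-by-epitope positivity
#'
#' Rows are subjects, columns are cohort epitopes (harmonized across
#' subjects). Two aligned matrices are kept: boolean positivity and the
#' per-cell mean signal intensity of the supporting tiles (`NA` where a
#' subject is negative).
#'
#' @slot positive logical matrix, subjects x epitopes.
#' @slot intensity numeric matrix, same shape, `NA` where negative.
#' @slot epitopes data.frame with `start`, `end`, `motif`, `label` per
#'   cohort epitope.
#' @slot subjects data.frame with `subject_id` and `group` per subject.
#'
#' @seealso [harmonizeCohort()], [subjectTotals()], [epitopeCounts()]
#' @export
setClass("EpitopeMatrix", slots = c(
  positive  = "matrix",
  intensity = "matrix",
  epitopes  = "data.frame",
  subjects  = "data.frame"
))

setValidity("EpitopeMatrix", function(object) {
  msg <- character()
  if (!is.logical(object@positive)) msg <- c(msg, "positive must be logical")
  if (!identical(dim(object@positive), dim(object@intensity)))
    msg <- c(msg, "positive and intensity must have identical dimensions")
  if (nrow(object@positive) != nrow(object@subjects))
    msg <- c(msg, "one row per subject required")
  if (ncol(object@positive) != nrow(object@epitopes))
    msg <- c(msg, "one column per epitope required")
  if (anyDuplicated(object@epitopes$label))
    msg <- c(msg, "epitope labels must be unique")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EpitopeMatrix", function(object) {
  grp <- table(object@subjects$group)
  cat(sprintf("EpitopeMatrix: %d subjects (%s) x %d cohort epitopes\n",
              nrow(object@positive),
              paste(sprintf("%d %s", grp, names(grp)), collapse = ", "),
              ncol(object@positive)))
  cat("  epitopes:", paste(object@epitopes$label, collapse = ", "), "\n")
})

#' @rdname EpitopeMatrix-accessors
#' @name EpitopeMatrix-accessors
#' @title Accessors for EpitopeMatrix objects
#' @description `positiveMatrix()` and `intensityMatrix()` return the
#'   subjects-by-epitopes matrices, `epitopeInfo()` and `subjectInfo()` the
#'   corresponding annotation frames, `subjectTotals()` the per-subject
#'   number of positive epitopes, and `epitopeCounts()` the per-group
#'   positive counts per epitope.
#' @param x an `EpitopeMatrix`.
#' @return See description; `epitopeCounts()` returns a data.frame with one
#'   row per epitope and one count column per group.
#' @export
positiveMatrix <- function(x) {
  stopifnot(is(x, "EpitopeMatrix"))
  x@positive
}

#' @rdname EpitopeMatrix-accessors
#' @export
intensityMatrix <- function(x) {
  stopifnot(is(x, "EpitopeMatrix"))
  x@intensity
}

#' @rdname EpitopeMatrix-accessors
#' @export
epitopeInfo <- function(x) {
  stopifnot(is(x, "EpitopeMatrix"))
  x@epitopes
}

#' @rdname EpitopeMatrix-accessors
#' @export
subjectInfo <- function(x) {
  stopifnot(is(x, "EpitopeMatrix"))
  x@subjects
}

#' @rdname EpitopeMatrix-accessors
#' @export
subjectTotals <- function(x) {
  stopifnot(is(x, "EpitopeMatrix"))
  setNames(rowSums(x@positive), x@subjects$subject_id)
}

#' @rdname EpitopeMatrix-accessors
#' @export
epitopeCounts <- function(x) {
  stopifnot(is(x, "EpitopeMatrix"))
  out <- x@epitopes
  for (g in unique(as.character(x@subjects$group)))
    out[[g]] <- colSums(x@positive[x@subjects$group == g, , drop = FALSE])
  out
}
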