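## Array data container, long-format I/O and control-grid QC.

#' Construct a PeptideArrayExperiment
#'
#' @param intensity numeric matrix of serum-scan fluorescence, tiles x
#'   subjects.
#' @param background numeric matrix of pre-serum background fluorescence,
#'   same shape.
#' @param tiling the [PeptideTiling] the rows refer to.
#' @param subjects data.frame with `subject_id` and `group`, one row per
#'   column of `intensity`.
#' @param control list (or [S4Vectors::NumericList]) of control-spot
#'   fluorescence vectors, one per subject (the antigen grid framing the
#'   print area); may be empty vectors.
#' @return a [PeptideArrayExperiment].
#' @export
PeptideArrayExperiment <- function(intensity, background, tiling, subjects,
                                   control = NULL) {
  intensity <- as.matrix(intensity)
  background <- as.matrix(background)
  stopifnot(is(tiling, "PeptideTiling"),
            nrow(subjects) == ncol(intensity),
            all(c("subject_id", "group") %in% names(subjects)))
  if (is.null(control))
    control <- rep(list(numeric()), nrow(subjects))
  colnames(intensity) <- colnames(background) <- subjects$subject_id
  se <- SummarizedExperiment(
    assays = list(intensity = intensity, background = background),
    rowData = DataFrame(tilingTable(tiling)),
    colData = DataFrame(subject_id = subjects$subject_id,
                        group = as.character(subjects$group),
                        control = NumericList(control),
                        row.names = subjects$subject_id),
    metadata = list(tiling = tiling))
  new("PeptideArrayExperiment", se)
}

#' Read / write per-subject array scans in long tabular format
#'
#' The long format has columns `subject_id`, `group`, `tile_index`,
#' `intensity`, `background`. Regular rows carry a numeric tile index;
#' control-spot rows use the reserved tile label `"control"` (background
#' column ignored for those rows). Subjects are ordered by `subject_id`,
#' tiles by index; the reader fails with a completeness error naming the
#' missing tiles if any subject lacks part of the library.
#'
#' @param path file path (tab-separated, UTF-8, '.' decimal).
#' @param tiling the [PeptideTiling] the table refers to.
#' @return `readArrayTable()` returns a [PeptideArrayExperiment];
#'   `writeArrayTable()` returns `path` invisibly.
#' @export
readArrayTable <- function(path, tiling) {
  stopifnot(is(tiling, "PeptideTiling"))
  tab <- read.delim(path, colClasses = c(tile_index = "character"))
  need <- c("subject_id", "group", "tile_index", "intensity", "background")
  if (!all(need %in% names(tab)))
    stop("array table must have columns: ", paste(need, collapse = ", "))
  isCtrl <- tab$tile_index == "control"
  if (any(tab$intensity < 0, na.rm = TRUE) ||
      any(tab$background[!isCtrl] < 0, na.rm = TRUE))
    stop("negative fluorescence value in array table")
  ids <- sort(unique(tab$subject_id))
  n <- length(tiling)
  main <- tab[!isCtrl, ]
  main$tile_index <- as.integer(main$tile_index)
  intensity <- background <- matrix(NA_real_, n, length(ids),
                                    dimnames = list(NULL, ids))
  for (s in ids) {
    rows <- main[main$subject_id == s, ]
    missing <- setdiff(seq_len(n), rows$tile_index)
    if (length(missing) || anyDuplicated(rows$tile_index))
      stop("incomplete array for subject ", s, ": missing/duplicated tiles ",
           paste(utils::head(missing, 10L), collapse = ", "))
    ord <- order(rows$tile_index)
    intensity[, s] <- rows$intensity[ord]
    background[, s] <- rows$background[ord]
  }
  groups <- vapply(ids, function(s)
    as.character(tab$group[tab$subject_id == s][1L]), character(1))
  control <- lapply(ids, function(s)
    tab$intensity[isCtrl & tab$subject_id == s])
  PeptideArrayExperiment(intensity, background, tiling,
                         data.frame(subject_id = ids, group = groups),
                         control = control)
}

#' @rdname readArrayTable
#' @param x a [PeptideArrayExperiment].
#' @export
writeArrayTable <- function(x, path) {
  stopifnot(is(x, "PeptideArrayExperiment"))
  cd <- colData(x)
  n <- nrow(x)
  rows <- lapply(seq_len(ncol(x)), function(j) {
    main <- data.frame(
      subject_id = cd$subject_id[j], group = cd$group[j],
      tile_index = as.character(seq_len(n)),
      intensity = assay(x, "intensity")[, j],
      background = assay(x, "background")[, j])
    ctrl <- cd$control[[j]]
    if (length(ctrl))
      main <- rbind(main, data.frame(
        subject_id = cd$subject_id[j], group = cd$group[j],
        tile_index = "control", intensity = ctrl, background = NA_real_))
    main
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-array background fluorescence level
#'
#' The scalar background against which peptide positivity is judged: the
#' median of the pre-serum background scan of each array. A per-array
#' scalar (rather than per-spot values) is robust to isolated bright
#' pre-scan spots; per-spot mode is available in [callPositiveTiles()].
#'
#' @param x a [PeptideArrayExperiment], or a numeric vector of one array's
#'   background scan.
#' @return named numeric vector, one median per subject (or one scalar).
#' @export
backgroundLevel <- function(x) {
  if (is.numeric(x)) {
    stopifnot(length(x) > 0L)
    return(median(x))
  }
  stopifnot(is(x, "PeptideArrayExperiment"))
  apply(assay(x, "background"), 2L, median)
}

#' Control-grid quality check
#'
#' An array passes if the median fluorescence of its control spots (the
#' antigen grid stained in the final scan) reaches `minFold` times the
#' array's background level. QC is advisory: failing arrays are flagged,
#' not dropped, unless downstream steps are asked to exclude them.
#'
#' @param x a [PeptideArrayExperiment].
#' @param minFold minimum control-to-background fold (default 2).
#' @return data.frame `subject_id`, `control_pass`, `background_level`,
#'   `control_median`, `note`.
#' @export
qcControlGrid <- function(x, minFold = 2.0) {
  stopifnot(is(x, "PeptideArrayExperiment"))
  bg <- backgroundLevel(x)
  cd <- colData(x)
  out <- lapply(seq_len(ncol(x)), function(j) {
    ctrl <- cd$control[[j]]
    if (!length(ctrl))
      return(data.frame(subject_id = cd$subject_id[j], control_pass = FALSE,
                        background_level = bg[j], control_median = NA_real_,
                        note = "no control spots on array"))
    med <- median(ctrl)
    data.frame(subject_id = cd$subject_id[j],
               control_pass = med >= minFold * bg[j],
               background_level = bg[j], control_median = med, note = "")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
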