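## File-level orchestration of the workflow stages. Each stage reads and
## writes flat tabular text plus a JSON run manifest (config snapshot,
## input/output digests, package version) so runs are reproducible and
## auditable.

.writeManifest <- function(outputDir, stage, params, inputs, outputs,
                           seed = NULL) {
  params <- unclass(params)
  manifest <- list(
    stage = stage,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(packageVersion("epitiler")),
    seed = seed,
    params = params,
    input_md5 = as.list(tools::md5sum(inputs)),
    output_md5 = as.list(tools::md5sum(outputs)))
  path <- file.path(outputDir, sprintf("manifest_%s.json", stage))
  write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Workflow stage: build and export a tiling library
#'
#' @param sequenceSource FASTA path or builtin antigen name (see
#'   [loadMatureSequence()]).
#' @param outputDir directory for outputs (created if needed).
#' @param tileLength,overlap,flank tiling geometry, see [tileSequence()].
#' @return path of the written tiling library, invisibly.
#' @export
runTile <- function(sequenceSource = "CRP", outputDir = ".",
                    tileLength = 15L, overlap = 14L, flank = "GSGSGSG") {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  seq <- loadMatureSequence(sequenceSource)
  tiling <- tileSequence(seq, tileLength = tileLength, overlap = overlap,
                         flank = flank)
  out <- file.path(outputDir, "tiling_library.tsv")
  writeTilingTable(tiling, out)
  .writeManifest(outputDir, "tile",
                 list(sequenceSource = sequenceSource,
                      tileLength = tileLength, overlap = overlap,
                      flank = flank),
                 character(), out)
  message("tiling library: ", length(tiling), " tiles -> ", out)
  invisible(out)
}

## Parse a JSON simulation config {seed, nSle, nHbd, planted: {id: [[s,e]..]}}
.configFromJson <- function(path) {
  cfg <- read_json(path, simplifyVector = TRUE)
  planted <- lapply(cfg$planted, function(sp) {
    sp <- matrix(unlist(sp), ncol = 2L, byrow = is.list(sp))
    data.frame(start = as.integer(sp[, 1L]), end = as.integer(sp[, 2L]))
  })
  args <- cfg[setdiff(names(cfg), "planted")]
  do.call(simulationConfig, c(args, list(planted = planted)))
}

#' Workflow stage: simulate a cohort and export its tables
#'
#' @param config `"fixture"` for the frozen fixture cohort, a
#'   [simulationConfig()], or the path of a JSON config file.
#' @param outputDir output directory.
#' @param sequenceSource antigen for the tiling (ignored for
#'   `"fixture"`).
#' @return named character vector of output paths, invisibly.
#' @export
runSimulate <- function(config, outputDir = ".", sequenceSource = "CRP") {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character()
  if (identical(config, "fixture")) {
    sim <- fixtureCohort()
    params <- list(config = "fixture")
    seed <- 20250515
  } else {
    if (is.character(config)) {
      inputs <- config
      config <- .configFromJson(config)
    }
    stopifnot(inherits(config, "simulationConfig"))
    tiling <- tileSequence(loadMatureSequence(sequenceSource))
    sim <- simulateCohort(config, tiling)
    params <- config
    seed <- config$seed
  }
  paths <- c(array = file.path(outputDir, "array_table.tsv"),
             records = file.path(outputDir, "subject_records.tsv"),
             truth = file.path(outputDir, "truth.json"))
  writeArrayTable(sim$samples, paths[["array"]])
  write.table(sim$records, paths[["records"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_json(lapply(sim$truth$assignment, function(sp)
    unname(as.list(as.data.frame(t(as.matrix(sp)))))),
    paths[["truth"]], auto_unbox = FALSE)
  .writeManifest(outputDir, "simulate", params, inputs, paths, seed = seed)
  message("simulated ", ncol(sim$samples), " arrays -> ", outputDir)
  invisible(paths)
}

#' Workflow stage: call epitopes and build the cohort matrix
#'
#' @param arrayFile long-format array table (see [readArrayTable()]).
#' @param tilingFile tiling library written by [runTile()].
#' @param outputDir output directory.
#' @param factor positivity cutoff in folds over background.
#' @param minOverlap minimum linking overlap in residues.
#' @param perSpot per-spot background mode (see [callPositiveTiles()]).
#' @param excludeQcFail drop arrays failing the control-grid QC instead of
#'   only flagging them.
#' @return named character vector of output paths, invisibly.
#' @export
runCall <- function(arrayFile, tilingFile, outputDir = ".", factor = 2.0,
                    minOverlap = 3L, perSpot = FALSE,
                    excludeQcFail = FALSE) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  tiling <- readTilingTable(tilingFile)
  pae <- readArrayTable(arrayFile, tiling)
  qc <- qcControlGrid(pae)
  if (excludeQcFail && any(!qc$control_pass)) {
    keep <- qc$control_pass
    message("excluding ", sum(!keep), " array(s) failing QC")
    pae <- pae[, keep]
    validObject(pae)
  }
  calls <- callEpitopes(pae, factor = factor, minOverlap = minOverlap,
                        perSpot = perSpot)
  em <- harmonizeCohort(calls, tiling, groups = colData(pae)$group,
                        minOverlap = minOverlap)
  paths <- c(calls = file.path(outputDir, "epitope_calls.tsv"),
             matrix = file.path(outputDir, "epitope_matrix.tsv"),
             qc = file.path(outputDir, "qc_report.tsv"))
  writeEpitopeCalls(calls, paths[["calls"]])
  writeEpitopeMatrix(em, paths[["matrix"]])
  write.table(qc, paths[["qc"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  .writeManifest(outputDir, "call",
                 list(factor = factor, minOverlap = minOverlap,
                      perSpot = perSpot, excludeQcFail = excludeQcFail),
                 c(arrayFile, tilingFile), paths)
  message(sum(vapply(calls, nrow, integer(1))), " subject-level calls, ",
          nrow(epitopeInfo(em)), " cohort epitopes -> ", outputDir)
  invisible(paths)
}

#' Workflow stage: association battery on a cohort matrix
#'
#' @param matrixFile cohort matrix written by [runCall()].
#' @param clinicalFile subject-record table.
#' @param assocFile JSON array of `{"lhs": ..., "rhs": ...}` pairs.
#' @param outputDir output directory.
#' @return path of the association table, invisibly.
#' @export
runCohort <- function(matrixFile, clinicalFile, assocFile, outputDir = ".") {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  em <- readEpitopeMatrix(matrixFile)
  records <- read.delim(clinicalFile)
  spec <- do.call(rbind, lapply(read_json(assocFile),
                                function(p) data.frame(lhs = p$lhs,
                                                       rhs = p$rhs)))
  tab <- buildAssociationTable(em, records, spec)
  out <- file.path(outputDir, "association_table.tsv")
  write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(outputDir, "cohort", list(),
                 c(matrixFile, clinicalFile, assocFile), out)
  message(nrow(tab), " associations -> ", out)
  invisible(out)
}

#' Workflow stage: functional-assay metrics
#'
#' `"ros"` expects a kinetic table with a `negative_control` condition and
#' reports each well's AUC as percent of the pointwise-mean control curve;
#' `"tracks"` reports per-cell and per-condition chemotaxis metrics;
#' `"net"` expects columns `condition` and `value` with a `control`
#' condition and reports the fluorescence fold index.
#'
#' @param type one of `"ros"`, `"tracks"`, `"net"`.
#' @param inputFile assay export (tab-separated).
#' @param outputDir output directory.
#' @param axisSign chemoattractant axis sign for `"tracks"`.
#' @return path of the metrics table, invisibly.
#' @export
runAssays <- function(type = c("ros", "tracks", "net"), inputFile,
                      outputDir = ".", axisSign = 1) {
  type <- match.arg(type)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(outputDir, sprintf("assay_%s.tsv", type))
  if (type == "ros") {
    tab <- readKineticTable(inputFile)
    ctrl <- tab[tab$condition == "negative_control", ]
    if (!nrow(ctrl)) stop("no negative_control condition in kinetic table")
    grid <- sort(unique(tab$time_s))
    ctrlCurve <- data.frame(
      time_s = grid,
      value = vapply(grid, function(t) mean(ctrl$value[ctrl$time_s == t]),
                     numeric(1)))
    wells <- split(tab, tab$well)
    metrics <- do.call(rbind, lapply(wells, function(w) {
      w <- w[order(w$time_s), ]
      data.frame(well = w$well[1L], condition = w$condition[1L],
                 auc_percent_control = rosAucPercent(
                   data.frame(time_s = w$time_s, value = w$value),
                   ctrlCurve))
    }))
    rownames(metrics) <- NULL
  } else if (type == "tracks") {
    metrics <- trackMetrics(readTrackTable(inputFile),
                            axisSign = axisSign)$summary
  } else {
    tab <- read.delim(inputFile)
    stopifnot(all(c("condition", "value") %in% names(tab)))
    ctrl <- mean(tab$value[tab$condition == "control"])
    metrics <- data.frame(condition = tab$condition,
                          value = tab$value,
                          fold_over_control = netReleaseIndex(tab$value,
                                                              ctrl))
  }
  write.table(metrics, out, sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(outputDir, paste0("assays_", type),
                 list(type = type, axisSign = axisSign), inputFile, out)
  invisible(out)
}
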