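## Neutrophil functional-assay metrics: oxidative burst AUC, 3D chemotaxis
## track metrics, extracellular-DNA release index.

#' Oxidative-burst response as percent of negative control (AUC basis)
#'
#' Integrates a kinetic chemiluminescence curve with the trapezoid rule on
#' its native time grid and expresses the area under the curve as a
#' percentage of the negative-control AUC. No baseline subtraction is
#' applied: the percent-of-control ratio already normalizes instrument
#' gain (the metric is invariant to multiplying both curves by a
#' constant).
#'
#' @param curve,control data.frames with columns `time_s` and `value`
#'   (identical, strictly increasing time grids), or numeric value vectors
#'   with the grid given in `time_s`.
#' @param time_s optional shared time grid when curves are bare vectors.
#' @return percent of control (100 = identical to control).
#' @export
rosAucPercent <- function(curve, control, time_s = NULL) {
  as_df <- function(v) {
    if (is.data.frame(v)) {
      stopifnot(all(c("time_s", "value") %in% names(v)))
      return(v[c("time_s", "value")])
    }
    stopifnot(!is.null(time_s), length(v) == length(time_s))
    data.frame(time_s = time_s, value = v)
  }
  curve <- as_df(curve); control <- as_df(control)
  if (!isTRUE(all.equal(curve$time_s, control$time_s)))
    stop("curve and control must share an identical time grid")
  if (any(diff(curve$time_s) <= 0))
    stop("time grid must be strictly increasing")
  if (any(curve$value < 0) || any(control$value < 0))
    stop("luminescence values must be >= 0")
  aucControl <- trapz(control$time_s, control$value)
  if (aucControl <= 0)
    stop("normalization error: control AUC must be > 0")
  100 * trapz(curve$time_s, curve$value) / aucControl
}

#' Chemotaxis metrics from manually tracked cells
#'
#' Per cell: (a) origin-zeroed net displacement along the chemoattractant
#' axis, `axisSign * (x_end - x_0)` in micrometres (every cell's origin is
#' set to 0); (b) velocity as total path length (sum of stepwise Euclidean
#' distances) divided by total observation time, in micrometres per
#' minute. Velocity is path-based, not chord-based, so it is always at
#' least `|net displacement| / time`. Condition summaries report mean and
#' SD for directional movement and median with range for velocity. Tracks
#' with fewer than 2 samples are skipped with a warning.
#'
#' @param tracks data.frame with columns `cell_id`, `t_min`, `x_um`,
#'   `y_um` and optionally `condition`.
#' @param axisSign `+1` when the chemoattractant gradient points toward
#'   positive x (default), `-1` otherwise.
#' @return list with `cells` (per-cell metrics) and `summary` (per
#'   condition).
#' @export
trackMetrics <- function(tracks, axisSign = 1) {
  stopifnot(all(c("cell_id", "t_min", "x_um", "y_um") %in% names(tracks)),
            axisSign %in% c(-1, 1))
  if (is.null(tracks$condition)) tracks$condition <- "all"
  if (!nrow(tracks)) stop("data error: no tracks")
  per <- lapply(split(tracks, ~ condition + cell_id, drop = TRUE),
                function(d) {
    if (nrow(d) < 2L) {
      warning("track with < 2 samples skipped: cell ", d$cell_id[1L])
      return(NULL)
    }
    d <- d[order(d$t_min), ]
    path <- sum(sqrt(diff(d$x_um)^2 + diff(d$y_um)^2))
    span <- d$t_min[nrow(d)] - d$t_min[1L]
    data.frame(cell_id = d$cell_id[1L], condition = d$condition[1L],
               net_x_um = axisSign * (d$x_um[nrow(d)] - d$x_um[1L]),
               path_um = path, time_min = span,
               velocity_um_min = path / span)
  })
  cells <- do.call(rbind, per)
  if (is.null(cells)) stop("data error: no track has >= 2 samples")
  rownames(cells) <- NULL
  summary <- do.call(rbind, lapply(split(cells, cells$condition), function(d)
    data.frame(condition = d$condition[1L], n_cells = nrow(d),
               mean_net_x = mean(d$net_x_um), sd_net_x = stats::sd(d$net_x_um),
               median_velocity = median(d$velocity_um_min),
               min_velocity = min(d$velocity_um_min),
               max_velocity = max(d$velocity_um_min))))
  rownames(summary) <- NULL
  list(cells = cells, summary = summary)
}

#' Extracellular-DNA release index
#'
#' Fold change of cell-impermeable DNA-dye fluorescence over the untreated
#' control: `sample / control`. Values near 1 indicate no effect on
#' extracellular-trap release. The index is invariant to instrument gain
#' (scaling both readings by a constant).
#'
#' @param sampleFluorescence numeric sample reading(s).
#' @param controlFluorescence control reading (> 0; recycled).
#' @return fold over control.
#' @export
netReleaseIndex <- function(sampleFluorescence, controlFluorescence) {
  if (any(controlFluorescence <= 0))
    stop("normalization error: control fluorescence must be > 0")
  sampleFluorescence / controlFluorescence
}

#' Read kinetic-plate and cell-track exports
#'
#' `readKineticTable()` expects columns `time_s`, `well`, `condition`,
#' `value`; `readTrackTable()` expects `cell_id`, `t_min`, `x_um`, `y_um`,
#' `condition` (compatible with manual-tracking exports).
#'
#' @param path tab-separated text file.
#' @return data.frame.
#' @export
readKineticTable <- function(path) {
  tab <- read.delim(path)
  need <- c("time_s", "well", "condition", "value")
  if (!all(need %in% names(tab)))
    stop("kinetic table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname readKineticTable
#' @export
readTrackTable <- function(path) {
  tab <- read.delim(path)
  need <- c("cell_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(tab)))
    stop("track table must have columns: ", paste(need, collapse = ", "))
  tab
}
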