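## Synthetic-data generators: array scans with planted epitopes, clinical
## tables, kinetic burst curves and chemotaxis tracks.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Simulation configuration for a synthetic array cohort
#'
#' Bundles and validates the parameters of [simulateCohort()]. The
#' reactivity model is containment: a tile is reactive for a subject
#' exactly when its mature span contains one of the subject's planted
#' epitope spans — the unique simple model under which intersection-based
#' calling returns exactly the planted span. With `fpRate = 0` and
#' `noiseSd = 0`, `gain > positivityFactor` guarantees exact planted
#' recovery; the seed fully determines the output.
#'
#' @param seed integer RNG seed.
#' @param nSle,nHbd subject counts per group (defaults 42 and 11, the
#'   mapped cohort sizes).
#' @param planted named list, subject id to data.frame with `start`,`end`
#'   (1-based mature spans, each at most the tile length).
#' @param backgroundMeanlog,backgroundSdlog log-normal parameters of the
#'   pre-serum background scan (fluorescence units).
#' @param gain intensity multiplier of reactive tiles over the array
#'   background level (must exceed `positivityFactor`).
#' @param fpRate per-tile false-positive probability.
#' @param noiseSd multiplicative intensity noise, SD on the log scale.
#' @param positivityFactor the calling cutoff the design must clear.
#' @param nControlSpots,controlFold control-grid spots per array and their
#'   fold over background.
#' @return validated list of class `"simulationConfig"`.
#' @export
simulationConfig <- function(seed = 1L, nSle = 42L, nHbd = 11L,
                             planted = list(),
                             backgroundMeanlog = log(100),
                             backgroundSdlog = 0.25,
                             gain = 5, fpRate = 0, noiseSd = 0,
                             positivityFactor = 2,
                             nControlSpots = 8L, controlFold = 10) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            nSle >= 0L, nHbd >= 0L, fpRate >= 0, fpRate <= 1, noiseSd >= 0,
            gain > positivityFactor)
  structure(list(seed = as.integer(seed), nSle = as.integer(nSle),
                 nHbd = as.integer(nHbd), planted = planted,
                 backgroundMeanlog = backgroundMeanlog,
                 backgroundSdlog = backgroundSdlog, gain = gain,
                 fpRate = fpRate, noiseSd = noiseSd,
                 positivityFactor = positivityFactor,
                 nControlSpots = as.integer(nControlSpots),
                 controlFold = controlFold),
            class = "simulationConfig")
}

## Clinical covariates loosely matching the published cohort's summary
## table (medians/IQRs); they exist to exercise the association battery.
.simulateRecords <- function(ids, groups) {
  n <- length(ids)
  sle <- groups == "SLE"
  rec <- data.frame(
    subject_id = ids, group = groups,
    age = round(ifelse(sle, rnorm(n, 51, 16), rnorm(n, 53, 7))),
    female = runif(n) < ifelse(sle, 0.93, 0.82),
    disease_duration = ifelse(sle, round(rlnorm(n, log(10), 0.8), 1), 0),
    sledai2k = ifelse(sle, rnbinom(n, size = 1, mu = 2.5), 0L),
    sdi = ifelse(sle, rpois(n, 0.9), 0L),
    esr = round(rlnorm(n, log(13), 0.5)),
    crp_mgl = round(rlnorm(n, log(2.4), 1), 1),
    il6 = round(rlnorm(n, log(3), 1), 1),
    c3d = round(rlnorm(n, log(3), 0.3), 1),
    complement_classical_pct = round(pmax(rnorm(n, 100, 18), 5)),
    anti_crp_au = round(ifelse(sle, rlnorm(n, log(17.5), 1.9),
                               rlnorm(n, log(5), 1)), 1),
    acl_igg = round(ifelse(sle, rlnorm(n, log(2), 1.2),
                           rlnorm(n, log(1), 0.7)), 2),
    acl_igm = round(ifelse(sle, rlnorm(n, log(2), 1.2),
                           rlnorm(n, log(1), 0.7)), 2),
    b2gpi_igg = round(ifelse(sle, rlnorm(n, log(1.5), 1.2),
                             rlnorm(n, log(0.8), 0.7)), 2),
    b2gpi_igm = round(ifelse(sle, rlnorm(n, log(1.5), 1.2),
                             rlnorm(n, log(0.8), 0.7)), 2))
  ## AU positivity cutoff: 95th percentile of an independent 100-donor panel
  panel <- rlnorm(100, log(5), 1)
  deriveSerologyFlags(rec, antiCrpCutoff = percentileCutoff(panel, 95))
}

#' Simulate a peptide-array cohort with planted epitopes
#'
#' Per subject the pre-serum background scan is log-normal; non-reactive
#' tiles have serum intensity `backgroundLevel * lognormal(0, noiseSd)`,
#' reactive tiles (mature span containing a planted epitope span)
#' `backgroundLevel * gain * lognormal(0, noiseSd)`; isolated false
#' positives are injected at `fpRate`. Control spots sit at `controlFold`
#' times the background level. Clinical covariates are drawn from
#' distributions matching the published cohort's summary table. The same
#' seed yields identical output.
#'
#' @param config a [simulationConfig()].
#' @param tiling a [PeptideTiling].
#' @return list with `samples` (a [PeptideArrayExperiment]), `records`
#'   (clinical data.frame) and `truth` (`assignment`: the planted list;
#'   `reactive`: tiles-x-subjects logical matrix before false positives;
#'   `falsePositive`: injected tiles).
#' @export
simulateCohort <- function(config, tiling) {
  stopifnot(inherits(config, "simulationConfig"), is(tiling, "PeptideTiling"))
  ids <- c(sprintf("SLE%02d", seq_len(config$nSle)),
           sprintf("HBD%02d", seq_len(config$nHbd)))
  groups <- rep(c("SLE", "HBD"), c(config$nSle, config$nHbd))
  extra <- setdiff(names(config$planted), ids)
  if (length(extra))
    stop("planted subjects not in the cohort: ", paste(extra, collapse = ", "))
  for (s in names(config$planted)) {
    sp <- config$planted[[s]]
    if (any(sp$end - sp$start + 1L > tiling@tileLength))
      stop("unreachable epitope: planted span longer than a tile (subject ",
           s, ")")
    if (any(sp$start < 1L) || any(sp$end > nchar(tiling@protein)))
      stop("planted span outside the mature sequence (subject ", s, ")")
  }
  n <- length(tiling)
  mS <- tiling@matureStart; mE <- tiling@matureEnd
  .withSeed(config$seed, {
    reactive <- fp <- matrix(FALSE, n, length(ids),
                             dimnames = list(NULL, ids))
    intensity <- background <- matrix(0, n, length(ids),
                                      dimnames = list(NULL, ids))
    control <- vector("list", length(ids))
    for (j in seq_along(ids)) {
      sp <- config$planted[[ids[j]]]
      if (!is.null(sp) && nrow(sp))
        for (i in seq_len(nrow(sp)))
          reactive[, j] <- reactive[, j] |
            (!is.na(mS) & mS <= sp$start[i] & mE >= sp$end[i])
      bg <- rlnorm(n, config$backgroundMeanlog, config$backgroundSdlog)
      lvl <- median(bg)
      fp[, j] <- !reactive[, j] & runif(n) < config$fpRate
      hot <- reactive[, j] | fp[, j]
      noise <- if (config$noiseSd > 0) exp(rnorm(n, 0, config$noiseSd))
               else rep(1, n)
      background[, j] <- bg
      intensity[, j] <- lvl * ifelse(hot, config$gain, 1) * noise
      control[[j]] <- rep(lvl * config$controlFold, config$nControlSpots)
    }
    records <- .simulateRecords(ids, groups)
    samples <- PeptideArrayExperiment(
      intensity, background, tiling,
      data.frame(subject_id = ids, group = groups), control = control)
    list(samples = samples, records = records,
         truth = list(assignment = config$planted, reactive = reactive,
                      falsePositive = fp))
  })
}

#' Simulate biased 3D chemotaxis tracks
#'
#' Biased random walks sampled once per minute: each step has length
#' `speed` micrometres and direction `uniform(-pi, pi) * (1 - bias)`, so
#' concentration around the +x chemoattractant axis grows with `bias`.
#' `bias = 1` gives straight +x tracks (net x displacement
#' `duration * speed`); `bias = 0` gives an unbiased walk with zero
#' expected net x.
#'
#' @param nCells number of cells.
#' @param speed step length in micrometres per minute.
#' @param bias directional bias in `[0, 1]`.
#' @param seed RNG seed.
#' @param duration observation window in minutes (default 60, sampled at
#'   1-minute intervals, so `duration + 1` points per cell).
#' @param condition label attached to the tracks.
#' @return data.frame `cell_id`, `t_min`, `x_um`, `y_um`, `condition`.
#' @export
simulateTracks <- function(nCells = 15L, speed = 10, bias = 0.5, seed = 1L,
                           duration = 60L, condition = "simulated") {
  stopifnot(bias >= 0, bias <= 1, nCells >= 1L, speed >= 0)
  .withSeed(seed, {
    theta <- matrix(runif(nCells * duration, -pi, pi) * (1 - bias),
                    nrow = duration)
    x <- rbind(0, apply(speed * cos(theta), 2L, cumsum))
    y <- rbind(0, apply(speed * sin(theta), 2L, cumsum))
    data.frame(
      cell_id = rep(sprintf("cell%04d", seq_len(nCells)),
                    each = duration + 1L),
      t_min = rep(0:duration, nCells),
      x_um = as.vector(x), y_um = as.vector(y),
      condition = condition)
  })
}

#' Simulate kinetic oxidative-burst curves
#'
#' Gamma-shaped burst curves on a 30-second grid over 15 minutes (31
#' points including t = 0) with multiplicative log-normal noise. A
#' condition with multiplier m has expected AUC close to m times the
#' unit-multiplier condition, so its percent-of-control is close to
#' 100 * m.
#'
#' @param effects named numeric vector of per-condition multipliers; name
#'   one condition `"negative_control"` (multiplier 1) to normalize
#'   against.
#' @param seed RNG seed.
#' @param noiseSd multiplicative noise SD on the log scale (0 for exact).
#' @param replicates wells per condition.
#' @param peakRlu luminescence scale of the burst peak.
#' @return long data.frame `time_s`, `well`, `condition`, `value`.
#' @export
simulateRos <- function(effects = c(negative_control = 1, pma = 8),
                        seed = 1L, noiseSd = 0.1, replicates = 3L,
                        peakRlu = 1000) {
  stopifnot(!is.null(names(effects)), all(effects >= 0))
  time_s <- seq(0, 900, by = 30)
  shape <- (time_s / 300)^2 * exp(2 * (1 - time_s / 300))
  .withSeed(seed, {
    do.call(rbind, lapply(names(effects), function(cond) {
      do.call(rbind, lapply(seq_len(replicates), function(r) {
        noise <- if (noiseSd > 0) exp(rnorm(length(time_s), 0, noiseSd))
                 else rep(1, length(time_s))
        data.frame(time_s = time_s,
                   well = sprintf("%s_%d", cond, r), condition = cond,
                   value = peakRlu * effects[[cond]] * shape * noise)
      }))
    }))
  })
}
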