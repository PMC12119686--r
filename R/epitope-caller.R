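## Positivity calling and minimal consensus epitope reduction.

#' Call seropositive tiles against the background cutoff
#'
#' A tile is positive when its serum-scan fluorescence reaches `factor`
#' times the array's background level (boundary inclusive: attainment of
#' the cutoff counts as positive). By default the background is the
#' per-array scalar of [backgroundLevel()]; with `perSpot = TRUE` each tile
#' is compared to `factor` times its own pre-serum value instead
#' (sensitivity-analysis mode).
#'
#' @param x a [PeptideArrayExperiment], or a numeric intensity vector.
#' @param factor positivity cutoff as a fold over background (default 2).
#' @param background required when `x` is a vector: that array's background
#'   scan (vector) or precomputed scalar level.
#' @param perSpot compare tile-wise instead of against the scalar level.
#' @return logical matrix tiles x subjects (or a logical vector).
#' @export
callPositiveTiles <- function(x, factor = 2.0, background = NULL,
                              perSpot = FALSE) {
  if (is.numeric(x)) {
    stopifnot(!is.null(background))
    cut <- if (perSpot) factor * background
           else factor * backgroundLevel(background)
    return(x >= cut)
  }
  stopifnot(is(x, "PeptideArrayExperiment"))
  int <- assay(x, "intensity")
  if (perSpot) return(int >= factor * assay(x, "background"))
  bg <- backgroundLevel(x)
  int >= factor * rep(bg, each = nrow(int))
}

## Split sorted positive tiles into single-linkage chains: consecutive tiles
## (in start order) belong to one chain when their mature spans share at
## least minOverlap residues. For interval families with nondecreasing
## starts and ends, checking consecutive pairs realizes full single linkage.
.chainBreaks <- function(starts, ends, minOverlap) {
  if (length(starts) <= 1L) return(integer())
  ov <- ends[-length(ends)] - starts[-1L] + 1L
  which(ov < minOverlap)
}

## Segment one chain of positive tiles (mature spans sorted, nondecreasing
## starts/ends) into runs, each with a non-empty running intersection.
## Suffix dynamic programme; preference order: fewest runs, then largest
## total intersection length, then largest minimum intersection length,
## then the longer leftmost run. Returns a list of integer index ranges.
.segmentChain <- function(starts, ends) {
  m <- length(starts)
  blocks <- integer(m + 1L); blocks[m + 1L] <- 0L
  sums <- numeric(m + 1L); mins <- numeric(m + 1L); mins[m + 1L] <- Inf
  split <- integer(m)
  for (i in m:1) {
    best <- NULL
    for (j in i:m) {
      if (starts[j] > ends[i]) break  # intersection of i..j would be empty
      len <- ends[i] - starts[j] + 1
      cand <- c(blocks[j + 1L] + 1L, sums[j + 1L] + len,
                min(len, mins[j + 1L]), len)
      if (is.null(best) ||
          cand[1L] < best[1L] ||
          (cand[1L] == best[1L] && (cand[2L] > best[2L] ||
            (cand[2L] == best[2L] && (cand[3L] > best[3L] ||
              (cand[3L] == best[3L] && cand[4L] > best[4L])))))) {
        best <- cand
        split[i] <- j
      }
    }
    blocks[i] <- as.integer(best[1L]); sums[i] <- best[2L]; mins[i] <- best[3L]
  }
  runs <- list()
  i <- 1L
  while (i <= m) {
    j <- split[i]
    runs[[length(runs) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  runs
}

#' Reduce positive tiles to minimal consensus epitopes for one subject
#'
#' Implements the reduction of overlapping positive peptides to the minimal
#' shared region: positive tiles are taken in ascending order of their
#' mature spans; tiles whose spans share at least `minOverlap` residues are
#' linked into chains; each chain is segmented into runs with a non-empty
#' common intersection of spans (fewest runs, then the largest and most
#' balanced total intersection, with ties resolved toward the longer
#' leftmost run); each run yields one epitope call equal to the
#' intersection of its tiles' mature spans. Flank-only tiles never seed or
#' extend a run. Calls shorter than `minOverlap` residues are flagged with
#' a warning (the shortest consensus regions reported in practice are three
#' residues).
#'
#' Near the termini the tiling is truncated, so the minimal consensus of a
#' terminal motif extends to the boundary of what the printed tiles can
#' resolve (the last tile starts `flank + 1` residues before the terminus).
#'
#' @param positives logical vector, one element per tile of `tiling`.
#' @param tiling the [PeptideTiling] the calls refer to.
#' @param minOverlap minimum shared residues linking two positive tiles
#'   (default 3).
#' @param intensity optional numeric vector of serum-scan fluorescence used
#'   for the per-call mean intensity.
#' @return data.frame with one row per call, sorted by `start`: `start`,
#'   `end`, `motif`, `n_supporting`, `mean_intensity`, `short`, and a
#'   list-column `supporting` of tile indices.
#' @export
callSubjectEpitopes <- function(positives, tiling, minOverlap = 3L,
                                intensity = NULL) {
  stopifnot(is(tiling, "PeptideTiling"))
  if (length(positives) != length(tiling))
    stop("positives must align to the tiling library (one value per tile)")
  idx <- which(positives & !is.na(tiling@matureStart))
  empty <- data.frame(start = integer(), end = integer(),
                      motif = character(), n_supporting = integer(),
                      mean_intensity = numeric(), short = logical())
  empty$supporting <- list()
  if (!length(idx)) return(empty)
  starts <- tiling@matureStart[idx]
  ends <- tiling@matureEnd[idx]
  ord <- order(starts, ends)
  idx <- idx[ord]; starts <- starts[ord]; ends <- ends[ord]
  breaks <- .chainBreaks(starts, ends, minOverlap)
  chainId <- cumsum(c(1L, as.integer(seq_along(idx)[-1L] %in% (breaks + 1L))))
  calls <- list()
  for (ch in split(seq_along(idx), chainId)) {
    runs <- .segmentChain(starts[ch], ends[ch])
    for (r in runs) {
      sel <- ch[r[1L]:r[2L]]
      s <- max(starts[sel]); e <- min(ends[sel])
      calls[[length(calls) + 1L]] <- list(
        start = s, end = e,
        motif = substring(tiling@protein, s, e),
        n_supporting = length(sel),
        mean_intensity = if (is.null(intensity)) NA_real_
                         else mean(intensity[idx[sel]]),
        short = (e - s + 1L) < minOverlap,
        supporting = idx[sel])
    }
  }
  out <- do.call(rbind, lapply(calls, function(cl)
    data.frame(start = cl$start, end = cl$end, motif = cl$motif,
               n_supporting = cl$n_supporting,
               mean_intensity = cl$mean_intensity, short = cl$short)))
  out$supporting <- lapply(calls, `[[`, "supporting")
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$short))
    warning(sum(out$short), " call(s) shorter than ", minOverlap, " residues")
  out
}

#' Call epitopes for every subject of an array experiment
#'
#' Convenience wrapper: [callPositiveTiles()] then [callSubjectEpitopes()]
#' per subject.
#'
#' @inheritParams callPositiveTiles
#' @inheritParams callSubjectEpitopes
#' @return named list of per-subject call data.frames.
#' @export
callEpitopes <- function(x, factor = 2.0, minOverlap = 3L, perSpot = FALSE) {
  stopifnot(is(x, "PeptideArrayExperiment"))
  pos <- callPositiveTiles(x, factor = factor, perSpot = perSpot)
  tiling <- metadata(x)$tiling
  int <- assay(x, "intensity")
  setNames(lapply(seq_len(ncol(x)), function(j)
    callSubjectEpitopes(pos[, j], tiling, minOverlap = minOverlap,
                        intensity = int[, j])),
    colData(x)$subject_id)
}

#' Harmonize per-subject epitope calls into cohort epitopes
#'
#' Clusters subject-level calls across subjects by single linkage on span
#' overlap (at least `minOverlap` shared residues); each cluster's
#' canonical span is the intersection of its member spans when non-empty,
#' otherwise the contiguous region of maximal member coverage (flagged with
#' a warning). A subject is positive for a cohort epitope when one of its
#' calls belongs to the cluster. Canonical spans that still share
#' `minOverlap` residues after clustering indicate an internal
#' inconsistency and raise an error.
#'
#' @param calls named list of per-subject call data.frames (from
#'   [callSubjectEpitopes()] / [callEpitopes()]).
#' @param tiling the [PeptideTiling] (source of motifs and coordinates).
#' @param groups character/factor vector of group labels, aligned to
#'   `names(calls)` (or named by subject).
#' @param minOverlap minimum shared residues linking two calls (default 3).
#' @return an [EpitopeMatrix].
#' @export
harmonizeCohort <- function(calls, tiling, groups, minOverlap = 3L) {
  stopifnot(is(tiling, "PeptideTiling"), !is.null(names(calls)))
  subjects <- names(calls)
  if (!is.null(names(groups))) groups <- groups[subjects]
  groups <- as.character(groups)
  stopifnot(length(groups) == length(subjects))
  all <- do.call(rbind, lapply(subjects, function(s) {
    cl <- calls[[s]]
    if (!nrow(cl)) return(NULL)
    data.frame(subject = s, start = cl$start, end = cl$end,
               mean_intensity = cl$mean_intensity)
  }))
  if (is.null(all) || !nrow(all)) {
    em <- new("EpitopeMatrix",
              positive = matrix(FALSE, length(subjects), 0L),
              intensity = matrix(NA_real_, length(subjects), 0L),
              epitopes = data.frame(start = integer(), end = integer(),
                                    motif = character(), label = character()),
              subjects = data.frame(subject_id = subjects, group = groups))
    return(em)
  }
  ord <- order(all$start, all$end)
  all <- all[ord, , drop = FALSE]
  ## single linkage over sorted intervals via the running maximum end
  cummaxEnd <- cummax(all$end)
  newClust <- c(TRUE, all$start[-1L] > cummaxEnd[-nrow(all)] - minOverlap + 1L)
  all$cluster <- cumsum(newClust)
  eps <- lapply(split(all, all$cluster), function(d) {
    s <- max(d$start); e <- min(d$end)
    if (s <= e) return(list(start = s, end = e, flagged = FALSE))
    ## empty intersection: take the contiguous region of maximal coverage
    cov <- integer(max(d$end))
    for (i in seq_len(nrow(d)))
      cov[d$start[i]:d$end[i]] <- cov[d$start[i]:d$end[i]] + 1L
    top <- which(cov == max(cov))
    runEnd <- c(which(diff(top) > 1L), length(top))
    list(start = top[1L], end = top[runEnd[1L]], flagged = TRUE)
  })
  if (any(vapply(eps, `[[`, logical(1), "flagged")))
    warning("cluster(s) with empty span intersection; canonical span set to ",
            "the region of maximal member coverage")
  epdf <- data.frame(
    start = vapply(eps, `[[`, numeric(1), "start"),
    end = vapply(eps, `[[`, numeric(1), "end"))
  epdf$motif <- substring(tiling@protein, epdf$start, epdf$end)
  epdf$label <- epitopeLabel(tiling@protein, epdf$start, epdf$end)
  o <- order(epdf$start, epdf$end)
  epdf <- epdf[o, , drop = FALSE]
  rownames(epdf) <- NULL
  remap <- match(seq_along(eps), o)
  all$cluster <- remap[all$cluster]
  ## internal consistency: canonical spans must not themselves link
  if (nrow(epdf) > 1L) {
    ov <- epdf$end[-nrow(epdf)] - epdf$start[-1L] + 1L
    if (any(ov >= minOverlap))
      stop("internal consistency error: canonical cohort spans overlap by >= ",
           minOverlap, " residues after clustering")
  }
  positive <- matrix(FALSE, length(subjects), nrow(epdf),
                     dimnames = list(subjects, epdf$label))
  intensity <- matrix(NA_real_, length(subjects), nrow(epdf),
                      dimnames = list(subjects, epdf$label))
  for (i in seq_len(nrow(all))) {
    r <- all$subject[i]; cidx <- all$cluster[i]
    positive[r, cidx] <- TRUE
    intensity[r, cidx] <-
      if (is.na(intensity[r, cidx])) all$mean_intensity[i]
      else mean(c(intensity[r, cidx], all$mean_intensity[i]))
  }
  new("EpitopeMatrix", positive = positive, intensity = intensity,
      epitopes = epdf,
      subjects = data.frame(subject_id = subjects, group = groups))
}

#' Epitope label in motif^start-end notation
#'
#' @param seq protein sequence ([Biostrings::AAString] or character).
#' @param start,end 1-based inclusive span (vectorized).
#' @return character vector like `"PDE^168-170"`.
#' @export
epitopeLabel <- function(seq, start, end) {
  seq <- as.character(seq)
  sprintf("%s^%d-%d", substring(seq, start, end), start, end)
}

#' @rdname epitopeLabel
#' @param label labels produced by `epitopeLabel()`.
#' @return `parseEpitopeLabel()` returns a data.frame `motif`, `start`,
#'   `end`.
#' @export
parseEpitopeLabel <- function(label) {
  m <- regmatches(label, regexec("^([A-Z]+)\\^([0-9]+)-([0-9]+)$", label))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("unparseable epitope label: ", label[bad][1L])
  data.frame(motif = vapply(m, `[`, character(1), 2L),
             start = as.integer(vapply(m, `[`, character(1), 3L)),
             end = as.integer(vapply(m, `[`, character(1), 4L)))
}

#' Export epitope calls / cohort matrix as tab-separated text
#'
#' @param calls named list of per-subject call data.frames.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeEpitopeCalls <- function(calls, path) {
  rows <- do.call(rbind, lapply(names(calls), function(s) {
    cl <- calls[[s]]
    if (!nrow(cl)) return(NULL)
    data.frame(subject_id = s, start = cl$start, end = cl$end,
               motif = cl$motif, n_supporting = cl$n_supporting,
               mean_intensity = cl$mean_intensity)
  }))
  if (is.null(rows))
    rows <- data.frame(subject_id = character(), start = integer(),
                       end = integer(), motif = character(),
                       n_supporting = integer(), mean_intensity = numeric())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEpitopeCalls
#' @param x an [EpitopeMatrix].
#' @export
writeEpitopeMatrix <- function(x, path) {
  stopifnot(is(x, "EpitopeMatrix"))
  tab <- data.frame(subject_id = x@subjects$subject_id,
                    group = x@subjects$group, check.names = FALSE)
  for (j in seq_len(ncol(x@positive))) {
    lb <- x@epitopes$label[j]
    tab[[paste0(lb, "|pos")]] <- as.integer(x@positive[, j])
    tab[[paste0(lb, "|int")]] <- x@intensity[, j]
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEpitopeCalls
#' @export
readEpitopeMatrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  labels <- unique(sub("\\|(pos|int)$", "",
                       grep("\\|pos$", names(tab), value = TRUE)))
  info <- parseEpitopeLabel(labels)
  info$label <- labels
  positive <- sapply(labels, function(lb) tab[[paste0(lb, "|pos")]] == 1L)
  intensity <- sapply(labels, function(lb) tab[[paste0(lb, "|int")]])
  if (!is.matrix(positive)) {  # single-subject tables
    positive <- matrix(positive, nrow = nrow(tab))
    intensity <- matrix(intensity, nrow = nrow(tab))
  }
  dimnames(positive) <- dimnames(intensity) <- list(tab$subject_id, labels)
  new("EpitopeMatrix", positive = positive, intensity = intensity,
      epitopes = info,
      subjects = data.frame(subject_id = tab$subject_id, group = tab$group))
}
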