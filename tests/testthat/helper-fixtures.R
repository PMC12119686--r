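# Shared helpers: small tilings and planted-positivity vectors built in code.

crpTiling <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- tileSequence(loadMatureSequence("CRP"))
    cache
  }
})

# logical tile vector: positive exactly for tiles whose mature span
# contains [s, e] (the containment reactivity model)
flagContaining <- function(tiling, s, e) {
  !is.na(tiling@matureStart) & tiling@matureStart <= s & tiling@matureEnd >= e
}

# a small 3-subject array experiment with planted spans and clean values
smallCohort <- function(planted = list(S1 = data.frame(start = 80, end = 83),
                                       S2 = data.frame(start = c(36, 168),
                                                       end = c(38, 170)),
                                       S3 = data.frame(start = integer(),
                                                       end = integer())),
                        tiling = crpTiling(), gain = 5) {
  n <- length(tiling)
  ids <- names(planted)
  intensity <- background <- matrix(100, n, length(ids),
                                    dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    sp <- planted[[j]]
    for (i in seq_len(nrow(sp))) {
      hot <- flagContaining(tiling, sp$start[i], sp$end[i])
      intensity[hot, j] <- 100 * gain
    }
  }
  PeptideArrayExperiment(intensity, background, tiling,
                         data.frame(subject_id = ids,
                                    group = rep(c("SLE", "HBD"),
                                                length.out = length(ids))),
                         control = rep(list(rep(1000, 4)), length(ids)))
}

# random non-linking planted spans: supporting-tile blocks of consecutive
# spans stay unlinked (> tile gap) so each epitope forms its own chain
randomPlantedSpans <- function(L = 206, tileLength = 15, flank = 7,
                               maxSpans = 4) {
  spans <- data.frame(start = integer(), end = integer())
  cursor <- flank + 1  # keep a fully containing tile on the left
  for (i in seq_len(maxSpans)) {
    len <- sample.int(tileLength, 1)
    start <- cursor + sample.int(20, 1)
    end <- start + len - 1
    # tiles of span A end at start(A)+flank; tiles of span B start at
    # end(B)-flank; require an index gap > tileLength - minOverlap
    if (end > L - flank) break
    spans <- rbind(spans, data.frame(start = start, end = end))
    cursor <- end + tileLength + 13  # generous non-linking separation
  }
  spans
}
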