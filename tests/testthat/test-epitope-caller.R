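test_that("positivity cutoff is boundary-inclusive at factor x background", {
  tl <- crpTiling()
  n <- length(tl)
  bg <- rep(100, n)
  intensity <- rep(100, n)
  intensity[5] <- 200     # exactly 2x: positive
  intensity[6] <- 199.9   # just under: negative
  pos <- callPositiveTiles(intensity, background = bg)
  expect_true(pos[5])
  expect_false(pos[6])
  expect_equal(sum(pos), 1)
  expect_false(any(callPositiveTiles(bg, background = bg)))  # all == bg
})

test_that("isolated planted islands yield one call each at the planted span", {
  tl <- crpTiling()
  pos <- flagContaining(tl, 36, 38) | flagContaining(tl, 99, 101)
  calls <- callSubjectEpitopes(pos, tl)
  expect_equal(calls$start, c(36, 99))
  expect_equal(calls$end, c(38, 101))
  expect_equal(calls$motif, c("CLH", "SWE"))
  expect_equal(callSubjectEpitopes(rep(FALSE, length(tl)), tl)$start,
               integer())
})

test_that("contiguous positive blocks of two neighbouring epitopes are split
           at the balanced intersection", {
  tl <- crpTiling()
  # the two most prevalent epitopes: their supporting-tile blocks touch
  pos <- flagContaining(tl, 155, 158) | flagContaining(tl, 168, 170)
  calls <- callSubjectEpitopes(pos, tl)
  expect_equal(calls$start, c(155, 168))
  expect_equal(calls$end, c(158, 170))
  # linked but gap-separated blocks also resolve exactly
  pos2 <- flagContaining(tl, 134, 137) | flagContaining(tl, 141, 152)
  calls2 <- callSubjectEpitopes(pos2, tl)
  expect_equal(calls2$motif, c("ILGQ", "SFGGNFEGSQSL"))
})

test_that("supporting tiles and mean intensity are reported per call", {
  tl <- crpTiling()
  pos <- flagContaining(tl, 168, 170)
  intensity <- rep(100, length(tl))
  intensity[pos] <- 700
  calls <- callSubjectEpitopes(pos, tl, intensity = intensity)
  expect_equal(calls$n_supporting, 13)
  expect_equal(calls$mean_intensity, 700)
  expect_equal(sort(calls$supporting[[1]]), which(pos))
})

test_that("flank-only tiles never seed a call", {
  tl <- tileSequence("ACDEFGHIKLMNPQRSTVWY", flank = "GSGSGSGSGSGSGSG",
                     tileLength = 15, overlap = 14)
  pos <- rep(FALSE, length(tl))
  pos[1] <- TRUE  # wholly inside the left flank
  expect_equal(nrow(callSubjectEpitopes(pos, tl)), 0)
})

test_that("calls shorter than the linking overlap are flagged with warning", {
  tl <- crpTiling()
  pos <- rep(FALSE, length(tl))
  # spans [3,17], [5,19], [16,30]: one linked chain whose single-run
  # intersection is [16,17] (2 residues)
  pos[c(10, 12, 23)] <- TRUE
  expect_warning(calls <- callSubjectEpitopes(pos, tl), "shorter")
  expect_true(all(calls$short))
})

test_that("length mismatch between positives and tiling errors", {
  expect_error(callSubjectEpitopes(c(TRUE, FALSE), crpTiling()), "align")
})

test_that("extra positive tiles that contain a planted span, or are
           isolated, never uncover a planted span", {
  tl <- crpTiling()
  set.seed(311)
  for (i in 1:20) {
    spans <- randomPlantedSpans()
    pos <- rep(FALSE, length(tl))
    for (k in seq_len(nrow(spans)))
      pos <- pos | flagContaining(tl, spans$start[k], spans$end[k])
    covered <- function(calls) all(vapply(seq_len(nrow(spans)), function(k) {
      any(calls$start <= spans$start[k] & calls$end >= spans$end[k])
    }, logical(1)))
    # (a) one more tile containing the first planted span
    supp <- which(flagContaining(tl, spans$start[1], spans$end[1]))
    extra <- pos
    extra[supp] <- TRUE  # idempotent: full containment set already positive
    expect_true(covered(suppressWarnings(callSubjectEpitopes(extra, tl))))
    # (b) an isolated, non-linking tile far from every positive block
    free <- setdiff(seq_len(length(tl)), unlist(lapply(which(pos),
                                                       function(j) (j - 13):(j + 13))))
    if (length(free)) {
      iso <- pos
      iso[free[1]] <- TRUE
      calls <- suppressWarnings(callSubjectEpitopes(iso, tl))
      expect_true(covered(calls))
      expect_equal(nrow(calls),
                   nrow(suppressWarnings(callSubjectEpitopes(pos, tl))) + 1)
    }
  }
})

test_that("epitope labels render and parse back to the same span", {
  crp <- as.character(loadMatureSequence("CRP"))
  expect_equal(epitopeLabel(crp, 168, 170), "PDE^168-170")
  expect_equal(epitopeLabel(crp, 1, 1), "Q^1-1")
  set.seed(7)
  for (i in 1:25) {
    s <- sample.int(200, 1); e <- s + sample.int(6, 1)
    lb <- epitopeLabel(crp, s, e)
    back <- parseEpitopeLabel(lb)
    expect_equal(back$start, s)
    expect_equal(back$end, e)
    expect_equal(back$motif, substr(crp, s, e))
  }
  expect_error(parseEpitopeLabel("PDE168-170"), "unparseable")
})

test_that("cohort harmonization clusters identical and nested calls", {
  tl <- crpTiling()
  mk <- function(s, e) data.frame(start = s, end = e, motif = "x",
                                  n_supporting = 1L, mean_intensity = 500,
                                  short = FALSE)
  em <- harmonizeCohort(list(A = mk(80, 83), B = mk(80, 83)), tl,
                        groups = c(A = "SLE", B = "HBD"))
  expect_equal(epitopeInfo(em)$label, "SEIL^80-83")
  expect_true(all(positiveMatrix(em)))

  # overlapping but unequal spans: canonical span is the intersection
  em2 <- harmonizeCohort(list(A = mk(80, 83), B = mk(81, 83)), tl,
                         groups = c(A = "SLE", B = "SLE"))
  expect_equal(epitopeInfo(em2)$start, 81)
  expect_equal(epitopeInfo(em2)$end, 83)
})

test_that("cohort matrix margins equal the per-epitope counts", {
  sim <- fixtureCohort()
  calls <- callEpitopes(sim$samples)
  em <- harmonizeCohort(calls, S4Vectors::metadata(sim$samples)$tiling,
                        groups = SummarizedExperiment::colData(
                          sim$samples)$group)
  counts <- epitopeCounts(em)
  pos <- positiveMatrix(em)
  grp <- subjectInfo(em)$group
  expect_equal(unname(counts$SLE), unname(colSums(pos[grp == "SLE", ])))
  expect_equal(unname(counts$HBD), unname(colSums(pos[grp == "HBD", ])))
  expect_equal(unname(subjectTotals(em)), unname(rowSums(pos)))
})

test_that("harmonization is invariant to subject order", {
  sim <- smallCohort()
  calls <- callEpitopes(sim)
  groups <- setNames(SummarizedExperiment::colData(sim)$group,
                     names(calls))
  tl <- S4Vectors::metadata(sim)$tiling
  em1 <- harmonizeCohort(calls, tl, groups)
  em2 <- harmonizeCohort(rev(calls), tl, groups)
  expect_equal(epitopeInfo(em1), epitopeInfo(em2))
  expect_equal(positiveMatrix(em1),
               positiveMatrix(em2)[rownames(positiveMatrix(em1)), ])
})

test_that("epitope matrix round-trips through its wide-table export", {
  sim <- smallCohort()
  calls <- callEpitopes(sim)
  em <- harmonizeCohort(calls, S4Vectors::metadata(sim)$tiling,
                        setNames(SummarizedExperiment::colData(sim)$group,
                                 names(calls)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEpitopeMatrix(em, f)
  em2 <- readEpitopeMatrix(f)
  expect_equal(positiveMatrix(em2), positiveMatrix(em))
  expect_equal(epitopeInfo(em2)$label, epitopeInfo(em)$label)
})
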