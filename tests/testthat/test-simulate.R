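test_that("noise-free planted reactivity is containment-exact", {
  tl <- crpTiling()
  cfg <- simulationConfig(seed = 4, nSle = 1, nHbd = 0,
                          planted = list(SLE01 = data.frame(start = 80,
                                                            end = 83)))
  sim <- simulateCohort(cfg, tl)
  reactive <- sim$truth$reactive[, 1]
  expect_equal(sum(reactive), 12)  # tiles 76..87 contain SEIL 80-83
  expect_equal(which(reactive), 76:87)
  pos <- callPositiveTiles(sim$samples)[, 1]
  expect_equal(which(pos), which(reactive))
  calls <- callSubjectEpitopes(pos, tl)
  expect_equal(calls$start, 80)
  expect_equal(calls$end, 83)
})

test_that("identical seeds give bit-identical cohorts", {
  tl <- crpTiling()
  cfg <- simulationConfig(seed = 99, nSle = 3, nHbd = 2, noiseSd = 0.2,
                          fpRate = 0.02)
  a <- simulateCohort(cfg, tl)
  b <- simulateCohort(cfg, tl)
  expect_identical(SummarizedExperiment::assay(a$samples, "intensity"),
                   SummarizedExperiment::assay(b$samples, "intensity"))
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
})

test_that("config validation rejects unreachable plants and weak gain", {
  tl <- crpTiling()
  expect_error(simulationConfig(gain = 1.5, positivityFactor = 2), "gain")
  long <- simulationConfig(planted = list(
    SLE01 = data.frame(start = 10, end = 30)))
  expect_error(simulateCohort(long, tl), "unreachable")
  out <- simulationConfig(planted = list(
    SLE01 = data.frame(start = 200, end = 210)))
  expect_error(simulateCohort(out, tl), "outside")
  expect_error(simulateCohort(simulationConfig(planted = list(
    NOTASUBJECT = data.frame(start = 1, end = 3))), tl), "not in the cohort")
})

test_that("simulated records satisfy the serology invariants", {
  tl <- crpTiling()
  sim <- simulateCohort(simulationConfig(seed = 12, nSle = 20, nHbd = 10), tl)
  expect_true(validateSubjectRecords(sim$records))
  expect_equal(table(sim$records$group)[["SLE"]], 20)
})

test_that("frozen fixture assignment passes its marginal self-check", {
  tab <- fixtureAssignment()
  expect_equal(nrow(tab), 53)
  m <- as.matrix(tab[, -(1:2)])
  expect_equal(sum(m[tab$group == "SLE", ]), 73)
  expect_equal(max(rowSums(m)), 7)
})

test_that("simulated tracks honour bias and seed", {
  straight <- simulateTracks(nCells = 3, speed = 7, bias = 1, seed = 2)
  m <- trackMetrics(straight)
  expect_equal(m$cells$net_x_um, rep(60 * 7, 3))
  expect_equal(m$cells$velocity_um_min, rep(7, 3))
  expect_identical(simulateTracks(nCells = 5, seed = 8),
                   simulateTracks(nCells = 5, seed = 8))
  # unbiased walk: mean net x within 3 standard errors of zero
  un <- trackMetrics(simulateTracks(nCells = 2000, speed = 10, bias = 0,
                                    seed = 5))
  se <- sd(un$cells$net_x_um) / sqrt(nrow(un$cells))
  expect_lt(abs(mean(un$cells$net_x_um)), 3 * se)
})

test_that("simulated burst curves scale with the condition multiplier", {
  clean <- simulateRos(c(negative_control = 1, half = 0.5), noiseSd = 0,
                       replicates = 1, seed = 1)
  ctrl <- clean[clean$condition == "negative_control", ]
  half <- clean[clean$condition == "half", ]
  expect_equal(rosAucPercent(data.frame(time_s = half$time_s,
                                        value = half$value),
                             data.frame(time_s = ctrl$time_s,
                                        value = ctrl$value)), 50)
  expect_identical(simulateRos(seed = 3), simulateRos(seed = 3))
})
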