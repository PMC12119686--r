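test_that("Mann-Whitney handles worked examples", {
  same <- compareGroupsContinuous(c(1, 2, 3, 1, 2, 3),
                                  rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 4.5)
  expect_gt(same$p_value, 0.99)
  sep <- compareGroupsContinuous(c(1, 2, 3, 10, 20, 30),
                                 rep(c("a", "b"), each = 3))
  expect_equal(sep$statistic, 0)
  expect_true(sep$exact)
  expect_equal(sep$p_value, 0.1)  # 2/20 rank assignments as extreme
  expect_error(compareGroupsContinuous(1:3, rep("a", 3)), "two non-empty")
})

test_that("exact Mann-Whitney matches full enumeration for small samples", {
  set.seed(31)
  for (i in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    repeat {
      x <- round(rnorm(n1, 0, 4), 3); y <- round(rnorm(n2, 1, 4), 3)
      if (!anyDuplicated(c(x, y))) break
    }
    res <- compareGroupsContinuous(c(x, y), rep(c("g1", "g2"), c(n1, n2)))
    expect_true(res$exact)
    expect_equal(res$p_value, mwExactOracle(x, y))
  }
})

test_that("group summaries use the nearest-rank quantile convention", {
  res <- compareGroupsContinuous(c(1:4, 10:14), rep(c("a", "b"), c(4, 5)))
  expect_equal(res$summaries["a", "median"], 2)   # ceil(0.5*4)-th order stat
  expect_equal(res$summaries["b", "q75"], 13)
})

test_that("Spearman matches the rank-then-Pearson oracle", {
  expect_equal(correlateSpearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(correlateSpearman(1:10, rev(1:10))$rho, -1)
  set.seed(42)
  x <- rnorm(42); y <- 0.3 * x + rnorm(42)
  res <- correlateSpearman(x, y)
  expect_equal(res$rho, cor(rank(x), rank(y)), tolerance = 1e-9)
  expect_equal(res$n, 42)
  # tie-aware: average ranks
  xt <- c(1, 2, 2, 3); yt <- c(4, 4, 5, 6)
  expect_equal(correlateSpearman(xt, yt)$rho, cor(rank(xt), rank(yt)),
               tolerance = 1e-12)
})

test_that("2x2 exact test reproduces enumeration and symmetry", {
  bal <- exact2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(bal$odds_ratio, 1)
  expect_equal(bal$p_value, 1)
  diag <- exact2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag$p_value, 2 / choose(20, 10))  # 1.0825e-5
  expect_equal(diag$p_value, fisherOracle(matrix(c(10, 0, 0, 10), 2)))
  set.seed(9)
  for (i in 1:15) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(exact2x2(tab)$p_value, fisherOracle(tab), tolerance = 1e-12)
    expect_equal(exact2x2(t(tab))$p_value, exact2x2(tab)$p_value)
    expect_equal(exact2x2(tab[2:1, ])$p_value, exact2x2(tab)$p_value)
  }
})

test_that("signed-rank comparison matches enumeration and handles
           degenerate pairs", {
  expect_warning(same <- pairedCompare(1:5, 1:5), "zero")
  expect_equal(same$p_value, 1)
  expect_warning(one <- pairedCompare(c(1, 1, 1), c(1, 1, 2)), "one non-zero")
  expect_equal(one$p_value, 1)
  set.seed(13)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    repeat {
      d <- round(rnorm(n, 0.4, 1), 3)
      if (all(d != 0) && !anyDuplicated(abs(d))) break
    }
    res <- pairedCompare(rep(0, n), d)
    expect_equal(res$p_value, signedRankOracle(d))
  }
})

test_that("Friedman + Dunn battery behaves on degenerate and paired data", {
  m <- matrix(rep(1:6, 3), ncol = 3)
  colnames(m) <- c("a", "b", "c")
  res <- multiPairedCompare(m)      # identical conditions
  expect_equal(res$friedman$chisq, 0)
  expect_equal(res$friedman$p_value, 1)
  expect_true(all(res$pairwise$z == 0))

  set.seed(17)
  m2 <- cbind(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  r1 <- multiPairedCompare(m2)
  r2 <- multiPairedCompare(m2[sample(8), ])  # subject order irrelevant
  expect_equal(r1$friedman, r2$friedman)
  expect_equal(r1$pairwise, r2$pairwise)

  # k = 2: Dunn direction agrees with the paired signed-rank direction
  two <- m2[, 1:2]
  dz <- multiPairedCompare(two)$pairwise$z
  expect_gt(dz, 0)  # column b stochastically larger
  expect_lt(pairedCompare(two[, 1], two[, 2])$p_value, 0.2)
})

test_that("association table dispatches by variable type", {
  sim <- fixtureCohort()
  calls <- callEpitopes(sim$samples)
  em <- harmonizeCohort(calls, S4Vectors::metadata(sim$samples)$tiling,
                        SummarizedExperiment::colData(sim$samples)$group)
  spec <- data.frame(
    lhs = c("any_epitope_positive", "n_epitopes", "anti_crp_au",
            "SEIL^80-83"),
    rhs = c("group", "sledai2k", "esr", "complement_classical_pct"))
  tab <- buildAssociationTable(em, sim$records, spec)
  expect_equal(tab$test,
               c("Fisher exact", "Spearman", "Spearman", "Mann-Whitney U"))
  expect_true(all(is.finite(tab$p_value)))
  # the fixture feeds 24/42 vs 4/11 into the group test
  pos <- subjectTotals(em) > 0
  grp <- subjectInfo(em)$group
  expect_equal(sum(pos[grp == "SLE"]), 24)
  expect_equal(sum(pos[grp == "HBD"]), 4)
})

test_that("degenerate and unknown association variables are handled", {
  sim <- smallCohort()
  calls <- callEpitopes(sim)
  em <- harmonizeCohort(calls, S4Vectors::metadata(sim)$tiling,
                        SummarizedExperiment::colData(sim)$group)
  rec <- data.frame(subject_id = c("S1", "S2", "S3"),
                    flat = c(1, 1, 1), val = c(2, 5, 9))
  expect_warning(tab <- buildAssociationTable(
    em, rec, data.frame(lhs = "flat", rhs = "val")), "degenerate")
  expect_true(is.na(tab$p_value))
  expect_error(buildAssociationTable(
    em, rec, data.frame(lhs = "nope", rhs = "val")), "unknown variable")
})
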