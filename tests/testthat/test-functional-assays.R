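test_that("burst AUC percent-of-control: identity, linearity, gain
           invariance", {
  t <- seq(0, 900, 30)
  v <- (t / 300)^2 * exp(2 * (1 - t / 300)) * 1000
  curve <- data.frame(time_s = t, value = v)
  expect_equal(rosAucPercent(curve, curve), 100)
  twice <- transform(curve, value = 2 * value)
  expect_equal(rosAucPercent(twice, curve), 200)
  # instrument gain cancels
  g <- transform(curve, value = value * 7.3)
  expect_equal(rosAucPercent(g, transform(curve, value = value * 7.3)), 100)
})

test_that("burst AUC matches a midpoint-refinement oracle on random curves", {
  set.seed(23)
  t <- seq(0, 900, 30)
  # midpoint Riemann sums are exact for the piecewise-linear interpolant
  riemann <- function(t, v, k = 50) {
    total <- 0
    for (i in seq_len(length(t) - 1)) {
      tt <- seq(t[i], t[i + 1], length.out = k + 1)
      mid <- (tt[-1] + tt[-length(tt)]) / 2
      total <- total + sum(approx(t, v, xout = mid)$y) * diff(t[i:(i + 1)]) / k
    }
    total
  }
  for (i in 1:10) {
    a <- rlnorm(length(t), 3, 0.7); b <- rlnorm(length(t), 3, 0.7)
    got <- rosAucPercent(data.frame(time_s = t, value = a),
                         data.frame(time_s = t, value = b))
    expect_equal(got, 100 * riemann(t, a) / riemann(t, b), tolerance = 1e-9)
  }
})

test_that("burst AUC validates grids and control area", {
  t <- seq(0, 900, 30)
  zero <- data.frame(time_s = t, value = rep(0, length(t)))
  one <- data.frame(time_s = t, value = rep(1, length(t)))
  expect_error(rosAucPercent(one, zero), "normalization")
  expect_error(rosAucPercent(one, data.frame(time_s = t + 1, value = t)),
               "identical time grid")
})

test_that("track metrics: straight runs, stationary cells, random walks", {
  straight <- data.frame(cell_id = "c1", t_min = 0:60,
                         x_um = 10 * (0:60), y_um = 0)
  m <- trackMetrics(straight)
  expect_equal(m$cells$net_x_um, 600)
  expect_equal(m$cells$velocity_um_min, 10)
  expect_equal(trackMetrics(straight, axisSign = -1)$cells$net_x_um, -600)

  still <- data.frame(cell_id = "c1", t_min = 0:60, x_um = 5, y_um = 5)
  expect_equal(trackMetrics(still)$cells$velocity_um_min, 0)
  expect_equal(trackMetrics(still)$cells$net_x_um, 0)

  set.seed(3)
  walk <- data.frame(cell_id = "w", t_min = 0:60,
                     x_um = cumsum(c(0, rnorm(60, 0, 4))),
                     y_um = cumsum(c(0, rnorm(60, 0, 4))))
  m2 <- trackMetrics(walk)
  oracle <- sum(sqrt(diff(walk$x_um)^2 + diff(walk$y_um)^2)) / 60
  expect_equal(m2$cells$velocity_um_min, oracle)
  # path >= chord for every track
  expect_gte(m2$cells$velocity_um_min,
             abs(m2$cells$net_x_um) / m2$cells$time_min)
})

test_that("tracks with fewer than two samples are skipped with a warning", {
  mixed <- rbind(
    data.frame(cell_id = "ok", t_min = 0:2, x_um = 0:2, y_um = 0),
    data.frame(cell_id = "single", t_min = 0, x_um = 0, y_um = 0))
  expect_warning(m <- trackMetrics(mixed), "skipped")
  expect_equal(nrow(m$cells), 1)
})

test_that("extracellular-DNA index is a gain-invariant fold over control", {
  expect_equal(netReleaseIndex(500, 500), 1)
  expect_equal(netReleaseIndex(0, 500), 0)
  expect_equal(netReleaseIndex(3 * 700, 3 * 350),
               netReleaseIndex(700, 350))
  expect_error(netReleaseIndex(1, 0), "normalization")
})
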