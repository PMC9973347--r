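test_that("geometric intact fold hits its anchors and midpoint", {
  tr <- truthTrajectory("23S", anchor_fold = 0.75, anchor_time = 80)
  expect_equal(intactFold(tr, 0), 1)
  expect_equal(intactFold(tr, 80), 0.75)
  expect_equal(intactFold(tr, 40), sqrt(0.75), tolerance = 1e-12)
  flat <- truthTrajectory("x", anchor_fold = 1)
  expect_equal(intactFold(flat, c(0, 7, 1000)), rep(1, 3))
  expect_error(intactFold(tr, -1), ">= 0")
})

test_that("intact fold is monotone for random anchors", {
  set.seed(42)
  ts <- seq(0, 200, by = 5)
  for (i in 1:25) {
    a <- runif(1, 0.05, 2.5)
    tr <- truthTrajectory("x", anchor_fold = a, anchor_time = runif(1, 10, 160))
    f <- intactFold(tr, ts)
    if (a < 1) {
      expect_true(all(diff(f) <= 1e-12))
    } else {
      expect_true(all(diff(f) >= -1e-12))
    }
    expect_equal(f[1], 1)
  }
})

test_that("piecewise-linear mode passes through its anchors and plateaus", {
  tr <- truthTrajectory("hisR",
                        points = data.frame(time = c(5, 40, 160),
                                            fold = c(0.9, 1, 1)))
  expect_equal(intactFold(tr, c(0, 5, 40, 160, 500)), c(1, 0.9, 1, 1, 1))
  expect_equal(intactFold(tr, 2.5), 0.95)
})

test_that("degraded mass partitions exactly between fragments and solubles", {
  tr <- truthTrajectory("x", anchor_fold = 0.8, f_sol = 0.35)
  # 0.194 is the default-registry degraded mass at t = 80 of the isoleucine
  # scenario: sum of mass_fraction * (1 - F(80)) over the decaying species
  degraded <- sum(c(0.50, 0.27, 0.03) * (1 - c(0.75, 0.75, 0.95)))
  expect_equal(degraded, 0.194)
  part <- degradedPartition(tr, degraded)
  expect_equal(unname(part["tca_fragments"]), 0.1261, tolerance = 1e-12)
  expect_equal(unname(part["acid_soluble"]), 0.0679, tolerance = 1e-12)
  expect_equal(sum(part), degraded)

  expect_equal(degradedPartition(tr, 0), c(tca_fragments = 0,
                                           acid_soluble = 0))
  full <- truthTrajectory("x", f_sol = 1)
  expect_equal(unname(degradedPartition(full, 0.1)["tca_fragments"]), 0)
  expect_error(degradedPartition(tr, -0.1), ">= 0")
})

test_that("hypomodified pool is constant with synthesis on and decays after
          shutoff", {
  tr <- truthTrajectory("ileTUV", h0 = 0.1, k_mod = 0.1)
  expect_equal(hypomodFraction(tr, c(0, 50, 500), TRUE), rep(0.1, 3))
  expect_equal(hypomodFraction(tr, 0, FALSE), 0.1)
  expect_equal(hypomodFraction(tr, 10, FALSE), 0.1 * exp(-1),
               tolerance = 1e-12)
  h <- hypomodFraction(tr, seq(0, 100, 5), FALSE)
  expect_true(all(diff(h) < 0))
  none <- truthTrajectory("x", h0 = 0)
  expect_equal(hypomodFraction(none, c(0, 10), FALSE), c(0, 0))
})

test_that("trajectory tables round-trip through the anchor/points format", {
  trajs <- list(
    `23S` = truthTrajectory("23S", anchor_fold = 0.75, anchor_time = 80),
    hisR = truthTrajectory("hisR", points = data.frame(time = c(5, 40),
                                                       fold = c(0.9, 1)))
  )
  tabs <- trajectoriesToTable(trajs)
  back <- trajectoriesFromTable(tabs$anchors, tabs$points)
  ts <- seq(0, 120, by = 3)
  expect_equal(intactFold(back$`23S`, ts), intactFold(trajs$`23S`, ts))
  expect_equal(intactFold(back$hisR, ts), intactFold(trajs$hisR, ts))
})
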