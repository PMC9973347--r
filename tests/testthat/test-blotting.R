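test_that("probe affinities follow the modification rule", {
  reg <- defaultRegistry()
  p <- probeFor("ileTUV", "anticodon", reg)
  expect_gt(p@affinity_hypo, p@affinity_mature)
  expect_equal(p@affinity_hypo, 2 * p@affinity_mature)
  for (rg in c("five_prime", "three_prime", "anticodon_alt")) {
    q <- probeFor("ileTUV", rg, reg)
    expect_equal(q@affinity_hypo, q@affinity_mature)
  }
  # no acp3U on leuPQVT: even the anticodon probe is unbiased
  q <- probeFor("leuPQVT", "anticodon", reg)
  expect_equal(q@affinity_hypo, q@affinity_mature)
  expect_error(probeFor("nosuch", "anticodon", reg), "unknown species")
})

test_that("PAGE band counts preserve composition and conserve the extract", {
  reg <- defaultRegistry()
  spike <- makePopulation(reg, t = 0, channel = "H3", state = "steady")
  pop <- makePopulation(reg, t = 0, channel = "C14", state = "steady")
  hot <- extractRNA(pop, spike, extractionPreset("hot_phenol"), reg)
  bands <- pageBandCounts(hot, reg)
  expect_equal(bands$dpm_c14[bands$fraction == "band:tRNA"] /
                 sum(bands$dpm_c14), 0.16, tolerance = 1e-12)
  # conservation: bands sum to the whole extract when fragments are lost
  expect_equal(sum(bands$dpm_c14), sum(hot$c14), tolerance = 1e-12)
  expect_equal(sum(bands$dpm_h3), sum(hot$h3), tolerance = 1e-12)

  cold <- extractRNA(pop, spike, extractionPreset("cold_phenol"), reg)
  cbands <- pageBandCounts(cold, reg)
  share23S <- cbands$dpm_c14[cbands$fraction == "band:23S"] /
    sum(cbands$dpm_c14)
  expect_equal(share23S, 0.097, tolerance = 1e-3)
})

test_that("northern lane arithmetic: identity configuration, loading and
          hypomodification mix", {
  reg <- defaultRegistry()
  p5 <- probeFor("valT", "five_prime", reg)
  amounts <- c(valT = 120, selC = 0)
  none <- setNames(numeric(2), c("valT", "selC"))
  lane <- northernLane(amounts, p5, none, load = 1)
  expect_equal(lane$intensity[lane$band == "valT"], 120)
  expect_equal(lane$intensity[lane$band == "selC"], 0)

  spike <- spikeCellAmounts(reg, spike_mass = 1000)
  l1 <- northernLane(amounts, p5, spike, load = 1)
  l2 <- northernLane(amounts, p5, spike, load = 2)
  expect_equal(l2$intensity, 2 * l1$intensity)
  r1 <- l1$intensity[1] / l1$intensity[2]
  r2 <- l2$intensity[1] / l2$intensity[2]
  expect_equal(r1, r2, tolerance = 1e-12)

  # anticodon probe on an acp3U target: signal tracks (1 + h) when
  # affinity_hypo = 2 * affinity_mature
  pa <- probeFor("ileTUV", "anticodon", reg)
  am <- c(ileTUV = 100, selC = 0)
  sig_h <- northernLane(am, pa, none, hypo_fraction = 0.10)
  sig_0 <- northernLane(am, pa, none, hypo_fraction = 0)
  expect_equal(sig_0$intensity[1] / sig_h$intensity[1], 1 / 1.10,
               tolerance = 1e-12)
})

test_that("spike-only lanes report the endogenous background at any load", {
  reg <- defaultRegistry()
  p <- probeFor("valT", "five_prime", reg)
  spike <- spikeCellAmounts(reg, spike_mass = 1000, endog_frac = 0.05)
  expect_equal(unname(spike[["selC"]]), 1000)
  expect_equal(unname(spike[["valT"]]) / spike[["selC"]], 0.05,
               tolerance = 1e-12)
  for (load in c(0.5, 1, 3)) {
    lane <- spikeOnlyLane(spike, p, load = load)
    expect_equal(lane$intensity[lane$band == "valT"] /
                   lane$intensity[lane$band == "selC"], 0.05,
                 tolerance = 1e-12)
  }
  empty <- setNames(numeric(2), c("valT", "selC"))
  lane0 <- spikeOnlyLane(empty, p)
  expect_equal(lane0$intensity[lane0$band == "valT"], 0)
})

test_that("densitometry noise is seeded, reproducible and mean-preserving", {
  reg <- defaultRegistry()
  p <- probeFor("valT", "five_prime", reg)
  spike <- spikeCellAmounts(reg, 1000)
  a <- northernLane(c(valT = 100), p, spike, noise_cv = 0.1, seed = 5)
  b <- northernLane(c(valT = 100), p, spike, noise_cv = 0.1, seed = 5)
  expect_identical(a$intensity, b$intensity)
  set.seed(99)
  draws <- replicate(2000, northernLane(c(valT = 100), p, spike,
                                        noise_cv = 0.05)$intensity[1])
  base <- northernLane(c(valT = 100), p, spike)$intensity[1]
  expect_lt(abs(mean(draws) / base - 1), 0.01)
})
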