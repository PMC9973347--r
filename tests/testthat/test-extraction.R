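test_that("size bias follows the logistic closed form", {
  cold <- extractionPreset("cold_phenol")
  expect_equal(sizeBiasS(cold, 1542), oracleLogistic(1542, 300, 60, 0.05),
               tolerance = 1e-12)
  expect_equal(sizeBiasS(cold, 1542), 0.05, tolerance = 1e-6)
  expect_equal(sizeBiasS(cold, 76), oracleLogistic(76, 300, 60, 0.05),
               tolerance = 1e-12)
  expect_equal(sizeBiasS(cold, 76), 0.9778, tolerance = 1e-3)
  hot <- extractionPreset("hot_phenol")
  expect_equal(sizeBiasS(hot, c(10, 76, 2904)), rep(1, 3))
  # monotone non-increasing in length
  L <- seq(10, 4000, by = 10)
  expect_true(all(diff(sizeBiasS(cold, L)) <= 0))
  expect_error(sizeBiasS(cold, 0), "> 0")
})

test_that("growth-state factor honours the spike contract and its closed
          form", {
  cold <- extractionPreset("cold_phenol")
  expect_equal(stateFactorG(cold, 80, "steady"), 1)
  expect_equal(stateFactorG(extractionPreset("hot_phenol"), 200, "perturbed"),
               1)
  expect_equal(stateFactorG(cold, 80, "perturbed"),
               0.35 + 0.65 * exp(-0.04 * 80), tolerance = 1e-12)
  expect_equal(stateFactorG(cold, 80, "perturbed"), 0.3765,
               tolerance = 1e-4)
  expect_equal(stateFactorG(cold, 0, "perturbed"), 1)
  ts <- seq(0, 160, 5)
  expect_true(all(diff(stateFactorG(cold, ts, "perturbed")) < 0))
})

test_that("hot phenol recovers composition proportionally; cold phenol
          reproduces the brute-force biased sums", {
  reg <- defaultRegistry()
  spike <- makePopulation(reg, t = 0, channel = "H3", state = "steady")
  pop <- makePopulation(reg, t = 0, channel = "C14", state = "steady",
                        total_dpm = 1e6)
  hot <- extractRNA(pop, spike, extractionPreset("hot_phenol"), reg)
  sp_rows <- hot$species != "fragments"
  expect_equal(hot$c14[sp_rows] / sum(hot$c14[sp_rows]),
               speciesTable(reg)$mass_fraction, tolerance = 1e-12)
  expect_equal(sum(hot$c14) / (0.92e6), 0.45, tolerance = 1e-12)

  cold_m <- extractionPreset("cold_phenol")
  cold <- extractRNA(pop, spike, cold_m, reg)
  # brute-force weighted sum oracle: e0 * sum mf * s(L)
  expected <- 0.30 * oracleWeightedSum(reg, function(nm, L) {
    oracleLogistic(L, 300, 60, 0.05)
  })
  expect_equal(sum(cold$c14) / 0.92e6, expected, tolerance = 1e-12)
  expect_equal(expected, 0.077, tolerance = 5e-3)
  trna_share <- cold$c14[cold$species == "tRNA"] / sum(cold$c14)
  expect_equal(trna_share, 0.61, tolerance = 5e-3)
})

test_that("spike amounts are invariant to t and extraction is scale
          equivariant", {
  reg <- defaultRegistry()
  trajs <- list(`23S` = truthTrajectory("23S", 0.75, 80))
  spike <- makePopulation(reg, t = 0, channel = "H3", state = "steady")
  m <- extractionPreset("tri_reagent")
  e0t <- extractRNA(makePopulation(reg, trajs, 0, "C14", "perturbed"),
                    spike, m, reg)
  e80 <- extractRNA(makePopulation(reg, trajs, 80, "C14", "perturbed"),
                    spike, m, reg)
  expect_identical(e80$h3, e0t$h3)

  pop1 <- makePopulation(reg, trajs, 40, "C14", "perturbed", total_dpm = 1e6)
  pop2 <- makePopulation(reg, trajs, 40, "C14", "perturbed", total_dpm = 2e6)
  ex1 <- extractRNA(pop1, spike, m, reg)
  ex2 <- extractRNA(pop2, spike, m, reg)
  expect_equal(ex2$c14, 2 * ex1$c14, tolerance = 1e-12)
})

test_that("TRI Reagent spares short species from the growth-state penalty", {
  reg <- defaultRegistry()
  tri <- extractionPreset("tri_reagent")
  spike <- makePopulation(reg, t = 0, channel = "H3", state = "steady")
  trajs <- list()  # everything flat: any decline is pure extraction bias
  e0t <- extractRNA(makePopulation(reg, trajs, 0, "C14", "perturbed"),
                    spike, tri, reg)
  e80 <- extractRNA(makePopulation(reg, trajs, 80, "C14", "perturbed"),
                    spike, tri, reg)
  ratio <- e80$c14 / e0t$c14
  expect_equal(ratio[e0t$species == "tRNA"], 1)  # 76 nt < 100 nt cutoff
  g80 <- 0.55 + 0.45 * exp(-0.05 * 80)
  expect_equal(ratio[e0t$species == "5S"], g80, tolerance = 1e-12)
})

test_that("method definition files round-trip", {
  m <- extractionPreset("tri_reagent")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeExtractionMethod(m, path)
  back <- loadExtractionMethod(path)
  expect_equal(back@e0, m@e0)
  expect_equal(back@state_min_length, 100)
  expect_equal(sizeBiasS(back, c(50, 200, 1000)),
               sizeBiasS(m, c(50, 200, 1000)))
})
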