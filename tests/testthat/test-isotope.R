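isoTrajs <- list(
  `23S` = truthTrajectory("23S", 0.75, 80),
  `16S` = truthTrajectory("16S", 0.75, 80),
  `5S` = truthTrajectory("5S", 0.95, 80),
  tRNA = truthTrajectory("tRNA", 1.10, 80)
)

test_that("TCA precipitate counts everything at t = 0 and excludes
          acid-soluble label later", {
  reg <- defaultRegistry()
  spike <- makePopulation(reg, t = 0, channel = "H3", state = "steady",
                          total_dpm = 5e5)
  p0 <- makePopulation(reg, isoTrajs, t = 0, channel = "C14",
                       state = "perturbed", total_dpm = 1e6)
  rec0 <- tcaPrecipitate(p0, spike, reg)
  expect_equal(rec0$dpm_c14, 1e6)  # nothing degraded, nothing lost
  expect_equal(rec0$dpm_h3, 5e5)

  p80 <- makePopulation(reg, isoTrajs, t = 80, channel = "C14",
                        state = "perturbed", total_dpm = 1e6)
  rec80 <- tcaPrecipitate(p80, spike, reg)
  # RNA-only part relative to t = 0: brute-force intact + retained fragments
  intact <- oracleWeightedSum(reg, function(nm, L) isoFold(nm, 80))
  frag <- 0.65 * oracleWeightedSum(reg, function(nm, L) {
    max(0, 1 - isoFold(nm, 80))
  })
  rna80 <- (rec80$dpm_c14 - 0.08e6) / 0.92e6
  expect_equal(rna80, intact + frag, tolerance = 1e-12)
  expect_equal(rna80, 0.9481, tolerance = 1e-4)
  # spike channel untouched by the sample's perturbation time
  expect_equal(rec80$dpm_h3, rec0$dpm_h3)
})

test_that("fully solubilized degradation removes fragments from the
          precipitate", {
  reg <- defaultRegistry()
  trajs <- lapply(isoTrajs, function(tr) {
    truthTrajectory(tr@species, tr@anchor_fold, tr@anchor_time, f_sol = 1)
  })
  names(trajs) <- names(isoTrajs)
  spike <- makePopulation(reg, t = 0, channel = "H3", state = "steady")
  p80 <- makePopulation(reg, trajs, t = 80, channel = "C14",
                        state = "perturbed", total_dpm = 1e6)
  rec <- tcaPrecipitate(p80, spike, reg)
  intact <- oracleWeightedSum(reg, function(nm, L) isoFold(nm, 80))
  expect_equal((rec$dpm_c14 - 0.08e6) / 0.92e6, intact, tolerance = 1e-12)
  expect_equal(intact, 0.822, tolerance = 1e-12)
})

test_that("NaOH treatment leaves the DNA label only, invariant in time", {
  reg <- defaultRegistry()
  spike <- makePopulation(reg, t = 0, channel = "H3", state = "steady",
                          total_dpm = 5e5)
  for (t in c(0, 80)) {
    pop <- makePopulation(reg, isoTrajs, t = t, channel = "C14",
                          state = "perturbed", total_dpm = 1000)
    rec <- naohThenTca(pop, spike, reg)
    expect_equal(rec$dpm_c14, 80)  # dna_fraction 0.08 of 1000 dpm
    total <- tcaPrecipitate(pop, spike, reg)
    expect_true(total$dpm_c14 >= rec$dpm_c14)
    expect_true(total$dpm_h3 >= rec$dpm_h3)
  }
  none <- Registry(speciesTable(reg), trnaMembers(reg), dna_fraction = 0)
  pop <- makePopulation(none, t = 0, channel = "C14", state = "steady")
  sp <- makePopulation(none, t = 0, channel = "H3", state = "steady")
  rec <- naohThenTca(pop, sp, none)
  expect_equal(rec$dpm_c14, 0)
  expect_equal(rec$dpm_h3, 0)
})

test_that("scintillation counting is exact, seeded and unbiased", {
  expect_equal(countLsc(1000, "none"), 1000)
  expect_equal(countLsc(0, "poisson", seed = 7), 0)
  expect_error(countLsc(-1), ">= 0")
  a <- countLsc(rep(500, 10), "poisson", seed = 11)
  b <- countLsc(rep(500, 10), "poisson", seed = 11)
  expect_identical(a, b)
  draws <- countLsc(rep(10000, 1000), "poisson", seed = 3)
  expect_lt(abs(mean(draws) - 10000) / 10000, 0.01)
})

test_that("the spike channel of every record type is invariant to the
          sample's perturbation time", {
  reg <- defaultRegistry()
  spike <- makePopulation(reg, t = 0, channel = "H3", state = "steady")
  method <- extractionPreset("cold_phenol")
  ref <- NULL
  for (t in c(0, 5, 40, 80)) {
    pop <- makePopulation(reg, isoTrajs, t = t, channel = "C14",
                          state = "perturbed")
    h3 <- c(tcaPrecipitate(pop, spike, reg)$dpm_h3,
            naohThenTca(pop, spike, reg)$dpm_h3,
            extractRNA(pop, spike, method, reg)$h3)
    if (is.null(ref)) ref <- h3 else expect_identical(h3, ref)
  }
})
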