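test_that("presets resolve and unknown names list the alternatives", {
  expect_true(all(c("isoleucine_radiolabel", "arginine_short",
                    "relA_minus_arginine", "phosphate_short", "rifampicin",
                    "longterm_phosphate") %in% scenarioPresets()))
  expect_error(buildScenario("nope"), "isoleucine_radiolabel")
  sc <- buildScenario("arginine_short",
                      overrides = list(steady_sample_count = 1), seed = 1)
  expect_equal(sc@steady_sample_count, 1)
  expect_equal(length(runScenario(sc)@samples$sample_id), 7)
})

test_that("the isoleucine design emits the full table set", {
  sc <- buildScenario("isoleucine_radiolabel", seed = 1)
  run <- runScenario(sc)
  expect_equal(nrow(run@samples), 8)  # 3 steady + 5 time points
  expect_setequal(unique(run@dpm$method),
                  c("hot_phenol", "cold_phenol", "tri_reagent"))
  expect_setequal(unique(run@dpm$fraction),
                  c("total_tca", "naoh_tca", "extract", "band:23S",
                    "band:16S", "band:5S", "band:tRNA", "band:other"))
  expect_equal(run@manifest$scenario, "isoleucine_radiolabel")
  expect_equal(run@manifest$seed, 1)
})

test_that("truth tables balance mass at every time point", {
  for (nm in c("isoleucine_radiolabel", "phosphate_short")) {
    truth <- runScenario(buildScenario(nm, seed = 1))@truth
    pool <- truth[truth$is_pool, , drop = FALSE]
    reg <- speciesTable(defaultRegistry())
    mf <- reg$mass_fraction[match(pool$species, reg$name)]
    decaying <- pool$intact_fold <= 1
    total <- pool$intact_mass + pool$tca_fragments + pool$acid_soluble
    expect_equal(total[decaying], mf[decaying], tolerance = 1e-12)
    # accumulating species gain mass and shed no fragments
    expect_true(all(pool$intact_mass[!decaying] >= mf[!decaying] - 1e-12))
    expect_true(all(pool$tca_fragments[!decaying] == 0))
  }
})

test_that("the spike 3H column is constant across timepoints within a
          method", {
  run <- runScenario(buildScenario("isoleucine_radiolabel", seed = 1))
  dpm <- run@dpm
  for (m in unique(dpm$method)) {
    for (fr in unique(dpm$fraction)) {
      h3 <- dpm$dpm_h3[dpm$method == m & dpm$fraction == fr &
                         dpm$replicate == 1]
      expect_equal(max(h3) - min(h3), 0)
    }
  }
})

test_that("rifampicin truth is flat except tyrTV", {
  q <- quantifyRun(runScenario(buildScenario("rifampicin", seed = 3)))
  n <- q$northern
  tyr <- n[n$probe_id == "tyrTV.five_prime", ]
  expect_equal(tyr$value[tyr$time == 80], 1.3, tolerance = 1e-9)
  rest <- n[n$probe_id != "tyrTV.five_prime", ]
  expect_equal(rest$value, rep(1, nrow(rest)), tolerance = 1e-9)
})

test_that("noiseless northern pipeline returns every preset anchor exactly", {
  cases <- list(
    list("relA_minus_arginine", "valT.five_prime", 160, 2.4),
    list("relA_minus_arginine", "argVYZQ.five_prime", 160, 1.5),
    list("relA_minus_arginine", "leuU.five_prime", 160, 1.5),
    list("phosphate_short", "ileTUV.five_prime", 80, 1.9),
    list("arginine_short", "valT.five_prime", 160, 0.82),
    list("arginine_short", "leuPQVT.five_prime", 160, 0.86),
    list("arginine_short", "hisR.five_prime", 5, 0.90)
  )
  for (cs in cases) {
    q <- quantifyRun(runScenario(buildScenario(cs[[1]], seed = 1)))
    n <- q$northern
    val <- n$value[n$probe_id == cs[[2]] & n$time == cs[[3]]]
    expect_equal(val, cs[[4]], tolerance = 1e-9,
                 label = paste(cs[[1]], cs[[2]]))
  }
})

test_that("runs are deterministic under a seed, and differ across seeds", {
  sc <- buildScenario("rifampicin",
                      overrides = list(noise = noisySettings), seed = 7)
  r1 <- runScenario(sc)
  r2 <- runScenario(sc)
  expect_identical(r1@dpm, r2@dpm)
  expect_identical(r1@northern_bands, r2@northern_bands)
  r3 <- runScenario(buildScenario("rifampicin",
                                  overrides = list(noise = noisySettings),
                                  seed = 8))
  expect_false(identical(r1@dpm$dpm_c14, r3@dpm$dpm_c14))
})

test_that("Welch p values appear under noise and Bonferroni only inflates
          them", {
  run <- runScenario(buildScenario("rifampicin",
                                   overrides = list(noise = noisySettings),
                                   seed = 11))
  plain <- quantifyRun(run)$northern
  expect_true(any(is.finite(plain$p_value)))
  adj <- quantifyRun(run, p_adjust = "bonferroni")$northern
  ok <- is.finite(plain$p_value)
  expect_true(all(adj$p_value[ok] >= plain$p_value[ok] - 1e-12))
  expect_equal(adj$value, plain$value)
})

test_that("long-term presets run on an hour clock and flag uncalibrated
          anchors", {
  sc <- buildScenario("longterm_phosphate", seed = 1)
  expect_equal(sc@time_unit, "h")
  run <- runScenario(sc)
  expect_true(length(run@manifest$uncalibrated) > 0)
  truth <- run@truth
  s16 <- truth[truth$species == "16S", ]
  expect_equal(s16$intact_fold[s16$time == 168], 0.35, tolerance = 1e-12)
  glt <- truth[truth$species == "gltTUVW", ]
  expect_true(all(glt$intact_fold >= 1))
})
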