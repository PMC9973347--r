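dpmDf <- function(ids, c14, h3, time = 0) {
  data.frame(sample_id = ids, time = time, dpm_c14 = c14, dpm_h3 = h3,
             stringsAsFactors = FALSE)
}

test_that("DNA subtraction is exact and rejects impossible states", {
  total <- dpmDf("s1", 1000, 600)
  dna <- dpmDf("s1", 50, 30)
  rna <- subtractDna(total, dna)
  expect_equal(rna$dpm_c14, 950)
  expect_equal(rna$dpm_h3, 570)
  expect_equal(subtractDna(dpmDf("s1", 100, 100),
                           dpmDf("s1", 100, 100))$dpm_c14, 0)
  expect_error(subtractDna(dpmDf("s1", 100, 100), dpmDf("s1", 120, 10)),
               "DNA exceeds total")
  # small negatives clamp under counting noise
  expect_warning(
    rna2 <- subtractDna(dpmDf("s1", 100, 100), dpmDf("s1", 110, 10),
                        noise = "poisson"),
    "clamped")
  expect_equal(rna2$dpm_c14, 0)
})

test_that("extraction efficiency is a guarded ratio", {
  expect_equal(extractionEfficiency(37, 100), 0.37)
  expect_error(extractionEfficiency(5, 0), "> 0")
  expect_warning(eff <- extractionEfficiency(110, 100), "above 1")
  expect_equal(eff, 1.1)
})

test_that("relative recovery normalizes to the steady mean exactly", {
  rec <- dpmDf(c("st1", "st2", "st3", "t80"),
               c(200, 220, 180, 160), c(100, 110, 90, 100),
               time = c(0, 0, 0, 80))
  out <- relativeRecovery(rec, c("st1", "st2", "st3"))
  expect_equal(mean(out$value[out$sample_id != "t80"]), 1)
  expect_equal(out$value[out$sample_id == "t80"], 1.6 / 2, tolerance = 1e-12)
  expect_equal(unique(out$n_steady), 3)
  expect_error(relativeRecovery(dpmDf("a", 1, 0), "a"), "dpm_h3")
  expect_error(relativeRecovery(rec, "nope"), "steady")
})

test_that("spike-in northern normalization implements the endogenous
          correction formula and loading invariance", {
  bands <- data.frame(
    lane_id = c("L1", "L1", "sp", "sp"),
    band = c("valT", "selC", "valT", "selC"),
    intensity = c(45, 10, 5, 100))
  lanes <- data.frame(
    lane_id = c("L1", "sp"), sample_id = c("st1", "spike_only"),
    time = c(0, NA), is_spike_only = c(FALSE, TRUE))
  out <- northernNormalize(bands, lanes, steady_ids = "st1")
  # corrected = 45 - 10 * (5/100) = 44.5; normalized = 44.5 / 10 = 4.45;
  # the single steady lane then maps to 1 by construction
  expect_equal(out$value, 1)
  multi <- rbind(bands,
                 data.frame(lane_id = c("L2", "L2"), band = c("valT", "selC"),
                            intensity = c(20, 10)))
  lanes2 <- rbind(lanes, data.frame(lane_id = "L2", sample_id = "t80",
                                    time = 80, is_spike_only = FALSE))
  out2 <- northernNormalize(multi, lanes2, steady_ids = "st1")
  expect_equal(out2$value[out2$sample_id == "t80"], 19.5 / 44.5,
               tolerance = 1e-12)
  # arbitrary per-lane loads cancel exactly
  loads <- c(L1 = 2.7, L2 = 0.4, sp = 13)
  scaled <- multi
  scaled$intensity <- scaled$intensity * loads[scaled$lane_id]
  out3 <- northernNormalize(scaled, lanes2, steady_ids = "st1")
  expect_equal(out3$value, out2$value, tolerance = 1e-12)

  expect_error(northernNormalize(multi, lanes2[!lanes2$is_spike_only, ],
                                 "st1"), "spike-only")
  zero <- multi
  zero$intensity[zero$lane_id == "L2" & zero$band == "selC"] <- 0
  expect_error(northernNormalize(zero, lanes2, "st1"), "selC")
})

test_that("14C tRNA-fraction normalization cancels loading", {
  target <- data.frame(sample_id = c("st1", "t80"), time = c(0, 80),
                       intensity = c(50, 40))
  den <- data.frame(sample_id = c("st1", "t80"), signal = c(100, 100))
  out <- radiolabelLaneNormalize(target, den, "st1")
  expect_equal(out$value, c(1, 0.8))
  half <- radiolabelLaneNormalize(
    transform(target, intensity = intensity / 2),
    transform(den, signal = signal / 2), "st1")
  expect_equal(half$value, out$value, tolerance = 1e-12)
  expect_error(radiolabelLaneNormalize(target,
                                       transform(den, signal = 0), "st1"),
               "> 0")
})

test_that("tRNA/rRNA ratio is the quotient of relative levels", {
  trna <- data.frame(sample_id = c("st1", "t80"), time = c(0, 80),
                     value = c(1, 1.10))
  rrna <- data.frame(sample_id = c("st1", "t80"), time = c(0, 80),
                     value = c(1, 0.75))
  out <- trnaRrnaRatio(trna, rrna)
  expect_equal(out$ratio, c(1, 1.10 / 0.75))
  expect_error(trnaRrnaRatio(trna, transform(rrna, value = 0)), "0")
})

test_that("Welch test matches the closed-form oracle to 6 decimals", {
  x <- c(2, 4, 6); y <- c(1, 2, 3)
  got <- welchTTest(x, y)
  want <- oracleWelch(x, y)
  expect_equal(got$t, want$t, tolerance = 1e-9)
  expect_equal(got$df, want$df, tolerance = 1e-9)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-9)
  expect_equal(got$t, 1.549, tolerance = 1e-3)
  expect_equal(got$df, 2.94, tolerance = 1e-2)

  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(5, 1, 0.3); b <- rnorm(7, 1.4, 0.8)
    g <- welchTTest(a, b); w <- oracleWelch(a, b)
    expect_equal(g$t, w$t, tolerance = 1e-6)
    expect_equal(g$df, w$df, tolerance = 1e-6)
    expect_equal(g$p_value, w$p_value, tolerance = 1e-6)
  }
  # equal variances and equal n: collapses to the pooled-variance test
  a <- c(1.1, 0.9, 1.3, 0.8); b <- c(2.0, 1.8, 2.2, 1.7)
  pooled <- stats::t.test(a, b, var.equal = TRUE)
  g <- welchTTest(a, b)
  expect_equal(g$t, unname(pooled$statistic), tolerance = 1e-6)
  expect_equal(g$p_value, pooled$p.value, tolerance = 1e-6)

  expect_equal(welchTTest(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(welchTTest(1, c(1, 2)), "at least 2")
})
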