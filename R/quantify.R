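#' Subtract the DNA label background
#'
#' Per channel, RNA counts are total TCA-precipitable counts minus the counts
#' of the matching NaOH-treated (DNA-only) record. In noiseless data a
#' negative difference is a physically impossible state and raises an error;
#' with Poisson counting, negatives within 3 counting-noise standard
#' deviations (\eqn{\sqrt{total + dna}}) clamp to zero with a warning.
#'
#' @param total DpmRecord data.frame of \code{total_tca} (or extract) records
#'   with columns \code{sample_id}, \code{dpm_c14}, \code{dpm_h3}.
#' @param dna matching \code{naoh_tca} records (same sample ids).
#' @param noise \code{"none"} or \code{"poisson"}; sets the clamp tolerance.
#' @return data.frame of RNA-only counts (\code{sample_id}, \code{time} if
#'   present, \code{dpm_c14}, \code{dpm_h3}).
#' @export
subtractDna <- function(total, dna, noise = c("none", "poisson")) {
  noise <- match.arg(noise)
  if (!all(total$sample_id %in% dna$sample_id)) {
    .stopf("no NaOH record for sample(s): %s",
           paste(setdiff(total$sample_id, dna$sample_id), collapse = ", "))
  }
  i <- match(total$sample_id, dna$sample_id)
  out <- data.frame(sample_id = total$sample_id, stringsAsFactors = FALSE)
  if ("time" %in% names(total)) out$time <- total$time
  for (ch in c("dpm_c14", "dpm_h3")) {
    diff <- total[[ch]] - dna[[ch]][i]
    tol <- if (noise == "poisson") 3 * sqrt(total[[ch]] + dna[[ch]][i]) else 0
    bad <- diff < -tol
    if (any(bad)) {
      .stopf("DNA exceeds total beyond tolerance in %s for sample(s): %s",
             ch, paste(total$sample_id[bad], collapse = ", "))
    }
    clamp <- diff < 0
    if (any(clamp)) {
      .warnf("clamped %d small negative RNA count(s) to 0 in %s",
             sum(clamp), ch)
      diff[clamp] <- 0
    }
    out[[ch]] <- diff
  }
  out
}

#' Extraction efficiency
#'
#' Fraction of the total TCA-precipitable RNA label recovered by an extraction
#' method; both inputs must already be DNA-subtracted. Values above 1 are
#' possible under counting noise and are kept, with a warning.
#'
#' @param extracted_rna_c14 extracted RNA counts (dpm, C14 channel).
#' @param total_rna_c14 total TCA-precipitable RNA counts (dpm, > 0).
#' @return efficiency fraction(s).
#' @export
extractionEfficiency <- function(extracted_rna_c14, total_rna_c14) {
  if (any(total_rna_c14 <= 0)) {
    .stopf("total RNA counts must be > 0")
  }
  eff <- extracted_rna_c14 / total_rna_c14
  if (any(eff > 1)) {
    .warnf("%d efficiency value(s) above 1 (counting noise)", sum(eff > 1))
  }
  eff
}

#' Steady-state-relative recovery from dual-isotope records
#'
#' Each record's \eqn{[^{14}C]/[^3H]} ratio is divided by the mean ratio of
#' the steady-state reference records, so steady samples average exactly 1 by
#' construction and perturbed samples read as fractions of the steady-state
#' level. Applies identically to whole-extract, TCA and band records.
#'
#' @param records data.frame with columns \code{sample_id}, \code{time},
#'   \code{dpm_c14}, \code{dpm_h3} (all \code{dpm_h3} > 0).
#' @param steady_ids sample ids forming the steady-state reference.
#' @return data.frame (\code{sample_id}, \code{time}, \code{value},
#'   \code{n_steady}).
#' @export
relativeRecovery <- function(records, steady_ids) {
  need <- c("sample_id", "time", "dpm_c14", "dpm_h3")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    .stopf("records lack column(s): %s", paste(missing, collapse = ", "))
  }
  if (any(records$dpm_h3 <= 0)) {
    .stopf("dpm_h3 must be > 0 for sample(s): %s",
           paste(records$sample_id[records$dpm_h3 <= 0], collapse = ", "))
  }
  steady <- records$sample_id %in% steady_ids
  if (!any(steady)) {
    .stopf("no steady-state reference records among: %s",
           paste(unique(records$sample_id), collapse = ", "))
  }
  ratio <- records$dpm_c14 / records$dpm_h3
  ref <- mean(ratio[steady])
  data.frame(
    sample_id = records$sample_id,
    time = records$time,
    value = ratio / ref,
    n_steady = sum(steady),
    stringsAsFactors = FALSE
  )
}

#' Spike-in northern normalization with endogenous correction
#'
#' Implements the whole-cell tRNA-selC spike-in normalization: for every lane
#' the target signal is corrected by subtracting the endogenous-expression
#' background of the spike cells, estimated from the spike-only lane and
#' scaled through the selC band of the same lane
#' (\eqn{corrected = I_{target} - I_{selC} \cdot
#' I^{spike}_{target} / I^{spike}_{selC}}), then divided by the selC signal of
#' the lane, and finally expressed relative to the mean of the steady-state
#' lanes. The whole chain is invariant to per-lane loading factors.
#'
#' @param bands BandIntensity data.frame (\code{lane_id}, \code{band},
#'   \code{intensity}) holding a target band and a selC band per lane.
#' @param lanes lane metadata (\code{lane_id}, \code{sample_id}, \code{time},
#'   \code{is_spike_only}) with exactly one spike-only lane.
#' @param steady_ids sample ids forming the steady-state reference.
#' @param noise_cv densitometry CV used to set the negative-correction
#'   tolerance (3 noise SDs; 0 demands exact non-negativity).
#' @return data.frame (\code{lane_id}, \code{sample_id}, \code{time},
#'   \code{value}, \code{n_steady}) over the sample lanes.
#' @export
northernNormalize <- function(bands, lanes, steady_ids, noise_cv = 0) {
  need_b <- c("lane_id", "band", "intensity")
  need_l <- c("lane_id", "sample_id", "time", "is_spike_only")
  if (!all(need_b %in% names(bands))) {
    .stopf("band table lacks column(s): %s",
           paste(setdiff(need_b, names(bands)), collapse = ", "))
  }
  if (!all(need_l %in% names(lanes))) {
    .stopf("lane table lacks column(s): %s",
           paste(setdiff(need_l, names(lanes)), collapse = ", "))
  }
  targets <- setdiff(unique(bands$band), "selC")
  if (length(targets) != 1L) {
    .stopf("band table must hold one target band plus selC (found: %s)",
           paste(unique(bands$band), collapse = ", "))
  }
  target <- targets
  getBand <- function(lane, band) {
    v <- bands$intensity[bands$lane_id == lane & bands$band == band]
    if (length(v) != 1L) {
      .stopf("lane '%s' lacks a unique '%s' band", lane, band)
    }
    v
  }
  spike_lanes <- lanes$lane_id[lanes$is_spike_only]
  if (length(spike_lanes) != 1L) {
    .stopf("expected exactly one spike-only lane, found %d",
           length(spike_lanes))
  }
  sp_sel <- getBand(spike_lanes, "selC")
  if (sp_sel <= 0) .stopf("selC band must be > 0 in lane '%s'", spike_lanes)
  spike_ratio <- getBand(spike_lanes, target) / sp_sel
  sample_lanes <- lanes[!lanes$is_spike_only, , drop = FALSE]
  norm <- vapply(sample_lanes$lane_id, function(lane) {
    it <- getBand(lane, target)
    isel <- getBand(lane, "selC")
    if (isel <= 0) .stopf("selC band must be > 0 in lane '%s'", lane)
    corrected <- it - isel * spike_ratio
    tol <- 3 * noise_cv * (abs(it) + isel * spike_ratio)
    if (corrected < -tol) {
      .stopf("corrected intensity negative beyond tolerance in lane '%s'",
             lane)
    }
    if (corrected < 0) {
      .warnf("clamped small negative corrected intensity to 0 in lane '%s'",
             lane)
      corrected <- 0
    }
    corrected / isel
  }, numeric(1))
  steady <- sample_lanes$sample_id %in% steady_ids
  if (!any(steady)) .stopf("no steady-state lanes in lane table")
  ref <- mean(norm[steady])
  data.frame(
    lane_id = sample_lanes$lane_id,
    sample_id = sample_lanes$sample_id,
    time = sample_lanes$time,
    value = unname(norm) / ref,
    n_steady = sum(steady),
    stringsAsFactors = FALSE
  )
}

#' Normalize a northern target band by the lane's 14C tRNA-fraction signal
#'
#' The normalization route for radiolabeled samples: the probe signal of the
#' target tRNA is divided by the \eqn{[^{14}C]} signal of the entire tRNA
#' fraction of the same lane (shown to be stable by the dual-isotope
#' approach), then expressed relative to the steady-state mean. Lane loading
#' cancels in the per-lane ratio.
#'
#' @param target data.frame (\code{sample_id}, \code{time},
#'   \code{intensity}) of target-band signals per lane.
#' @param trna_c14 data.frame (\code{sample_id}, \code{signal}) of the
#'   lane-matched 14C tRNA-fraction signals (> 0).
#' @param steady_ids sample ids forming the steady-state reference.
#' @return data.frame (\code{sample_id}, \code{time}, \code{value},
#'   \code{n_steady}).
#' @export
radiolabelLaneNormalize <- function(target, trna_c14, steady_ids) {
  if (!all(target$sample_id %in% trna_c14$sample_id)) {
    .stopf("missing tRNA-fraction signal for sample(s): %s",
           paste(setdiff(target$sample_id, trna_c14$sample_id),
                 collapse = ", "))
  }
  denom <- trna_c14$signal[match(target$sample_id, trna_c14$sample_id)]
  if (any(denom <= 0)) {
    .stopf("tRNA-fraction signal must be > 0")
  }
  ratio <- target$intensity / denom
  steady <- target$sample_id %in% steady_ids
  if (!any(steady)) .stopf("no steady-state reference samples")
  data.frame(
    sample_id = target$sample_id,
    time = target$time,
    value = ratio / mean(ratio[steady]),
    n_steady = sum(steady),
    stringsAsFactors = FALSE
  )
}

#' tRNA/rRNA abundance ratio relative to steady state
#'
#' @param trna_level,rrna_level data.frames with \code{sample_id} and
#'   \code{value} columns (steady-state-relative levels of a tRNA and an
#'   rRNA series over the same samples).
#' @return data.frame (\code{sample_id}, \code{time} if present,
#'   \code{ratio}); equals 1 at steady state by construction.
#' @export
trnaRrnaRatio <- function(trna_level, rrna_level) {
  if (!all(trna_level$sample_id %in% rrna_level$sample_id)) {
    .stopf("rRNA series lacks sample(s): %s",
           paste(setdiff(trna_level$sample_id, rrna_level$sample_id),
                 collapse = ", "))
  }
  i <- match(trna_level$sample_id, rrna_level$sample_id)
  if (any(rrna_level$value[i] == 0)) {
    .stopf("rRNA level is 0; ratio undefined")
  }
  out <- data.frame(sample_id = trna_level$sample_id,
                    stringsAsFactors = FALSE)
  if ("time" %in% names(trna_level)) out$time <- trna_level$time
  out$ratio <- trna_level$value / rrna_level$value[i]
  out
}

#' Welch's unequal-variance t test
#'
#' Two-tailed Student's t test assuming unequal variances, as used to compare
#' each post-perturbation time point against the pooled steady-state samples.
#'
#' @param sample_values numeric vector (>= 2 values).
#' @param steady_values numeric vector (>= 2 values).
#' @return list with \code{t}, \code{df} (Welch-Satterthwaite) and the
#'   two-tailed \code{p_value}.
#' @export
welchTTest <- function(sample_values, steady_values) {
  if (length(sample_values) < 2 || length(steady_values) < 2) {
    .stopf("each group needs at least 2 values")
  }
  res <- stats::t.test(sample_values, steady_values, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}
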