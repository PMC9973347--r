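#' Run a scenario end to end
#'
#' Simulates the full experiment deterministically under the scenario seed:
#' ground-truth tables, dual-isotope scintillation records (TCA, NaOH, whole
#' extract and PAGE bands for every extraction method and replicate) and
#' northern-blot lanes for every probe, including steady-state reference
#' lanes and, for the spike-in route, a spike-only lane per blot. Every
#' observation table is directly consumable by the quantification functions.
#'
#' @param scenario a \code{\linkS4class{Scenario}}.
#' @return a \code{\linkS4class{ScenarioRun}}.
#' @examples
#' run <- runScenario(buildScenario("rifampicin", seed = 1))
#' head(run@dpm)
#' @export
runScenario <- function(scenario) {
  stopifnot(is(scenario, "Scenario"))
  validObject(scenario)
  .withSeed(scenario@seed, .runScenarioInner(scenario))
}

# minutes conversion for maturation kinetics (k_mod is per minute)
.toMinutes <- function(t, time_unit) if (time_unit == "h") t * 60 else t

.runScenarioInner <- function(scenario) {
  reg <- scenario@registry
  trajs <- scenario@trajectories
  nz <- scenario@noise
  steady_ids <- paste0("st", seq_len(scenario@steady_sample_count))
  time_ids <- paste0("t", scenario@timepoints)
  samples <- data.frame(
    sample_id = c(steady_ids, time_ids),
    time = c(rep(0, length(steady_ids)), scenario@timepoints),
    is_steady = c(rep(TRUE, length(steady_ids)),
                  rep(FALSE, length(time_ids))),
    stringsAsFactors = FALSE
  )

  truth <- .truthTable(scenario)

  # populations are deterministic; noise enters only at the counting step
  spike_pop <- makePopulation(reg, trajs, t = 0, channel = "H3",
                              state = "steady",
                              total_dpm = scenario@spike_dpm)
  pops <- lapply(seq_len(nrow(samples)), function(i) {
    makePopulation(reg, trajs, t = samples$time[i], channel = "C14",
                   state = if (samples$is_steady[i]) "steady" else "perturbed",
                   total_dpm = scenario@sample_dpm)
  })

  dpm <- do.call(rbind, lapply(seq_len(scenario@n_replicates), function(rep_i) {
    do.call(rbind, lapply(scenario@methods, function(method) {
      do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
        sid <- samples$sample_id[i]
        pop <- pops[[i]]
        total <- tcaPrecipitate(pop, spike_pop, reg, sample_id = sid)
        naoh <- naohThenTca(pop, spike_pop, reg, sample_id = sid)
        ext <- extractRNA(pop, spike_pop, method, reg)
        whole <- data.frame(sample_id = sid, time = pop@time,
                            fraction = "extract",
                            dpm_c14 = sum(ext$c14), dpm_h3 = sum(ext$h3),
                            stringsAsFactors = FALSE)
        bands <- pageBandCounts(ext, reg, sample_id = sid)
        rec <- rbind(total, naoh, whole, bands)
        rec$dpm_c14 <- countLsc(rec$dpm_c14, nz$counting)
        rec$dpm_h3 <- countLsc(rec$dpm_h3, nz$counting)
        cbind(method = method@name, replicate = rep_i, rec,
              stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(dpm) <- NULL

  northern <- .simulateNorthern(scenario, samples)

  manifest <- list(
    scenario = scenario@name,
    seed = scenario@seed,
    package = "spikeQuant",
    version = as.character(utils::packageVersion("spikeQuant")),
    time_unit = scenario@time_unit,
    normalization = scenario@normalization,
    northern_method = scenario@northern_method,
    synthesis_on = scenario@synthesis_on,
    noise = nz,
    n_replicates = scenario@n_replicates,
    steady_sample_count = scenario@steady_sample_count,
    uncalibrated = scenario@uncalibrated,
    timestamp = format(Sys.time(), tz = "UTC")
  )

  new("ScenarioRun", scenario = scenario, truth = truth, samples = samples,
      dpm = dpm, northern_bands = northern$bands,
      northern_lanes = northern$lanes, manifest = manifest)
}

# ground truth per species and time, masses as fractions of the t = 0 labeled
# RNA of the sample culture; pool species carry the mass bookkeeping, named
# tRNAs carry fold and hypomodification
.truthTable <- function(scenario) {
  reg <- scenario@registry
  times <- c(0, scenario@timepoints)
  sp <- reg@species
  mem <- reg@trna_members
  trna_mf <- sp$mass_fraction[sp$rna_class == "tRNA"]
  rows <- list()
  for (i in seq_len(nrow(sp))) {
    tr <- .trajFor(scenario@trajectories, sp$name[i])
    f <- intactFold(tr, times)
    degraded <- sp$mass_fraction[i] * pmax(0, 1 - f)
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp$name[i], is_pool = TRUE, time = times, intact_fold = f,
      intact_mass = sp$mass_fraction[i] * f,
      tca_fragments = (1 - tr@f_sol) * degraded,
      acid_soluble = tr@f_sol * degraded,
      hypomod_fraction = hypomodFraction(
        tr, .toMinutes(times, scenario@time_unit), scenario@synthesis_on),
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(mem))) {
    tr <- .trajFor(scenario@trajectories, mem$name[i])
    f <- intactFold(tr, times)
    rows[[length(rows) + 1L]] <- data.frame(
      species = mem$name[i], is_pool = FALSE, time = times, intact_fold = f,
      intact_mass = trna_mf * mem$pool_share[i] * f,
      tca_fragments = NA_real_, acid_soluble = NA_real_,
      hypomod_fraction = hypomodFraction(
        tr, .toMinutes(times, scenario@time_unit), scenario@synthesis_on),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-member extracted amounts (a.u.) of the sample culture at time t
.memberExtracted <- function(scenario, method, t, steady) {
  reg <- scenario@registry
  mem <- reg@trna_members
  sp <- reg@species
  trna_mf <- sp$mass_fraction[sp$rna_class == "tRNA"]
  scale <- scenario@sample_dpm * (1 - reg@dna_fraction) * trna_mf
  t_eff <- if (steady) 0 else t
  state <- if (steady) "steady" else "perturbed"
  folds <- vapply(mem$name, function(nm) {
    intactFold(.trajFor(scenario@trajectories, nm), t_eff)
  }, numeric(1))
  g <- .stateFactorSpecies(method, t_eff, state, mem$length_nt)
  amounts <- scale * mem$pool_share * folds * method@e0 *
    sizeBiasS(method, mem$length_nt) * g
  names(amounts) <- mem$name
  amounts
}

.simulateNorthern <- function(scenario, samples) {
  reg <- scenario@registry
  nz <- scenario@noise
  method <- scenario@methods[[
    match(scenario@northern_method,
          vapply(scenario@methods, function(m) m@name, character(1)))]]
  mem <- reg@trna_members
  selc_route <- scenario@normalization == "selc"
  spike_extracted <- if (selc_route) {
    raw <- spikeCellAmounts(reg, scenario@spike_mass,
                            scenario@spike_endog_frac)
    raw * method@e0 * sizeBiasS(method, mem$length_nt[match(names(raw),
                                                            mem$name)])
  } else {
    setNames(numeric(nrow(mem)), mem$name)
  }
  # extracted sample amounts depend only on the sample, not the probe or
  # replicate; precompute them once per sample
  amounts_by_sample <- lapply(seq_len(nrow(samples)), function(i) {
    .memberExtracted(scenario, method, samples$time[i], samples$is_steady[i])
  })
  bands <- list()
  lanes <- list()
  for (rep_i in seq_len(scenario@n_replicates)) {
    for (pb in scenario@probes) {
      pid <- paste(pb@target, pb@region, sep = ".")
      tr_target <- .trajFor(scenario@trajectories, pb@target)
      for (i in seq_len(nrow(samples))) {
        sid <- samples$sample_id[i]
        steady <- samples$is_steady[i]
        t <- samples$time[i]
        lane_id <- sprintf("r%d.%s.%s", rep_i, pid, sid)
        amounts <- amounts_by_sample[[i]]
        h <- if (steady) tr_target@h0 else {
          hypomodFraction(tr_target, .toMinutes(t, scenario@time_unit),
                          scenario@synthesis_on)
        }
        load <- .lognormFactor(1, nz$load_cv)
        lane <- northernLane(amounts, pb, spike_extracted, load = load,
                             hypo_fraction = h,
                             noise_cv = nz$densitometry_cv,
                             lane_id = lane_id)
        if (!selc_route) {
          # phosphorimaged 14C signal of the whole tRNA fraction of this lane
          lane <- lane[lane$band != "selC", , drop = FALSE]
          lane <- rbind(lane, data.frame(
            lane_id = lane_id, band = "tRNA_c14",
            intensity = load * sum(amounts) *
              .lognormFactor(1, nz$densitometry_cv),
            stringsAsFactors = FALSE))
        }
        bands[[length(bands) + 1L]] <- cbind(replicate = rep_i,
                                             probe_id = pid, lane,
                                             stringsAsFactors = FALSE)
        lanes[[length(lanes) + 1L]] <- data.frame(
          replicate = rep_i, probe_id = pid, lane_id = lane_id,
          sample_id = sid, time = t, is_spike_only = FALSE,
          stringsAsFactors = FALSE)
      }
      if (selc_route) {
        lane_id <- sprintf("r%d.%s.spike_only", rep_i, pid)
        load <- .lognormFactor(1, nz$load_cv)
        lane <- spikeOnlyLane(spike_extracted, pb, load = load,
                              noise_cv = nz$densitometry_cv,
                              lane_id = lane_id)
        bands[[length(bands) + 1L]] <- cbind(replicate = rep_i,
                                             probe_id = pid, lane,
                                             stringsAsFactors = FALSE)
        lanes[[length(lanes) + 1L]] <- data.frame(
          replicate = rep_i, probe_id = pid, lane_id = lane_id,
          sample_id = "spike_only", time = NA_real_, is_spike_only = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  bands <- do.call(rbind, bands)
  lanes <- do.call(rbind, lanes)
  rownames(bands) <- rownames(lanes) <- NULL
  list(bands = bands, lanes = lanes)
}

setMethod("show", "ScenarioRun", function(object) {
  cat(sprintf("ScenarioRun '%s' (seed %g): %d dpm records, %d northern band records\n",
              object@scenario@name, object@scenario@seed, nrow(object@dpm),
              nrow(object@northern_bands)))
})

#' Quantify a simulated run
#'
#' Applies the full quantification pipeline to the observation tables of a
#' \code{\linkS4class{ScenarioRun}}: DNA subtraction and extraction
#' efficiency, steady-state-relative recovery of the TCA, whole-extract and
#' band records per method, northern normalization per probe (spike-in selC
#' route with endogenous correction, or the 14C tRNA-fraction route for
#' radiolabeled samples), tRNA/rRNA ratios, and Welch t statistics of each
#' time point against the pooled steady samples.
#'
#' @param run a \code{\linkS4class{ScenarioRun}}.
#' @param steady_ids steady reference sample ids; defaults to the run's
#'   steady samples.
#' @param p_adjust \code{"none"} (default) or \code{"bonferroni"}; see
#'   \code{\link{quantifyTables}}.
#' @return list of data.frames: \code{efficiency} (per method/replicate/
#'   sample), \code{efficiency_summary} (steady-state mean per method),
#'   \code{recovery} (mean/sd/n per method, series and time),
#'   \code{recovery_repl} (per-replicate values), \code{northern} (mean/sd/n
#'   and Welch p per probe and time), \code{northern_repl}, \code{ratios}
#'   (tRNA band over each rRNA band, per method and time).
#' @export
quantifyRun <- function(run, steady_ids = NULL,
                        p_adjust = c("none", "bonferroni")) {
  stopifnot(is(run, "ScenarioRun"))
  tables <- list(samples = run@samples, dpm = run@dpm,
                 northern_bands = run@northern_bands,
                 northern_lanes = run@northern_lanes,
                 manifest = run@manifest)
  quantifyTables(tables, steady_ids = steady_ids, p_adjust = p_adjust)
}

#' Quantify from observation tables
#'
#' The table-level work-horse behind \code{\link{quantifyRun}} and the
#' command-line \code{quantify} verb; operates purely on the delimited-text
#' table set written by \code{\link{writeScenarioRun}}.
#'
#' @param tables list with \code{samples}, \code{dpm}, \code{northern_bands},
#'   \code{northern_lanes} data.frames and the run \code{manifest} list.
#' @param steady_ids steady reference sample ids; defaults to the sample
#'   table's \code{is_steady} flags.
#' @param p_adjust multiple-testing correction of the per-time Welch p values
#'   within each probe series: \code{"none"} (default, mirroring routine
#'   practice) or \code{"bonferroni"}.
#' @return see \code{\link{quantifyRun}}.
#' @export
quantifyTables <- function(tables, steady_ids = NULL,
                           p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  samples <- tables$samples
  dpm <- tables$dpm
  manifest <- tables$manifest
  noise <- if (identical(manifest$noise$counting, "poisson")) {
    "poisson"
  } else {
    "none"
  }
  if (is.null(steady_ids)) {
    steady_ids <- samples$sample_id[samples$is_steady]
  }
  if (!length(steady_ids)) .stopf("no steady-state reference samples")

  eff_rows <- list()
  rec_rows <- list()
  for (m in unique(dpm$method)) {
    for (r in unique(dpm$replicate)) {
      sub <- dpm[dpm$method == m & dpm$replicate == r, , drop = FALSE]
      total <- sub[sub$fraction == "total_tca", , drop = FALSE]
      naoh <- sub[sub$fraction == "naoh_tca", , drop = FALSE]
      extract <- sub[sub$fraction == "extract", , drop = FALSE]
      rna <- subtractDna(total, naoh, noise = noise)
      i <- match(rna$sample_id, extract$sample_id)
      eff <- extractionEfficiency(extract$dpm_c14[i], rna$dpm_c14)
      eff_rows[[length(eff_rows) + 1L]] <- data.frame(
        method = m, replicate = r, sample_id = rna$sample_id,
        time = rna$time, efficiency = eff, stringsAsFactors = FALSE)
      series <- list(tca_rna = rna, extract = extract)
      for (b in unique(sub$fraction[startsWith(sub$fraction, "band:")])) {
        series[[b]] <- sub[sub$fraction == b, , drop = FALSE]
      }
      for (s in names(series)) {
        rl <- relativeRecovery(series[[s]], steady_ids)
        rec_rows[[length(rec_rows) + 1L]] <- cbind(
          method = m, replicate = r, series = s, rl,
          stringsAsFactors = FALSE)
      }
    }
  }
  efficiency <- do.call(rbind, eff_rows)
  recovery_repl <- do.call(rbind, rec_rows)
  rownames(efficiency) <- rownames(recovery_repl) <- NULL

  steady_eff <- efficiency[efficiency$sample_id %in% steady_ids, ,
                           drop = FALSE]
  efficiency_summary <- stats::aggregate(
    efficiency ~ method, data = steady_eff, FUN = mean)
  names(efficiency_summary)[2] <- "steady_efficiency"

  recovery <- .aggregateValues(recovery_repl, c("method", "series", "time"))

  northern_repl <- .normalizeNorthern(tables, steady_ids)
  northern <- NULL
  stats_tab <- NULL
  if (!is.null(northern_repl)) {
    northern <- .aggregateValues(northern_repl, c("probe_id", "time"))
    stats_tab <- .welchByTime(northern_repl, steady_ids)
    if (p_adjust == "bonferroni") {
      for (pid in unique(stats_tab$probe_id)) {
        sel <- stats_tab$probe_id == pid
        stats_tab$p_value[sel] <- stats::p.adjust(stats_tab$p_value[sel],
                                                  method = "bonferroni")
      }
    }
    northern <- merge(northern, stats_tab, by = c("probe_id", "time"),
                      all.x = TRUE, sort = FALSE)
    northern <- northern[order(northern$probe_id, northern$time), ,
                         drop = FALSE]
    rownames(northern) <- NULL
  }

  ratios <- .bandRatios(recovery_repl)

  list(efficiency = efficiency, efficiency_summary = efficiency_summary,
       recovery = recovery, recovery_repl = recovery_repl,
       northern = northern, northern_repl = northern_repl, ratios = ratios)
}

.aggregateValues <- function(df, by) {
  agg <- stats::aggregate(df$value, by = df[by], FUN = function(v) {
    c(mean = mean(v), sd = stats::sd(v), n = length(v))
  })
  out <- cbind(agg[by], as.data.frame(agg$x))
  names(out)[names(out) == "mean"] <- "value"
  out <- out[do.call(order, unname(out[by])), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# northern normalization dispatched on the manifest's route
.normalizeNorthern <- function(tables, steady_ids) {
  bands <- tables$northern_bands
  lanes <- tables$northern_lanes
  manifest <- tables$manifest
  if (is.null(bands) || nrow(bands) == 0) return(NULL)
  cv <- manifest$noise$densitometry_cv %||% 0
  out <- list()
  for (pid in unique(bands$probe_id)) {
    for (r in unique(bands$replicate)) {
      b <- bands[bands$probe_id == pid & bands$replicate == r, , drop = FALSE]
      l <- lanes[lanes$probe_id == pid & lanes$replicate == r, , drop = FALSE]
      if (identical(manifest$normalization, "selc")) {
        res <- northernNormalize(b[, c("lane_id", "band", "intensity")],
                                 l[, c("lane_id", "sample_id", "time",
                                       "is_spike_only")],
                                 steady_ids, noise_cv = cv)
        res <- res[, c("sample_id", "time", "value", "n_steady")]
      } else {
        target <- setdiff(unique(b$band), c("selC", "tRNA_c14"))
        tgt <- b[b$band == target, , drop = FALSE]
        den <- b[b$band == "tRNA_c14", , drop = FALSE]
        li <- match(tgt$lane_id, l$lane_id)
        target_df <- data.frame(sample_id = l$sample_id[li],
                                time = l$time[li],
                                intensity = tgt$intensity,
                                stringsAsFactors = FALSE)
        den_df <- data.frame(
          sample_id = l$sample_id[match(den$lane_id, l$lane_id)],
          signal = den$intensity, stringsAsFactors = FALSE)
        res <- radiolabelLaneNormalize(target_df, den_df, steady_ids)
      }
      out[[length(out) + 1L]] <- cbind(probe_id = pid, replicate = r, res,
                                       stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Welch t test of every post-perturbation time point against the pooled
# steady samples; NA where variance is degenerate (noiseless runs)
.welchByTime <- function(repl, steady_ids) {
  out <- list()
  for (pid in unique(repl$probe_id)) {
    sub <- repl[repl$probe_id == pid, , drop = FALSE]
    steady_vals <- sub$value[sub$sample_id %in% steady_ids]
    for (t in unique(sub$time[!sub$sample_id %in% steady_ids])) {
      vals <- sub$value[sub$time == t & !sub$sample_id %in% steady_ids]
      res <- if (length(vals) >= 2 && length(steady_vals) >= 2 &&
                 (stats::sd(vals) > 0 || stats::sd(steady_vals) > 0)) {
        tryCatch(welchTTest(vals, steady_vals),
                 error = function(e) list(t = NA_real_, df = NA_real_,
                                          p_value = NA_real_))
      } else {
        list(t = NA_real_, df = NA_real_, p_value = NA_real_)
      }
      out[[length(out) + 1L]] <- data.frame(
        probe_id = pid, time = t, t_statistic = res$t, df = res$df,
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# tRNA band over each rRNA band, steady-state-relative, per method
.bandRatios <- function(recovery_repl) {
  out <- list()
  for (m in unique(recovery_repl$method)) {
    for (r in unique(recovery_repl$replicate)) {
      sub <- recovery_repl[recovery_repl$method == m &
                             recovery_repl$replicate == r, , drop = FALSE]
      trna <- sub[sub$series == "band:tRNA", , drop = FALSE]
      if (nrow(trna) == 0) next
      for (rr in intersect(c("band:23S", "band:16S", "band:5S"),
                           unique(sub$series))) {
        rrna <- sub[sub$series == rr, , drop = FALSE]
        rat <- trnaRrnaRatio(trna, rrna)
        out[[length(out) + 1L]] <- data.frame(
          method = m, replicate = r, rrna = sub("band:", "", rr),
          sample_id = rat$sample_id, time = rat$time, ratio = rat$ratio,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  repl <- do.call(rbind, out)
  agg <- stats::aggregate(repl$ratio, by = repl[c("method", "rrna", "time")],
                          FUN = mean)
  names(agg)[4] <- "ratio"
  agg <- agg[order(agg$method, agg$rrna, agg$time), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
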