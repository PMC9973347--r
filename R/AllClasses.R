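#' @import methods
NULL

.RNA_CLASSES <- c("rRNA", "tRNA", "other")
.PROBE_REGIONS <- c("anticodon", "five_prime", "three_prime", "anticodon_alt")

.SPECIES_COLS <- c("name", "rna_class", "length_nt", "mass_fraction",
                   "acp3u_in_anticodon_region", "is_spike_marker")
.MEMBER_COLS <- c("name", "length_nt", "pool_share",
                  "acp3u_in_anticodon_region", "is_spike_marker")

#' Registry of RNA species
#'
#' A \code{Registry} holds the bookkeeping units of every simulation and every
#' quantification: the major, electrophoretically resolvable RNA species of a
#' bacterial cell (23S, 16S and 5S rRNA, the pooled tRNA fraction, and a pooled
#' "other" non-coding fraction), the named tRNAs that subdivide the tRNA pool
#' (each with its own length, modification flag and, for tRNA-selC, the
#' spike-marker role), and the fraction of incorporated, TCA-precipitable label
#' that resides in DNA rather than RNA.
#'
#' @slot species data.frame of pool-level species with columns \code{name},
#'   \code{rna_class} (one of rRNA/tRNA/other), \code{length_nt},
#'   \code{mass_fraction} (fractions sum to 1), \code{acp3u_in_anticodon_region}
#'   and \code{is_spike_marker}.
#' @slot trna_members data.frame of named tRNAs subdividing the tRNA pool, with
#'   columns \code{name}, \code{length_nt}, \code{pool_share} (shares sum to 1),
#'   \code{acp3u_in_anticodon_region} and \code{is_spike_marker}.
#' @slot dna_fraction fraction of total TCA-precipitable label in DNA,
#'   in [0, 0.5).
#' @seealso \code{\link{defaultRegistry}}, \code{\link{loadRegistry}}
#' @exportClass Registry
setClass("Registry",
  representation(
    species = "data.frame",
    trna_members = "data.frame",
    dna_fraction = "numeric"
  )
)

.validRegistry <- function(object) {
  sp <- object@species
  mem <- object@trna_members
  msgs <- character()
  missing_sp <- setdiff(.SPECIES_COLS, names(sp))
  if (length(missing_sp)) {
    return(sprintf("species table lacks column(s): %s",
                   paste(missing_sp, collapse = ", ")))
  }
  if (nrow(mem) > 0) {
    missing_mem <- setdiff(.MEMBER_COLS, names(mem))
    if (length(missing_mem)) {
      return(sprintf("trna_members table lacks column(s): %s",
                     paste(missing_mem, collapse = ", ")))
    }
  }
  if (!all(sp$rna_class %in% .RNA_CLASSES)) {
    msgs <- c(msgs, sprintf("rna_class must be one of %s",
                            paste(.RNA_CLASSES, collapse = "/")))
  }
  if (any(sp$length_nt <= 0) || (nrow(mem) > 0 && any(mem$length_nt <= 0))) {
    msgs <- c(msgs, "length_nt must be positive")
  }
  if (any(sp$mass_fraction < 0) || any(sp$mass_fraction > 1)) {
    msgs <- c(msgs, "mass_fraction must lie in [0, 1]")
  }
  if (abs(sum(sp$mass_fraction) - 1) > 1e-9) {
    msgs <- c(msgs, sprintf(
      "species mass fractions must sum to 1 (got %.12g)", sum(sp$mass_fraction)))
  }
  all_names <- c(sp$name, if (nrow(mem) > 0) mem$name)
  if (anyDuplicated(all_names)) {
    msgs <- c(msgs, sprintf("duplicate species name(s): %s",
                            paste(unique(all_names[duplicated(all_names)]),
                                  collapse = ", ")))
  }
  n_spike <- sum(sp$is_spike_marker) + if (nrow(mem) > 0) sum(mem$is_spike_marker) else 0L
  if (n_spike > 1) {
    msgs <- c(msgs, "at most one species may be the spike marker")
  }
  if (nrow(mem) > 0) {
    if (sum(sp$rna_class == "tRNA") != 1L) {
      msgs <- c(msgs, "tRNA members require exactly one tRNA pool species")
    }
    if (abs(sum(mem$pool_share) - 1) > 1e-9) {
      msgs <- c(msgs, sprintf("tRNA pool shares must sum to 1 (got %.12g)",
                              sum(mem$pool_share)))
    }
    if (any(mem$pool_share < 0)) {
      msgs <- c(msgs, "pool_share must be non-negative")
    }
  }
  if (!.is_number(object@dna_fraction) ||
      object@dna_fraction < 0 || object@dna_fraction >= 0.5) {
    msgs <- c(msgs, "dna_fraction must lie in [0, 0.5)")
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("Registry", .validRegistry)

#' Ground-truth abundance trajectory of one RNA species
#'
#' A \code{TruthTrajectory} parameterizes what actually happens to the labeled
#' pool of one species during a perturbation: the fold-change of the intact
#' species relative to time zero, how the degraded mass partitions between
#' TCA-precipitable fragments and acid-soluble oligomers, and the kinetics of
#' the hypomodified (newly synthesized, not yet fully modified) sub-pool.
#'
#' The default intact-fold form is geometric interpolation,
#' \eqn{F(t) = a^{t/T}} with anchor fold \eqn{a} at anchor time \eqn{T}, which
#' is monotone and hits \eqn{F(0)=1} and \eqn{F(T)=a} exactly. Supplying a
#' \code{points} table (columns \code{time}, \code{fold}) switches the species
#' to piecewise-linear interpolation through those anchors, held constant
#' beyond the last anchor; this expresses transient dips and plateaus.
#'
#' @slot species species name.
#' @slot anchor_fold intact fold at \code{anchor_time} relative to t = 0.
#' @slot anchor_time anchor time (same unit as the scenario clock).
#' @slot f_sol fraction of degraded mass rendered acid-soluble.
#' @slot h0 hypomodified fraction during steady-state growth, in [0, 1).
#' @slot k_mod maturation rate of hypomodified tRNA (per minute).
#' @slot points optional piecewise-linear anchors (data.frame time/fold).
#' @seealso \code{\link{intactFold}}, \code{\link{degradedPartition}},
#'   \code{\link{hypomodFraction}}
#' @exportClass TruthTrajectory
setClass("TruthTrajectory",
  representation(
    species = "character",
    anchor_fold = "numeric",
    anchor_time = "numeric",
    f_sol = "numeric",
    h0 = "numeric",
    k_mod = "numeric",
    points = "data.frame"
  )
)

setValidity("TruthTrajectory", function(object) {
  msgs <- character()
  if (length(object@species) != 1L || !nzchar(object@species)) {
    msgs <- c(msgs, "species must be a single non-empty name")
  }
  if (!.is_number(object@anchor_fold) || object@anchor_fold < 0) {
    msgs <- c(msgs, "anchor_fold must be >= 0")
  }
  if (!.is_number(object@anchor_time) || object@anchor_time <= 0) {
    msgs <- c(msgs, "anchor_time must be > 0")
  }
  if (!.is_number(object@f_sol) || object@f_sol < 0 || object@f_sol > 1) {
    msgs <- c(msgs, "f_sol must lie in [0, 1]")
  }
  if (!.is_number(object@h0) || object@h0 < 0 || object@h0 >= 1) {
    msgs <- c(msgs, "h0 must lie in [0, 1)")
  }
  if (!.is_number(object@k_mod) || object@k_mod < 0) {
    msgs <- c(msgs, "k_mod must be >= 0")
  }
  pts <- object@points
  if (nrow(pts) > 0) {
    if (!all(c("time", "fold") %in% names(pts))) {
      msgs <- c(msgs, "points must have columns time and fold")
    } else {
      if (is.unsorted(pts$time, strictly = TRUE)) {
        msgs <- c(msgs, "points times must be strictly increasing")
      }
      if (any(pts$fold < 0)) {
        msgs <- c(msgs, "points folds must be >= 0")
      }
      if (pts$time[1] != 0 || pts$fold[1] != 1) {
        msgs <- c(msgs, "points must start at (time = 0, fold = 1)")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Radiolabeled cell population
#'
#' A \code{Population} carries the per-species labeled amounts (in
#' dpm-equivalents) of one culture on one isotope channel, split into intact
#' species, TCA-precipitable degradation fragments, acid-soluble degradation
#' products, and the alkali-stable DNA component. Steady-state populations
#' (the \eqn{[^3H]} spike culture, and pre-perturbation reference samples) have
#' time-invariant amounts and no degradation products.
#'
#' @slot channel isotope channel, \code{"C14"} or \code{"H3"}.
#' @slot state \code{"steady"} or \code{"perturbed"}.
#' @slot time sampling time (scenario clock; 0 for steady populations).
#' @slot intact named vector of intact labeled amounts per pool species.
#' @slot tca_fragments named vector of TCA-precipitable fragment label.
#' @slot acid_soluble named vector of acid-soluble degradation label.
#' @slot dna labeled DNA amount (alkali-stable).
#' @slot signature registry fingerprint used to reject cross-registry mixes.
#' @exportClass Population
setClass("Population",
  representation(
    channel = "character",
    state = "character",
    time = "numeric",
    intact = "numeric",
    tca_fragments = "numeric",
    acid_soluble = "numeric",
    dna = "numeric",
    signature = "character"
  )
)

setValidity("Population", function(object) {
  msgs <- character()
  if (!object@channel %in% c("C14", "H3")) {
    msgs <- c(msgs, "channel must be C14 or H3")
  }
  if (!object@state %in% c("steady", "perturbed")) {
    msgs <- c(msgs, "state must be steady or perturbed")
  }
  amounts <- c(object@intact, object@tca_fragments, object@acid_soluble,
               object@dna)
  if (any(!is.finite(amounts)) || any(amounts < 0)) {
    msgs <- c(msgs, "all labeled amounts must be finite and >= 0")
  }
  if (object@state == "steady" &&
      (sum(object@tca_fragments) > 0 || sum(object@acid_soluble) > 0)) {
    msgs <- c(msgs, "steady populations carry no degradation products")
  }
  if (length(msgs)) msgs else TRUE
})

#' RNA extraction method with size and growth-state bias
#'
#' An \code{ExtractionMethod} models the per-species recovery of an RNA
#' purification protocol as the product of a base efficiency \eqn{e_0}, a
#' logistic size-bias curve
#' \eqn{s(L) = floor + (1-floor)/(1+\exp((L-L_{50})/w))}, and a growth-state
#' factor \eqn{g(t) = p + (1-p)\exp(-kt)} that penalizes material from
#' perturbed (starved or drug-treated) cells but never the steady-state spike
#' cells. Degradation fragments are recovered at rate \code{fragment_recovery}
#' (0 in all shipped presets: fragments are TCA-precipitable in the lysate but
#' lost during purification).
#'
#' @slot name method identifier.
#' @slot e0 base extraction efficiency, in (0, 1].
#' @slot l50,width,floor logistic size-bias parameters (midpoint nt, width nt,
#'   large-size floor); \code{floor = 1} disables the size bias.
#' @slot state_plateau,state_rate growth-state factor parameters p and k.
#' @slot state_min_length state factor applies only to species at least this
#'   long (TRI Reagent spares short tRNAs).
#' @slot fragment_recovery recovery rate of degradation fragments, in [0, 1].
#' @seealso \code{\link{extractionPreset}}, \code{\link{sizeBiasS}},
#'   \code{\link{stateFactorG}}, \code{\link{extractRNA}}
#' @exportClass ExtractionMethod
setClass("ExtractionMethod",
  representation(
    name = "character",
    e0 = "numeric",
    l50 = "numeric",
    width = "numeric",
    floor = "numeric",
    state_plateau = "numeric",
    state_rate = "numeric",
    state_min_length = "numeric",
    fragment_recovery = "numeric"
  )
)

setValidity("ExtractionMethod", function(object) {
  msgs <- character()
  if (!.is_number(object@e0) || object@e0 <= 0 || object@e0 > 1) {
    msgs <- c(msgs, "e0 must lie in (0, 1]")
  }
  if (!.is_number(object@l50) || object@l50 <= 0) {
    msgs <- c(msgs, "l50 must be > 0")
  }
  if (!.is_number(object@width) || object@width <= 0) {
    msgs <- c(msgs, "width must be > 0")
  }
  if (!.is_number(object@floor) || object@floor < 0 || object@floor > 1) {
    msgs <- c(msgs, "floor must lie in [0, 1]")
  }
  if (!.is_number(object@state_plateau) ||
      object@state_plateau <= 0 || object@state_plateau > 1) {
    msgs <- c(msgs, "state_plateau must lie in (0, 1]")
  }
  if (!.is_number(object@state_rate) || object@state_rate < 0) {
    msgs <- c(msgs, "state_rate must be >= 0")
  }
  if (!.is_number(object@state_min_length) || object@state_min_length < 0) {
    msgs <- c(msgs, "state_min_length must be >= 0")
  }
  if (!.is_number(object@fragment_recovery) ||
      object@fragment_recovery < 0 || object@fragment_recovery > 1) {
    msgs <- c(msgs, "fragment_recovery must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Northern-blot oligonucleotide probe
#'
#' A \code{Probe} targets one tRNA species at one of four regions. Probes
#' against the anticodon region of a tRNA carrying the bulky acp3U modification
#' hybridize more strongly to the hypomodified (not yet modified) form than to
#' the mature form; probes on unmodified regions, or on targets without the
#' modification, see both forms identically.
#'
#' @slot target species name of the target tRNA.
#' @slot region one of \code{anticodon}, \code{five_prime}, \code{three_prime},
#'   \code{anticodon_alt}.
#' @slot affinity_mature,affinity_hypo signal per unit of mature and of
#'   hypomodified target (arbitrary units, > 0).
#' @seealso \code{\link{probeFor}}, \code{\link{northernLane}}
#' @exportClass Probe
setClass("Probe",
  representation(
    target = "character",
    region = "character",
    affinity_mature = "numeric",
    affinity_hypo = "numeric"
  )
)

setValidity("Probe", function(object) {
  msgs <- character()
  if (!object@region %in% .PROBE_REGIONS) {
    msgs <- c(msgs, sprintf("region must be one of %s",
                            paste(.PROBE_REGIONS, collapse = "/")))
  }
  if (!.is_number(object@affinity_mature) || object@affinity_mature <= 0 ||
      !.is_number(object@affinity_hypo) || object@affinity_hypo <= 0) {
    msgs <- c(msgs, "probe affinities must be > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' In-silico experiment description
#'
#' A \code{Scenario} bundles everything needed to simulate one figure-style
#' experiment deterministically: the registry, the ground-truth trajectories of
#' every species, the sampling schedule (steady-state reference samples plus a
#' perturbation time course), the extraction methods applied, the northern
#' probe set and normalization route, the noise configuration and the seed.
#'
#' @slot name scenario identifier.
#' @slot time_unit \code{"min"} (short-term) or \code{"h"} (long-term).
#' @slot timepoints strictly increasing post-perturbation sampling times.
#' @slot steady_sample_count number of steady-state reference samples.
#' @slot n_replicates number of biological replicates simulated.
#' @slot registry the \code{\linkS4class{Registry}} in force.
#' @slot trajectories named list of \code{\linkS4class{TruthTrajectory}};
#'   species without an entry are flat at 1.
#' @slot synthesis_on whether stable-RNA synthesis continues after the
#'   perturbation (TRUE only for relaxed, relA-deficient cells); controls the
#'   depletion of the hypomodified tRNA pool.
#' @slot methods list of \code{\linkS4class{ExtractionMethod}} applied.
#' @slot northern_method name of the method feeding the northern lanes.
#' @slot probes list of \code{\linkS4class{Probe}}.
#' @slot normalization northern normalization route: \code{"selc"} (whole-cell
#'   tRNA-selC spike-in) or \code{"trna_c14"} (per-lane 14C tRNA-fraction
#'   signal of radiolabeled samples).
#' @slot noise list with \code{counting} ("none"/"poisson"),
#'   \code{densitometry_cv} and \code{load_cv}.
#' @slot sample_dpm,spike_dpm total incorporated label (dpm) of the sample and
#'   spike cultures.
#' @slot spike_mass selC amount contributed by spike cells per lane (a.u.).
#' @slot spike_endog_frac endogenous tRNA signal in spike cells as a fraction
#'   of their selC signal.
#' @slot seed integer seed making every run reproducible.
#' @slot uncalibrated character vector of trajectory groups whose anchor values
#'   are order-of-magnitude defaults rather than printed measurements.
#' @seealso \code{\link{buildScenario}}, \code{\link{runScenario}}
#' @exportClass Scenario
setClass("Scenario",
  representation(
    name = "character",
    time_unit = "character",
    timepoints = "numeric",
    steady_sample_count = "numeric",
    n_replicates = "numeric",
    registry = "Registry",
    trajectories = "list",
    synthesis_on = "logical",
    methods = "list",
    northern_method = "character",
    probes = "list",
    normalization = "character",
    noise = "list",
    sample_dpm = "numeric",
    spike_dpm = "numeric",
    spike_mass = "numeric",
    spike_endog_frac = "numeric",
    seed = "numeric",
    uncalibrated = "character"
  )
)

setValidity("Scenario", function(object) {
  msgs <- character()
  if (!object@time_unit %in% c("min", "h")) {
    msgs <- c(msgs, "time_unit must be 'min' or 'h'")
  }
  tp <- object@timepoints
  if (length(tp) == 0 || any(tp <= 0) || is.unsorted(tp, strictly = TRUE)) {
    msgs <- c(msgs, "timepoints must be strictly increasing and positive")
  }
  if (!.is_number(object@steady_sample_count) ||
      object@steady_sample_count < 1) {
    msgs <- c(msgs, "steady_sample_count must be >= 1")
  }
  if (!.is_number(object@n_replicates) || object@n_replicates < 1) {
    msgs <- c(msgs, "n_replicates must be >= 1")
  }
  if (!all(vapply(object@trajectories, is, logical(1), "TruthTrajectory"))) {
    msgs <- c(msgs, "trajectories must be TruthTrajectory objects")
  }
  if (!all(vapply(object@methods, is, logical(1), "ExtractionMethod"))) {
    msgs <- c(msgs, "methods must be ExtractionMethod objects")
  }
  if (!all(vapply(object@probes, is, logical(1), "Probe"))) {
    msgs <- c(msgs, "probes must be Probe objects")
  }
  if (!object@normalization %in% c("selc", "trna_c14")) {
    msgs <- c(msgs, "normalization must be 'selc' or 'trna_c14'")
  }
  nz <- object@noise
  if (!is.list(nz) ||
      !all(c("counting", "densitometry_cv", "load_cv") %in% names(nz))) {
    msgs <- c(msgs, "noise must list counting, densitometry_cv and load_cv")
  } else {
    if (!nz$counting %in% c("none", "poisson")) {
      msgs <- c(msgs, "noise$counting must be 'none' or 'poisson'")
    }
    if (nz$densitometry_cv < 0 || nz$load_cv < 0) {
      msgs <- c(msgs, "noise CVs must be >= 0")
    }
  }
  if (length(object@methods) > 0 &&
      !object@northern_method %in%
        vapply(object@methods, function(m) m@name, character(1))) {
    msgs <- c(msgs, "northern_method must be one of the scenario methods")
  }
  if (length(msgs)) msgs else TRUE
})

#' Simulated experiment bundle
#'
#' The result of \code{\link{runScenario}}: ground-truth tables plus every
#' observation table a wet-lab run of the same design would produce, ready for
#' the quantification pipeline.
#'
#' @slot scenario the \code{\linkS4class{Scenario}} that was run.
#' @slot truth ground-truth per species and time: intact fold, intact mass,
#'   fragment and acid-soluble mass (as fractions of the t = 0 labeled RNA),
#'   hypomodified fraction.
#' @slot samples sample metadata (sample_id, time, is_steady).
#' @slot dpm scintillation records: method, replicate, sample_id, time,
#'   fraction, dpm_c14, dpm_h3.
#' @slot northern_bands densitometry records: replicate, probe_id, lane_id,
#'   band, intensity.
#' @slot northern_lanes lane metadata: replicate, probe_id, lane_id, sample_id,
#'   time, is_spike_only.
#' @slot manifest reproducibility metadata (scenario, seed, version, ...).
#' @exportClass ScenarioRun
setClass("ScenarioRun",
  representation(
    scenario = "Scenario",
    truth = "data.frame",
    samples = "data.frame",
    dpm = "data.frame",
    northern_bands = "data.frame",
    northern_lanes = "data.frame",
    manifest = "list"
  )
)
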