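#' Construct a northern probe for a registry target
#'
#' Affinities follow the modification rule: an \code{anticodon}-region probe
#' on a target carrying acp3U in its anticodon region binds the hypomodified
#' form more strongly (\code{affinity_hypo = hypo_affinity_ratio *
#' affinity_mature}); every other probe/target combination sees mature and
#' hypomodified molecules identically.
#'
#' @param target species name (pool species or named tRNA).
#' @param region probed region: \code{anticodon}, \code{five_prime},
#'   \code{three_prime} or \code{anticodon_alt} (anticodon-adjacent, shifted
#'   off the modification).
#' @param registry a \code{\linkS4class{Registry}} used to look up the
#'   target's modification flag.
#' @param affinity_mature signal per unit mature target (a.u.).
#' @param hypo_affinity_ratio affinity_hypo / affinity_mature applied when the
#'   modification rule triggers (default 2).
#' @return a \code{\linkS4class{Probe}}.
#' @examples
#' reg <- defaultRegistry()
#' probeFor("ileTUV", "anticodon", reg)   # modification-sensitive
#' probeFor("ileTUV", "five_prime", reg)  # equal affinities
#' @export
probeFor <- function(target, region = c("anticodon", "five_prime",
                                        "three_prime", "anticodon_alt"),
                     registry, affinity_mature = 1, hypo_affinity_ratio = 2) {
  region <- match.arg(region)
  stopifnot(is(registry, "Registry"))
  info <- .lookupSpecies(registry, target)
  hypo <- if (region == "anticodon" && info$acp3u) {
    affinity_mature * hypo_affinity_ratio
  } else {
    affinity_mature
  }
  obj <- new("Probe", target = target, region = region,
             affinity_mature = affinity_mature, affinity_hypo = hypo)
  validObject(obj)
  obj
}

setMethod("show", "Probe", function(object) {
  cat(sprintf("Probe %s/%s: affinity mature %.3g, hypomodified %.3g\n",
              object@target, object@region, object@affinity_mature,
              object@affinity_hypo))
})

#' Cut PAGE bands and count them
#'
#' Converts an extract into one scintillation record per visible gel band.
#' rRNA species and the pooled "other" fraction run as their own bands; all
#' individual tRNAs co-migrate and are counted as a single tRNA band. The
#' fragments row of the extract belongs to no band (smear), so with
#' \code{fragment_recovery = 0} the band records sum exactly to the
#' whole-extract counts.
#'
#' @param extract data.frame from \code{\link{extractRNA}}.
#' @param registry the \code{\linkS4class{Registry}}.
#' @param sample_id identifier stamped on the records.
#' @return DpmRecord data.frame with \code{fraction = "band:<species>"} rows.
#' @export
pageBandCounts <- function(extract, registry, sample_id = "sample") {
  stopifnot(is(registry, "Registry"), is.data.frame(extract))
  mem_names <- registry@trna_members$name
  rows <- extract[extract$species != "fragments", , drop = FALSE]
  band <- ifelse(rows$species %in% mem_names, "tRNA", rows$species)
  c14 <- tapply(rows$c14, band, sum)
  h3 <- tapply(rows$h3, band, sum)
  bands <- unique(band)
  data.frame(
    sample_id = sample_id,
    time = attr(extract, "time") %||% NA_real_,
    fraction = paste0("band:", bands),
    dpm_c14 = as.numeric(c14[bands]),
    dpm_h3 = as.numeric(h3[bands]),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Labeled amounts contributed by spike-in cells
#'
#' Whole spike cells overexpress the rare marker tRNA-selC and additionally
#' carry every endogenous tRNA at registry steady-state proportions. The
#' endogenous background is scaled so a typical (average-share) tRNA
#' contributes \code{endog_frac} of the selC amount.
#'
#' @param registry a \code{\linkS4class{Registry}} with a spike marker.
#' @param spike_mass selC amount contributed per lane (a.u.).
#' @param endog_frac endogenous-to-selC amount ratio for an average-share
#'   tRNA (default 0.05).
#' @return named numeric vector of amounts over the named tRNAs.
#' @export
spikeCellAmounts <- function(registry, spike_mass = 1e4, endog_frac = 0.05) {
  stopifnot(is(registry, "Registry"))
  mem <- registry@trna_members
  marker <- spikeMarker(registry)
  if (is.na(marker) || !marker %in% mem$name) {
    .stopf("registry declares no spike-marker tRNA")
  }
  shares <- mem$pool_share
  names(shares) <- mem$name
  endog <- shares / mean(shares[names(shares) != marker])
  amounts <- endog_frac * spike_mass * endog
  amounts[marker] <- spike_mass
  amounts
}

#' Simulate one northern-blot lane
#'
#' The target band signal mixes mature and hypomodified sample molecules at
#' their respective probe affinities and adds the endogenous background from
#' co-extracted spike cells (hybridizing as mature). The selC band reads the
#' spike marker alone. Both bands share the lane's load factor, and carry
#' independent multiplicative log-normal densitometry noise of the given CV.
#'
#' @param sample_amounts named numeric vector of extracted sample amounts per
#'   named tRNA (a.u.); the probe target must be present.
#' @param probe a \code{\linkS4class{Probe}}.
#' @param spike_amounts named numeric vector from
#'   \code{\link{spikeCellAmounts}} (after extraction); use zeros for lanes
#'   without spike cells.
#' @param load dimensionless lane loading factor.
#' @param hypo_fraction hypomodified fraction of the sample target, in [0, 1).
#' @param noise_cv densitometry coefficient of variation (0 = noiseless).
#' @param seed integer seed or \code{NULL} (ambient stream).
#' @param lane_id identifier stamped on the records.
#' @param selc_affinity signal per unit selC (a.u.).
#' @return BandIntensity data.frame with rows for the target band and the
#'   selC band.
#' @export
northernLane <- function(sample_amounts, probe, spike_amounts, load = 1,
                         hypo_fraction = 0, noise_cv = 0, seed = NULL,
                         lane_id = "lane", selc_affinity = 1) {
  stopifnot(is(probe, "Probe"))
  if (!probe@target %in% names(sample_amounts)) {
    .stopf("probe target '%s' absent from sample amounts", probe@target)
  }
  if (hypo_fraction < 0 || hypo_fraction >= 1) {
    .stopf("hypo_fraction must lie in [0, 1)")
  }
  h <- hypo_fraction
  mix <- (1 - h) * probe@affinity_mature + h * probe@affinity_hypo
  endog <- if (probe@target %in% names(spike_amounts)) {
    spike_amounts[[probe@target]]
  } else 0
  selc <- if ("selC" %in% names(spike_amounts)) spike_amounts[["selC"]] else 0
  target_int <- load * (sample_amounts[[probe@target]] * mix +
                          endog * probe@affinity_mature)
  selc_int <- load * selc * selc_affinity
  noise <- .withSeed(seed, .lognormFactor(2, noise_cv))
  data.frame(
    lane_id = lane_id,
    band = c(probe@target, "selC"),
    intensity = c(target_int * noise[1], selc_int * noise[2]),
    stringsAsFactors = FALSE
  )
}

#' Simulate the spike-only reference lane
#'
#' A lane loaded with RNA extracted from spike cells alone, used downstream to
#' estimate the endogenous-expression background of the target tRNA in the
#' spike culture.
#'
#' @inheritParams northernLane
#' @return BandIntensity data.frame as in \code{\link{northernLane}}.
#' @export
spikeOnlyLane <- function(spike_amounts, probe, load = 1, noise_cv = 0,
                          seed = NULL, lane_id = "spike_only",
                          selc_affinity = 1) {
  empty <- setNames(numeric(length(spike_amounts)), names(spike_amounts))
  northernLane(sample_amounts = empty, probe = probe,
               spike_amounts = spike_amounts, load = load, hypo_fraction = 0,
               noise_cv = noise_cv, seed = seed, lane_id = lane_id,
               selc_affinity = selc_affinity)
}
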