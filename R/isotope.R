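#' Build a labeled population from ground truth
#'
#' Distributes a culture's incorporated label over the registry species at a
#' sampling time: \code{dna_fraction} of the label sits in alkali-stable DNA;
#' the rest is RNA, split by steady-state mass fractions and then propagated
#' by each species' trajectory into intact material, TCA-precipitable
#' fragments and acid-soluble degradation products. Steady populations are
#' evaluated at their steady composition regardless of \code{t}.
#'
#' @param registry a \code{\linkS4class{Registry}}.
#' @param trajectories named list of \code{\linkS4class{TruthTrajectory}};
#'   species without an entry stay flat at 1.
#' @param t sampling time (scenario clock units).
#' @param channel isotope channel, \code{"C14"} or \code{"H3"}.
#' @param state \code{"steady"} or \code{"perturbed"}.
#' @param total_dpm total incorporated label of the culture (dpm).
#' @return a \code{\linkS4class{Population}}.
#' @export
makePopulation <- function(registry, trajectories = list(), t = 0,
                           channel = c("C14", "H3"),
                           state = c("perturbed", "steady"),
                           total_dpm = 1e6) {
  stopifnot(is(registry, "Registry"))
  channel <- match.arg(channel)
  state <- match.arg(state)
  if (!.is_number(total_dpm) || total_dpm < 0) {
    .stopf("total_dpm must be a single non-negative number")
  }
  sp <- registry@species
  rna_label <- total_dpm * (1 - registry@dna_fraction)
  dna_label <- total_dpm * registry@dna_fraction
  t_eff <- if (state == "steady") 0 else t
  intact <- numeric(nrow(sp))
  frag <- numeric(nrow(sp))
  sol <- numeric(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    tr <- .trajFor(trajectories, sp$name[i])
    f <- intactFold(tr, t_eff)
    base <- rna_label * sp$mass_fraction[i]
    intact[i] <- base * f
    degraded <- base * max(0, 1 - f)
    part <- degradedPartition(tr, degraded)
    frag[i] <- part[["tca_fragments"]]
    sol[i] <- part[["acid_soluble"]]
  }
  names(intact) <- names(frag) <- names(sol) <- sp$name
  obj <- new("Population", channel = channel, state = state, time = t_eff,
             intact = intact, tca_fragments = frag, acid_soluble = sol,
             dna = dna_label, signature = .registrySignature(registry))
  validObject(obj)
  obj
}

.checkPopPair <- function(sample_pop, spike_pop, registry) {
  sig <- .registrySignature(registry)
  if (!identical(sample_pop@signature, sig) ||
      !identical(spike_pop@signature, sig)) {
    .stopf("populations and registry stem from different registries")
  }
  if (sample_pop@channel != "C14" || spike_pop@channel != "H3") {
    .stopf("expected a C14 sample population and an H3 spike population")
  }
  if (spike_pop@state != "steady") {
    .stopf("the spike population must be steady state")
  }
  invisible(TRUE)
}

#' TCA precipitation of a dual-labeled lysate
#'
#' The TCA precipitate captures nucleic-acid polymers longer than about 16 nt:
#' intact RNA, TCA-precipitable degradation fragments and DNA. Acid-soluble
#' degradation products are excluded. Both isotope channels are counted.
#'
#' @param sample_pop C14 \code{\linkS4class{Population}}.
#' @param spike_pop H3 steady-state \code{\linkS4class{Population}}.
#' @param registry the shared \code{\linkS4class{Registry}}.
#' @param sample_id identifier for the emitted record.
#' @return one-row DpmRecord data.frame (\code{sample_id}, \code{time},
#'   \code{fraction = "total_tca"}, \code{dpm_c14}, \code{dpm_h3}).
#' @export
tcaPrecipitate <- function(sample_pop, spike_pop, registry,
                           sample_id = "sample") {
  .checkPopPair(sample_pop, spike_pop, registry)
  data.frame(
    sample_id = sample_id,
    time = sample_pop@time,
    fraction = "total_tca",
    dpm_c14 = sample_pop@dna + sum(sample_pop@intact) +
      sum(sample_pop@tca_fragments),
    dpm_h3 = spike_pop@dna + sum(spike_pop@intact),
    stringsAsFactors = FALSE
  )
}

#' NaOH treatment followed by TCA precipitation
#'
#' Alkaline hydrolysis destroys RNA but leaves DNA intact, so the subsequent
#' TCA precipitate counts only the alkali-stable DNA label on each channel.
#' This record is the DNA background subtracted from all other counts.
#'
#' @inheritParams tcaPrecipitate
#' @return one-row DpmRecord data.frame with \code{fraction = "naoh_tca"}.
#' @export
naohThenTca <- function(sample_pop, spike_pop, registry,
                        sample_id = "sample") {
  .checkPopPair(sample_pop, spike_pop, registry)
  data.frame(
    sample_id = sample_id,
    time = sample_pop@time,
    fraction = "naoh_tca",
    dpm_c14 = sample_pop@dna,
    dpm_h3 = spike_pop@dna,
    stringsAsFactors = FALSE
  )
}

#' Liquid scintillation counting
#'
#' Converts a true labeled amount into observed counts. In \code{"none"} mode
#' the amount is returned unchanged; in \code{"poisson"} mode one Poisson draw
#' with that mean is taken per value, reproducibly under \code{seed}.
#'
#' @param true_amount non-negative amount(s) in dpm-equivalents.
#' @param noise_mode \code{"none"} or \code{"poisson"}.
#' @param seed integer seed, or \code{NULL} to draw from the ambient RNG
#'   stream.
#' @return observed counts, same length as \code{true_amount}.
#' @export
countLsc <- function(true_amount, noise_mode = c("none", "poisson"),
                     seed = NULL) {
  noise_mode <- match.arg(noise_mode)
  if (any(!is.finite(true_amount)) || any(true_amount < 0)) {
    .stopf("true_amount must be finite and >= 0")
  }
  if (noise_mode == "none") {
    return(true_amount)
  }
  .withSeed(seed, stats::rpois(length(true_amount), lambda = true_amount))
}

setMethod("show", "Population", function(object) {
  cat(sprintf("Population [%s, %s, t = %g]: %.4g dpm intact RNA, %.4g dpm fragments, %.4g dpm acid-soluble, %.4g dpm DNA\n",
              object@channel, object@state, object@time, sum(object@intact),
              sum(object@tca_fragments), sum(object@acid_soluble),
              object@dna))
})
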