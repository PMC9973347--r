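#' Construct an extraction method
#'
#' @param name method identifier.
#' @param e0 base extraction efficiency in (0, 1].
#' @param l50,width logistic size-bias midpoint and width (nt).
#' @param floor recovery floor for very large species; \code{floor = 1}
#'   disables the size bias entirely.
#' @param state_plateau,state_rate growth-state factor
#'   \eqn{g(t) = p + (1-p) e^{-kt}} parameters; \code{state_plateau = 1}
#'   disables the state bias.
#' @param state_min_length apply the state factor only to species at least
#'   this many nt long.
#' @param fragment_recovery recovery rate of degradation fragments in [0, 1].
#' @return an \code{\linkS4class{ExtractionMethod}}.
#' @export
extractionMethod <- function(name, e0, l50 = 300, width = 60, floor = 1,
                             state_plateau = 1, state_rate = 0,
                             state_min_length = 0, fragment_recovery = 0) {
  obj <- new("ExtractionMethod", name = name, e0 = e0, l50 = l50,
             width = width, floor = floor, state_plateau = state_plateau,
             state_rate = state_rate, state_min_length = state_min_length,
             fragment_recovery = fragment_recovery)
  validObject(obj)
  obj
}

#' Shipped extraction-method presets
#'
#' Calibrated bias models for the three protocols compared in the underlying
#' experiments:
#' \describe{
#'   \item{hot_phenol}{e0 = 0.45, no size bias, no state bias. Recovers every
#'     species proportionally to its true abundance.}
#'   \item{cold_phenol}{e0 = 0.30, logistic size bias (L50 = 300 nt,
#'     width = 60 nt, floor = 0.05) and a strong growth-state penalty
#'     (plateau 0.35, rate 0.04/min) on all species from perturbed cells.}
#'   \item{tri_reagent}{e0 = 0.28, size bias (L50 = 200 nt, width = 50 nt,
#'     floor = 0.02) and a growth-state penalty (plateau 0.55, rate 0.05/min)
#'     applied only to species of at least 100 nt, sparing the tRNA pool.}
#' }
#' All presets lose degradation fragments (\code{fragment_recovery = 0}).
#'
#' @param name one of \code{"hot_phenol"}, \code{"cold_phenol"},
#'   \code{"tri_reagent"}.
#' @return an \code{\linkS4class{ExtractionMethod}}.
#' @examples
#' sizeBiasS(extractionPreset("cold_phenol"), c(76, 120, 1542))
#' @export
extractionPreset <- function(name = c("hot_phenol", "cold_phenol",
                                      "tri_reagent")) {
  name <- match.arg(name)
  switch(name,
    hot_phenol = extractionMethod("hot_phenol", e0 = 0.45, floor = 1,
                                  state_plateau = 1),
    cold_phenol = extractionMethod("cold_phenol", e0 = 0.30, l50 = 300,
                                   width = 60, floor = 0.05,
                                   state_plateau = 0.35, state_rate = 0.04),
    tri_reagent = extractionMethod("tri_reagent", e0 = 0.28, l50 = 200,
                                   width = 50, floor = 0.02,
                                   state_plateau = 0.55, state_rate = 0.05,
                                   state_min_length = 100)
  )
}

#' Size-bias recovery factor
#'
#' Logistic in length:
#' \eqn{s(L) = floor + (1-floor) / (1 + e^{(L - L_{50})/w})}, monotone
#' non-increasing, saturating at \code{floor} for very large species.
#'
#' @param method an \code{\linkS4class{ExtractionMethod}}.
#' @param length_nt species length(s) in nucleotides (> 0).
#' @return recovery factor(s) in (0, 1].
#' @export
sizeBiasS <- function(method, length_nt) {
  stopifnot(is(method, "ExtractionMethod"))
  if (any(length_nt <= 0)) .stopf("length_nt must be > 0")
  method@floor + (1 - method@floor) /
    (1 + exp((length_nt - method@l50) / method@width))
}

#' Growth-state recovery factor
#'
#' Perturbed (starved or drug-treated) populations are extracted at
#' \eqn{g(t) = p + (1-p) e^{-kt}}; steady-state populations always get
#' \eqn{g = 1} regardless of the sampling time. This is the spike contract:
#' the co-extracted steady-state spike cells are never penalized, which is
#' what makes spike normalization meaningful.
#'
#' @param method an \code{\linkS4class{ExtractionMethod}}.
#' @param t time(s) since perturbation (minutes; >= 0).
#' @param population_state \code{"steady"} or \code{"perturbed"}.
#' @return factor(s) in (0, 1].
#' @export
stateFactorG <- function(method, t, population_state = c("perturbed",
                                                         "steady")) {
  stopifnot(is(method, "ExtractionMethod"))
  population_state <- match.arg(population_state)
  if (any(t < 0)) .stopf("time must be >= 0")
  if (population_state == "steady") {
    return(rep(1, length(t)))
  }
  p <- method@state_plateau
  p + (1 - p) * exp(-method@state_rate * t)
}

# per-species state factor respecting state_min_length
.stateFactorSpecies <- function(method, t, state, length_nt) {
  g <- stateFactorG(method, t, state)
  ifelse(length_nt >= method@state_min_length, g, 1)
}

#' Extract RNA from a sample plus its co-harvested spike population
#'
#' Applies the method's per-species recovery, intact amount times
#' \eqn{e_0 \, s(L) \, g(t)}, to the \eqn{[^{14}C]} sample population (state
#' factor per its perturbation time) and to the \eqn{[^3H]} spike population
#' (steady; state factor 1). Degradation fragments are recovered at the
#' method's \code{fragment_recovery} rate without size bias.
#'
#' @param sample_pop \code{\linkS4class{Population}} on the C14 channel.
#' @param spike_pop \code{\linkS4class{Population}} on the H3 channel,
#'   steady state.
#' @param method an \code{\linkS4class{ExtractionMethod}}.
#' @param registry the shared \code{\linkS4class{Registry}}; populations
#'   built from a different registry are rejected.
#' @return data.frame with one row per pool species (columns \code{species},
#'   \code{length_nt}, \code{c14}, \code{h3}) plus a final \code{fragments}
#'   row, with attributes \code{time} and \code{method}.
#' @export
extractRNA <- function(sample_pop, spike_pop, method, registry) {
  stopifnot(is(sample_pop, "Population"), is(spike_pop, "Population"),
            is(method, "ExtractionMethod"), is(registry, "Registry"))
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
  sp <- registry@species
  s <- sizeBiasS(method, sp$length_nt)
  g_sample <- .stateFactorSpecies(method, sample_pop@time, sample_pop@state,
                                  sp$length_nt)
  c14 <- sample_pop@intact[sp$name] * method@e0 * s * g_sample
  h3 <- spike_pop@intact[sp$name] * method@e0 * s
  frag_c14 <- method@fragment_recovery * method@e0 *
    sum(sample_pop@tca_fragments) *
    stateFactorG(method, sample_pop@time, sample_pop@state)
  frag_h3 <- method@fragment_recovery * method@e0 *
    sum(spike_pop@tca_fragments)
  out <- data.frame(
    species = c(sp$name, "fragments"),
    length_nt = c(sp$length_nt, NA_real_),
    c14 = c(unname(c14), frag_c14),
    h3 = c(unname(h3), frag_h3),
    stringsAsFactors = FALSE
  )
  attr(out, "time") <- sample_pop@time
  attr(out, "method") <- method@name
  out
}

#' Read and write extraction-method definition files
#'
#' A method definition is a YAML document with the five parameter groups:
#' \code{name}, \code{e0}, \code{size_bias} (\code{l50}, \code{width},
#' \code{floor}), \code{state_factor} (\code{plateau}, \code{rate},
#' \code{min_length}) and \code{fragment_recovery}.
#'
#' @param path file path.
#' @param method an \code{\linkS4class{ExtractionMethod}}.
#' @return \code{loadExtractionMethod}: a validated
#'   \code{\linkS4class{ExtractionMethod}}; the writer returns \code{path}
#'   invisibly.
#' @export
loadExtractionMethod <- function(path) {
  if (!file.exists(path)) .stopf("method file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  need <- c("name", "e0", "size_bias", "state_factor", "fragment_recovery")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    .stopf("method config lacks field(s): %s", paste(missing, collapse = ", "))
  }
  extractionMethod(cfg$name, e0 = cfg$e0,
                   l50 = cfg$size_bias$l50, width = cfg$size_bias$width,
                   floor = cfg$size_bias$floor,
                   state_plateau = cfg$state_factor$plateau,
                   state_rate = cfg$state_factor$rate,
                   state_min_length = cfg$state_factor$min_length %||% 0,
                   fragment_recovery = cfg$fragment_recovery)
}

#' @rdname loadExtractionMethod
#' @export
writeExtractionMethod <- function(method, path) {
  stopifnot(is(method, "ExtractionMethod"))
  yaml::write_yaml(list(
    name = method@name, e0 = method@e0,
    size_bias = list(l50 = method@l50, width = method@width,
                     floor = method@floor),
    state_factor = list(plateau = method@state_plateau,
                        rate = method@state_rate,
                        min_length = method@state_min_length),
    fragment_recovery = method@fragment_recovery
  ), path)
  invisible(path)
}

setMethod("show", "ExtractionMethod", function(object) {
  size <- if (object@floor >= 1) "none" else {
    sprintf("logistic(L50 = %g nt, w = %g nt, floor = %.2f)",
            object@l50, object@width, object@floor)
  }
  state <- if (object@state_plateau >= 1) "none" else {
    sprintf("g(t) = %.2f + %.2f exp(-%.3g t)%s", object@state_plateau,
            1 - object@state_plateau, object@state_rate,
            if (object@state_min_length > 0) {
              sprintf(" for L >= %g nt", object@state_min_length)
            } else "")
  }
  cat(sprintf("ExtractionMethod '%s': e0 = %.2f; size bias: %s; state bias: %s; fragment recovery %.2f\n",
              object@name, object@e0, size, state, object@fragment_recovery))
})
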