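# scenario presets: each returns the argument list resolved by buildScenario()

.MEMBER_SET <- c("argVYZQ", "ileTUV", "leuPQVT", "leuU", "hisR", "valT",
                 "gltTUVW", "asnTUVW", "tyrTV", "serV")

.geom <- function(sp, fold, at, f_sol = 0.35) {
  truthTrajectory(sp, anchor_fold = fold, anchor_time = at, f_sol = f_sol)
}

.plateau <- function(sp, fold, at, last, f_sol = 0.35) {
  truthTrajectory(sp, f_sol = f_sol,
                  points = data.frame(time = c(at, last),
                                      fold = c(fold, fold)))
}

.memberTrajs <- function(folds, at, last = at, plateau = FALSE) {
  out <- list()
  for (sp in names(folds)) {
    out[[sp]] <- if (plateau) {
      .plateau(sp, folds[[sp]], at, last)
    } else {
      .geom(sp, folds[[sp]], at)
    }
  }
  out
}

.presetList <- function() {
  list(
    # valine-induced isoleucine starvation with dual-isotope radiolabeling:
    # the extraction-method comparison experiment
    isoleucine_radiolabel = function() {
      trajs <- list(
        `23S` = .geom("23S", 0.75, 80),
        `16S` = .geom("16S", 0.75, 80),
        `5S` = .geom("5S", 0.95, 80),
        tRNA = .geom("tRNA", 1.10, 80)
      )
      list(
        time_unit = "min", timepoints = c(5, 10, 20, 40, 80),
        synthesis_on = FALSE, trajectories = trajs,
        methods = c("hot_phenol", "cold_phenol", "tri_reagent"),
        northern_method = "hot_phenol", normalization = "trna_c14",
        probes = do.call(rbind, lapply(
          c("argVYZQ", "ileTUV", "leuPQVT"),
          function(tg) data.frame(target = tg, region = .PROBE_REGIONS))),
        uncalibrated = character()
      )
    },
    # wild-type arginine starvation, spike-in northern time course
    arginine_short = function() {
      members <- .memberTrajs(
        list(leuPQVT = 0.86, valT = 0.82, argVYZQ = 1.05, ileTUV = 1.05,
             leuU = 1.0, gltTUVW = 1.10, asnTUVW = 1.05, tyrTV = 1.0,
             serV = 1.0), at = 160)
      members$hisR <- truthTrajectory(
        "hisR", points = data.frame(time = c(5, 40, 160),
                                    fold = c(0.90, 1.0, 1.0)))
      pools <- list(`23S` = .geom("23S", 0.85, 160),
                    `16S` = .geom("16S", 0.85, 160))
      list(
        time_unit = "min", timepoints = c(5, 10, 20, 40, 80, 160),
        synthesis_on = FALSE, trajectories = c(pools, members),
        methods = "hot_phenol", northern_method = "hot_phenol",
        normalization = "selc",
        probes = data.frame(target = setdiff(.MEMBER_SET, "serV"),
                            region = "five_prime"),
        uncalibrated = character()
      )
    },
    # relaxed (relA-) mutant under arginine starvation: stable-RNA synthesis
    # continues, all tRNAs accumulate
    relA_minus_arginine = function() {
      folds <- list(argVYZQ = 1.5, leuU = 1.5, valT = 2.4, ileTUV = 1.8,
                    leuPQVT = 1.8, hisR = 1.8, gltTUVW = 1.8, asnTUVW = 1.8,
                    tyrTV = 1.8, serV = 1.8)
      pools <- list(`23S` = .geom("23S", 1.5, 160),
                    `16S` = .geom("16S", 1.5, 160),
                    `5S` = .geom("5S", 1.5, 160),
                    tRNA = .geom("tRNA", 1.8, 160))
      list(
        time_unit = "min", timepoints = c(5, 10, 20, 40, 80, 160),
        synthesis_on = TRUE,
        trajectories = c(pools, .memberTrajs(folds, at = 160)),
        methods = "hot_phenol", northern_method = "hot_phenol",
        normalization = "selc",
        probes = data.frame(target = setdiff(.MEMBER_SET, "serV"),
                            region = "five_prime"),
        uncalibrated = character()
      )
    },
    # short-term phosphate starvation: several tRNAs rise to a plateau
    phosphate_short = function() {
      folds <- list(ileTUV = 1.9, argVYZQ = 1.2, leuPQVT = 1.2, leuU = 1.2,
                    hisR = 1.2, valT = 1.2, gltTUVW = 1.2, asnTUVW = 1.2,
                    tyrTV = 1.2, serV = 1.2)
      pools <- list(`23S` = .geom("23S", 0.60, 160),
                    `16S` = .geom("16S", 0.60, 160),
                    `5S` = .geom("5S", 0.80, 160),
                    tRNA = .plateau("tRNA", 1.27, 80, 160))
      list(
        time_unit = "min", timepoints = c(5, 10, 20, 40, 80, 160),
        synthesis_on = FALSE,
        trajectories = c(pools, .memberTrajs(folds, at = 80, last = 160,
                                             plateau = TRUE)),
        methods = "hot_phenol", northern_method = "hot_phenol",
        normalization = "selc",
        probes = data.frame(target = setdiff(.MEMBER_SET, "serV"),
                            region = "five_prime"),
        uncalibrated = character()
      )
    },
    # rifampicin transcription arrest: everything flat except tyrTV
    rifampicin = function() {
      list(
        time_unit = "min", timepoints = c(5, 10, 20, 40, 80),
        synthesis_on = FALSE,
        trajectories = list(tyrTV = .geom("tyrTV", 1.3, 80)),
        methods = "hot_phenol", northern_method = "hot_phenol",
        normalization = "selc",
        probes = data.frame(target = setdiff(.MEMBER_SET, "serV"),
                            region = "five_prime"),
        uncalibrated = character()
      )
    },
    longterm_glucose = function() .longtermPreset(0.75, 1.0),
    longterm_phosphate = function() .longtermPreset(0.35, 0.50),
    longterm_ammonium = function() .longtermPreset(0.55, 1.0),
    longterm_arginine = function() .longtermPreset(0.75, 1.0)
  )
}

# long-term starvation presets (hours): rRNA plateaus ordered by nutrient,
# tRNAs modestly above 1 with gltTUVW highest. The rRNA plateau values and the
# long-term tRNA folds are order-of-magnitude defaults, flagged uncalibrated
# in the run manifest.
.longtermPreset <- function(rrna_plateau, fiveS_plateau) {
  folds <- list(gltTUVW = 1.6, argVYZQ = 1.2, ileTUV = 1.2, leuPQVT = 1.2,
                leuU = 1.2, hisR = 1.2, valT = 1.2, asnTUVW = 1.2,
                tyrTV = 1.2, serV = 1.2)
  pools <- list(`23S` = .plateau("23S", rrna_plateau, 24, 168),
                `16S` = .plateau("16S", rrna_plateau, 24, 168),
                `5S` = .plateau("5S", fiveS_plateau, 24, 168),
                tRNA = .plateau("tRNA", 1.25, 24, 168))
  list(
    time_unit = "h", timepoints = c(2, 4, 8, 24, 48, 96, 144, 168),
    synthesis_on = FALSE,
    trajectories = c(pools, .memberTrajs(folds, at = 24, last = 168,
                                         plateau = TRUE)),
    methods = "hot_phenol", northern_method = "hot_phenol",
    normalization = "selc",
    probes = data.frame(target = setdiff(.MEMBER_SET, "serV"),
                        region = "five_prime"),
    uncalibrated = c("rRNA plateau levels", "long-term tRNA fold-changes")
  )
}

#' List the shipped scenario presets
#'
#' @return character vector of preset names accepted by
#'   \code{\link{buildScenario}}.
#' @export
scenarioPresets <- function() names(.presetList())

#' Build a fully resolved scenario
#'
#' Resolves a shipped preset into a \code{\linkS4class{Scenario}}, optionally
#' overriding any of its fields. Presets define the experimental designs of
#' the supported perturbations (sampling schedules, ground-truth trajectory
#' anchors, extraction methods, probe sets, normalization route); overrides
#' are merged on top, with trajectory overrides merged per species.
#'
#' @param name preset name; see \code{\link{scenarioPresets}}.
#' @param overrides named list of field overrides. Recognized names:
#'   \code{timepoints}, \code{steady_sample_count}, \code{n_replicates},
#'   \code{methods} (character vector of preset names or list of
#'   \code{\linkS4class{ExtractionMethod}}), \code{northern_method},
#'   \code{normalization}, \code{noise} (partial list), \code{sample_dpm},
#'   \code{spike_dpm}, \code{spike_mass}, \code{spike_endog_frac},
#'   \code{synthesis_on}, \code{trajectories} (named list, merged),
#'   \code{probes} (data.frame target/region), \code{registry}.
#' @param seed integer seed governing every random draw of the run.
#' @return a validated \code{\linkS4class{Scenario}}.
#' @examples
#' sc <- buildScenario("isoleucine_radiolabel", seed = 1)
#' sc
#' @export
buildScenario <- function(name, overrides = list(), seed = 1L) {
  presets <- .presetList()
  if (!name %in% names(presets)) {
    .stopf("unknown scenario preset '%s'; available: %s", name,
           paste(names(presets), collapse = ", "))
  }
  args <- presets[[name]]()
  defaults <- list(
    steady_sample_count = 3, n_replicates = 3,
    registry = defaultRegistry(),
    noise = list(counting = "none", densitometry_cv = 0, load_cv = 0),
    sample_dpm = 1e6, spike_dpm = 5e5, spike_mass = 1e4,
    spike_endog_frac = 0.05
  )
  args <- c(args, defaults[setdiff(names(defaults), names(args))])
  if (length(overrides)) {
    bad <- setdiff(names(overrides),
                   c(names(args), "trajectories", "noise", "probes"))
    if (length(bad)) {
      .stopf("unknown scenario override(s): %s", paste(bad, collapse = ", "))
    }
    for (nm in names(overrides)) {
      if (nm == "trajectories") {
        for (sp in names(overrides$trajectories)) {
          args$trajectories[[sp]] <- overrides$trajectories[[sp]]
        }
      } else if (nm == "noise") {
        args$noise <- utils::modifyList(args$noise, overrides$noise)
      } else {
        args[[nm]] <- overrides[[nm]]
      }
    }
  }
  methods <- args$methods
  if (is.character(methods)) {
    methods <- lapply(methods, extractionPreset)
  }
  probes <- args$probes
  if (is.data.frame(probes)) {
    probes <- lapply(seq_len(nrow(probes)), function(i) {
      probeFor(probes$target[i], probes$region[i], args$registry)
    })
  }
  obj <- new("Scenario",
    name = name, time_unit = args$time_unit,
    timepoints = as.numeric(args$timepoints),
    steady_sample_count = args$steady_sample_count,
    n_replicates = args$n_replicates,
    registry = args$registry, trajectories = args$trajectories,
    synthesis_on = args$synthesis_on, methods = methods,
    northern_method = args$northern_method, probes = probes,
    normalization = args$normalization, noise = args$noise,
    sample_dpm = args$sample_dpm, spike_dpm = args$spike_dpm,
    spike_mass = args$spike_mass, spike_endog_frac = args$spike_endog_frac,
    seed = as.numeric(seed), uncalibrated = args$uncalibrated)
  validObject(obj)
  obj
}

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario '%s' (%s): %d steady + %d time points x %d replicates, seed %g\n",
              object@name, object@time_unit, object@steady_sample_count,
              length(object@timepoints), object@n_replicates, object@seed))
  cat(sprintf("  methods: %s; northern via %s (%s normalization), %d probes\n",
              paste(vapply(object@methods, function(m) m@name, character(1)),
                    collapse = ", "),
              object@northern_method, object@normalization,
              length(object@probes)))
  cat(sprintf("  noise: counting %s, densitometry CV %.3g, load CV %.3g\n",
              object@noise$counting, object@noise$densitometry_cv,
              object@noise$load_cv))
})
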