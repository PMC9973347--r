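#' Construct a Registry
#'
#' Validates and assembles the species bookkeeping used by every other module.
#' See \code{\linkS4class{Registry}} for the invariants enforced.
#'
#' @param species data.frame of pool-level species (columns \code{name},
#'   \code{rna_class}, \code{length_nt}, \code{mass_fraction},
#'   \code{acp3u_in_anticodon_region}, \code{is_spike_marker}).
#' @param trna_members data.frame of named tRNAs subdividing the tRNA pool
#'   (columns \code{name}, \code{length_nt}, \code{pool_share},
#'   \code{acp3u_in_anticodon_region}, \code{is_spike_marker}); may be empty.
#' @param dna_fraction fraction of TCA-precipitable label residing in DNA.
#' @return a validated \code{\linkS4class{Registry}}.
#' @examples
#' reg <- defaultRegistry()
#' speciesTable(reg)
#' @export
Registry <- function(species, trna_members = .emptyMembers(),
                     dna_fraction = 0.08) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  trna_members <- as.data.frame(trna_members, stringsAsFactors = FALSE)
  obj <- new("Registry", species = species, trna_members = trna_members,
             dna_fraction = dna_fraction)
  validObject(obj)
  obj
}

.emptyMembers <- function() {
  data.frame(name = character(), length_nt = numeric(),
             pool_share = numeric(),
             acp3u_in_anticodon_region = logical(),
             is_spike_marker = logical(), stringsAsFactors = FALSE)
}

#' Default E. coli stable-RNA registry
#'
#' Ships the species set of a typical exponentially growing E. coli culture:
#' 23S (2904 nt), 16S (1542 nt) and 5S (120 nt) rRNA, a pooled tRNA fraction
#' (76 nt representative length) and a pooled "other" non-coding fraction
#' (200 nt representative), with steady-state labeled mass fractions
#' 0.50 / 0.27 / 0.03 / 0.16 / 0.04. Eleven named tRNAs subdivide the tRNA
#' pool; tRNA-argVYZQ and tRNA-ileTUV carry the acp3U modification in their
#' anticodon region, and the rare tRNA-selC is the whole-cell spike-in marker.
#' The alkali-stable DNA component holds 8\% of the incorporated label.
#'
#' @return a \code{\linkS4class{Registry}}.
#' @export
defaultRegistry <- function() {
  species <- data.frame(
    name = c("23S", "16S", "5S", "tRNA", "other"),
    rna_class = c("rRNA", "rRNA", "rRNA", "tRNA", "other"),
    length_nt = c(2904, 1542, 120, 76, 200),
    mass_fraction = c(0.50, 0.27, 0.03, 0.16, 0.04),
    acp3u_in_anticodon_region = FALSE,
    is_spike_marker = FALSE,
    stringsAsFactors = FALSE
  )
  mem_names <- c("argVYZQ", "ileTUV", "leuPQVT", "leuU", "hisR", "valT",
                 "gltTUVW", "asnTUVW", "tyrTV", "serV", "selC")
  selc_share <- 0.002
  members <- data.frame(
    name = mem_names,
    length_nt = c(rep(76, 9), 93, 95),
    pool_share = c(rep((1 - selc_share) / 10, 10), selc_share),
    acp3u_in_anticodon_region = mem_names %in% c("argVYZQ", "ileTUV"),
    is_spike_marker = mem_names == "selC",
    stringsAsFactors = FALSE
  )
  Registry(species, members, dna_fraction = 0.08)
}

#' Registry accessors
#'
#' \code{speciesTable} returns the pool-level species table,
#' \code{trnaMembers} the named-tRNA table, \code{dnaFraction} the DNA label
#' fraction and \code{spikeMarker} the name of the spike-in marker species
#' (or \code{NA} if none is declared).
#'
#' @param x a \code{\linkS4class{Registry}}.
#' @return see the individual descriptions.
#' @rdname speciesTable
#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))

#' @rdname speciesTable
#' @aliases speciesTable,Registry-method
#' @export
setMethod("speciesTable", "Registry", function(x) x@species)

#' @rdname speciesTable
#' @export
setGeneric("trnaMembers", function(x) standardGeneric("trnaMembers"))

#' @rdname speciesTable
#' @aliases trnaMembers,Registry-method
#' @export
setMethod("trnaMembers", "Registry", function(x) x@trna_members)

#' @rdname speciesTable
#' @export
setGeneric("dnaFraction", function(x) standardGeneric("dnaFraction"))

#' @rdname speciesTable
#' @aliases dnaFraction,Registry-method
#' @export
setMethod("dnaFraction", "Registry", function(x) x@dna_fraction)

#' @rdname speciesTable
#' @export
setGeneric("spikeMarker", function(x) standardGeneric("spikeMarker"))

#' @rdname speciesTable
#' @aliases spikeMarker,Registry-method
#' @export
setMethod("spikeMarker", "Registry", function(x) {
  hits <- c(x@species$name[x@species$is_spike_marker],
            x@trna_members$name[x@trna_members$is_spike_marker])
  if (length(hits)) hits else NA_character_
})

setMethod("show", "Registry", function(object) {
  cat(sprintf("Registry: %d pool species, %d named tRNAs, DNA label %.1f%%\n",
              nrow(object@species), nrow(object@trna_members),
              100 * object@dna_fraction))
  cat(sprintf("  spike marker: %s\n", spikeMarker(object)))
  print(object@species, row.names = FALSE)
})

# registry fingerprint used to detect cross-registry population mixes
.registrySignature <- function(registry) {
  sp <- registry@species
  paste(c(sp$name, sp$length_nt, signif(sp$mass_fraction, 12),
          signif(registry@dna_fraction, 12)), collapse = "|")
}

# lengths and acp3U flags for any species or member name
.lookupSpecies <- function(registry, name) {
  sp <- registry@species
  mem <- registry@trna_members
  if (name %in% sp$name) {
    i <- match(name, sp$name)
    list(length_nt = sp$length_nt[i],
         acp3u = sp$acp3u_in_anticodon_region[i], member = FALSE)
  } else if (name %in% mem$name) {
    i <- match(name, mem$name)
    list(length_nt = mem$length_nt[i],
         acp3u = mem$acp3u_in_anticodon_region[i], member = TRUE)
  } else {
    .stopf("unknown species '%s' in registry", name)
  }
}

#' Read and write registry configuration files
#'
#' The registry is serialized as a YAML document with keys
#' \code{dna_fraction}, \code{species} and \code{trna_members}; the round trip
#' is lossless field-for-field.
#'
#' @param path file path.
#' @param registry a \code{\linkS4class{Registry}}.
#' @return \code{loadRegistry} returns a validated
#'   \code{\linkS4class{Registry}}; \code{writeRegistry} returns \code{path}
#'   invisibly.
#' @export
loadRegistry <- function(path) {
  if (!file.exists(path)) .stopf("registry file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!all(c("dna_fraction", "species") %in% names(cfg))) {
    .stopf("registry config must define 'dna_fraction' and 'species'")
  }
  bindRows <- function(lst, cols) {
    if (is.null(lst) || length(lst) == 0) return(NULL)
    do.call(rbind, lapply(lst, function(rec) {
      missing <- setdiff(cols, names(rec))
      if (length(missing)) {
        .stopf("registry config species entry lacks field(s): %s",
               paste(missing, collapse = ", "))
      }
      as.data.frame(rec[cols], stringsAsFactors = FALSE)
    }))
  }
  species <- bindRows(cfg$species, .SPECIES_COLS)
  members <- bindRows(cfg$trna_members, .MEMBER_COLS)
  if (is.null(members)) members <- .emptyMembers()
  Registry(species, members, dna_fraction = cfg$dna_fraction)
}

#' @rdname loadRegistry
#' @export
writeRegistry <- function(registry, path) {
  stopifnot(is(registry, "Registry"))
  rowList <- function(df) {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  cfg <- list(
    dna_fraction = registry@dna_fraction,
    species = rowList(registry@species),
    trna_members = rowList(registry@trna_members)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
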