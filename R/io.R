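# delimited-text table I/O: comma separator, period decimal, mandatory header

.readTable <- function(path, numeric_cols = character(),
                       logical_cols = character(), required = character()) {
  if (!file.exists(path)) .stopf("table file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    .stopf("%s lacks column(s): %s", basename(path),
           paste(missing, collapse = ", "))
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad)) {
      .stopf("%s: column '%s' has a non-numeric value at row %d",
             basename(path), col, bad[1])
    }
    df[[col]] <- v
  }
  for (col in intersect(logical_cols, names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

.writeTable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write scintillation (dpm) record tables
#'
#' Columns: \code{sample_id}, \code{time}, \code{fraction} (one of
#' \code{total_tca}, \code{naoh_tca}, \code{extract}, \code{band:<species>}),
#' \code{dpm_c14}, \code{dpm_h3}, plus \code{method} and \code{replicate}
#' when written by \code{\link{writeScenarioRun}}. Malformed tables are
#' rejected with the offending column and row named.
#'
#' @param path file path.
#' @param records data.frame of records.
#' @return \code{readDpmTable}: validated data.frame; writers return the path
#'   invisibly.
#' @export
readDpmTable <- function(path) {
  df <- .readTable(path, numeric_cols = c("time", "dpm_c14", "dpm_h3"),
                   required = c("sample_id", "fraction", "dpm_c14", "dpm_h3"))
  if (any(df$dpm_c14 < 0, na.rm = TRUE) || any(df$dpm_h3 < 0, na.rm = TRUE)) {
    .stopf("%s: dpm values must be >= 0", basename(path))
  }
  df
}

#' @rdname readDpmTable
#' @export
writeDpmTable <- function(records, path) .writeTable(records, path)

#' Read and write band-intensity tables and lane metadata
#'
#' Band tables have columns \code{lane_id}, \code{band}, \code{intensity}
#' (plus \code{replicate} and \code{probe_id} in scenario output); lane
#' metadata has \code{lane_id}, \code{sample_id}, \code{time},
#' \code{is_spike_only}.
#'
#' @param path file path.
#' @param bands,lanes data.frames.
#' @return readers return validated data.frames; writers the path, invisibly.
#' @export
readBandTable <- function(path) {
  df <- .readTable(path, numeric_cols = "intensity",
                   required = c("lane_id", "band", "intensity"))
  if (any(df$intensity < 0, na.rm = TRUE)) {
    .stopf("%s: intensities must be >= 0", basename(path))
  }
  df
}

#' @rdname readBandTable
#' @export
writeBandTable <- function(bands, path) .writeTable(bands, path)

#' @rdname readBandTable
#' @export
readLaneTable <- function(path) {
  .readTable(path, numeric_cols = "time", logical_cols = "is_spike_only",
             required = c("lane_id", "sample_id", "time", "is_spike_only"))
}

#' @rdname readBandTable
#' @export
writeLaneTable <- function(lanes, path) .writeTable(lanes, path)

#' Write a simulated run to a directory of delimited-text tables
#'
#' Emits \code{samples.csv}, \code{truth.csv}, \code{dpm.csv},
#' \code{northern_bands.csv}, \code{northern_lanes.csv}, \code{probes.csv}
#' and a \code{manifest.json} sufficient to reproduce and re-quantify the run.
#'
#' @param run a \code{\linkS4class{ScenarioRun}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeScenarioRun <- function(run, dir) {
  stopifnot(is(run, "ScenarioRun"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .writeTable(run@samples, file.path(dir, "samples.csv"))
  .writeTable(run@truth, file.path(dir, "truth.csv"))
  writeDpmTable(run@dpm, file.path(dir, "dpm.csv"))
  writeBandTable(run@northern_bands, file.path(dir, "northern_bands.csv"))
  writeLaneTable(run@northern_lanes, file.path(dir, "northern_lanes.csv"))
  probes <- do.call(rbind, lapply(run@scenario@probes, function(p) {
    data.frame(probe_id = paste(p@target, p@region, sep = "."),
               target = p@target, region = p@region,
               affinity_mature = p@affinity_mature,
               affinity_hypo = p@affinity_hypo, stringsAsFactors = FALSE)
  }))
  if (is.null(probes)) {
    probes <- data.frame(probe_id = character(), target = character(),
                         region = character(), affinity_mature = numeric(),
                         affinity_hypo = numeric())
  }
  .writeTable(probes, file.path(dir, "probes.csv"))
  jsonlite::write_json(run@manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a simulated run back from a directory
#'
#' @param dir directory written by \code{\link{writeScenarioRun}}.
#' @return list of tables (\code{samples}, \code{truth}, \code{dpm},
#'   \code{northern_bands}, \code{northern_lanes}, \code{probes}) and the
#'   \code{manifest} list, consumable by \code{\link{quantifyTables}}.
#' @export
readScenarioRun <- function(dir) {
  if (!dir.exists(dir)) .stopf("run directory not found: %s", dir)
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    .stopf("manifest.json not found in %s", dir)
  }
  list(
    samples = .readTable(file.path(dir, "samples.csv"),
                         numeric_cols = "time", logical_cols = "is_steady",
                         required = c("sample_id", "time", "is_steady")),
    truth = .readTable(file.path(dir, "truth.csv"),
                       numeric_cols = c("time", "intact_fold", "intact_mass",
                                        "tca_fragments", "acid_soluble",
                                        "hypomod_fraction"),
                       logical_cols = "is_pool",
                       required = c("species", "time", "intact_fold")),
    dpm = readDpmTable(file.path(dir, "dpm.csv")),
    northern_bands = readBandTable(file.path(dir, "northern_bands.csv")),
    northern_lanes = readLaneTable(file.path(dir, "northern_lanes.csv")),
    probes = .readTable(file.path(dir, "probes.csv"),
                        required = c("probe_id", "target", "region")),
    manifest = jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  )
}
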