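#' Assemble the delimited report bundle
#'
#' Writes whichever stage outputs are supplied as tab-delimited tables plus
#' a JSON run-metadata file (seed, configuration echo, filter-stage audit
#' counts) and a manifest listing the artifacts present and the gaps.
#' Re-running with identical inputs reproduces byte-identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param signals drug-level table from [screen_signals()].
#' @param pairs pair table from [screen_pairs()] (its `edges` attribute, if
#'   present, is written as `pair_edges.tsv` for network tools).
#' @param summary descriptive table from [summarize_cohort()].
#' @param performance method table from [evaluate_methods()].
#' @param atc class aggregate from [aggregate_by_atc()].
#' @param meta named list of run metadata (seed, audit counts, config echo).
#' @return invisibly, the manifest as a named list.
#' @export
build_report <- function(out_dir, signals = NULL, pairs = NULL,
                         summary = NULL, performance = NULL, atc = NULL,
                         meta = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  gaps <- character(0)
  emit <- function(obj, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    if (is.null(obj)) {
      gaps <<- c(gaps, name)
    } else {
      data.table::fwrite(as.data.table(obj), path, sep = "\t", quote = FALSE)
      artifacts <<- c(artifacts, basename(path))
    }
  }
  emit(signals, "signals")
  emit(pairs, "pairs")
  if (!is.null(pairs) && !is.null(attr(pairs, "edges"))) {
    emit(attr(pairs, "edges"), "pair_edges")
  }
  emit(summary, "descriptive_summary")
  emit(performance, "method_performance")
  emit(atc, "atc_aggregate")

  meta_path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  artifacts <- c(artifacts, basename(meta_path))

  manifest <- list(artifacts = artifacts, gaps = gaps)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Echo a simulator configuration as plain metadata
#'
#' Flattens a [sim_config()] (including planted signals) into JSON-ready
#' lists for the run-metadata file.
#'
#' @param config a `sim_config`.
#' @return named list.
#' @export
config_echo <- function(config) {
  out <- unclass(config)
  out$planted_signals <- lapply(config$planted_signals, function(s) {
    list(exposure = s$exposure, event_term = s$event_term,
         relative_rate = s$relative_rate,
         interaction_only = s$interaction_only)
  })
  out$background_event_terms <- as.list(out$background_event_terms)
  out$shock_terms <- as.list(out$shock_terms)
  out
}
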