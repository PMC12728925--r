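# Shared file I/O: .smi corpora, YAML run configs, and the standard
# result bundle (CSV aggregate + JSONL sample stream + summary JSON).
# Outputs contain no timestamps, so reruns of the same config and seed are
# byte-identical.

#' Read a .smi file
#'
#' One record per line, `SMILES<TAB>optional_id`, UTF-8; `#` comment lines
#' and blank lines are skipped.
#'
#' @param path file path.
#' @return character vector of SMILES, named by id where ids are present.
#' @export
read_smi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) return(character())
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  smi <- vapply(parts, `[[`, character(1), 1)
  bad <- !nzchar(smi) | grepl("[[:space:]]", smi)
  if (any(bad)) {
    stop("malformed .smi record at line ", keep[which(bad)[1]], ": '",
         lines[keep[which(bad)[1]]], "'")
  }
  ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else "", character(1))
  if (any(nzchar(ids))) names(smi) <- ids
  smi
}

#' Write a .smi file
#'
#' @param mols character vector of SMILES; names, if any, become ids.
#' @param path output path.
#' @export
write_smi <- function(mols, path) {
  ids <- names(mols)
  lines <- if (is.null(ids)) as.character(mols) else {
    ifelse(nzchar(ids), paste(mols, ids, sep = "\t"), as.character(mols))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Stable hash of a run configuration
#'
#' Hash of the canonical JSON rendering of the configuration, so identical
#' configurations hash identically across platforms.
#'
#' @param config a list of serializable configuration values.
#' @return hash string.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE)
  rlang::hash(as.character(json))
}

#' Write a result bundle
#'
#' Writes `results.csv` (one row per task/replicate/setting),
#' `samples.jsonl` (one JSON object per sampled molecule) and
#' `summary.json` (aggregate scores plus the config hash) into `out_dir`.
#' Outputs are deterministic: rerunning the same config and seed
#' reproduces them byte for byte.
#'
#' @param out_dir output directory (created if missing).
#' @param results data frame of aggregate rows.
#' @param samples optional data frame of per-sample records.
#' @param summary named list of summary quantities.
#' @param config optional configuration list; its hash is recorded in the
#'   summary.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(out_dir, results, samples = NULL,
                          summary = list(), config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  if (!is.null(samples)) {
    con <- file(file.path(out_dir, "samples.jsonl"), open = "wb")
    jsonlite::stream_out(samples, con, verbose = FALSE, digits = NA,
                         auto_unbox = TRUE)
    close(con)
  }
  if (!is.null(config)) summary$config_hash <- config_hash(config)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' Read a YAML run configuration with defaults
#'
#' Unknown keys are kept; missing keys take the supplied defaults.
#'
#' @param path YAML file path (`NULL` returns the defaults).
#' @param defaults named list of default values.
#' @return named list.
#' @export
read_run_config <- function(path = NULL, defaults = list()) {
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  cfg
}
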