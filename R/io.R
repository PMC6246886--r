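# Delimited-text and JSON interchange for pipeline artifacts.

#' Write session kinematics and the trial table to TSV
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_dataset_tsv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    kinematics = file.path(dir, "kinematics.tsv"),
    trials = file.path(dir, "trials.tsv")
  )
  utils::write.table(dataset$kinematics, paths["kinematics"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$trial_table, paths["trials"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a kinematics TSV (t, x, y, z per sample)
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_kinematics_tsv <- function(path) {
  utils::read.delim(path, sep = "\t")
}

#' Read a trial table TSV
#'
#' @param path file path.
#' @return data.frame with one row per trial.
#' @export
read_trial_table_tsv <- function(path) {
  utils::read.delim(path, sep = "\t")
}

#' Serialize an accuracy table or statistics report to TSV
#'
#' @param x data.frame.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_report_tsv <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest (seeds, configuration hash, timings) as JSON
#'
#' @param manifest manifest list from [run_pipeline()].
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_manifest_json <- function(manifest, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
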