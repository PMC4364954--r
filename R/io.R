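#' Read coded trials from CSV
#'
#' Reads a trial-level CSV file into a validated [dyad_dataset()]. The file
#' must be UTF-8, comma-separated, with a header row and exactly these
#' columns in order: `dyad_id`, `experiment`, `age_group`, `gender`,
#' `familiarity`, `trial_index`, `outcome`, `tray`, `large_recipient`,
#' `protest`, `change_of_tray`. Enum values use the lowercase spellings of
#' the schema and booleans are written `true`/`false`.
#'
#' @param path Path to the CSV file.
#' @param design The [tray_design()] the trials were collected under.
#' @return A [dyad_dataset()].
#' @seealso [write_trials()] for the inverse operation.
#' @export
read_trials <- function(path, design) {
  if (!file.exists(path)) abort(sprintf("Trials file not found: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!identical(names(raw), .trial_columns)) {
    abort(sprintf(
      "Unexpected CSV header. Expected columns (in order): %s; got: %s",
      toString(.trial_columns), toString(names(raw))
    ))
  }
  bad_bool <- which(!(raw$change_of_tray %in% c("true", "false")))
  if (length(bad_bool) > 0) {
    abort(sprintf(
      "Invalid trial data (row %d, field `change_of_tray`): expected 'true' or 'false', got '%s'",
      bad_bool[1], raw$change_of_tray[bad_bool[1]]
    ))
  }
  bad_int <- which(is.na(suppressWarnings(as.integer(raw$trial_index))))
  if (length(bad_int) > 0) {
    abort(sprintf(
      "Invalid trial data (row %d, field `trial_index`): expected an integer, got '%s'",
      bad_int[1], raw$trial_index[bad_int[1]]
    ))
  }
  raw$trial_index <- as.integer(raw$trial_index)
  raw$experiment <- suppressWarnings(as.integer(raw$experiment))
  raw$change_of_tray <- raw$change_of_tray == "true"
  dyad_dataset(design, raw)
}

#' Write coded trials to canonical CSV
#'
#' Emits the trial table of a dataset in the canonical format read by
#' [read_trials()]: fixed column order, lowercase enum spellings, booleans
#' as `true`/`false`, Unix newlines, rows in dyad-then-trial order.
#' `write_trials()` and `read_trials()` are mutual inverses on canonical
#' files, byte for byte.
#'
#' @param dataset A [dyad_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(dataset, path) {
  stopifnot(inherits(dataset, "dyad_dataset"))
  out <- dataset$trials[.trial_columns]
  out$change_of_tray <- ifelse(out$change_of_tray, "true", "false")
  readr::write_csv(out, path, eol = "\n", progress = FALSE)
  invisible(path)
}
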