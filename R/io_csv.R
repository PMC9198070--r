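# CSV derivative dialect: comma-separated, header row of channel names, one
# sample per row, amplitudes in uV. A JSON sidecar of the same base name
# carries sampling rate, condition, session and subject metadata.

#' Write a recording as a CSV derivative plus JSON sidecar
#'
#' @param rec an `eeg_recording`.
#' @param dir output directory (created if needed).
#' @param base file base name; default is the recording's entry name.
#' @return character vector of the two written paths (csv, json), invisibly.
#' @export
write_csv_derivative <- function(rec, dir, base = NULL) {
  if (is.null(base)) {
    base <- format_entry_name(rec$participant_id, rec$session, rec$condition)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(base, ".csv"))
  json <- file.path(dir, paste0(base, ".json"))
  dt <- data.table::as.data.table(t(rec$data))
  data.table::setnames(dt, rec$channels)
  data.table::fwrite(dt, csv)
  meta <- list(participant_id = rec$participant_id,
               session = rec$session,
               condition = rec$condition,
               sampling_rate = rec$srate,
               units = "uV",
               n_channels = nrow(rec$data),
               n_samples = ncol(rec$data))
  if (!is.na(rec$age)) meta$age <- rec$age
  if (!is.na(rec$gender)) meta$gender <- rec$gender
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}

#' Read a CSV derivative recording
#'
#' @param path path to the `.csv` data file.
#' @param sidecar path to the JSON sidecar; defaults to the same base name
#'   with `.json`.
#' @return an `eeg_recording`.
#' @export
read_csv_derivative <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("csv file not found: ", path)
  if (is.null(sidecar)) sidecar <- sub("\\.csv$", ".json", path)
  if (!file.exists(sidecar)) stop("sidecar file not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  # fread downgrades structural problems (ragged rows, early stop) to
  # warnings; treat them as hard errors for a data file
  dt <- withCallingHandlers(
    data.table::fread(path, header = TRUE, sep = ",",
                      colClasses = "numeric", fill = FALSE,
                      showProgress = FALSE),
    warning = function(w) stop("malformed csv ", path, ": ",
                               conditionMessage(w)))
  mat <- t(as.matrix(dt))
  if (any(!is.finite(mat))) {
    stop("csv contains missing or non-numeric cells: ", path)
  }
  if (!is.null(meta$n_samples) && ncol(mat) != meta$n_samples) {
    stop("csv has ", ncol(mat), " samples but sidecar declares ",
         meta$n_samples, ": ", path)
  }
  new_recording(mat, channels = canonical_channel_names(colnames(dt)),
                srate = meta$sampling_rate %||% 500,
                participant_id = meta$participant_id %||% "00000000",
                session = meta$session %||% 1L,
                condition = meta$condition %||% "EO",
                age = meta$age %||% NA_real_,
                gender = meta$gender %||% NA_character_)
}

#' Read a participants table
#'
#' Reads the dataset-level `participants.tsv` (and optional `participants.json`
#' field descriptions). Rows whose id starts with `sub-19` belong to the
#' blinded replication subset and are flagged. Columns beyond the required
#' ones are passed through untouched.
#'
#' @param tsv_path path to `participants.tsv`.
#' @param json_path optional path to `participants.json`.
#' @return data frame with at least `participant_id`, `age` (numeric, NA when
#'   missing), `gender`, `indication` and logical `replication_flag`; the
#'   sidecar, when given, is attached as attribute `"fields"`.
#' @export
read_participants <- function(tsv_path, json_path = NULL) {
  if (!file.exists(tsv_path)) stop("participants file not found: ", tsv_path)
  tab <- utils::read.delim(tsv_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("", "n/a", "NA"))
  required <- c("participant_id", "age", "gender")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("participants table is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  if (!"indication" %in% names(tab)) tab$indication <- NA_character_
  tab$age <- suppressWarnings(as.numeric(tab$age))
  tab$replication_flag <- startsWith(as.character(tab$participant_id), "sub-19")
  if (!is.null(json_path) && file.exists(json_path)) {
    attr(tab, "fields") <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  }
  tab
}

#' List condition files of a dataset directory
#'
#' Walks the `sub-<id>/ses-<n>/eeg/` tree and returns every CSV derivative
#' found, with its parsed entry name.
#'
#' @param dir dataset root directory.
#' @return data frame with columns `path`, `participant_id`, `session`,
#'   `condition`.
#' @export
list_condition_files <- function(dir) {
  paths <- list.files(dir, pattern = "\\.csv$", recursive = TRUE,
                      full.names = TRUE)
  paths <- paths[basename(paths) != "participants.csv"]
  rows <- lapply(paths, function(p) {
    parsed <- tryCatch(parse_entry_name(basename(p)), error = function(e) NULL)
    if (is.null(parsed)) return(NULL)
    data.frame(path = p, participant_id = parsed$participant_id,
               session = parsed$session, condition = parsed$condition,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(path = character(), participant_id = character(),
                      session = integer(), condition = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
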