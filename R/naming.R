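#' Parse a condition-file entry name
#'
#' Dataset entries follow `<8-digit participant id>-<session>.<CONDITION>`,
#' e.g. `"19530428-1.EO"`. The condition code has at most 4 characters.
#'
#' @param name entry name (any `.csv`/`.json` extension is stripped first).
#' @return list with `participant_id` (character), `session` (integer) and
#'   `condition` (character).
#' @seealso [format_entry_name()]
#' @export
parse_entry_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  base <- sub("\\.(csv|json|vhdr|vmrk|eeg)$", "", name, ignore.case = TRUE)
  m <- regmatches(base, regexec("^([0-9]+)-([0-9]+)\\.([A-Za-z0-9]+)$", base))[[1]]
  if (length(m) == 0) {
    stop("malformed entry name '", name,
         "': expected <8 digits>-<session>.<condition>")
  }
  if (nchar(m[2]) != 8) {
    stop("malformed entry name '", name, "': participant id must have ",
         "exactly 8 digits, got ", nchar(m[2]))
  }
  if (nchar(m[4]) > 4) {
    stop("malformed entry name '", name,
         "': condition must have at most 4 characters")
  }
  session <- as.integer(m[3])
  if (session < 1) stop("malformed entry name '", name, "': session must be >= 1")
  list(participant_id = m[2], session = session, condition = m[4])
}

#' Format a condition-file entry name
#'
#' Inverse of [parse_entry_name()].
#'
#' @param participant_id 8-digit identifier.
#' @param session positive integer.
#' @param condition condition code, at most 4 characters.
#' @return entry name string.
#' @export
format_entry_name <- function(participant_id, session, condition) {
  if (!grepl("^[0-9]{8}$", participant_id)) {
    stop("participant_id must be exactly 8 digits, got '", participant_id, "'")
  }
  if (nchar(condition) > 4 || nchar(condition) == 0) {
    stop("condition must have 1-4 characters")
  }
  sprintf("%s-%d.%s", participant_id, as.integer(session), condition)
}
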