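# BrainVision Core Data Format: an INI-style .vhdr text header pointing at a
# flat binary .eeg data file (and an optional .vmrk marker file). Only the
# dialect used by resting-state recordings of this kind is supported:
# MULTIPLEXED orientation with INT_16 or IEEE_FLOAT_32 samples.

.bv_parse_header <- function(lines) {
  sec <- NULL
  out <- list()
  for (ln in lines) {
    ln <- sub("\\r$", "", ln)
    if (grepl("^\\s*($|;)", ln)) next
    m <- regmatches(ln, regexec("^\\[(.+)\\]\\s*$", ln))[[1]]
    if (length(m)) { sec <- m[2]; out[[sec]] <- list(); next }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) && !is.null(sec)) out[[sec]][[trimws(kv[2])]] <- trimws(kv[3])
  }
  out
}

#' Read a BrainVision recording
#'
#' Reads the `.vhdr` text header and the binary data file it references.
#' Supported dialect: `DataFormat=BINARY`, `DataOrientation=MULTIPLEXED`,
#' `BinaryFormat` `INT_16` (scaled by the per-channel resolution) or
#' `IEEE_FLOAT_32`. Anything else is rejected with a descriptive error.
#'
#' @param header_path path to the `.vhdr` file.
#' @param ... metadata overrides passed to [new_recording()] (e.g.
#'   `participant_id`, `session`, `condition`, `age`).
#' @return an [new_recording()] object with amplitudes in uV.
#' @export
read_brainvision <- function(header_path, ...) {
  if (!file.exists(header_path)) stop("header file not found: ", header_path)
  hdr <- .bv_parse_header(readLines(header_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  bi <- hdr[["Binary Infos"]]
  chi <- hdr[["Channel Infos"]]
  if (is.null(ci)) stop("not a BrainVision header (no [Common Infos]): ", header_path)
  if (!identical(toupper(ci$DataFormat %||% "BINARY"), "BINARY")) {
    stop("unsupported DataFormat '", ci$DataFormat, "' (only BINARY)")
  }
  if (!identical(toupper(ci$DataOrientation %||% "MULTIPLEXED"), "MULTIPLEXED")) {
    stop("unsupported DataOrientation '", ci$DataOrientation,
         "' (only MULTIPLEXED)")
  }
  n_ch <- as.integer(ci$NumberOfChannels)
  srate <- 1e6 / as.numeric(ci$SamplingInterval)  # header stores microseconds
  fmt <- toupper(bi$BinaryFormat %||% "INT_16")
  if (!fmt %in% c("INT_16", "IEEE_FLOAT_32")) {
    stop("unsupported BinaryFormat '", fmt,
         "' (only INT_16 and IEEE_FLOAT_32)")
  }

  keys <- sprintf("Ch%d", seq_len(n_ch))
  if (!all(keys %in% names(chi))) {
    stop("header declares ", n_ch, " channels but [Channel Infos] lists ",
         sum(grepl("^Ch[0-9]+$", names(chi))))
  }
  fields <- lapply(chi[keys], function(v) strsplit(v, ",", fixed = TRUE)[[1]])
  ch_names <- vapply(fields, `[`, "", 1)
  resolution <- vapply(fields, function(f) {
    r <- suppressWarnings(as.numeric(f[3]))
    if (is.na(r)) 1 else r
  }, 0)

  data_file <- file.path(dirname(header_path), ci$DataFile)
  if (!file.exists(data_file)) stop("binary data file not found: ", data_file)
  sz <- file.size(data_file)
  bytes <- if (fmt == "INT_16") 2L else 4L
  n_total <- sz %/% (bytes)
  if (n_total %% n_ch != 0) {
    stop("data file size (", sz, " bytes) is not a whole number of ",
         n_ch, "-channel frames")
  }
  n_samp <- n_total %/% n_ch
  con <- file(data_file, "rb")
  on.exit(close(con))
  raw <- if (fmt == "INT_16") {
    readBin(con, "integer", n = n_total, size = 2L, signed = TRUE,
            endian = "little")
  } else {
    readBin(con, "double", n = n_total, size = 4L, endian = "little")
  }
  mat <- matrix(raw, nrow = n_ch, ncol = n_samp)  # multiplexed: ch fastest
  mat <- mat * resolution
  new_recording(mat, channels = canonical_channel_names(ch_names),
                srate = srate, ...)
}

#' Write a recording in BrainVision format
#'
#' Produces the `.vhdr`/`.vmrk`/`.eeg` triplet. `IEEE_FLOAT_32` round-trips
#' within float32 quantization; `INT_16` quantizes to the given resolution.
#'
#' @param rec an `eeg_recording`.
#' @param dir output directory (created if needed).
#' @param base file base name; default is the entry name of `rec`.
#' @param binary_format `"IEEE_FLOAT_32"` (default) or `"INT_16"`.
#' @param resolution uV per integer count for `INT_16`.
#' @return invisibly, the path of the written header file.
#' @export
write_brainvision <- function(rec, dir, base = NULL,
                              binary_format = c("IEEE_FLOAT_32", "INT_16"),
                              resolution = 0.1) {
  binary_format <- match.arg(binary_format)
  if (is.null(base)) {
    base <- format_entry_name(rec$participant_id, rec$session, rec$condition)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vhdr <- file.path(dir, paste0(base, ".vhdr"))
  vmrk <- file.path(dir, paste0(base, ".vmrk"))
  eeg <- file.path(dir, paste0(base, ".eeg"))
  n_ch <- nrow(rec$data)
  res <- if (binary_format == "INT_16") resolution else 1

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", basename(eeg)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / rec$srate, scientific = FALSE)),
    "",
    "[Binary Infos]",
    paste0("BinaryFormat=", binary_format),
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,µV", seq_len(n_ch), rec$channels,
            format(res, scientific = FALSE))
  )
  writeLines(hdr, vhdr, useBytes = TRUE)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "",
               "[Common Infos]",
               paste0("DataFile=", basename(eeg)),
               "",
               "[Marker Infos]",
               sprintf("Mk1=New Segment,,1,1,0,%s",
                       format(Sys.time(), "%Y%m%d%H%M%S000000"))), vmrk)

  con <- file(eeg, "wb")
  on.exit(close(con))
  x <- as.vector(rec$data)  # column-major = multiplexed frames
  if (binary_format == "INT_16") {
    q <- as.integer(round(x / res))
    if (any(abs(q) > 32767)) {
      stop("data exceeds INT_16 range at resolution ", res,
           " uV; increase resolution or use IEEE_FLOAT_32")
    }
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(x, con, size = 4L, endian = "little")
  }
  invisible(vhdr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
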