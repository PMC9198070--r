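#' Built-in 33-channel recording montage
#'
#' The standard cap used throughout this package: 26 scalp EEG electrodes of
#' the international 10-10 system with 3-D cap coordinates, plus 7 auxiliary
#' electrodes (vertical/horizontal EOG pairs, ECG at the clavicle, orbicularis
#' oculi and masseter EMG) that carry no coordinates. Coordinates are used
#' only for relative Euclidean distances (neighbour ranking and repair
#' weights), so their absolute unit is irrelevant.
#'
#' @return An object of class `eeg_montage`: a data frame with columns
#'   `name`, `role` (one of `"EEG"`, `"EOG"`, `"ECG"`, `"EMG"`) and numeric
#'   `x`, `y`, `z` (NA for auxiliary channels).
#' @examples
#' m <- load_builtin_montage()
#' sum(m$role == "EEG")
#' @export
load_builtin_montage <- function() {
  eeg <- data.frame(
    name = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
             "FC3", "FCz", "FC4", "T7", "C3", "Cz", "C4", "T8",
             "CP3", "CPz", "CP4", "P7", "P3", "Pz", "P4", "P8",
             "O1", "Oz", "O2"),
    role = "EEG",
    x = c(-26.81, 29.41, -66.99, -48.05, 0.90, 50.38, 68.71,
          -58.83, 0.57, 60.29, -83.36, -65.57, 0.23, 66.50, 84.44,
          -65.51, -0.42, 65.03, -71.46, -55.07, -0.87, 53.51, 71.10,
          -28.98, -1.41, 26.89),
    y = c(84.06, 83.74, 41.69, 51.87, 57.01, 51.84, 41.16,
          21.02, 24.63, 21.16, -16.52, -13.25, -11.28, -12.80, -16.65,
          -48.48, -48.77, -48.35, -75.17, -80.11, -82.23, -80.13, -75.17,
          -114.52, -117.79, -114.68),
    z = c(-10.56, -10.04, -15.96, 39.87, 66.36, 41.33, -15.31,
          54.82, 87.63, 55.58, -12.65, 64.98, 99.81, 65.11, -11.79,
          68.57, 98.37, 68.57, -3.70, 59.44, 82.43, 59.40, -3.69,
          9.67, 15.84, 9.45),
    stringsAsFactors = FALSE
  )
  aux <- data.frame(
    name = c("VPVA", "VNVB", "HOHL", "HNHR", "Erbs", "OrbOcc", "Mass"),
    role = c("EOG", "EOG", "EOG", "EOG", "ECG", "EMG", "EMG"),
    x = NA_real_, y = NA_real_, z = NA_real_,
    stringsAsFactors = FALSE
  )
  m <- rbind(eeg, aux)
  class(m) <- c("eeg_montage", "data.frame")
  m
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels (%d EEG, %d auxiliary)\n",
              nrow(x), sum(x$role == "EEG"), sum(x$role != "EEG")))
  print.data.frame(x, ...)
  invisible(x)
}

# Legacy aliases occasionally seen in channel tables / headers.
.channel_aliases <- c("P7/T5" = "P7", "T5" = "P7",
                      "P8/T6" = "P8", "T6" = "P8",
                      "MASS" = "Mass")

#' Canonicalize channel names against the built-in montage
#'
#' Matching is case-insensitive and accepts the legacy temporal labels
#' T5/T6 (alias of P7/P8).
#'
#' @param names character vector of channel names.
#' @param montage montage to match against (default [load_builtin_montage()]).
#' @return character vector of canonical names; unknown names are returned
#'   unchanged.
#' @export
canonical_channel_names <- function(names, montage = load_builtin_montage()) {
  out <- as.character(names)
  hit <- match(toupper(out), toupper(names(.channel_aliases)))
  out[!is.na(hit)] <- unname(.channel_aliases[hit[!is.na(hit)]])
  hit <- match(toupper(out), toupper(montage$name))
  out[!is.na(hit)] <- montage$name[hit[!is.na(hit)]]
  out
}

#' Pairwise Euclidean distances between EEG electrodes
#'
#' @param montage an `eeg_montage`.
#' @return symmetric matrix of distances between the EEG-role channels, with
#'   dimnames set to channel names and zero diagonal.
#' @export
montage_distances <- function(montage = load_builtin_montage()) {
  e <- montage[montage$role == "EEG", , drop = FALSE]
  xyz <- as.matrix(e[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(e$name, e$name)
  d
}

#' Nearest EEG neighbours of an EEG channel
#'
#' @param channel channel name.
#' @param montage an `eeg_montage`.
#' @param k number of neighbours to return.
#' @return data frame with columns `name` and `distance`, nearest first; the
#'   channel itself is excluded.
#' @export
nearest_neighbors <- function(channel, montage = load_builtin_montage(), k = 3) {
  d <- montage_distances(montage)
  if (!channel %in% rownames(d)) {
    stop("not an EEG channel in this montage: ", channel)
  }
  v <- d[channel, ]
  v <- v[names(v) != channel]
  v <- sort(v)
  k <- min(k, length(v))
  data.frame(name = names(v)[seq_len(k)], distance = unname(v[seq_len(k)]),
             stringsAsFactors = FALSE)
}
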