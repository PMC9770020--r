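#' Multichannel iEEG recording container
#'
#' A `Recording` is a channels-by-samples numeric matrix in microvolts plus a
#' sampling rate and unique channel labels. All pipeline stages consume and
#' return this container.
#'
#' @param data numeric matrix, one row per channel, values in uV.
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param channel_labels character vector of unique labels, one per row.
#' @param start_time optional POSIXct start timestamp.
#' @return An object of class `ieeg_recording`.
#' @export
recording <- function(data, fs, channel_labels = rownames(data),
                      start_time = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_labels))
    channel_labels <- paste0("CH", seq_len(nrow(data)))
  channel_labels <- as.character(channel_labels)
  if (nrow(data) < 1L) stop("a recording needs at least one channel")
  if (length(channel_labels) != nrow(data))
    stop("one label per channel is required")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         start_time = start_time),
    class = "ieeg_recording"
  )
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("<ieeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, duration_s(x)))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "...", "\n")
  invisible(x)
}

#' Number of channels in a recording
#' @param rec an `ieeg_recording`.
#' @return integer channel count.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' Duration of a recording in seconds
#' @param rec an `ieeg_recording`.
#' @return duration in seconds.
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Subset a recording by channel
#' @param rec an `ieeg_recording`.
#' @param labels channel labels to keep (order preserved as given).
#' @return an `ieeg_recording` with the selected channels.
#' @export
select_channels <- function(rec, labels) {
  missing <- setdiff(labels, rec$channel_labels)
  if (length(missing))
    stop("channel(s) not present in recording: ",
         paste(missing, collapse = ", "))
  recording(rec$data[labels, , drop = FALSE], rec$fs, labels, rec$start_time)
}

#' Extract a time segment from a recording
#' @param rec an `ieeg_recording`.
#' @param onset_ms segment onset in ms from the start of the recording.
#' @param duration_ms segment duration in ms (> 0).
#' @return an `ieeg_recording` covering the requested segment.
#' @export
extract_segment <- function(rec, onset_ms, duration_ms) {
  if (duration_ms <= 0) stop("duration_ms must be positive")
  i0 <- floor(onset_ms / 1000 * rec$fs) + 1L
  i1 <- i0 + round(duration_ms / 1000 * rec$fs) - 1L
  if (i0 < 1L || i1 > ncol(rec$data))
    stop("segment extends beyond the recording")
  recording(rec$data[, i0:i1, drop = FALSE], rec$fs, rec$channel_labels,
            rec$start_time)
}

#' Read a channel metadata table
#'
#' Expected columns: `label`, `x_mm`, `y_mm`, `z_mm` (MNI millimetres, RAS),
#' `region` (one of M/L/E: mesial temporal, lateral temporal, extratemporal),
#' `soz` (0/1 seizure-onset-zone flag), `hemisphere` (L/R),
#' `gray_matter` (0/1), `noise_free` (0/1).
#'
#' @param path path to a tab-separated file with a header row.
#' @return a tibble with validated columns.
#' @export
read_channel_metadata <- function(path) {
  meta <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_channel_metadata(tibble::as_tibble(meta))
}

#' Validate a channel metadata table
#' @param meta a data frame of channel metadata.
#' @return the validated tibble (invisibly coerced types).
#' @export
validate_channel_metadata <- function(meta) {
  required <- c("label", "x_mm", "y_mm", "z_mm", "region", "soz",
                "hemisphere", "gray_matter", "noise_free")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(meta$label)) stop("metadata labels must be unique")
  bad_region <- setdiff(unique(meta$region), c("M", "L", "E"))
  if (length(bad_region))
    stop("unknown region code(s): ", paste(bad_region, collapse = ", "))
  bad_hemi <- setdiff(unique(meta$hemisphere), c("L", "R"))
  if (length(bad_hemi))
    stop("unknown hemisphere code(s): ", paste(bad_hemi, collapse = ", "))
  for (col in c("soz", "gray_matter", "noise_free")) {
    v <- meta[[col]]
    if (!all(v %in% c(0, 1, TRUE, FALSE)))
      stop("column '", col, "' must be 0/1")
    meta[[col]] <- as.integer(v)
  }
  tibble::as_tibble(meta)
}

#' Load a recording from file, restricted to analyzable channels
#'
#' Reads an EDF file (16-bit) or a delimited numeric matrix (one row per
#' channel; optional first column of labels) and keeps only the channels the
#' metadata marks as in gray matter and free of electrical noise. The
#' sampling rate is preserved as stored (EDF) or must be supplied (text).
#'
#' @param path path to a `.edf` file or a delimited text matrix.
#' @param metadata channel metadata table (see [read_channel_metadata()]);
#'   every metadata label must be present in the file.
#' @param fs sampling rate in Hz, required for text input, ignored for EDF.
#' @param scale multiplicative amplitude scale applied at load (signals are
#'   analyzed in uV; the event-detection threshold is amplitude-dependent).
#' @return an `ieeg_recording` containing the retained channels.
#' @export
load_recording <- function(path, metadata, fs = NULL, scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  metadata <- validate_channel_metadata(metadata)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    rec <- read_edf(path)
  } else {
    tab <- utils::read.delim(path, header = FALSE, sep = "",
                             stringsAsFactors = FALSE)
    if (is.character(tab[[1]]) || is.factor(tab[[1]])) {
      labels <- as.character(tab[[1]])
      mat <- as.matrix(tab[, -1, drop = FALSE])
    } else {
      labels <- paste0("CH", seq_len(nrow(tab)))
      mat <- as.matrix(tab)
    }
    storage.mode(mat) <- "double"
    if (is.null(fs)) stop("fs is required for delimited matrix input")
    rec <- recording(mat, fs, labels)
  }
  missing <- setdiff(metadata$label, rec$channel_labels)
  if (length(missing))
    stop("metadata label(s) absent from recording: ",
         paste(missing, collapse = ", "))
  keep <- metadata$label[metadata$gray_matter == 1L & metadata$noise_free == 1L]
  if (!length(keep)) stop("no channels pass the gray-matter/noise-free filter")
  rec <- select_channels(rec, keep)
  if (scale != 1) rec$data <- rec$data * scale
  rec
}

#' Filter segment annotations by the interictal selection criteria
#'
#' Implements the metadata-driven segment selection used for interictal
#' analysis: quiet wakefulness, a minimum delay after electrode implantation,
#' a minimum distance to the next seizure, and recording before medication
#' taper. Criteria set to `NULL` are not applied.
#'
#' @param annotations data frame with columns `onset_ms`, `duration_ms`,
#'   `state_label`, `post_implant_h`, `hours_to_next_seizure`, `pre_taper`.
#' @param state required state label (default "quiet_wakefulness").
#' @param min_post_implant_h minimum hours since implantation (default 24).
#' @param min_hours_to_seizure minimum hours to the next seizure (default 6).
#' @param require_pre_taper require the pre-taper flag (default TRUE).
#' @return the subset of rows passing all criteria.
#' @export
filter_segments <- function(annotations,
                            state = "quiet_wakefulness",
                            min_post_implant_h = 24,
                            min_hours_to_seizure = 6,
                            require_pre_taper = TRUE) {
  if (any(annotations$duration_ms <= 0))
    stop("segment durations must be positive")
  keep <- rep(TRUE, nrow(annotations))
  if (!is.null(state)) keep <- keep & annotations$state_label == state
  if (!is.null(min_post_implant_h))
    keep <- keep & annotations$post_implant_h > min_post_implant_h
  if (!is.null(min_hours_to_seizure))
    keep <- keep & annotations$hours_to_next_seizure >= min_hours_to_seizure
  if (isTRUE(require_pre_taper) && "pre_taper" %in% names(annotations))
    keep <- keep & as.logical(annotations$pre_taper)
  annotations[keep, , drop = FALSE]
}
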