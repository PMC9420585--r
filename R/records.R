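#' Recognised pulse morphology types
#'
#' The seven waveform categories handled by the simulator and the reports:
#' three-peak `normal`, the bimodal slippery family (`slippery`,
#' `fine_slippery`, `string_slippery`) with a clear dicrotic notch, and the
#' "flat top" string/fine family (`string`, `fine`, `fine_string`) whose
#' tidal wave merges with the main wave and whose notch is weak.
#'
#' @export
pulse_types <- c(
  "normal", "slippery", "fine_slippery", "string_slippery",
  "string", "fine", "fine_string"
)

#' Construct a pulse record
#'
#' A `pulse_record` is a single-channel arterial pulse waveform with its
#' sampling rate, morphology tag and identifier. All sample indices used by
#' this package are 1-based inside R; files on disk use 0-based half-open
#' intervals (see [write_intervals()]).
#'
#' @param samples numeric vector of amplitudes (arbitrary units), all finite.
#' @param fs sampling rate in Hz (default 720).
#' @param pulse_type one of [pulse_types].
#' @param record_id identifier string.
#' @param meta optional named list of provenance flags (e.g. `preprocessed`).
#' @return an object of class `pulse_record`.
#' @export
pulse_record <- function(samples, fs = 720, pulse_type = "normal",
                         record_id = "rec", meta = list()) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("samples must be non-empty")
  if (!all(is.finite(samples))) stop("samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  pulse_type <- match.arg(pulse_type, pulse_types)
  structure(
    list(samples = samples, fs = fs, pulse_type = pulse_type,
         record_id = as.character(record_id), meta = meta),
    class = "pulse_record"
  )
}

#' @export
print.pulse_record <- function(x, ...) {
  cat(sprintf("<pulse_record %s: %d samples @ %g Hz (%.2f s), type=%s>\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$pulse_type))
  invisible(x)
}

#' @export
length.pulse_record <- function(x) length(x$samples)

#' Ground truth boundaries for one beat
#'
#' Sample indices (1-based) of the beat onset, the dicrotic notch and the
#' next beat's onset. The systolic phase is `[onset, notch)` and the
#' diastolic phase `[notch, next_onset)` in half-open convention.
#'
#' @param onset,notch,next_onset 1-based sample indices, strictly increasing.
#' @return an object of class `beat_truth`.
#' @export
beat_truth <- function(onset, notch, next_onset) {
  onset <- as.integer(onset); notch <- as.integer(notch)
  next_onset <- as.integer(next_onset)
  if (!(onset < notch && notch < next_onset)) {
    stop("beat_truth requires onset < notch < next_onset")
  }
  structure(list(onset = onset, notch = notch, next_onset = next_onset),
            class = "beat_truth")
}

#' Validate a per-sample label sequence
#'
#' Classes are 0 (background), 1 (systole), 2 (diastole). Within the labeled
#' region runs of 1 and 2 must strictly alternate.
#'
#' @param classes integer vector with values in `{0, 1, 2}`.
#' @return `classes`, invisibly, or an error.
#' @export
validate_labels <- function(classes) {
  if (!all(classes %in% 0:2)) stop("labels must be in {0, 1, 2}")
  r <- rle(classes)
  phase <- r$values[r$values != 0L]
  if (length(phase) > 1L && any(diff(phase) == 0)) {
    stop("systolic/diastolic runs must alternate")
  }
  invisible(classes)
}

#' Convert a label sequence to phase intervals
#'
#' @param classes integer vector in `{0,1,2}`.
#' @param record_id identifier copied into every row.
#' @return data.frame with columns `record_id`, `start`, `end`, `phase`;
#'   `start`/`end` are 0-based half-open sample bounds, `phase` is 1 or 2.
#' @export
labels_to_intervals <- function(classes, record_id = "rec") {
  r <- rle(as.integer(classes))
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  keep <- r$values != 0L
  data.frame(
    record_id = rep(as.character(record_id), sum(keep)),
    start = start[keep], end = end[keep], phase = r$values[keep],
    stringsAsFactors = FALSE
  )
}

#' Convert phase intervals back to a label sequence
#'
#' @param intervals data.frame as produced by [labels_to_intervals()].
#' @param n total signal length in samples.
#' @return integer label vector of length `n`.
#' @export
intervals_to_labels <- function(intervals, n) {
  classes <- integer(n)
  if (nrow(intervals) == 0L) return(classes)
  if (any(intervals$start < 0 | intervals$end > n | intervals$start >= intervals$end)) {
    stop("intervals out of bounds or inverted")
  }
  for (i in seq_len(nrow(intervals))) {
    classes[(intervals$start[i] + 1L):intervals$end[i]] <- intervals$phase[i]
  }
  classes
}

#' Read / write single-column signal files
#'
#' Signals are stored as plain text, one amplitude per line.
#'
#' @param record a [pulse_record()].
#' @param path file path.
#' @export
write_signal <- function(record, path) {
  writeLines(formatC(record$samples, format = "g", digits = 17), path)
  invisible(path)
}

#' @rdname write_signal
#' @param fs,pulse_type,record_id metadata for the loaded record.
#' @export
read_signal <- function(path, fs = 720, pulse_type = "normal",
                        record_id = sub("\\.[^.]*$", "", basename(path))) {
  x <- scan(path, what = numeric(), quiet = TRUE)
  pulse_record(x, fs = fs, pulse_type = pulse_type, record_id = record_id)
}

#' Read / write phase interval files
#'
#' Tab-separated files with columns `record_id`, `start`, `end`, `phase`;
#' sample bounds are 0-based half-open.
#'
#' @param intervals data.frame of intervals.
#' @param path file path.
#' @export
write_intervals <- function(intervals, path) {
  utils::write.table(intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "integer", "integer"))
}
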