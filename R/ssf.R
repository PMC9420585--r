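#' Slope-sum-function configuration
#'
#' Classical windowed slope-sum onset detection with an adaptive threshold,
#' plus a derivative-based dicrotic-notch rule, together yielding a
#' non-learned phase segmentation to compare the sequence labeller against.
#' Window and threshold defaults follow the values conventional for
#' pressure/PPG onset detection (roughly 128 ms window, 60% adaptive
#' threshold, 300 ms refractory).
#'
#' @param window_s slope-sum window length in seconds (default 0.13).
#' @param threshold_frac threshold as a fraction of the running median of
#'   recent SSF peak heights (default 0.6).
#' @param refractory_s minimum spacing between onsets in seconds
#'   (default 0.3).
#' @param notch_search search window for the notch, as fractions of the
#'   beat length measured from the systolic peak (default `c(0.15, 0.6)`).
#' @return object of class `ssf_config`.
#' @export
ssf_config <- function(window_s = 0.13, threshold_frac = 0.6,
                       refractory_s = 0.3, notch_search = c(0.15, 0.6)) {
  if (window_s <= 0) stop("window_s must be positive")
  if (threshold_frac <= 0 || threshold_frac >= 1) stop("threshold_frac must be in (0, 1)")
  if (refractory_s <= 0) stop("refractory_s must be positive")
  if (length(notch_search) != 2L || notch_search[1] >= notch_search[2]) {
    stop("notch_search must be an increasing fraction pair")
  }
  structure(list(window_s = window_s, threshold_frac = threshold_frac,
                 refractory_s = refractory_s, notch_search = notch_search),
            class = "ssf_config")
}

#' Windowed slope sum function
#'
#' `ssf[k] = sum_{i = k-w+1 .. k} max(x[i] - x[i-1], 0)`, with the first
#' difference at the start defined as 0 and the first `w` values using the
#' available prefix. Rising edges accumulate; falling edges contribute
#' nothing, so the transform is non-negative and peaks on the systolic
#' upstroke.
#'
#' @param samples numeric signal.
#' @param window_w window length in samples.
#' @return numeric vector, same length as `samples`.
#' @export
ssf_transform <- function(samples, window_w) {
  n <- length(samples)
  window_w <- as.integer(window_w)
  if (window_w < 1L) stop("window_w must be >= 1")
  if (window_w >= n) stop("window_w must be smaller than the signal length")
  d <- pmax(c(0, diff(samples)), 0)
  cs <- cumsum(d)
  lag <- c(rep(0, window_w), cs[seq_len(n - window_w)])
  cs - lag
}

#' Detect beat onsets from a slope-sum signal
#'
#' Adaptive thresholding: the threshold is `threshold_frac` times the running
#' median of the last five accepted SSF peak heights, initialised from the
#' global 90th percentile of the SSF. Each upward threshold crossing is
#' resolved to the local SSF peak ahead of it; the onset is the nearest
#' preceding sample where the SSF falls below 1% of that peak. Crossings
#' within the refractory period of the previous onset are suppressed.
#' The threshold adapts multiplicatively, so scaling the input rescales
#' nothing in the detected indices.
#'
#' @param ssf slope-sum signal from [ssf_transform()].
#' @param cfg an [ssf_config()].
#' @param fs sampling rate in Hz.
#' @return strictly increasing integer vector of onset indices (possibly
#'   empty).
#' @export
detect_onsets <- function(ssf, cfg = ssf_config(), fs = 720) {
  n <- length(ssf)
  refractory <- round(cfg$refractory_s * fs)
  peak_ahead <- max(1L, round(0.25 * fs))   # local-peak resolution horizon
  init <- stats::quantile(ssf, 0.9, names = FALSE)
  if (init <= 0) return(integer(0))
  ssf_median <- stats::median(ssf)
  recent_peaks <- numeric(0)
  onsets <- integer(0)
  thr <- cfg$threshold_frac * init
  k <- 2L
  last_onset <- -Inf
  while (k <= n) {
    if (ssf[k] >= thr && ssf[k - 1L] < thr) {
      hi <- min(n, k + peak_ahead)
      peak <- max(ssf[k:hi])
      # backward search for the foot: nearest sample below 1% of the peak;
      # residual noise gives the SSF a pedestal that can sit above 1%, so
      # the floor is raised to the SSF median (the pedestal level) and the
      # search is bounded to 0.25 s, falling back to the latest minimal
      # sample in that window
      foot_floor <- max(0.01 * peak, ssf_median)
      lb <- max(1L, k - as.integer(round(0.25 * fs)))
      j <- k
      while (j > lb && ssf[j] > foot_floor) j <- j - 1L
      if (ssf[j] > foot_floor) {
        idx <- lb:k
        j <- max(idx[ssf[idx] <= min(ssf[idx]) + 1e-12])
      }
      if (j - last_onset >= refractory) {
        onsets <- c(onsets, j)
        last_onset <- j
        recent_peaks <- utils::tail(c(recent_peaks, peak), 5L)
        thr <- cfg$threshold_frac * stats::median(recent_peaks)
      }
      k <- k + max(1L, refractory %/% 2L)
    } else {
      k <- k + 1L
    }
  }
  onsets
}

#' Locate the dicrotic notch within one beat
#'
#' The systolic peak is the beat's maximum; the notch is searched in the
#' window from `notch_search[1]` to `notch_search[2]` beat-lengths after it.
#' If the signal has an interior local minimum there, the deepest one is the
#' notch; for notch-less "flat top" beats the fallback is the sample where
#' the first derivative's magnitude is smallest (the inflection surrogate),
#' flagged via the `fallback` field.
#'
#' @param samples numeric signal.
#' @param onset_pair `c(onset, next_onset)` (1-based, >= 0.3 s apart).
#' @param cfg an [ssf_config()].
#' @param fs sampling rate in Hz.
#' @return list with `notch` (index or `NA`), `fallback` (logical), and
#'   `ok` (FALSE when the window was degenerate).
#' @export
detect_notch <- function(samples, onset_pair, cfg = ssf_config(), fs = 720) {
  onset <- onset_pair[1]; next_onset <- onset_pair[2]
  beat_len <- next_onset - onset
  if (beat_len < 0.3 * fs) {
    return(list(notch = NA_integer_, fallback = FALSE, ok = FALSE))
  }
  seg <- samples[onset:(next_onset - 1L)]
  peak <- which.max(seg)
  lo <- onset + peak - 1L + round(cfg$notch_search[1] * beat_len)
  hi <- onset + peak - 1L + round(cfg$notch_search[2] * beat_len)
  hi <- min(hi, next_onset - 2L)
  if (hi - lo < 2L) {
    return(list(notch = NA_integer_, fallback = FALSE, ok = FALSE))
  }
  w <- samples[lo:hi]
  interior <- which(diff(sign(diff(w))) > 0) + 1L   # local minima
  if (length(interior) > 0) {
    # the notch is the minimum whose rebound (rise to the next local
    # maximum) is largest: the dicrotic wave gives the true notch a tall
    # rebound, while ripples on the decaying diastolic tail rebound barely
    maxima <- which(diff(sign(diff(w))) < 0) + 1L
    rebound <- vapply(interior, function(i) {
      nxt <- maxima[maxima > i]
      hi_val <- if (length(nxt)) w[nxt[1]] else w[length(w)]
      hi_val - w[i]
    }, numeric(1))
    notch <- lo + interior[which.max(rebound)] - 1L
    return(list(notch = notch, fallback = FALSE, ok = TRUE))
  }
  dw <- abs(diff(w))
  notch <- lo + which.min(dw) - 1L
  list(notch = notch, fallback = TRUE, ok = TRUE)
}

#' Slope-sum-function phase segmentation
#'
#' Full baseline pipeline: slope-sum transform, adaptive-threshold onset
#' detection, per-beat notch location, then labels 1 on `[onset, notch)`,
#' 2 on `[notch, next_onset)` and 0 outside complete beats. Beats whose
#' notch is undefined are labelled entirely systolic and flagged.
#'
#' @param record a [pulse_record()] (preprocess first for noisy input).
#' @param cfg an [ssf_config()].
#' @return object of class `segmentation_result`: list with `classes`,
#'   `segments` (interval data.frame), `onsets`, and `flags` (per-beat
#'   notch fallback/undefined markers).
#' @export
ssf_segment <- function(record, cfg = ssf_config()) {
  x <- record$samples
  fs <- record$fs
  ssf <- ssf_transform(x, round(cfg$window_s * fs))
  onsets <- detect_onsets(ssf, cfg, fs)
  n <- length(x)
  classes <- integer(n)
  flags <- character(0)
  if (length(onsets) >= 2L) {
    for (b in seq_len(length(onsets) - 1L)) {
      on <- onsets[b]; nxt <- onsets[b + 1L]
      nd <- detect_notch(x, c(on, nxt), cfg, fs)
      if (!nd$ok || is.na(nd$notch)) {
        classes[on:(nxt - 1L)] <- 1L
        flags <- c(flags, "undefined")
      } else {
        classes[on:(nd$notch - 1L)] <- 1L
        classes[nd$notch:(nxt - 1L)] <- 2L
        flags <- c(flags, if (nd$fallback) "fallback" else "ok")
      }
    }
  }
  structure(list(classes = classes,
                 segments = labels_to_intervals(classes, record$record_id),
                 onsets = onsets, flags = flags, probs = NULL),
            class = "segmentation_result")
}
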