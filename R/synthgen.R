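#' Beat shape parameters
#'
#' One beat is modelled as a mixture of three Gaussians on the beat interval:
#' the main (percussion) wave, the tidal wave / dicrotic prewave, and the
#' dicrotic wave. Centers and widths are expressed as fractions of the beat
#' period so the same shape serves any heart rate. The dicrotic-wave
#' amplitude must be at least 5% of the main amplitude so a notch region
#' exists between the second and third components.
#'
#' @param period_s beat period in seconds.
#' @param amps three non-negative amplitudes `(main, tidal, dicrotic)`;
#'   `amps[1]` must strictly dominate `amps[2]` and `amps[3]`, and
#'   `amps[3] >= 0.05 * amps[1]`.
#' @param centers three Gaussian centers, strictly increasing in `(0, 1)`.
#' @param widths three positive Gaussian standard deviations (period
#'   fractions).
#' @return object of class `beat_params`.
#' @export
beat_params <- function(period_s = 0.8,
                        amps = c(1, 0.45, 0.30),
                        centers = c(0.15, 0.35, 0.55),
                        widths = c(0.055, 0.07, 0.07)) {
  stopifnot(length(amps) == 3L, length(centers) == 3L, length(widths) == 3L)
  if (!all(is.finite(c(period_s, amps, centers, widths)))) {
    stop("beat parameters must be finite")
  }
  if (period_s <= 0) stop("period_s must be positive")
  if (any(amps < 0)) stop("amplitudes must be non-negative")
  if (!(amps[1] > amps[2] && amps[1] > amps[3])) {
    stop("the main-wave amplitude must dominate the tidal and dicrotic waves")
  }
  if (amps[3] < 0.05 * amps[1]) {
    stop("dicrotic-wave amplitude must be >= 5% of the main wave (notch region)")
  }
  if (!(centers[1] > 0 && all(diff(centers) > 0) && centers[3] < 1)) {
    stop("centers must satisfy 0 < c1 < c2 < c3 < 1")
  }
  if (any(widths <= 0)) stop("widths must be positive")
  structure(list(period_s = period_s, amps = amps, centers = centers,
                 widths = widths), class = "beat_params")
}

# continuous three-Gaussian beat model, t in seconds on [0, period)
.beat_model <- function(t, p) {
  mu <- p$centers * p$period_s
  sd <- p$widths * p$period_s
  p$amps[1] * exp(-(t - mu[1])^2 / (2 * sd[1]^2)) +
    p$amps[2] * exp(-(t - mu[2])^2 / (2 * sd[2]^2)) +
    p$amps[3] * exp(-(t - mu[3])^2 / (2 * sd[3]^2))
}

#' Sample one beat and locate its dicrotic notch
#'
#' Evaluates the three-Gaussian beat model over one period and finds the
#' notch as the minimum of the continuous model between the tidal and
#' dicrotic-wave centers, evaluated on a grid ten times denser than the
#' sampling rate and snapped to the nearest output sample. For "flat top"
#' morphologies the model may descend monotonically through that interval;
#' the minimum then sits at its upper edge, mirroring how weak-notch pulses
#' defeat valley-seeking detectors.
#'
#' @param params a [beat_params()].
#' @param fs sampling rate in Hz.
#' @return list with `waveform` (numeric, `round(period_s * fs)` samples) and
#'   `notch_offset` (1-based sample offset of the notch within the beat).
#' @export
make_beat <- function(params, fs = 720) {
  if (!inherits(params, "beat_params")) params <- do.call(beat_params, params)
  n <- round(params$period_s * fs)
  if (n < 4L) stop("period too short at this sampling rate")
  t <- (seq_len(n) - 1L) / fs
  waveform <- .beat_model(t, params)
  lo <- params$centers[2] * params$period_s
  hi <- params$centers[3] * params$period_s
  grid <- seq(lo, hi, by = 1 / (10 * fs))
  tmin <- grid[which.min(.beat_model(grid, params))]
  notch_offset <- min(n, max(1L, round(tmin * fs) + 1L))
  list(waveform = waveform, notch_offset = notch_offset)
}

#' Noise model parameters
#'
#' Additive contaminants emulating what raw wrist-pulse acquisitions carry:
#' broadband sensor noise, 50 Hz powerline pickup, and sub-0.4 Hz sinusoidal
#' respiratory baseline drift. All amplitudes are fractions of the realized
#' main-wave amplitude of the clean record.
#'
#' @param white_sigma standard deviation of white noise.
#' @param powerline_amp amplitude of the 50 Hz tone.
#' @param drift_amp amplitude of the respiratory drift.
#' @param drift_freq drift frequency in Hz, within `[0.15, 0.35]`.
#' @param drift_phase drift phase in radians, or `NULL` to draw it from the
#'   record's seeded RNG stream.
#' @return object of class `noise_params`.
#' @export
noise_params <- function(white_sigma = 0.03, powerline_amp = 0.05,
                         drift_amp = 0.4, drift_freq = 0.25,
                         drift_phase = NULL) {
  if (any(c(white_sigma, powerline_amp, drift_amp) < 0)) {
    stop("noise amplitudes must be non-negative")
  }
  if (drift_freq < 0.15 || drift_freq > 0.35) {
    stop("drift_freq must lie in [0.15, 0.35] Hz (below the 0.4 Hz respiration bound)")
  }
  structure(list(white_sigma = white_sigma, powerline_amp = powerline_amp,
                 drift_amp = drift_amp, drift_freq = drift_freq,
                 drift_phase = drift_phase), class = "noise_params")
}

#' Morphology presets for the seven pulse types
#'
#' Shape parameters chosen to realize the qualitative descriptions of the
#' seven categories: `normal` has three distinct peaks; the slippery family
#' is bimodal with the tidal wave merged into the main wave and a clear
#' dicrotic wave; the string/fine family forms a "flat top" whose tidal wave
#' sits close to the main wave at ~0.9x its amplitude and whose dicrotic
#' wave is weak (<= 0.15x), leaving only a shallow, hard-to-see notch. The
#' `fine` variants are the same shapes at reduced overall amplitude.
#' These presets are this package's invention; they are plausible, not
#' clinically validated.
#'
#' @return named list of parameter lists (`amps`, `centers`, `widths`).
#' @export
pulse_type_presets <- function() {
  list(
    normal          = list(amps = c(1.00, 0.45, 0.30),
                           centers = c(0.15, 0.35, 0.55),
                           widths = c(0.055, 0.07, 0.07)),
    slippery        = list(amps = c(1.00, 0.55, 0.35),
                           centers = c(0.15, 0.22, 0.45),
                           widths = c(0.055, 0.07, 0.06)),
    fine_slippery   = list(amps = c(0.55, 0.30, 0.19),
                           centers = c(0.15, 0.22, 0.44),
                           widths = c(0.055, 0.07, 0.06)),
    string_slippery = list(amps = c(1.00, 0.75, 0.30),
                           centers = c(0.17, 0.24, 0.42),
                           widths = c(0.07, 0.08, 0.06)),
    string          = list(amps = c(1.00, 0.90, 0.13),
                           centers = c(0.20, 0.26, 0.30),
                           widths = c(0.10, 0.10, 0.09)),
    fine            = list(amps = c(0.50, 0.45, 0.065),
                           centers = c(0.20, 0.26, 0.30),
                           widths = c(0.10, 0.10, 0.09)),
    fine_string     = list(amps = c(0.62, 0.558, 0.08),
                           centers = c(0.19, 0.26, 0.29),
                           widths = c(0.10, 0.105, 0.09))
  )
}

#' Generate one synthetic pulse record with ground truth
#'
#' Concatenates beats of the requested morphology with per-beat period
#' jitter, records exact onset/notch/next-onset truth for every complete
#' beat, builds the per-sample label sequence (1 systole, 2 diastole, 0
#' background before the first onset and after the last complete beat), and
#' finally adds noise. Same seed, same output.
#'
#' @param pulse_type one of [pulse_types].
#' @param n_samples record length (default 2160 samples, i.e. 3 s at 720 Hz).
#' @param fs sampling rate in Hz.
#' @param hr_bpm mean heart rate; the default 75 bpm corresponds to the
#'   0.27 s + 0.53 s systolic + diastolic ventricular timing (0.8 s beats).
#' @param hr_jitter fractional standard deviation of the per-beat period.
#' @param noise a [noise_params()].
#' @param seed integer seed.
#' @return list with `record` ([pulse_record()]), `truths` (list of
#'   [beat_truth()]), and `labels` (integer vector of length `n_samples`).
#' @export
generate_record <- function(pulse_type, n_samples = 2160, fs = 720,
                            hr_bpm = 75, hr_jitter = 0.05,
                            noise = noise_params(), seed = 1L) {
  pulse_type <- match.arg(pulse_type, pulse_types)
  mean_period <- 60 / hr_bpm
  if (n_samples < round(mean_period * fs)) {
    stop("n_samples must hold at least one full beat at hr_bpm")
  }
  preset <- pulse_type_presets()[[pulse_type]]
  set.seed(as.integer(seed))

  draw_period <- function() {
    mean_period * min(1.25, max(0.75, 1 + hr_jitter * stats::rnorm(1)))
  }

  # lead-in: tail of a virtual previous beat, labelled background
  lead_len <- round(stats::runif(1, 0.05, 0.25) * fs)
  p0 <- do.call(beat_params, c(list(period_s = draw_period()), preset))
  b0 <- make_beat(p0, fs)
  lead <- if (lead_len > 0) utils::tail(b0$waveform, lead_len) else numeric(0)

  samples <- numeric(n_samples)
  labels <- integer(n_samples)
  if (lead_len > 0) samples[seq_len(lead_len)] <- lead
  truths <- list()
  pos <- lead_len + 1L  # onset of the next beat, 1-based

  repeat {
    p <- do.call(beat_params, c(list(period_s = draw_period()), preset))
    b <- make_beat(p, fs)
    nb <- length(b$waveform)
    if (pos + nb > n_samples) {
      # partial beat fills the tail, labelled background
      room <- n_samples - pos + 1L
      if (room > 0) samples[pos:n_samples] <- b$waveform[seq_len(room)]
      break
    }
    samples[pos:(pos + nb - 1L)] <- b$waveform
    notch <- pos + b$notch_offset - 1L
    truth <- beat_truth(pos, notch, pos + nb)
    truths <- c(truths, list(truth))
    labels[truth$onset:(truth$notch - 1L)] <- 1L
    labels[truth$notch:(truth$next_onset - 1L)] <- 2L
    pos <- pos + nb
  }
  # the final complete beat must have its next_onset inside the record;
  # otherwise demote it to background (partial-beat rule)
  while (length(truths) > 0) {
    last <- truths[[length(truths)]]
    if (last$next_onset <= n_samples) break
    labels[last$onset:n_samples] <- 0L
    truths <- truths[-length(truths)]
  }

  a0 <- max(samples)
  t <- (seq_len(n_samples) - 1L) / fs
  pl_phase <- stats::runif(1, 0, 2 * pi)
  dr_phase <- if (is.null(noise$drift_phase)) stats::runif(1, 0, 2 * pi) else noise$drift_phase
  noisy <- samples +
    stats::rnorm(n_samples, 0, noise$white_sigma * a0) +
    noise$powerline_amp * a0 * sin(2 * pi * 50 * t + pl_phase) +
    noise$drift_amp * a0 * sin(2 * pi * noise$drift_freq * t + dr_phase)

  record <- pulse_record(noisy, fs = fs, pulse_type = pulse_type,
                         record_id = sprintf("%s_s%d", pulse_type, as.integer(seed)),
                         meta = list(seed = as.integer(seed), clean = FALSE))
  list(record = record, truths = truths, labels = labels)
}

#' Default dataset composition
#'
#' Counts per pulse type mirroring the 1400-case clinical composition
#' (120 normal, 100 slippery, 360 fine+slippery, 100 string+slippery,
#' 100 string, 100 fine, 520 fine+string), scaled by `scale` and rounded.
#'
#' @param scale scaling factor (1 reproduces the 1400-case composition;
#'   0.1 gives the 140-record desk-scale dataset).
#' @return named integer vector over [pulse_types].
#' @export
default_counts <- function(scale = 1) {
  base <- c(normal = 120, slippery = 100, fine_slippery = 360,
            string_slippery = 100, string = 100, fine = 100,
            fine_string = 520)
  round(base * scale)
}

#' Generate a full synthetic dataset
#'
#' Generates `counts[type]` records per type, each from a seed derived from
#' the master seed by a fixed counter scheme, so any subset is reproducible.
#'
#' @param counts named integer vector over [pulse_types] (see
#'   [default_counts()]).
#' @param seed master seed.
#' @param ... passed through to [generate_record()] (`n_samples`, `fs`,
#'   `hr_bpm`, `hr_jitter`, `noise`).
#' @return list of `generate_record()` results, one per record.
#' @export
generate_dataset <- function(counts = default_counts(0.1), seed = 1L, ...) {
  if (any(counts < 0)) stop("counts must be >= 0")
  unknown <- setdiff(names(counts), pulse_types)
  if (length(unknown)) stop("unknown pulse types: ", paste(unknown, collapse = ", "))
  base <- as.integer(seed) %% 1000000L
  out <- vector("list", sum(counts))
  k <- 0L
  for (type in pulse_types) {
    if (!type %in% names(counts)) next
    m <- counts[[type]]
    if (is.na(m)) next
    for (j in seq_len(m)) {
      k <- k + 1L
      rec_seed <- base * 2000L + k
      r <- generate_record(type, seed = rec_seed, ...)
      r$record$record_id <- sprintf("%s_%04d", type, j)
      out[[k]] <- r
    }
  }
  out[seq_len(k)]
}
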