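test_that("make_beat geometry: valley structure, linearity, argmin oracle", {
  # no tidal wave: exactly one interior local minimum between c1 and c3
  p <- beat_params(0.8, amps = c(1, 0, 0.05),
                   centers = c(0.15, 0.35, 0.55), widths = c(0.055, 0.07, 0.06))
  b <- make_beat(p, 720)
  n <- length(b$waveform)
  lo <- round(0.15 * n); hi <- round(0.55 * n)
  seg <- b$waveform[lo:hi]
  minima <- which(diff(sign(diff(seg))) > 0)
  expect_length(minima, 1L)

  # amplitude scaling is linear and leaves the notch where it was
  p2 <- beat_params(0.8, amps = 2 * c(1, 0.45, 0.30))
  b1 <- make_beat(beat_params(0.8), 720)
  b2 <- make_beat(p2, 720)
  expect_equal(b2$waveform, 2 * b1$waveform, tolerance = 1e-12)
  expect_identical(b2$notch_offset, b1$notch_offset)

  # notch matches a brute-force argmin over the output samples restricted
  # to the inter-peak interval (independent of the dense-grid search)
  p <- do.call(beat_params, c(list(period_s = 0.8), pulse_type_presets()$normal))
  b <- make_beat(p, 720)
  idx <- seq(ceiling(p$centers[2] * 0.8 * 720), floor(p$centers[3] * 0.8 * 720)) + 1L
  brute <- idx[which.min(b$waveform[idx])]
  expect_equal(b$notch_offset, brute, tolerance = 1)
})

test_that("beat parameter invariants are enforced", {
  expect_error(beat_params(amps = c(1, 1.2, 0.3)), "dominate")
  expect_error(beat_params(amps = c(1, 0.4, 0.01)), "5%")
  expect_error(beat_params(centers = c(0.4, 0.2, 0.6)), "centers")
  expect_error(beat_params(widths = c(0, 0.07, 0.07)), "widths")
  expect_error(beat_params(period_s = NaN), "finite")
  expect_error(noise_params(drift_freq = 0.5), "0.4")
})

test_that("generate_record is deterministic and correctly shaped", {
  a <- generate_record("normal", seed = 7)
  b <- generate_record("normal", seed = 7)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$truths, b$truths)
  expect_identical(a$labels, b$labels)

  expect_length(a$record$samples, 2160L)
  expect_gte(length(a$truths), 2L)
  expect_lte(length(a$truths), 4L)
  expect_error(generate_record("sine"), "arg")
})

test_that("labels partition beats and agree with the stored truths", {
  for (ty in pulse_types) {
    r <- generate_record(ty, seed = 31)
    expect_silent(validate_labels(r$labels))
    for (tr in r$truths) {
      expect_true(all(r$labels[tr$onset:(tr$notch - 1L)] == 1L))
      expect_true(all(r$labels[tr$notch:(tr$next_onset - 1L)] == 2L))
    }
    # background before first onset and after last complete beat
    first <- r$truths[[1]]$onset
    last <- r$truths[[length(r$truths)]]$next_onset
    if (first > 1L) expect_true(all(r$labels[1:(first - 1L)] == 0L))
    if (last <= 2160L) expect_true(all(r$labels[last:2160L] == 0L))
  }
})

test_that("noiseless notch is exactly identifiable by exhaustive argmin", {
  # independent oracle: argmin of the generated samples over the interval
  # between the tidal and dicrotic-wave centers of each beat
  for (ty in pulse_types) {
    r <- generate_record(ty, noise = no_noise(), seed = 53)
    preset <- pulse_type_presets()[[ty]]
    x <- r$record$samples
    for (tr in r$truths) {
      per <- tr$next_onset - tr$onset
      lo <- tr$onset + round(preset$centers[2] * per)
      hi <- tr$onset + round(preset$centers[3] * per)
      win <- lo:hi
      expect_lte(abs(win[which.min(x[win])] - tr$notch), 1)
    }
  }
})

test_that("flat-top presets have a weak notch valley", {
  for (ty in c("string", "fine", "fine_string")) {
    preset <- pulse_type_presets()[[ty]]
    expect_lte(preset$amps[3] / preset$amps[1], 0.15)
    expect_lte(abs(preset$centers[2] - preset$centers[1]), 0.1)
    b <- make_beat(do.call(beat_params, c(list(period_s = 0.8), preset)), 720)
    w <- b$waveform; nf <- b$notch_offset
    maxima <- which(diff(sign(diff(w))) < 0) + 1L
    maxima <- maxima[maxima <= nf]
    pre_max <- if (length(maxima)) w[max(maxima)] else max(w[1:nf])
    depth <- pre_max - w[nf]
    expect_lte(depth, 0.2 * max(w))
  }
})

test_that("dataset generation honours counts, seeds and composition", {
  expect_identical(sum(default_counts(1)), 1400)
  expect_identical(sum(default_counts(0.1)), 140)
  expect_identical(unname(default_counts(0.1)),
                   c(12, 10, 36, 10, 10, 10, 52))

  ds <- generate_dataset(counts = c(normal = 2, string = 3), seed = 5)
  expect_length(ds, 5L)
  expect_identical(vapply(ds, function(r) r$record$pulse_type, character(1)),
                   c("normal", "normal", "string", "string", "string"))
  ds2 <- generate_dataset(counts = c(normal = 2, string = 3), seed = 5)
  expect_identical(ds, ds2)
  # distinct per-record seeds produce distinct records
  expect_false(identical(ds[[1]]$record$samples, ds[[2]]$record$samples))

  expect_length(generate_dataset(counts = c(normal = 0), seed = 1), 0L)
  expect_error(generate_dataset(counts = c(sine = 1)), "unknown")
})

test_that("signal and interval files round-trip", {
  r <- generate_record("slippery", seed = 2)
  tmp <- tempfile(fileext = ".txt")
  write_signal(r$record, tmp)
  back <- read_signal(tmp, pulse_type = "slippery")
  expect_equal(back$samples, r$record$samples, tolerance = 1e-14)

  iv <- labels_to_intervals(r$labels, "slippery_01")
  tmp2 <- tempfile(fileext = ".tsv")
  write_intervals(iv, tmp2)
  iv2 <- read_intervals(tmp2)
  expect_equal(iv2$start, iv$start)
  expect_identical(intervals_to_labels(iv2, 2160L), r$labels)
})
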