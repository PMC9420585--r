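# independent oracle: naive O(n*w) double-loop slope sum
ssf_naive <- function(x, w) {
  n <- length(x)
  d <- c(0, pmax(diff(x), 0))
  out <- numeric(n)
  for (k in seq_len(n)) {
    out[k] <- sum(d[max(1, k - w + 1):k])
  }
  out
}

test_that("slope sum has its closed forms on monotone signals", {
  w <- 10
  ramp <- seq(0, 99) * 0.3
  s <- ssf_transform(ramp, w)
  expect_equal(s[(w + 1):100], rep(w * 0.3, 100 - w), tolerance = 1e-12)
  dec <- rev(ramp)
  expect_true(all(ssf_transform(dec, w) == 0))
})

test_that("slope sum agrees exactly with the double-loop oracle", {
  set.seed(61)
  for (n in c(50, 1000, 5000)) {
    x <- cumsum(rnorm(n)) + sin(seq_len(n) / 20)
    for (w in c(3, min(94, n - 1))) {
      expect_equal(ssf_transform(x, w), ssf_naive(x, w), tolerance = 1e-9)
    }
  }
  r <- generate_record("normal", noise = no_noise(), seed = 61)
  x <- r$record$samples
  expect_equal(ssf_transform(x, 94), ssf_naive(x, 94), tolerance = 1e-9)
  # SSF peaks after the onset and before the main-wave crest
  s <- ssf_transform(x, 94)
  tr <- r$truths[[1]]
  beat <- tr$onset:(tr$next_onset - 1)
  peak_ssf <- beat[which.max(s[beat])]
  peak_sig <- beat[which.max(x[beat])]
  expect_gt(peak_ssf, tr$onset)
  expect_lte(peak_ssf, peak_sig + 94)
})

test_that("onset detection recovers noiseless beats within 20 ms", {
  hits <- 0; total <- 0
  for (ty in pulse_types) {
    r <- generate_record(ty, noise = no_noise(), seed = 67)
    sr <- ssf_segment(r$record)
    for (tr in r$truths) {
      total <- total + 1
      if (length(sr$onsets) && min(abs(sr$onsets - tr$onset)) <= 0.02 * 720) {
        hits <- hits + 1
      }
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("onset detection is amplitude- and shift-invariant", {
  r <- generate_record("slippery", noise = no_noise(), seed = 71)
  x <- r$record$samples
  s <- ssf_transform(x, 94)
  o1 <- detect_onsets(s, ssf_config(), 720)
  o3 <- detect_onsets(ssf_transform(3 * x, 94), ssf_config(), 720)
  expect_identical(o1, o3)
  # translation equivariance: delay the signal by a constant lead-in
  shift <- 100L
  xs <- c(rep(x[1], shift), x)
  os <- detect_onsets(ssf_transform(xs, 94), ssf_config(), 720)
  # the foot floor adapts to the whole record, so equivariance is within a
  # few samples rather than exact
  matched <- vapply(o1 + shift, function(o) any(abs(os - o) <= 7), logical(1))
  expect_true(all(matched))

  expect_identical(detect_onsets(rep(0, 2160), ssf_config(), 720), integer(0))
})

test_that("notch location is exact for clear notches, falls back for flat tops", {
  r <- generate_record("normal", noise = no_noise(), seed = 73)
  x <- r$record$samples
  for (tr in r$truths) {
    nd <- detect_notch(x, c(tr$onset, tr$next_onset), ssf_config(), 720)
    expect_true(nd$ok)
    expect_false(nd$fallback)
    expect_lte(abs(nd$notch - tr$notch), 0.02 * 720)
  }

  # barely-there dicrotic wave on a merged descending branch: no interior
  # local minimum, so the inflection surrogate must be used
  p <- beat_params(0.8, amps = c(1, 0.9, 0.05),
                   centers = c(0.20, 0.26, 0.34), widths = c(0.10, 0.10, 0.09))
  b <- make_beat(p, 720)
  x2 <- c(b$waveform, b$waveform)
  nd <- detect_notch(x2, c(1L, length(b$waveform) + 1L), ssf_config(), 720)
  expect_true(nd$ok)
  expect_true(nd$fallback)
  win_len <- length(b$waveform)
  expect_gt(nd$notch, 1)
  expect_lt(nd$notch, win_len)

  # degenerate two-sample window: flagged, no crash
  nd2 <- detect_notch(x2, c(1L, 3L), ssf_config(), 720)
  expect_false(nd2$ok)
  expect_true(is.na(nd2$notch))
})

test_that("full SSF segmentation labels noiseless records accurately", {
  r <- generate_record("normal", noise = no_noise(), seed = 79)
  sr <- ssf_segment(r$record)
  expect_gte(per_sample_accuracy(sr$classes, r$labels), 0.95)

  # no beats: all background
  flat <- pulse_record(rep(0, 2160))
  expect_true(all(ssf_segment(flat)$classes == 0L))

  # adversarial: time-reversed record must not crash and must stay valid
  rev_rec <- pulse_record(rev(r$record$samples))
  out <- ssf_segment(rev_rec)
  expect_silent(validate_labels(out$classes))
})
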