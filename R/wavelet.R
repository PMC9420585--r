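# Multilevel discrete wavelet transform with half-point symmetric extension.
# Implemented in-package: the installed R stack carries no wavelet transform,
# and baseline removal by zeroing the deepest approximation band is one of the
# two preprocessing stages. Only what the pipeline needs is provided: one
# orthogonal filter bank (sym8), analysis/synthesis single steps, and the
# multilevel wrappers.

# Symlet-8 analysis/synthesis filter taps (standard published constants,
# least-asymmetric Daubechies family, 16 taps).
.sym8_dec_lo <- c(
  -0.0033824159510061256, -0.00054213233179114812, 0.031695087811492981,
  0.0076074873249176054, -0.14329423835080971, -0.061273359067658524,
  0.48135965125837221, 0.77718575170052351, 0.3644418948353314,
  -0.051945838107709037, -0.027219029917056003, 0.049137179673607506,
  0.0038087520138906151, -0.014952258337048231, -0.0003029205147213668,
  0.0018899503327594609
)

#' Sym8 wavelet filter bank
#'
#' Decomposition and reconstruction filters for the 16-tap symlet used by the
#' baseline-removal stage. The high-pass and synthesis filters are derived
#' from the low-pass taps by the standard quadrature-mirror relations.
#'
#' @return list with numeric vectors `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`.
#' @export
sym8_filters <- function() {
  lo <- .sym8_dec_lo
  L <- length(lo)
  dec_hi <- rev(lo) * (-1)^(seq_len(L))      # g[k] = (-1)^k h[L-1-k]
  rec_lo <- rev(lo)
  rec_hi <- lo * (-1)^(seq_len(L) - 1)
  list(dec_lo = lo, dec_hi = dec_hi, rec_lo = rec_lo, rec_hi = rec_hi)
}

# half-point symmetric extension by m samples each side: [a b c] -> b a|a b c|c b
# (the infinite half-point-symmetric extension is 2n-periodic, so any m works)
.wext_sym <- function(x, m) {
  n <- length(x)
  p <- seq(1L - m, n + m)
  q <- (p - 1L) %% (2L * n)
  idx <- ifelse(q < n, q + 1L, 2L * n - q)
  x[idx]
}

# plain full convolution, O(n L); filters here are 16 taps
.conv_full <- function(x, f) {
  nx <- length(x); nf <- length(f)
  out <- numeric(nx + nf - 1L)
  for (j in seq_len(nf)) {
    out[j:(j + nx - 1L)] <- out[j:(j + nx - 1L)] + f[j] * x
  }
  out
}

#' Single-level DWT analysis step
#'
#' Half-point symmetric extension, filtering and dyadic downsampling.
#' Output length is `floor((n + L - 1) / 2)` for an `L`-tap filter.
#'
#' @param x numeric signal.
#' @param filt filter bank from [sym8_filters()].
#' @return list with `ca` (approximation) and `cd` (detail) coefficients.
#' @export
dwt_step <- function(x, filt = sym8_filters()) {
  L <- length(filt$dec_lo)
  ext <- .wext_sym(x, L - 1L)
  full_lo <- .conv_full(ext, filt$dec_lo)
  full_hi <- .conv_full(ext, filt$dec_hi)
  # valid part of the convolution of the extended signal
  valid <- seq(L, length(ext))
  keep <- valid[seq(2L, length(valid), by = 2L)]
  list(ca = full_lo[keep], cd = full_hi[keep])
}

#' Single-level DWT synthesis step
#'
#' Inverts [dwt_step()]: dyadic upsampling, synthesis filtering, and central
#' cropping to `out_len` samples.
#'
#' @param ca,cd approximation and detail coefficients (equal length).
#' @param out_len length of the reconstructed signal.
#' @param filt filter bank from [sym8_filters()].
#' @return numeric vector of length `out_len`.
#' @export
idwt_step <- function(ca, cd, out_len, filt = sym8_filters()) {
  if (length(ca) != length(cd)) stop("ca and cd must have equal length")
  L <- length(filt$rec_lo)
  m <- length(ca)
  up <- function(c) {
    u <- numeric(2L * m)
    u[seq(1L, 2L * m, by = 2L)] <- c
    u
  }
  y <- .conv_full(up(ca), filt$rec_lo) + .conv_full(up(cd), filt$rec_hi)
  # drop filter transients; the remaining central part holds the signal
  y <- y[(L - 1L):(length(y) - (L - 2L))]
  if (length(y) < out_len) stop("inconsistent coefficient/output lengths")
  y[seq_len(out_len)]
}

#' Multilevel wavelet decomposition
#'
#' @param x numeric signal.
#' @param levels number of analysis levels.
#' @param filt filter bank from [sym8_filters()].
#' @return object of class `wavedec`: list with `ca` (deepest approximation),
#'   `cd` (list of detail vectors, level 1 first), and `lengths` (input
#'   length at each level, used by [waverec()]).
#' @export
wavedec <- function(x, levels = 10L, filt = sym8_filters()) {
  if (levels < 1L) stop("levels must be >= 1")
  cds <- vector("list", levels)
  lens <- integer(levels)
  cur <- as.numeric(x)
  for (j in seq_len(levels)) {
    lens[j] <- length(cur)
    s <- dwt_step(cur, filt)
    cds[[j]] <- s$cd
    cur <- s$ca
  }
  structure(list(ca = cur, cd = cds, lengths = lens), class = "wavedec")
}

#' Multilevel wavelet reconstruction
#'
#' @param dec a `wavedec` object, possibly with modified coefficients.
#' @param filt filter bank from [sym8_filters()].
#' @return reconstructed numeric signal of the original length.
#' @export
waverec <- function(dec, filt = sym8_filters()) {
  levels <- length(dec$cd)
  cur <- dec$ca
  for (j in rev(seq_len(levels))) {
    cur <- idwt_step(cur, dec$cd[[j]], dec$lengths[j], filt)
  }
  cur
}

#' Frequency edge of the deepest approximation band
#'
#' After `levels` dyadic analysis steps the approximation coefficients span
#' `[0, fs / 2^(levels + 1)]` Hz. At 720 Hz and 10 levels this is 0.3516 Hz,
#' which rounds to the 0.35 Hz bound quoted for respiratory baseline wander.
#'
#' @param fs sampling rate in Hz.
#' @param levels number of analysis levels.
#' @return band edge in Hz.
#' @export
band_edge_hz <- function(fs = 720, levels = 10L) {
  fs / 2^(levels + 1)
}

#' Respiration-rate frequency bound
#'
#' Converts a breathing rate in breaths per minute to Hz; the conventional
#' adult upper bound of 24 breaths/min gives 0.4 Hz, the ceiling assumed for
#' respiratory baseline drift.
#'
#' @param breaths_per_min breathing rate.
#' @return frequency in Hz.
#' @export
respiration_bound_hz <- function(breaths_per_min = 24) {
  breaths_per_min / 60
}
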