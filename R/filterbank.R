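#' Default analysis bands
#'
#' Nine non-overlapping 4 Hz bands spanning 4-40 Hz:
#' (4,8), (8,12), ..., (36,40).  These cover theta through low gamma, the
#' range carrying ERD/ERS signatures of imagery tasks.
#'
#' @return a list of `c(low, high)` pairs in Hz.
#' @export
default_bands <- function() {
  lows <- seq(4, 36, by = 4)
  lapply(lows, function(lo) c(lo, lo + 4))
}

#' Define a Chebyshev Type II band-pass filter bank
#'
#' Each band is realised as a Chebyshev Type II band-pass design with the
#' given order and stop-band attenuation.  By default filters are applied
#' forward-backward (zero phase) so band outputs stay time-aligned; a
#' single-pass causal mode is available.
#'
#' @param bands list of `c(low, high)` Hz pairs; default [default_bands()].
#'   Bands must be sorted and non-overlapping (shared edges allowed).
#' @param order filter order of the low-pass prototype (default 4).
#' @param rs_db stop-band attenuation in dB (default 30).
#' @param zero_phase apply forward-backward (default `TRUE`)?
#' @return a `filter_bank_spec`.
#' @export
filter_bank <- function(bands = default_bands(), order = 4, rs_db = 30,
                        zero_phase = TRUE) {
  bands <- lapply(bands, as.numeric)
  if (!length(bands)) stop("need at least one band")
  for (b in bands) {
    if (length(b) != 2L || !all(is.finite(b)) || b[1] <= 0 || b[1] >= b[2])
      stop("each band must be a finite pair 0 < low < high")
  }
  lows <- vapply(bands, `[`, 0, 1L)
  highs <- vapply(bands, `[`, 0, 2L)
  if (is.unsorted(lows, strictly = TRUE))
    stop("bands must be sorted by lower edge")
  if (any(highs[-length(highs)] > lows[-1L] + 1e-12))
    stop("bands must not overlap")
  structure(list(bands = bands, design = "cheby2",
                 order = as.integer(order), rs_db = as.numeric(rs_db),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_bank_spec")
}

# b/a coefficients for one band at a given sampling rate; the stop-band
# edges sit one transition width (2 Hz) outside the pass band.
band_coefficients <- function(spec, band, sfreq, transition_hz = 2) {
  nyq <- sfreq / 2
  if (band[2] >= nyq)
    stop(sprintf("band (%g, %g) violates Nyquist at sfreq %g",
                 band[1], band[2], sfreq))
  lo <- max(band[1] - transition_hz, 0.1)
  hi <- min(band[2] + transition_hz, nyq * 0.999)
  f <- signal::cheby2(spec$order, spec$rs_db, W = c(lo, hi) / nyq,
                      type = "pass")
  list(b = as.numeric(f$b), a = as.numeric(f$a))
}

# Complex frequency response H(e^{i 2 pi f / sfreq}) by direct polynomial
# evaluation of b/a (no table lookup).
iir_response <- function(ba, freqs_hz, sfreq) {
  z <- exp(-2i * pi * freqs_hz / sfreq)
  polyval_c <- function(p, z) {
    acc <- rep(0 + 0i, length(z))
    for (c in p) acc <- acc * z + c
    acc
  }
  polyval_c(ba$b, z) / polyval_c(ba$a, z)
}

#' Magnitude response of the bank on a frequency grid
#'
#' Evaluates each band filter's transfer function by direct polynomial
#' evaluation.  For zero-phase (forward-backward) application the effective
#' magnitude is the squared single-pass magnitude.
#'
#' @param spec a [filter_bank()].
#' @param sfreq sampling rate in Hz.
#' @param freqs frequency grid in Hz (default 0 to Nyquist, 0.25 Hz steps).
#' @return data.frame with columns `band`, `freq_hz`, `magnitude`.
#' @export
filterbank_response <- function(spec, sfreq,
                                freqs = seq(0, sfreq / 2, by = 0.25)) {
  out <- lapply(seq_along(spec$bands), function(i) {
    ba <- band_coefficients(spec, spec$bands[[i]], sfreq)
    mag <- Mod(iir_response(ba, freqs, sfreq))
    if (spec$zero_phase) mag <- mag^2
    data.frame(band = i, freq_hz = freqs, magnitude = mag)
  })
  do.call(rbind, out)
}

# Apply an IIR filter down the rows of a [T x m] matrix.  MA and AR parts
# run through stats::filter's C implementation, column-wise.  The filter
# state is initialized to the steady-state response to the first sample of
# each column (the lfilter_zi idea), so a constant input produces exactly
# its DC-gain-scaled value with no startup transient; callers additionally
# pad with reflected signal to absorb the remaining edge effects.
iir_filter_mat <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  T_ <- nrow(x)
  x1 <- x[1L, , drop = FALSE]
  if (nb > 1L) {
    head_pad <- x1[rep(1L, nb - 1L), , drop = FALSE]
    y <- as.matrix(stats::filter(rbind(head_pad, x), b,
                                 method = "convolution", sides = 1L))
    y <- y[nb:(T_ + nb - 1L), , drop = FALSE]
  } else y <- b * x
  if (length(a) > 1L) {
    dc_gain <- sum(b) / sum(a)
    init <- x1[rep(1L, length(a) - 1L), , drop = FALSE] * dc_gain
    y <- stats::filter(y, -a[-1L], method = "recursive", init = init)
  }
  matrix(as.numeric(y), T_, ncol(x))
}

# Zero-phase (or causal) filtering of matrix columns with odd-reflection
# padding.  The pad length covers three time constants of the slowest pole
# (zero initial state would otherwise leak a step transient into short
# epochs), capped at the epoch length.
filter_columns <- function(ba, x, zero_phase = TRUE) {
  T_ <- nrow(x)
  poles <- Mod(polyroot(rev(ba$a)))
  maxmod <- min(max(poles), 1 - 1e-6)
  pad <- min(max(3L * (length(ba$a) - 1L),
                 ceiling(3 / (1 - maxmod))), T_ - 1L)
  if (pad > 0) {
    top <- 2 * x[rep(1L, pad), , drop = FALSE] -
      x[(pad + 1L):2L, , drop = FALSE]
    bot <- 2 * x[rep(T_, pad), , drop = FALSE] -
      x[(T_ - 1L):(T_ - pad), , drop = FALSE]
    xp <- rbind(top, x, bot)
  } else xp <- x
  y <- iir_filter_mat(ba$b, ba$a, xp)
  if (zero_phase) {
    y <- y[nrow(y):1L, , drop = FALSE]
    y <- iir_filter_mat(ba$b, ba$a, y)
    y <- y[nrow(y):1L, , drop = FALSE]
  }
  if (pad > 0) y[(pad + 1L):(pad + T_), , drop = FALSE] else y
}

#' Decompose epochs into a band tensor
#'
#' Runs every channel of every trial through each band filter, producing the
#' multi-view input of the network front end.  The operation is linear and
#' preserves the time length (no decimation).
#'
#' @param epochs an `epoch_set`.
#' @param spec a [filter_bank()].
#' @return a `band_tensor`: list with `data` array
#'   `[n_bands, n_channels, n_times, n_trials]`, `band_edges`, `sfreq`,
#'   `labels`.
#' @export
apply_filterbank <- function(epochs, spec = filter_bank()) {
  validate_epochs(epochs)
  sf <- epochs$sfreq
  d <- dim(epochs$data)
  n <- d[1L]; C <- d[2L]; T_ <- d[3L]
  min_len <- 3L * spec$order
  if (T_ < min_len)
    stop(sprintf("epochs too short (%d samples) for filter transients", T_))
  B <- length(spec$bands)
  # time-major matrix [T x (C*n)]
  xm <- matrix(aperm(epochs$data, c(3L, 2L, 1L)), nrow = T_)
  out <- array(0, c(B, C, T_, n))
  for (i in seq_len(B)) {
    ba <- band_coefficients(spec, spec$bands[[i]], sf)
    y <- filter_columns(ba, xm, spec$zero_phase)
    out[i, , , ] <- aperm(array(y, c(T_, C, n)), c(2L, 1L, 3L))
  }
  structure(list(data = out, band_edges = spec$bands, sfreq = sf,
                 labels = epochs$labels),
            class = "band_tensor")
}
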