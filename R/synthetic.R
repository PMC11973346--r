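#' Synthetic epoch generator configuration
#'
#' Emulates the class structure the decoder assumes in imagery data:
#' band-limited power modulation (ERD/ERS-like) on class-specific channel
#' subsets, riding on 1/f background activity plus white sensor noise,
#' with a constant phase lag between coupled channels so that
#' phase-lag-index estimation has known ground truth.
#'
#' Default desk-scale geometry: 32 channels at 250 Hz, 2 s epochs
#' (T = 500), 4 classes x 100 trials.  Each class modulates one
#' filter-bank band — (8,12), (12,16), (20,24), (28,32) Hz — on its own
#' block of 8 channels with modulation depth 3 (the oscillation's RMS is 3x
#' the background's in-band RMS on those channels).
#'
#' @param n_trials_per_class trials per class.
#' @param n_classes number of classes (>= 2).
#' @param n_channels number of channels.
#' @param sfreq sampling frequency, Hz.
#' @param duration_s epoch length in seconds.
#' @param class_bands list of per-class `c(low, high)` Hz pairs.
#' @param class_channels list of per-class channel index vectors.
#' @param modulation_depth oscillation RMS as a multiple of the
#'   background's in-band RMS on the affected channels; 0 means no class
#'   signal at all.
#' @param background_exponent 1/f spectral slope of the background.
#' @param noise_sigma white sensor-noise standard deviation (background
#'   has unit RMS).
#' @param coupling_lag_deg constant phase lag injected between coupled
#'   channels of a class (degrees).
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a `synth_config`.
#' @export
synth_config <- function(n_trials_per_class = 100L, n_classes = 4L,
                         n_channels = 32L, sfreq = 250, duration_s = 2,
                         class_bands = NULL, class_channels = NULL,
                         modulation_depth = 3, background_exponent = 1,
                         noise_sigma = 0.5, coupling_lag_deg = 90,
                         seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("need at least 2 classes")
  if (is.null(class_bands)) {
    defaults <- list(c(8, 12), c(12, 16), c(20, 24), c(28, 32),
                     c(4, 8), c(16, 20), c(24, 28), c(32, 36))
    if (n_classes > length(defaults))
      stop("supply class_bands for more than 8 classes")
    class_bands <- defaults[seq_len(n_classes)]
  }
  if (is.null(class_channels)) {
    per <- n_channels %/% n_classes
    if (per < 1L) stop("need at least one channel per class")
    class_channels <- lapply(seq_len(n_classes) - 1L,
                             function(k) k * per + seq_len(min(per, 8L)))
  }
  for (b in class_bands)
    if (b[2] >= sfreq / 2) stop("class band outside Nyquist")
  for (chs in class_channels) {
    if (!length(chs)) stop("class_channels must be non-empty")
    if (any(chs < 1L | chs > n_channels)) stop("class channel out of range")
  }
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 n_classes = n_classes,
                 n_channels = as.integer(n_channels),
                 sfreq = as.numeric(sfreq),
                 duration_s = as.numeric(duration_s),
                 class_bands = class_bands,
                 class_channels = class_channels,
                 modulation_depth = as.numeric(modulation_depth),
                 background_exponent = as.numeric(background_exponent),
                 noise_sigma = as.numeric(noise_sigma),
                 coupling_lag_deg = as.numeric(coupling_lag_deg),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# 1/f^(exponent) power-shaped Gaussian noise, unit RMS, columns independent
pink_noise <- function(T_, m, exponent) {
  x <- matrix(stats::rnorm(T_ * m), T_, m)
  if (exponent == 0) return(x)
  X <- stats::mvfft(x)
  f <- c(1, seq_len(T_ - 1L))               # avoid DC blow-up
  f <- pmin(f, T_ - f + 1)                  # two-sided frequency index
  scale <- f^(-exponent / 2)
  scale[1L] <- 0
  y <- Re(stats::mvfft(X * scale, inverse = TRUE)) / T_
  sweep(y, 2L, sqrt(colMeans(y^2)), `/`)
}

# narrow-band noise in [lo, hi] Hz with unit RMS (band-passed white noise)
narrowband_noise <- function(T_, m, band, sfreq, bank) {
  ba <- band_coefficients(bank, band, sfreq)
  y <- filter_columns(ba, matrix(stats::rnorm(T_ * m), T_, m))
  sweep(y, 2L, pmax(sqrt(colMeans(y^2)), 1e-12), `/`)
}

phase_shift <- function(x, theta) Re(analytic_signal(x) * exp(-1i * theta))

#' Generate a synthetic epoch set
#'
#' Each trial is unit-RMS 1/f background on every channel plus white sensor
#' noise; on the trial's class channels a narrow-band oscillation
#' (band-passed white noise, shared waveform) is added with RMS equal to
#' `modulation_depth` times the background's in-band RMS, successive class
#' channels lagged by `coupling_lag_deg`.  Labels are exactly balanced and
#' the result is deterministic given `config$seed`.
#'
#' @param config a [synth_config()].
#' @return an `epoch_set` with `n_trials_per_class * n_classes` trials.
#' @export
generate_epochs <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  restore <- local_rng(config$seed)
  on.exit(restore(), add = TRUE)
  T_ <- round(config$sfreq * config$duration_s)
  C <- config$n_channels
  K <- config$n_classes
  npc <- config$n_trials_per_class
  n <- npc * K
  labels <- rep(seq_len(K) - 1L, times = npc)
  bank <- filter_bank()    # designs reused for band-limiting
  data <- array(0, c(n, C, T_))
  theta <- config$coupling_lag_deg * pi / 180
  for (i in seq_len(n)) {
    bg <- pink_noise(T_, C, config$background_exponent)
    x <- bg + config$noise_sigma * matrix(stats::rnorm(T_ * C), T_, C)
    if (config$modulation_depth > 0) {
      k <- labels[i] + 1L
      band <- config$class_bands[[k]]
      chs <- config$class_channels[[k]]
      # in-band RMS of the background on the affected channels
      ba <- band_coefficients(bank, band, config$sfreq)
      bg_band <- filter_columns(ba, bg[, chs, drop = FALSE])
      amp <- config$modulation_depth * sqrt(colMeans(bg_band^2))
      s <- narrowband_noise(T_, 1L, band, config$sfreq, bank)[, 1L]
      for (j in seq_along(chs)) {
        sj <- if (j == 1L) s else phase_shift(s, (j - 1L) * theta)
        x[, chs[j]] <- x[, chs[j]] + amp[j] * sj
      }
    }
    data[i, , ] <- t(x)
  }
  epoch_set(data, labels, config$sfreq)
}

#' Write the standard fixture suite
#'
#' Generates and saves four small HDF5 epoch sets used throughout the
#' tests and examples, with a JSON manifest of seeds and parameters:
#' `tiny` (8 trials, 4 channels), `separable-2class`, `separable-4class`
#' (the desk-scale benchmark: 32 channels, 500 samples, 4 x 100 trials)
#' and `null` (modulation depth 0).
#'
#' @param dir output directory (created if needed).
#' @param seed base seed recorded in the manifest.
#' @return named character vector of file paths, invisibly.
#' @export
make_fixture_suite <- function(dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfgs <- list(
    tiny = synth_config(n_trials_per_class = 2L, n_classes = 4L,
                        n_channels = 4L, duration_s = 0.4,
                        class_channels = as.list(1:4), seed = seed),
    `separable-2class` = synth_config(n_trials_per_class = 50L,
                                      n_classes = 2L, seed = seed + 1L),
    `separable-4class` = synth_config(seed = seed + 2L),
    null = synth_config(modulation_depth = 0, seed = seed + 3L))
  paths <- character(0)
  for (nm in names(cfgs)) {
    p <- file.path(dir, paste0(nm, ".h5"))
    save_epochs(generate_epochs(cfgs[[nm]]), p)
    paths[nm] <- p
  }
  manifest <- lapply(cfgs, function(cf) {
    cf <- unclass(cf)
    cf$class_bands <- lapply(cf$class_bands, as.numeric)
    cf$class_channels <- lapply(cf$class_channels, as.integer)
    cf
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
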