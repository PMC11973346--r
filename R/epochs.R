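#' Construct an epoch set
#'
#' An `epoch_set` is the universal input container of the package: a
#' trials x channels x times array of real-valued samples with one integer
#' class label per trial, the sampling frequency, channel names and
#' (optionally) 3-D sensor positions.
#'
#' Labels are stored 0-based and contiguous internally.  Arbitrary external
#' label sets (e.g. 1..4) are remapped on construction and the mapping is
#' kept in `label_map` so that original labels can be recovered.
#'
#' @param data numeric array `[n_trials, n_channels, n_times]`; all values
#'   must be finite.
#' @param labels integer vector of length `n_trials`.
#' @param sfreq sampling frequency in Hz (positive scalar).
#' @param channel_names character vector of length `n_channels`; defaults to
#'   `"MEG001"`, `"MEG002"`, ...
#' @param positions optional numeric matrix `[n_channels, 3]` of sensor
#'   coordinates in meters.
#' @return an object of class `epoch_set` with elements `data`, `labels`
#'   (0-based integers), `sfreq`, `channel_names`, `positions` (or `NULL`)
#'   and `label_map` (original label value for each internal code).
#' @export
epoch_set <- function(data, labels, sfreq, channel_names = NULL,
                      positions = NULL) {
  data <- as_epoch_array(data)
  labels <- as.vector(labels)
  if (length(labels) != dim(data)[1L])
    stop(sprintf("labels length (%d) does not match n_trials (%d)",
                 length(labels), dim(data)[1L]))
  if (anyNA(labels) || any(labels != round(labels)))
    stop("labels must be integers without NA")
  uniq <- sort(unique(labels))
  codes <- match(labels, uniq) - 1L
  if (is.null(channel_names))
    channel_names <- sprintf("MEG%03d", seq_len(dim(data)[2L]))
  x <- structure(list(
    data = data,
    labels = as.integer(codes),
    sfreq = as.numeric(sfreq),
    channel_names = as.character(channel_names),
    positions = if (!is.null(positions)) as.matrix(positions) else NULL,
    label_map = uniq
  ), class = "epoch_set")
  validate_epochs(x)
}

as_epoch_array <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("data must be a 3-D array [n_trials, n_channels, n_times]")
  storage.mode(data) <- "double"
  data
}

#' Validate an epoch set
#'
#' Checks the container invariants: array shape, finiteness, label range,
#' positive sampling rate and metadata lengths.  Called by every consumer;
#' errors name the offending field (and, for non-finite samples, the trial
#' and channel index).
#'
#' @param x an `epoch_set`.
#' @return `x`, invisibly usable, after passing all checks.
#' @export
validate_epochs <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  d <- dim(x$data)
  if (d[1L] < 1L) stop("need at least 1 trial")
  if (d[2L] < 2L) stop("need at least 2 channels")
  if (d[3L] < 2L) stop("need at least 2 time samples")
  if (!all(is.finite(x$data))) {
    bad <- which(!is.finite(x$data), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite sample at trial %d, channel %d, time %d",
                 bad[1L], bad[2L], bad[3L]))
  }
  if (length(x$labels) != d[1L])
    stop("labels length does not match n_trials")
  nc <- length(x$label_map)
  if (any(x$labels < 0L | x$labels >= nc))
    stop("internal labels out of range 0..Nc-1")
  if (!is.finite(x$sfreq) || x$sfreq <= 0) stop("sfreq must be positive")
  if (length(x$channel_names) != d[2L])
    stop("channel_names length does not match n_channels")
  if (!is.null(x$positions)) {
    if (nrow(x$positions) != d[2L] || ncol(x$positions) != 3L)
      stop("positions must be an [n_channels, 3] matrix")
    if (!all(is.finite(x$positions))) stop("positions contain non-finite values")
  }
  x
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$sfreq))
  tab <- table(x$labels)
  cat("  classes:", length(x$label_map),
      sprintf("(%s)", paste(sprintf("%s:%d", names(tab), tab), collapse = " ")),
      "\n")
  if (!is.null(x$positions)) cat("  sensor positions: present\n")
  invisible(x)
}

n_trials <- function(x) dim(x$data)[1L]
n_channels <- function(x) dim(x$data)[2L]
n_times <- function(x) dim(x$data)[3L]
n_classes <- function(x) length(x$label_map)

subset_epochs <- function(x, idx) {
  y <- x
  y$data <- x$data[idx, , , drop = FALSE]
  y$labels <- x$labels[idx]
  y
}

#' Save an epoch set to HDF5
#'
#' Writes the canonical interchange layout: `/data` (float, trials x
#' channels x times), `/labels` (integer), `/sfreq` (scalar),
#' `/channel_names` (strings) and, when present, `/positions`
#' (channels x 3).  [load_epochs()] on the result reproduces the arrays
#' bit-exactly.
#'
#' @param epochs a valid `epoch_set`.
#' @param path output file path (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
save_epochs <- function(epochs, path) {
  validate_epochs(epochs)
  if (file.exists(path)) unlink(path)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: %s", dir))
  rhdf5::h5createFile(path)
  rhdf5::h5write(epochs$data, path, "data")
  rhdf5::h5write(as.integer(epochs$label_map[epochs$labels + 1L]),
                 path, "labels")
  rhdf5::h5write(epochs$sfreq, path, "sfreq")
  rhdf5::h5write(epochs$channel_names, path, "channel_names")
  if (!is.null(epochs$positions))
    rhdf5::h5write(epochs$positions, path, "positions")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Load an epoch set
#'
#' Reads the HDF5 interchange layout written by [save_epochs()].  Channel
#' order is preserved from the file; labels are remapped to internal 0-based
#' codes (the original values are kept in `label_map`).
#'
#' @param path file to read.
#' @param format `"hdf5"` (the canonical layout).  `"fif"` is recognised but
#'   not supported by this package; requesting it raises an error.
#' @return an `epoch_set`.
#' @export
load_epochs <- function(path, format = c("hdf5", "fif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "fif")
    stop("FIF reading is not supported; convert epochs to the HDF5 layout")
  present <- rhdf5::h5ls(path)$name
  for (need in c("data", "labels", "sfreq", "channel_names"))
    if (!need %in% present)
      stop(sprintf("format error: required dataset '%s' missing", need))
  data <- rhdf5::h5read(path, "data")
  labels <- as.vector(rhdf5::h5read(path, "labels"))
  sfreq <- as.numeric(rhdf5::h5read(path, "sfreq"))
  channel_names <- as.vector(rhdf5::h5read(path, "channel_names"))
  positions <- if ("positions" %in% present)
    rhdf5::h5read(path, "positions") else NULL
  rhdf5::h5closeAll()
  if (length(dim(data)) != 3L)
    stop("format error: 'data' must be 3-dimensional")
  if (length(labels) != dim(data)[1L])
    stop(sprintf("format error: 'labels' length %d does not match %d trials",
                 length(labels), dim(data)[1L]))
  if (length(channel_names) != dim(data)[2L])
    stop("format error: 'channel_names' length does not match n_channels")
  epoch_set(data, labels, sfreq, channel_names, positions)
}

#' Specify a train/validation/test split
#'
#' @param train_fraction,val_fraction,test_fraction fractions in (0,1)
#'   summing to 1.
#' @param stratified draw the split per class so proportions match within
#'   one trial per class?
#' @param seed integer seed making the split deterministic.
#' @return a `split_spec` list.
#' @export
split_spec <- function(train_fraction = 0.6, val_fraction = 0.2,
                       test_fraction = 0.2, stratified = TRUE, seed = 1L) {
  fr <- c(train_fraction, val_fraction, test_fraction)
  if (any(fr <= 0) || any(fr >= 1))
    stop("fractions must lie strictly between 0 and 1")
  if (abs(sum(fr) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(list(train_fraction = train_fraction,
                 val_fraction = val_fraction,
                 test_fraction = test_fraction,
                 stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "split_spec")
}

# largest-remainder apportionment of n into 3 parts proportional to fr
apportion <- function(n, fr) {
  raw <- n * fr
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split an epoch set into train/validation/test partitions
#'
#' Partitions are disjoint and jointly cover all trials.  With
#' `stratified = TRUE` the split is drawn within each class so that
#' per-class proportions match the requested fractions within one trial.
#' Deterministic given `spec$seed`.
#'
#' @param epochs an `epoch_set`.
#' @param spec a [split_spec()].
#' @return a list with `epoch_set` elements `train`, `val`, `test`, plus
#'   `indices` (the trial indices of each partition).
#' @export
split_epochs <- function(epochs, spec = split_spec()) {
  validate_epochs(epochs)
  stopifnot(inherits(spec, "split_spec"))
  fr <- c(spec$train_fraction, spec$val_fraction, spec$test_fraction)
  n <- n_trials(epochs)
  assign_part <- integer(n)
  rng <- local_rng(spec$seed)
  on.exit(rng(), add = TRUE)
  if (spec$stratified) {
    for (k in sort(unique(epochs$labels))) {
      idx <- which(epochs$labels == k)
      if (length(idx) < 3L)
        stop(sprintf("class %d has %d trials; stratified split needs >= 3",
                     k, length(idx)))
      sizes <- apportion(length(idx), fr)
      perm <- sample(idx)
      assign_part[perm] <- rep(1:3, times = sizes)
    }
  } else {
    sizes <- apportion(n, fr)
    perm <- sample.int(n)
    assign_part[perm] <- rep(1:3, times = sizes)
  }
  idx <- lapply(1:3, function(p) which(assign_part == p))
  names(idx) <- c("train", "val", "test")
  list(train = subset_epochs(epochs, idx$train),
       val = subset_epochs(epochs, idx$val),
       test = subset_epochs(epochs, idx$test),
       indices = idx)
}

# Seed the session RNG locally; returns a restore function.
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
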