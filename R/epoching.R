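#' Epoching and artifact-rejection specification
#'
#' Defaults follow the conventional CKC analysis: 4000-ms epochs with a
#' 5-ms overlap, peak-to-peak rejection at 2000 fT/cm (gradiometers) and
#' 4000 fT (magnetometers), and a 0.5--195 Hz band-pass for the
#' accelerometer axes.
#'
#' @param epoch_length_ms epoch length in ms.
#' @param overlap_ms overlap between consecutive epochs in ms
#'   (`0 <= overlap < epoch_length`).
#' @param grad_thresh peak-to-peak rejection threshold for gradiometers
#'   (fT/cm).
#' @param mag_thresh peak-to-peak rejection threshold for magnetometers
#'   (fT).
#' @param accel_band two-element band (Hz) for the acceleration band-pass.
#' @return object of class `epoch_spec`.
#' @export
epoch_spec <- function(epoch_length_ms = 4000, overlap_ms = 5,
                       grad_thresh = 2000, mag_thresh = 4000,
                       accel_band = c(0.5, 195)) {
  if (overlap_ms < 0 || overlap_ms >= epoch_length_ms)
    stop_ckc("overlap must satisfy 0 <= overlap < epoch_length")
  if (grad_thresh <= 0 || mag_thresh <= 0)
    stop_ckc("rejection thresholds must be > 0")
  if (length(accel_band) != 2L || accel_band[1] <= 0 || accel_band[2] <= accel_band[1])
    stop_ckc("accel_band must be an increasing pair of positive frequencies")
  structure(list(epoch_length_ms = epoch_length_ms, overlap_ms = overlap_ms,
                 grad_thresh = grad_thresh, mag_thresh = mag_thresh,
                 accel_band = accel_band),
            class = "epoch_spec")
}

#' Zero-phase band-pass of accelerometer axes
#'
#' Forward--backward Butterworth filtering (no group delay, DC removed).
#' The filter order is chosen so that the stop-band attenuation one octave
#' fraction above the upper edge exceeds 20 dB while the pass-band stays
#' flat within 1%.
#'
#' @param axes numeric matrix (axes x samples) or vector.
#' @param low,high band edges in Hz.
#' @param sample_rate sampling rate in Hz.
#' @param order_high,order_low Butterworth orders of the high-pass and
#'   low-pass stages (each applied twice by filtfilt). The band is
#'   realized as a cascade of the two one-sided filters, which stays
#'   numerically well conditioned for wide bands where a direct band-pass
#'   design does not.
#' @return filtered axes, same shape as the input.
#' @export
bandpass_acceleration <- function(axes, low = 0.5, high = 195, sample_rate = 1000,
                                  order_high = 2, order_low = 5) {
  nyq <- sample_rate / 2
  if (!(0 < low && low < high && high < nyq))
    stop_ckc("band (%g, %g) Hz must lie strictly inside (0, %g) Hz", low, high, nyq)
  vec <- is.null(dim(axes))
  m <- if (vec) matrix(axes, nrow = 1) else as.matrix(axes)
  hp <- signal::butter(order_high, low / nyq, type = "high")
  lp <- signal::butter(order_low, high / nyq, type = "low")
  out <- t(apply(m, 1, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x - mean(x)))))
  if (vec) as.vector(out) else out
}

#' Euclidean-norm magnitude of three-axis acceleration
#'
#' @param x,y,z equal-length numeric vectors (the three accelerometer
#'   axes).
#' @return `sqrt(x^2 + y^2 + z^2)`, element-wise.
#' @export
euclidean_norm_magnitude <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z))
    stop_ckc("axes must have equal length (got %d, %d, %d)",
             length(x), length(y), length(z))
  sqrt(x^2 + y^2 + z^2)
}

#' Segment a recording and its reference signal into paired epochs
#'
#' Continuous MEG data and the (band-passed, magnitude) acceleration
#' reference are cut into epochs of `epoch_length_ms` starting every
#' `epoch_length_ms - overlap_ms` (default step 3995 ms). Epochs are laid
#' out independently inside each stimulation burst and must lie entirely
#' within one burst; with a single burst covering the whole recording the
#' epoch count is `floor((T - L)/step) + 1`.
#'
#' @param recording a `sensor_recording`.
#' @param kinematic a `kinematic_signal` for the finger of interest (its
#'   axes are band-passed per `spec` and collapsed to the Euclidean-norm
#'   magnitude), or a numeric vector already prepared as the reference.
#' @param spec an [epoch_spec()].
#' @param bursts optional two-column matrix (start, duration; seconds)
#'   overriding the bursts stored in the recording's design; if neither is
#'   available the whole recording is one window.
#' @return object of class `epoch_set`: `meg` (channels x samples x K
#'   array), `ref` (samples x K matrix), `start_s`, `K`, channel table and
#'   provenance flags.
#' @export
segment_epochs <- function(recording, kinematic, spec = epoch_spec(),
                           bursts = NULL) {
  stopifnot(inherits(recording, "sensor_recording"), inherits(spec, "epoch_spec"))
  fs <- recording$sample_rate
  n <- ncol(recording$data)
  L <- round(spec$epoch_length_ms / 1000 * fs)
  step <- round((spec$epoch_length_ms - spec$overlap_ms) / 1000 * fs)
  if (n < L) stop_ckc("recording (%d samples) shorter than one epoch (%d samples)", n, L)

  if (inherits(kinematic, "kinematic_signal")) {
    if (ncol(kinematic$axes) != n)
      stop_ckc("kinematic signal length (%d) does not match recording (%d)",
               ncol(kinematic$axes), n)
    ax <- bandpass_acceleration(kinematic$axes, spec$accel_band[1],
                                spec$accel_band[2], fs)
    ref <- euclidean_norm_magnitude(ax[1, ], ax[2, ], ax[3, ])
  } else {
    ref <- as.numeric(kinematic)
    if (length(ref) != n)
      stop_ckc("reference length (%d) does not match recording (%d)", length(ref), n)
  }

  bursts <- bursts %||% recording$design$bursts %||%
    cbind(start = 0, duration = n / fs)
  starts <- integer(0)
  for (b in seq_len(nrow(bursts))) {
    b0 <- round(bursts[b, "start"] * fs)
    b1 <- round((bursts[b, "start"] + bursts[b, "duration"]) * fs)
    if (b1 - b0 < L) next
    k <- 0:floor((b1 - b0 - L) / step)
    starts <- c(starts, b0 + k * step)
  }
  if (length(starts) == 0L)
    stop_ckc("no epoch fits inside any stimulation burst")

  K <- length(starts)
  meg <- array(0, dim = c(nrow(recording$data), L, K))
  refm <- matrix(0, nrow = L, ncol = K)
  for (k in seq_len(K)) {
    idx <- starts[k] + seq_len(L)          # half-open [start, start + L)
    meg[, , k] <- recording$data[, idx]
    refm[, k] <- ref[idx]
  }
  structure(list(meg = meg, ref = refm, start_s = starts / fs, K = K,
                 channels = recording$channels, sample_rate = fs,
                 spec = spec, rejected = integer(0), normalized = FALSE),
            class = "epoch_set")
}

#' Assemble an epoch set from arrays
#'
#' Programmatic constructor for users (and tests) who already hold paired
#' MEG and reference epochs, e.g. from an external epoching tool.
#'
#' @param meg numeric channels x samples x K array.
#' @param ref numeric samples x K matrix, sample-aligned with `meg`.
#' @param sample_rate sampling rate in Hz.
#' @param channels optional channel table (columns `channel`, `kind`,
#'   `pair`, positions); defaults to unpaired gradiometer-kind channels.
#' @param spec optional [epoch_spec()] recorded as provenance.
#' @return an `epoch_set`.
#' @export
epoch_set <- function(meg, ref, sample_rate, channels = NULL, spec = epoch_spec()) {
  meg <- if (length(dim(meg)) == 2L) array(meg, c(1L, dim(meg))) else meg
  if (length(dim(meg)) != 3L) stop_ckc("meg must be a channels x samples x K array")
  ref <- as.matrix(ref)
  if (!identical(dim(meg)[2:3], dim(ref)))
    stop_ckc("ref (%d x %d) must be samples x K matching meg (%d x %d)",
             nrow(ref), ncol(ref), dim(meg)[2], dim(meg)[3])
  nc <- dim(meg)[1]
  channels <- channels %||% data.frame(channel = seq_len(nc), site = NA_integer_,
                                       kind = "grad", unit = "fT/cm",
                                       x = 0, y = 0, z = 0, pair = NA_integer_)
  structure(list(meg = meg, ref = ref, start_s = rep(NA_real_, dim(meg)[3]),
                 K = dim(meg)[3], channels = channels, sample_rate = sample_rate,
                 spec = spec, rejected = integer(0), normalized = FALSE),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: K = %d epochs of %d samples, %d channels%s%s\n",
              x$K, dim(x$meg)[2], dim(x$meg)[1],
              if (length(x$rejected)) sprintf(" (%d rejected)", length(x$rejected)) else "",
              if (x$normalized) ", reference normalized" else ""))
  invisible(x)
}

#' Reject epochs by peak-to-peak amplitude
#'
#' An epoch is dropped iff any gradiometer exceeds `grad_thresh` fT/cm or
#' any magnetometer exceeds `mag_thresh` fT in peak-to-peak amplitude
#' (strictly greater: at-threshold epochs are kept). Rejected indices are
#' recorded in the returned set.
#'
#' @param epochs an `epoch_set`.
#' @param spec an [epoch_spec()] carrying the thresholds (defaults to the
#'   spec stored in `epochs`).
#' @return the pruned `epoch_set` with updated `K`.
#' @export
reject_epochs <- function(epochs, spec = epochs$spec) {
  stopifnot(inherits(epochs, "epoch_set"))
  kind <- epochs$channels$kind
  thr <- ifelse(kind == "grad", spec$grad_thresh, spec$mag_thresh)
  K <- epochs$K
  bad <- logical(K)
  maxp2p <- numeric(nrow(epochs$channels))
  for (k in seq_len(K)) {
    p <- apply(epochs$meg[, , k, drop = FALSE], 1, p2p)
    maxp2p <- pmax(maxp2p, p)
    bad[k] <- any(p > thr)
  }
  if (all(bad)) {
    worst <- order(maxp2p / thr, decreasing = TRUE)[seq_len(min(5, length(maxp2p)))]
    stop_ckc("all %d epochs rejected; largest peak-to-peak amplitudes: %s",
             K, paste(sprintf("ch%d=%.0f", worst, maxp2p[worst]), collapse = ", "))
  }
  keep <- which(!bad)
  epochs$meg <- epochs$meg[, , keep, drop = FALSE]
  epochs$ref <- epochs$ref[, keep, drop = FALSE]
  epochs$start_s <- epochs$start_s[keep]
  epochs$rejected <- c(epochs$rejected, which(bad))
  epochs$K <- length(keep)
  epochs
}

#' Normalize reference epochs to unit Euclidean norm
#'
#' Each acceleration (reference) epoch is divided by its vector Euclidean
#' norm, making every epoch contribute with equal weight to the averaged
#' cross-spectrum.
#'
#' @param epochs an `epoch_set`.
#' @return the `epoch_set` with unit-norm reference epochs and the
#'   `normalized` flag set.
#' @export
normalize_ref_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  nrm <- sqrt(colSums(epochs$ref^2))
  if (any(nrm == 0))
    stop_ckc("reference epoch(s) %s have zero norm",
             paste(which(nrm == 0), collapse = ", "))
  epochs$ref <- sweep(epochs$ref, 2, nrm, "/")
  epochs$normalized <- TRUE
  epochs
}

#' Match accepted-trial counts between two epoch sets
#'
#' Truncates the larger of two epoch sets to the smaller accepted count,
#' so that coherence estimates compared across conditions carry the same
#' estimator bias. By default the earliest epochs are kept; with
#' `method = "random"` a seeded random subset is drawn.
#'
#' @param a,b `epoch_set` objects.
#' @param method `"first"` (default) or `"random"`.
#' @param seed seed for the random subset.
#' @return list with the two (possibly truncated) sets and the original
#'   counts (`K_a`, `K_b`).
#' @export
match_trial_counts <- function(a, b, method = c("first", "random"), seed = NULL) {
  stopifnot(inherits(a, "epoch_set"), inherits(b, "epoch_set"))
  method <- match.arg(method)
  K <- min(a$K, b$K)
  if (K < 1) stop_ckc("both epoch sets must be nonempty")
  take <- function(e) {
    if (e$K == K) return(e)
    idx <- if (method == "first") seq_len(K) else {
      set_seed_if(seed)
      sort(sample.int(e$K, K))
    }
    e$meg <- e$meg[, , idx, drop = FALSE]
    e$ref <- e$ref[, idx, drop = FALSE]
    e$start_s <- e$start_s[idx]
    e$K <- K
    e
  }
  list(a = take(a), b = take(b), K_a = a$K, K_b = b$K)
}
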