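#' Epoch-averaged auto- and cross-spectra
#'
#' Computes, over the K accepted epochs, the averaged MEG auto-spectra
#' `Pxx(f) = (1/K) sum_k X_k X_k*`, the reference auto-spectrum
#' `Pyy(f) = (1/K) sum_k Y_k Y_k*`, and the cross-spectrum
#' `Pxy(f) = (1/K) sum_k X_k Y_k*`, where `X_k` and `Y_k` are discrete
#' Fourier transforms of the raw (rectangular-windowed) epochs. The DFT
#' length equals the epoch length, giving a bin width of
#' `1/epoch_length` (0.25 Hz for 4000-ms epochs).
#'
#' @param epochs an `epoch_set` with `K >= 2`.
#' @return object of class `spectral_estimate`: `freqs` (Hz, one-sided),
#'   `Pxx` (channels x bins), `Pyy` (bins), `Pxy` (channels x bins,
#'   complex), `K`, and the channel table.
#' @export
epoch_spectra <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  K <- epochs$K
  if (K < 2) stop_ckc("coherence needs K >= 2 epochs (got %d)", K)
  n <- dim(epochs$meg)[2]
  n_chan <- dim(epochs$meg)[1]
  nb <- n %/% 2 + 1L
  Pxx <- matrix(0, nrow = n_chan, ncol = nb)
  Pxy <- matrix(0 + 0i, nrow = n_chan, ncol = nb)
  Pyy <- numeric(nb)
  for (k in seq_len(K)) {
    X <- stats::mvfft(t(matrix(epochs$meg[, , k], nrow = n_chan)))  # samples x channels
    Y <- stats::fft(epochs$ref[, k])
    X <- X[seq_len(nb), , drop = FALSE]
    Y <- Y[seq_len(nb)]
    Pxx <- Pxx + t(Re(X * Conj(X)))
    Pyy <- Pyy + Re(Y * Conj(Y))
    Pxy <- Pxy + t(X * Conj(Y))
  }
  fs <- epochs$sample_rate
  structure(list(freqs = (0:(nb - 1L)) * fs / n, Pxx = Pxx / K, Pyy = Pyy / K,
                 Pxy = Pxy / K, K = K, channels = epochs$channels,
                 n_fft = n, sample_rate = fs),
            class = "spectral_estimate")
}

#' Magnitude-squared coherence from averaged spectra
#'
#' `Coh(f) = |Pxy(f)|^2 / (Pxx(f) Pyy(f))`, element-wise per channel and
#' frequency bin; values lie in `[0, 1]` up to floating-point rounding.
#' Bins where either auto-spectrum vanishes are returned as `NA`
#' (undefined), never as 0.
#'
#' @param spec a [epoch_spectra()] result.
#' @return numeric channels x bins matrix of coherence values.
#' @export
coherence <- function(spec) {
  stopifnot(inherits(spec, "spectral_estimate"))
  denom <- sweep(spec$Pxx, 2, spec$Pyy, "*")
  coh <- Mod(spec$Pxy)^2 / denom
  coh[denom == 0] <- NA_real_
  coh
}

#' Overlap-corrected significance threshold for peak coherence
#'
#' The threshold above which the maximum coherence over `n_sens` channels
#' and `n_f` frequencies of interest is significant at level `alpha`:
#' `1 - (alpha / (n_sens * n_f))^(1 / (n_trials/d - 1))`. The divisor `d`
#' accounts for dependence between overlapping trials and defaults to 1
#' (no correction).
#'
#' @param alpha significance level in (0, 1).
#' @param n_sens number of channels searched for the maximum.
#' @param n_f number of frequencies of interest (default 1, the
#'   stimulation frequency).
#' @param n_trials number of accepted epochs.
#' @param d trial-overlap divisor; `n_trials/d` must exceed 1.
#' @return threshold in (0, 1).
#' @export
significance_threshold <- function(alpha = 0.05, n_sens = 1, n_f = 1,
                                   n_trials, d = 1) {
  if (!(alpha > 0 && alpha < 1)) stop_ckc("alpha must lie in (0, 1)")
  if (n_sens < 1 || n_f < 1) stop_ckc("n_sens and n_f must be >= 1")
  eff <- n_trials / d
  if (eff <= 1) stop_ckc("n_trials/d must exceed 1 (got %g)", eff)
  1 - (alpha / (n_sens * n_f))^(1 / (eff - 1))
}

# resolve a frequency to a bin index on the spectral grid
freq_bin <- function(freqs, f, snap = FALSE) {
  df <- freqs[2] - freqs[1]
  i <- which(abs(freqs - f) < df * 1e-6)
  if (length(i) == 1L) return(i)
  if (!snap)
    stop_ckc("frequency %g Hz is not on the %g-Hz bin grid (use snap = TRUE to snap)",
             f, df)
  i <- which.min(abs(freqs - f))
  message(sprintf("snapping %g Hz to nearest bin %g Hz", f, freqs[i]))
  i
}

#' Peak coherence at the stimulation frequency
#'
#' Finds the maximum coherence at the stimulation-frequency bin over a
#' designated channel set (gradiometers by default, matching the usual
#' reporting convention). Ties are broken toward the lowest channel
#' index; the planar partner of the winning gradiometer is reported
#' alongside.
#'
#' @param coh channels x bins coherence matrix.
#' @param freqs bin center frequencies (Hz).
#' @param stim_freq stimulation frequency; must lie on the bin grid
#'   unless `snap = TRUE`.
#' @param channels channel table (with `kind` and `pair` columns).
#' @param channel_set `"grad"` (default) or `"all"`.
#' @param snap snap off-grid frequencies to the nearest bin (logged).
#' @return list with `value`, `channel`, `pair`, `pair_value`, `bin`.
#' @export
peak_ckc <- function(coh, freqs, stim_freq, channels,
                     channel_set = c("grad", "all"), snap = FALSE) {
  channel_set <- match.arg(channel_set)
  bin <- freq_bin(freqs, stim_freq, snap)
  idx <- if (channel_set == "grad") which(channels$kind == "grad")
         else seq_len(nrow(channels))
  v <- coh[idx, bin]
  best <- idx[which.max(v)]                 # which.max takes the first maximum
  pair <- channels$pair[best]
  list(value = unname(coh[best, bin]), channel = best,
       pair = if (is.na(pair)) NA_integer_ else pair,
       pair_value = if (is.na(pair)) NA_real_ else unname(coh[pair, bin]),
       bin = bin)
}

#' Fit corticokinematic coherence for one epoch set
#'
#' The main sensor-level estimator: computes epoch-averaged spectra and
#' magnitude-squared coherence between every MEG channel and the
#' (normalized) acceleration reference, extracts the peak coherence at
#' the stimulation frequency over the designated channel set, and
#' attaches the multiple-comparison significance threshold.
#'
#' @param epochs an `epoch_set` (reference epochs are normalized here if
#'   not already).
#' @param stim_freq stimulation frequency in Hz; must fall on a bin
#'   center of the epoch-length DFT grid.
#' @param alpha significance level for the peak-coherence threshold.
#' @param channel_set channels searched for the peak: `"grad"` (default)
#'   or `"all"`.
#' @param d trial-overlap divisor of the threshold formula (default 1).
#' @param n_f number of frequencies of interest for the threshold.
#' @param snap snap an off-grid `stim_freq` to the nearest bin (logged).
#' @return object of class `ckc` with the coherence matrix, peak
#'   information, threshold and significance flag. Methods: `print`,
#'   `summary`, `coef`, `plot`.
#' @examples
#' sim <- ckc_toy_simulation(seed = 3)
#' fit <- ckc(sim$epochs, stim_freq = 3)
#' fit
#' @export
ckc <- function(epochs, stim_freq, alpha = 0.05, channel_set = c("grad", "all"),
                d = 1, n_f = 1, snap = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  channel_set <- match.arg(channel_set)
  if (!epochs$normalized) epochs <- normalize_ref_epochs(epochs)
  spec <- epoch_spectra(epochs)
  coh <- coherence(spec)
  peak <- peak_ckc(coh, spec$freqs, stim_freq, spec$channels, channel_set, snap)
  n_sens <- if (channel_set == "grad") sum(spec$channels$kind == "grad")
            else nrow(spec$channels)
  thr <- significance_threshold(alpha, n_sens, n_f, spec$K, d)
  structure(list(coh = coh, freqs = spec$freqs, stim_freq = spec$freqs[peak$bin],
                 K = spec$K, peak = peak, threshold = thr, alpha = alpha,
                 channel_set = channel_set, n_sens = n_sens, d = d, n_f = n_f,
                 channels = spec$channels, spectra = spec,
                 significant = peak$value > thr),
            class = "ckc")
}

#' Sum onset-aligned recordings
#'
#' Element-wise sum of several recordings whose stimulus-onset grids
#' coincide (e.g., the four separate-stimulation runs of one subject),
#' producing the summed-response recording whose coherence can be
#' compared with simultaneous stimulation. Recordings must share channel
#' layout, length and onset grid (within one sample).
#'
#' @param recordings list of `sensor_recording` objects.
#' @return a `sensor_recording` holding the sum (design and onsets taken
#'   from the first recording, condition tagged `separate_sum`).
#' @export
sum_recordings <- function(recordings) {
  stopifnot(is.list(recordings), length(recordings) >= 1L)
  lapply(recordings, function(r) stopifnot(inherits(r, "sensor_recording")))
  r1 <- recordings[[1]]
  all_on <- lapply(recordings, function(r) sort(unlist(r$onsets, use.names = FALSE)))
  for (r in recordings[-1]) {
    if (!identical(dim(r$data), dim(r1$data)) || r$sample_rate != r1$sample_rate)
      stop_ckc("recordings must share channel count, length and sample rate")
  }
  n_on <- lengths(all_on)
  if (length(unique(n_on)) != 1L ||
      max(vapply(all_on, function(o) max(abs(o - all_on[[1]])), numeric(1))) >
        1 / r1$sample_rate + 1e-12)
    stop_ckc("stimulus-onset grids are misaligned between recordings")
  data <- Reduce(`+`, lapply(recordings, `[[`, "data"))
  out <- r1
  out$data <- data
  attr(out, "condition") <- "separate_sum"
  out
}

#' Per-channel coherence topography table
#'
#' One row per channel with its position and the coherence at the
#' stimulation-frequency bin; the plain-data contract used for
#' topographic visualization by external tools.
#'
#' @param fit a [ckc()] object.
#' @return data.frame with columns `channel`, `kind`, `x`, `y`, `z`,
#'   `coherence`.
#' @export
topography_table <- function(fit) {
  stopifnot(inherits(fit, "ckc"))
  data.frame(channel = fit$channels$channel, kind = fit$channels$kind,
             x = fit$channels$x, y = fit$channels$y, z = fit$channels$z,
             coherence = fit$coh[, fit$peak$bin])
}
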