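#' Stimulus design for rhythmic proprioceptive stimulation
#'
#' Describes one stimulation run: which fingers are moved, at which
#' frequency each finger is driven, and when stimulation is active. Three
#' condition layouts are supported: all fingers together at one common
#' frequency (`simultaneous_constant`), one finger at a time
#' (`separate`), and all fingers together at finger-specific frequencies
#' (`simultaneous_varied`).
#'
#' @param condition one of `"simultaneous_constant"`, `"separate"`,
#'   `"simultaneous_varied"`.
#' @param fingers character vector of finger ids (defaults to digits
#'   D2--D5 of the right hand).
#' @param freq stimulation frequency in Hz; a scalar (recycled over
#'   fingers) or one value per finger.
#' @param bursts two-column matrix (`start`, `duration`, both seconds) of
#'   active stimulation windows. Defaults to three 60-s bursts separated
#'   by 10-s rests.
#' @param total_duration total run length in seconds; defaults to the end
#'   of the last burst.
#' @param sample_rate sampling rate in Hz (default 1000).
#' @return an object of class `stimulus_design`.
#' @examples
#' d <- stimulus_design("simultaneous_constant", freq = 3)
#' d
#' @export
stimulus_design <- function(condition = c("simultaneous_constant", "separate",
                                          "simultaneous_varied"),
                            fingers = c("D2", "D3", "D4", "D5"),
                            freq = 3,
                            bursts = cbind(start = c(0, 70, 140),
                                           duration = c(60, 60, 60)),
                            total_duration = NULL,
                            sample_rate = 1000) {
  condition <- match.arg(condition)
  if (!is.character(fingers) || length(fingers) < 1L || anyDuplicated(fingers))
    stop_ckc("fingers must be a character vector of distinct finger ids")
  freq <- rep_len(as.double(freq), length(fingers))
  names(freq) <- fingers
  if (any(!is.finite(freq)) || any(freq <= 0))
    stop_ckc("stimulation frequencies must be finite and > 0")
  if (condition == "simultaneous_constant" && length(unique(freq)) != 1L)
    stop_ckc("simultaneous_constant requires a single common frequency")
  if (condition == "simultaneous_varied" && anyDuplicated(freq))
    stop_ckc("simultaneous_varied requires pairwise distinct frequencies")
  if (condition == "separate" && length(fingers) != 1L)
    stop_ckc("a 'separate' design describes one finger per run; got %d fingers",
             length(fingers))

  bursts <- as.matrix(bursts)
  if (ncol(bursts) != 2L) stop_ckc("bursts must have two columns (start, duration)")
  colnames(bursts) <- c("start", "duration")
  if (any(bursts < 0) || any(bursts[, "duration"] <= 0))
    stop_ckc("burst starts must be >= 0 and durations > 0")
  o <- order(bursts[, "start"])
  bursts <- bursts[o, , drop = FALSE]
  ends <- bursts[, "start"] + bursts[, "duration"]
  if (nrow(bursts) > 1L && any(bursts[-1L, "start"] < ends[-nrow(bursts)]))
    stop_ckc("bursts must not overlap")
  total_duration <- total_duration %||% max(ends)
  if (max(ends) > total_duration + 1e-9)
    stop_ckc("bursts extend beyond total_duration")
  if (sample_rate <= 0) stop_ckc("sample_rate must be > 0")

  structure(list(condition = condition, fingers = fingers, freq = freq,
                 bursts = bursts, total_duration = total_duration,
                 sample_rate = sample_rate),
            class = "stimulus_design")
}

#' @export
print.stimulus_design <- function(x, ...) {
  cat("Stimulus design:", x$condition, "\n")
  cat("  fingers:", paste(sprintf("%s@%g Hz", x$fingers, x$freq), collapse = ", "), "\n")
  cat(sprintf("  %d burst(s), total %g s at %g Hz sampling\n",
              nrow(x$bursts), x$total_duration, x$sample_rate))
  invisible(x)
}

#' Pulse kernels for stimulus and response waveforms
#'
#' Builds short discrete kernels used to turn an onset (spike) train into a
#' continuous waveform. `"hann"` is a positive unit-area bump (a smooth
#' movement/drive pulse); `"accel"` is the second time-derivative of a Hann
#' displacement pulse (the acceleration trace of one flexion--extension
#' cycle, zero-mean); `"biphasic"` is a zero-mean two-lobed response shape
#' with a faster first lobe (a stylized evoked-response waveform);
#' `"delta"` is a single-sample identity kernel.
#'
#' @param shape kernel shape, see Details.
#' @param width_ms kernel support in milliseconds.
#' @param sample_rate sampling rate in Hz.
#' @return numeric vector; `"hann"` sums to 1, the zero-mean shapes have
#'   unit peak absolute amplitude.
#' @export
pulse_kernel <- function(shape = c("hann", "accel", "biphasic", "delta"),
                         width_ms = 60, sample_rate = 1000) {
  shape <- match.arg(shape)
  if (shape == "delta") return(1)
  n <- max(3L, round(width_ms / 1000 * sample_rate))
  t <- seq(0, 1, length.out = n)
  k <- switch(shape,
    hann = {
      w <- 0.5 * (1 - cos(2 * pi * t))
      w / sum(w)
    },
    accel = {
      disp <- 0.5 * (1 - cos(2 * pi * t))
      a <- diff(disp, differences = 2)
      a <- a - mean(a)
      a / max(abs(a))
    },
    biphasic = {
      # first (positive) lobe occupies 40% of the support, second 60%
      split <- 0.4
      k <- ifelse(t < split,
                  sin(pi * t / split),
                  -split / (1 - split) * sin(pi * (t - split) / (1 - split)))
      k <- k - mean(k)
      k / max(abs(k))
    })
  k
}

#' Generate onset trains and drive waveforms from a stimulus design
#'
#' For each finger, stimulus onsets are laid out strictly periodically at
#' `1/f` within each active burst and quantized to the nearest sample of
#' the recording grid (nearest-millisecond at 1 kHz, so a 3-Hz train has a
#' stimulus-onset asynchrony of 333 ms). The continuous drive waveform is
#' the onset spike train convolved with a unit-area pulse kernel.
#'
#' @param design a [stimulus_design()].
#' @param kernel drive pulse kernel (numeric vector); defaults to a 50-ms
#'   unit-area Hann bump.
#' @return an object of class `stimulus_train`: a list with `onsets`
#'   (per-finger onset times, seconds, quantized), `drive` (per-finger
#'   drive waveforms, one row per finger), `time` (seconds), plus the
#'   design.
#' @export
make_stimulus_train <- function(design,
                                kernel = pulse_kernel("hann", 50, design$sample_rate)) {
  stopifnot(inherits(design, "stimulus_design"))
  fs <- design$sample_rate
  n <- round(design$total_duration * fs)
  onsets <- vector("list", length(design$fingers))
  names(onsets) <- design$fingers
  drive <- matrix(0, nrow = length(design$fingers), ncol = n,
                  dimnames = list(design$fingers, NULL))
  for (i in seq_along(design$fingers)) {
    f <- design$freq[i]
    if (fs / f < 2)
      stop_ckc("stimulation frequency %g Hz for finger %s is not representable on the %g Hz sample grid",
               f, design$fingers[i], fs)
    on_t <- numeric(0)
    for (b in seq_len(nrow(design$bursts))) {
      b0 <- design$bursts[b, "start"]
      b1 <- b0 + design$bursts[b, "duration"]
      k <- 0:floor((b1 - b0) * f)
      t_true <- b0 + k / f
      t_true <- t_true[t_true < b1 - 1e-12]
      samp <- round(t_true * fs)
      if (anyDuplicated(samp))
        stop_ckc("stimulation frequency %g Hz for finger %s collapses onsets on the %g Hz sample grid",
                 f, design$fingers[i], fs)
      on_t <- c(on_t, samp / fs)
    }
    onsets[[i]] <- on_t
    spikes <- numeric(n)
    idx <- round(on_t * fs) + 1L
    spikes[idx[idx <= n]] <- 1
    d <- convolve_causal(spikes, kernel)
    drive[i, ] <- d
  }
  structure(list(onsets = onsets, drive = drive, time = (seq_len(n) - 1L) / fs,
                 design = design, kernel = kernel),
            class = "stimulus_train")
}

# causal linear convolution truncated to the length of x; FFT-based with
# padding to a highly composite length
convolve_causal <- function(x, kernel) {
  if (length(kernel) == 1L) return(x * kernel)
  n <- length(x)
  m <- length(kernel)
  N <- stats::nextn(n + m - 1L, c(2L, 3L, 5L))
  X <- stats::fft(c(x, numeric(N - n)))
  K <- stats::fft(c(kernel, numeric(N - m)))
  Re(stats::fft(X * K, inverse = TRUE))[seq_len(n)] / N
}
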