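test_that("epoch spectra match direct DFT identities", {
  fs <- 1000; n <- 400
  # bin-centered sinusoid (10 Hz = bin 5 at 2.5 Hz resolution): all power
  # lands in that bin
  t <- (0:(n - 1)) / fs
  s <- sin(2 * pi * 10 * t)
  es <- epoch_set(array(rep(s, 2), c(1, n, 2)), cbind(s, s), fs)
  sp <- epoch_spectra(es)
  bin <- which(sp$freqs == 10)
  expect_gt(sp$Pxx[1, bin] / sum(sp$Pxx[1, ]), 0.999999)

  # X = Y per epoch: Pxy = Pxx = Pyy at every bin, coherence 1 where power
  set.seed(1)
  x <- matrix(rnorm(n * 6), n, 6)
  es <- epoch_set(array(x, c(1, n, 6)), x, fs)
  sp <- epoch_spectra(es)
  expect_equal(Re(sp$Pxy[1, ]), sp$Pxx[1, ], tolerance = 1e-12)
  expect_equal(sp$Pxx[1, ], sp$Pyy, tolerance = 1e-12)
  expect_equal(max(abs(coherence(sp) - 1)), 0, tolerance = 1e-9)

  # averaged white-noise auto-spectrum is flat at sigma^2 * n
  esw <- white_epochs(400, n = 64, seed = 6)
  spw <- epoch_spectra(esw)
  inner <- 2:32
  expect_equal(mean(spw$Pxx[1, inner]) / 64, 1, tolerance = 0.05)
  expect_lt(max(abs(spw$Pxx[1, inner] / 64 - 1)), 5 / sqrt(400))

  expect_error(epoch_spectra(white_epochs(1, n = 64)), "K >= 2")
})

test_that("coherence of independent noise concentrates at the 1/K bias", {
  es <- white_epochs(50, n = 256, nch = 2, seed = 3)
  coh <- coherence(epoch_spectra(es))
  v <- as.vector(coh[, 2:128])              # 254 bin-replicates, DC/Nyquist out
  se <- stats::sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 1 / 50), 3 * se)
})

test_that("equal-variance additive noise drives coherence to one half", {
  set.seed(4)
  K <- 1000; n <- 64
  x <- matrix(rnorm(n * K), n, K)
  es <- epoch_set(array(x, c(1, n, K)), x + matrix(rnorm(n * K), n, K), 1000)
  coh <- coherence(epoch_spectra(es))
  expect_lt(abs(mean(coh[1, 2:32]) - 0.5), 0.02)
})

test_that("coherence is bounded and invariant to channel or reference scaling", {
  set.seed(9)
  for (case in 1:10) {
    K <- sample(2:12, 1); n <- sample(c(32, 64, 100), 1); nch <- sample(1:3, 1)
    es <- epoch_set(array(rnorm(nch * n * K), c(nch, n, K)),
                    matrix(rnorm(n * K), n, K), 1000)
    coh <- coherence(epoch_spectra(es))
    expect_true(all(coh >= 0 & coh <= 1 + 1e-12))
  }

  es <- white_epochs(8, n = 64, nch = 2, seed = 10)
  base <- coherence(epoch_spectra(es))
  es$ref <- es$ref * 37.5
  expect_equal(coherence(epoch_spectra(es)), base, tolerance = 1e-12)
  es$meg[2, , ] <- es$meg[2, , ] * -0.003
  expect_equal(coherence(epoch_spectra(es)), base, tolerance = 1e-12)

  # zero-power bin is undefined, not zero
  es$meg[1, , ] <- 0
  expect_true(all(is.na(coherence(epoch_spectra(es))[1, ])))
})

test_that("significance threshold follows the closed form and is monotone", {
  # n_trials/d = 2 makes the exponent 1: threshold = 1 - alpha/(Nsens Nf)
  expect_equal(significance_threshold(0.05, 1, 1, n_trials = 2), 0.95)
  expect_equal(significance_threshold(0.05, 204, 1, n_trials = 2),
               1 - 0.05 / 204)
  expect_equal(significance_threshold(0.01, 10, 2, n_trials = 10, d = 5),
               1 - (0.01 / 20)^(1 / (10 / 5 - 1)))
  # strictly decreasing in the effective trial count
  thr <- vapply(seq(3, 300, by = 7), function(m)
    significance_threshold(0.05, 204, 1, m), numeric(1))
  expect_true(all(diff(thr) < 0))
  expect_true(all(thr > 0 & thr < 1))
  expect_error(significance_threshold(0.05, 204, 1, n_trials = 1), "exceed")
  expect_error(significance_threshold(1.5, 204, 1, n_trials = 10), "alpha")
})

test_that("peak extraction honors the channel set, tie rule and bin grid", {
  freqs <- seq(0, 10, by = 0.25)
  channels <- data.frame(channel = 1:4, kind = c("grad", "grad", "mag", "grad"),
                         pair = c(2L, 1L, NA, NA), x = 0, y = 0, z = 0)
  coh <- matrix(0.1, 4, length(freqs))
  bin3 <- which(freqs == 3)
  coh[2, bin3] <- 0.8
  coh[3, bin3] <- 0.95                     # magnetometer: excluded by default
  p <- peak_ckc(coh, freqs, 3, channels)
  expect_equal(p$channel, 2L)
  expect_equal(p$value, 0.8)
  expect_equal(p$pair, 1L)
  expect_equal(peak_ckc(coh, freqs, 3, channels, channel_set = "all")$channel, 3L)

  # exact tie resolves to the lowest channel index
  coh[4, bin3] <- 0.8
  expect_equal(peak_ckc(coh, freqs, 3, channels)$channel, 2L)

  expect_error(peak_ckc(coh, freqs, 3.1, channels), "bin grid")
  expect_message(p2 <- peak_ckc(coh, freqs, 3.1, channels, snap = TRUE), "snap")
  expect_equal(p2$bin, bin3)
})

test_that("ckc fit ties together spectra, peak and threshold", {
  sim <- cached_toy("fit", seed = 2, n_sites = 12, duration_s = 60, gain = 12,
                    sample_rate = 500)
  fit <- ckc(sim$epochs, 3)
  expect_s3_class(fit, "ckc")
  expect_equal(fit$K, sim$epochs$K)
  expect_equal(fit$peak$value, max(fit$coh[fit$channels$kind == "grad",
                                           fit$peak$bin]))
  expect_equal(fit$threshold,
               significance_threshold(0.05, sum(fit$channels$kind == "grad"),
                                      1, fit$K))
  expect_equal(fit$significant, fit$peak$value > fit$threshold)
  expect_true(fit$significant)             # coupled simulation must couple
  co <- coef(fit)
  expect_equal(unname(co["peak_ckc"]), fit$peak$value)
  expect_output(print(fit), "peak CKC")
  expect_output(print(summary(fit)), "threshold")
})

test_that("peak CKC is robust to the exact reference waveform", {
  sim <- cached_toy("robust", seed = 5, n_sites = 12, duration_s = 120, gain = 60,
                    sample_rate = 500)
  fit_true <- ckc(sim$epochs, 3)
  # surrogate periodic reference with identical onsets but a different shape
  fs <- 500
  n <- ncol(sim$recording$data)
  spikes <- numeric(n)
  spikes[round(unlist(sim$recording$onsets) * fs) + 1] <- 1
  surrogate <- as.vector(stats::filter(spikes, rep(1, 25), sides = 1))
  surrogate[is.na(surrogate)] <- 0
  ep <- segment_epochs(sim$recording, surrogate, epoch_spec())
  fit_surr <- ckc(normalize_ref_epochs(reject_epochs(ep)), 3)
  expect_lt(abs(fit_surr$peak$value - fit_true$peak$value), 0.05)
})

test_that("phase-scrambled surrogate references destroy significance", {
  # per-epoch random circular shifts of the reference randomize the
  # stimulus phase epoch by epoch, which is the surrogate that breaks the
  # MEG-reference phase locking (plain epoch re-pairing does not: with a
  # 3995-ms step the 3-Hz phase advances only ~5 degrees per epoch, so
  # re-paired epochs remain nearly aligned)
  sim <- cached_toy("fit", seed = 2, n_sites = 12, duration_s = 60, gain = 12,
                    sample_rate = 500)
  expect_true(ckc(sim$epochs, 3)$significant)
  set.seed(77)
  L <- nrow(sim$epochs$ref)
  hits <- vapply(1:10, function(i) {
    ep <- sim$epochs
    for (k in seq_len(ep$K)) {
      sft <- sample(L - 1, 1)
      ep$ref[, k] <- ep$ref[c((sft + 1):L, 1:sft), k]
    }
    ckc(ep, 3)$significant
  }, logical(1))
  expect_lte(sum(hits), 1)
})

test_that("summed recordings preserve alignment contracts", {
  sim <- cached_toy("fit", seed = 2, n_sites = 12, duration_s = 60, gain = 12,
                    sample_rate = 500)
  rec <- sim$recording
  # summing a recording with itself rescales the data: coherence unchanged
  s2 <- sum_recordings(list(rec, rec))
  expect_equal(s2$data, 2 * rec$data)
  ep <- segment_epochs(s2, sim$acc$D2, epoch_spec())
  fit2 <- ckc(normalize_ref_epochs(reject_epochs(ep)), 3)
  expect_equal(fit2$peak$value, ckc(sim$epochs, 3)$peak$value, tolerance = 1e-9)

  bad <- rec
  bad$onsets$D2 <- bad$onsets$D2 + 0.05    # 50-ms misalignment
  expect_error(sum_recordings(list(rec, bad)), "misaligned")
  short <- rec
  short$data <- short$data[, 1:1000]
  expect_error(sum_recordings(list(rec, short)), "share")
})

test_that("topography tables round-trip losslessly", {
  sim <- cached_toy("fit", seed = 2, n_sites = 12, duration_s = 60, gain = 12,
                    sample_rate = 500)
  fit <- ckc(sim$epochs, 3)
  tab <- topography_table(fit)
  expect_equal(nrow(tab), nrow(fit$channels))
  expect_equal(max(tab$coherence[tab$kind == "grad"]), fit$peak$value)
  path <- tempfile(fileext = ".tsv")
  write_topography(tab, path)
  back <- read_topography(path)
  expect_equal(back$coherence, tab$coherence)
  expect_equal(back$channel, tab$channel)
})
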