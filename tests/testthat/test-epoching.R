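test_that("epoch segmentation counts follow the step arithmetic", {
  fs <- 1000
  mk <- function(T_s) bare_recording(matrix(0, 3, T_s * fs), fs)
  ref <- function(T_s) rep(1, T_s * fs)
  spec <- epoch_spec()                      # 4000 ms epochs, 5 ms overlap

  # 60 s: floor((60000 - 4000)/3995) + 1 = 15 epochs
  e <- segment_epochs(mk(60), ref(60), spec)
  expect_equal(e$K, 15)
  expect_equal(e$start_s[1:2], c(0, 3.995))

  # exactly one epoch at the boundary
  expect_equal(segment_epochs(mk(4), ref(4), spec)$K, 1)

  # zero overlap: 10 s gives epochs at 0 and 4 s
  e0 <- segment_epochs(mk(10), ref(10), epoch_spec(overlap_ms = 0))
  expect_equal(e0$K, 2)
  expect_equal(e0$start_s, c(0, 4))

  # epochs must lie entirely within one burst: 3 x 60-s bursts -> 3 x 15
  eb <- segment_epochs(mk(200), ref(200), spec,
                       bursts = cbind(start = c(0, 70, 140),
                                      duration = c(60, 60, 60)))
  expect_equal(eb$K, 45)
  expect_true(all(eb$start_s + 4 <= c(rep(60, 15), rep(130, 15), rep(200, 15))))

  expect_error(segment_epochs(mk(2), ref(2), spec), "shorter")
})

test_that("acceleration band-pass keeps the passband and kills DC and 250 Hz", {
  t <- seq(1e-3, 60, by = 1e-3)
  mid <- 10000:50000
  f3 <- bandpass_acceleration(sin(2 * pi * 3 * t), 0.5, 195, 1000)
  amp <- sqrt(sum(f3[mid] * sin(2 * pi * 3 * t[mid]))^2 +
              sum(f3[mid] * cos(2 * pi * 3 * t[mid]))^2) / (length(mid) / 2)
  expect_equal(amp, 1, tolerance = 0.01)

  dc <- bandpass_acceleration(rep(5, 60000), 0.5, 195, 1000)
  expect_lt(max(abs(dc[mid])), 1e-3 * 5)

  f250 <- bandpass_acceleration(sin(2 * pi * 250 * t), 0.5, 195, 1000)
  expect_lt(20 * log10(max(abs(f250[mid]))), -20)

  expect_error(bandpass_acceleration(t, 0.5, 600, 1000), "inside")
})

test_that("euclidean norm magnitude matches the element-wise oracle", {
  expect_equal(euclidean_norm_magnitude(3, 4, 0), 5)
  expect_equal(euclidean_norm_magnitude(numeric(5), numeric(5), numeric(5)),
               numeric(5))
  set.seed(2)
  x <- rnorm(100); y <- rnorm(100); z <- rnorm(100)
  expect_equal(euclidean_norm_magnitude(x, y, z),
               vapply(1:100, function(i) sqrt(x[i]^2 + y[i]^2 + z[i]^2), numeric(1)))
  expect_error(euclidean_norm_magnitude(1:3, 1:3, 1:4), "equal length")
})

test_that("peak-to-peak rejection drops planted artifact epochs one-for-one", {
  fs <- 1000
  data <- matrix(0, 3, 60 * fs)             # grad, grad, mag
  # plant super-threshold transients wholly inside epochs 2, 7 and 11
  planted <- c(2L, 7L, 11L)
  for (k in planted) {
    s <- (k - 1) * 3995 + 500
    data[1, s:(s + 100)] <- 2500            # > 2000 fT/cm on a gradiometer
  }
  # at-threshold magnetometer excursion (p2p exactly 4000) must be kept
  s <- 3 * 3995 + 500
  data[3, s:(s + 50)] <- 2000
  data[3, (s + 60):(s + 110)] <- -2000
  rec <- bare_recording(data, fs)
  ep <- segment_epochs(rec, rep(1, 60 * fs), epoch_spec())
  kept <- reject_epochs(ep)
  expect_equal(kept$rejected, planted)
  expect_equal(kept$K, 12)

  # all-zero data: nothing rejected
  ep0 <- segment_epochs(bare_recording(matrix(0, 3, 60 * fs), fs),
                        rep(1, 60 * fs), epoch_spec())
  expect_equal(reject_epochs(ep0)$K, 15)

  # everything over threshold: informative error
  epb <- segment_epochs(bare_recording(matrix(3000, 3, 10 * fs) +
                                         matrix(rnorm(30000), 3), fs),
                        rep(1, 10 * fs),
                        epoch_spec(grad_thresh = 1, mag_thresh = 1))
  expect_error(reject_epochs(epb), "all .* rejected|peak-to-peak")
})

test_that("rejection is monotone in the thresholds", {
  set.seed(5)
  data <- matrix(rnorm(3 * 30000, sd = 600), 3)
  rec <- bare_recording(data)
  ep <- segment_epochs(rec, rep(1, 30000), epoch_spec())
  Ks <- vapply(c(1000, 2000, 3000, 5000), function(thr)
    tryCatch(reject_epochs(ep, epoch_spec(grad_thresh = thr,
                                          mag_thresh = 2 * thr))$K,
             error = function(e) 0L), integer(1))
  expect_true(all(diff(Ks) >= 0))
})

test_that("cleaning commutes with channel reordering", {
  set.seed(8)
  data <- matrix(rnorm(4 * 20000, sd = 250), 4)
  kinds <- c("grad", "grad", "mag", "mag")
  perm <- c(3L, 1L, 4L, 2L)
  e1 <- reject_epochs(segment_epochs(bare_recording(data, kinds = kinds),
                                     rep(1, 20000), epoch_spec()))
  e2 <- reject_epochs(segment_epochs(bare_recording(data[perm, ],
                                                    kinds = kinds[perm]),
                                     rep(1, 20000), epoch_spec()))
  expect_equal(e1$rejected, e2$rejected)
  expect_equal(e1$meg[perm, , ], e2$meg)
})

test_that("reference normalization yields exact unit norms and is idempotent", {
  fs <- 1000
  rec <- bare_recording(matrix(0, 2, 12 * fs), fs)
  ep <- segment_epochs(rec, rep(2, 12 * fs), epoch_spec(overlap_ms = 0))
  nn <- normalize_ref_epochs(ep)
  # constant 2.0 epoch of N samples becomes constant 1/sqrt(N)
  expect_equal(nn$ref[, 1], rep(1 / sqrt(4000), 4000))
  expect_equal(max(abs(sqrt(colSums(nn$ref^2)) - 1)), 0, tolerance = 1e-9)
  # idempotent on already-unit epochs
  expect_equal(normalize_ref_epochs(nn)$ref, nn$ref)

  set.seed(3)
  epr <- segment_epochs(rec, rnorm(12 * fs), epoch_spec(overlap_ms = 0))
  expect_equal(sqrt(colSums(normalize_ref_epochs(epr)$ref^2)), rep(1, 3),
               tolerance = 1e-9)

  ep$ref[] <- 0
  expect_error(normalize_ref_epochs(ep), "zero norm")
})

test_that("trial-count matching truncates the larger set reproducibly", {
  e15 <- white_epochs(15, n = 64, seed = 1)
  e9 <- white_epochs(9, n = 64, seed = 2)
  m <- match_trial_counts(e15, e9)
  expect_equal(m$a$K, 9)
  expect_equal(m$b$K, 9)
  expect_equal(m$K_a, 15)
  expect_equal(m$a$meg, e15$meg[, , 1:9, drop = FALSE])   # earliest kept

  # equal counts pass through unchanged
  m2 <- match_trial_counts(e9, white_epochs(9, n = 64, seed = 3))
  expect_identical(m2$a$meg, e9$meg)

  # seeded random subset is stable across reruns
  r1 <- match_trial_counts(e15, e9, method = "random", seed = 11)
  r2 <- match_trial_counts(e15, e9, method = "random", seed = 11)
  expect_identical(r1$a$meg, r2$a$meg)
})
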