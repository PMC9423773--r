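test_that("single-frequency CSD agrees with the spectral estimates and a loop oracle", {
  es <- white_epochs(6, n = 64, nch = 3, seed = 12)
  sp <- epoch_spectra(es)
  bin_f <- 125                              # 125 Hz = bin 9 at 1 kHz / 64
  cs <- csd_at_frequency(es, bin_f, channel_idx = 1:3)
  bin <- which(sp$freqs == bin_f)
  # diagonal equals the averaged auto-spectra
  expect_equal(Re(diag(cs$csd)), unname(sp$Pxx[, bin]), tolerance = 1e-10)
  expect_equal(cs$cross, unname(sp$Pxy[, bin]), tolerance = 1e-10)
  expect_equal(cs$ref_power, sp$Pyy[bin], tolerance = 1e-10)

  # brute-force loop over epochs
  acc <- matrix(0 + 0i, 3, 3)
  for (k in 1:6) {
    X <- vapply(1:3, function(c) stats::fft(es$meg[c, , k])[bin], complex(1))
    acc <- acc + X %*% Conj(t(X))
  }
  expect_equal(cs$csd, acc / 6, tolerance = 1e-10)
  expect_true(max(Mod(cs$csd - Conj(t(cs$csd)))) < 1e-12)   # Hermitian

  # a duplicated channel makes the CSD rank deficient
  es$meg[2, , ] <- es$meg[1, , ]
  cs2 <- csd_at_frequency(es, bin_f, channel_idx = 1:2)
  ev <- eigen(cs2$csd, only.values = TRUE)$values
  expect_lt(Re(ev[2]) / Re(ev[1]), 1e-10)
})

test_that("lead-field rank reduction keeps the top-2 singular subspace", {
  set.seed(13)
  # third column zero: reduction spans the first two columns exactly
  b <- cbind(rnorm(8), rnorm(8), 0)
  red <- reduce_leadfield_rank(b)
  fitres <- b[, 1:2] - red %*% qr.solve(red, b[, 1:2])
  expect_lt(max(abs(fitres)), 1e-10)

  # generic block: residual of projecting the block on the reduced space
  # equals the third singular value
  b2 <- matrix(rnorm(24), 8, 3)
  red2 <- reduce_leadfield_rank(b2)
  proj <- red2 %*% qr.solve(red2, b2)
  expect_equal(svd(b2 - proj)$d[1], svd(b2)$d[3], tolerance = 1e-9)
  expect_equal(attr(red2, "sv"), svd(b2)$d)

  # deterministic sign convention
  expect_true(all(apply(red2, 2, function(col) col[which.max(abs(col))] > 0)))
  expect_error(reduce_leadfield_rank(matrix(0, 8, 3)), "all-zero")
})

test_that("DICS maps vanish without cross-spectrum and find a planted source", {
  # zero sensor-reference cross-spectral vector: all node coherences 0
  set.seed(14)
  nc <- 6
  Xm <- matrix(complex(real = rnorm(nc * 40), imaginary = rnorm(nc * 40)), nc)
  csd <- (Xm %*% Conj(t(Xm))) / 40
  fake <- list(csd = (csd + Conj(t(csd))) / 2, cross = complex(nc),
               ref_power = 1, K = 40, channel_idx = 1:nc, freq = 3)
  lf <- list(blocks = replicate(4, matrix(rnorm(nc * 2), nc), simplify = FALSE),
             grid = source_grid(matrix(rnorm(12), 4), 3))
  map <- dics_coherence_map(fake, lf)
  expect_equal(map$coh, rep(0, 4))

  # high-SNR coupled source on a coarse grid localizes to the true node
  sim <- cached_toy("dics", seed = 3, n_sites = 8, duration_s = 300, gain = 150,
                    grid = small_grid(), sample_rate = 500)
  cs <- csd_at_frequency(sim$epochs, 3)
  map <- dics_coherence_map(cs, sim$leadfield)
  expect_equal(peak_source_location(map)$node, sim$node)
  expect_true(all(map$coh >= 0 & map$coh <= 1))
})

test_that("source peak coherence is comparable to the sensor peak", {
  sim <- cached_toy("dics", seed = 3, n_sites = 8, duration_s = 300, gain = 150,
                    grid = small_grid(), sample_rate = 500)
  sens <- ckc(sim$epochs, 3)$peak$value
  src <- dics_coherence_map(csd_at_frequency(sim$epochs, 3), sim$leadfield)$peak_value
  expect_gt(src, 0.8 * sens)
})

test_that("DICS maps are invariant to reference scaling and channel permutation", {
  sim <- cached_toy("dics", seed = 3, n_sites = 8, duration_s = 300, gain = 150,
                    grid = small_grid(), sample_rate = 500)
  cs <- csd_at_frequency(sim$epochs, 3)
  base <- dics_coherence_map(cs, sim$leadfield)$coh

  ep2 <- sim$epochs
  ep2$ref <- ep2$ref * 4.2                  # rescaled reference
  cs2 <- csd_at_frequency(ep2, 3)
  expect_equal(dics_coherence_map(cs2, sim$leadfield)$coh, base, tolerance = 1e-9)

  # permute gradiometer channels together with the lead-field rows
  grads <- which(sim$epochs$channels$kind == "grad")
  set.seed(15)
  perm <- sample(grads)
  blocks <- lapply(seq_len(dim(sim$leadfield$L)[3]), function(k)
    reduce_leadfield_rank(sim$leadfield$L[perm, , k]))
  cs3 <- csd_at_frequency(sim$epochs, 3, channel_idx = perm)
  map3 <- dics_coherence_map(cs3, list(blocks = blocks, grid = sim$leadfield$grid))
  expect_equal(map3$coh, base, tolerance = 1e-8)
})

test_that("a coupled node outranks an uncoupled one", {
  grid <- small_grid()
  lf <- cached_leadfield(12, grid)
  ok <- vapply(1:5, function(s) {
    d <- stimulus_design("simultaneous_varied", fingers = c("D2", "D3"),
                         freq = c(3, 2), bursts = cbind(start = 0, duration = 120),
                         sample_rate = 500)
    truth <- ground_truth(source_nodes = c(D2 = 1L, D3 = 27L),
                          gains = c(D2 = 40, D3 = 40),
                          cross_finger_interference = 0, seed = s)
    run <- ckc:::simulate_and_epoch(d, truth, lf, epoch_spec(), "D2")
    map <- dics_coherence_map(csd_at_frequency(run$epochs, 3), lf)
    # D2 (3 Hz, coupled to the reference) must beat D3 (2 Hz, uncoupled)
    map$coh[1] > map$coh[27]
  }, logical(1))
  expect_true(all(ok))
})

test_that("peak extraction from maps follows the scan oracle and tie rule", {
  grid <- source_grid(matrix(c(0, 0, 40, 0, 0, 50, 0, 0, 60), 3, byrow = TRUE), 10)
  mk <- function(v) structure(list(coh = v, grid = grid, peak_node = which.max(v),
                                   peak_value = max(v), reg = 0.05, freq = 3, K = 10),
                              class = "ckc_source_map")
  p <- peak_source_location(mk(c(0, 0.4, 0)))
  expect_equal(p$node, 2L)
  expect_equal(unname(p$xyz), c(0, 0, 50))
  # uniform map: lowest node index wins
  expect_equal(peak_source_location(mk(rep(0.2, 3)))$node, 1L)
  set.seed(16)
  v <- runif(3)
  expect_equal(peak_source_location(mk(v))$node, which(v == max(v))[1])
})
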