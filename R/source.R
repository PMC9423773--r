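#' Cross-spectral density at one frequency
#'
#' At the stimulation-frequency bin, computes the sensor cross-spectral
#' density matrix `CSD = (1/K) sum_k x_k x_k^H`, the sensor--reference
#' cross-spectral vector `(1/K) sum_k x_k y_k*` and the reference power
#' `(1/K) sum_k |y_k|^2` from the same epochs, where `x_k` and `y_k` are
#' the DFT coefficients of MEG and reference epoch `k` at that bin.
#'
#' @param epochs an `epoch_set` with `K >= 2`.
#' @param stim_freq frequency (Hz) on the epoch DFT bin grid.
#' @param channel_idx channels entering the CSD; defaults to the
#'   gradiometers (one sensor unit, so no cross-unit whitening is
#'   needed).
#' @param snap snap an off-grid frequency to the nearest bin (logged).
#' @return list with `csd` (Hermitian complex matrix), `cross` (complex
#'   vector), `ref_power` (scalar), `K`, `channel_idx`, `freq`.
#' @export
csd_at_frequency <- function(epochs, stim_freq, channel_idx = NULL, snap = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  K <- epochs$K
  if (K < 2) stop_ckc("CSD needs K >= 2 epochs (got %d)", K)
  channel_idx <- channel_idx %||% which(epochs$channels$kind == "grad")
  n <- dim(epochs$meg)[2]
  freqs <- (0:(n %/% 2)) * epochs$sample_rate / n
  bin <- freq_bin(freqs, stim_freq, snap)
  nc <- length(channel_idx)
  csd <- matrix(0 + 0i, nc, nc)
  cross <- complex(nc)
  ref_power <- 0
  for (k in seq_len(K)) {
    X <- stats::mvfft(t(matrix(epochs$meg[channel_idx, , k], nrow = nc)))[bin, ]
    Y <- stats::fft(epochs$ref[, k])[bin]
    csd <- csd + tcrossprod(X, Conj(X))
    cross <- cross + X * Conj(Y)
    ref_power <- ref_power + Re(Y * Conj(Y))
  }
  csd <- csd / K
  csd <- (csd + Conj(t(csd))) / 2           # enforce exact Hermitian symmetry
  list(csd = csd, cross = cross / K, ref_power = ref_power / K, K = K,
       channel_idx = channel_idx, freq = freqs[bin])
}

#' Reduce a lead-field block from three to two orientation components
#'
#' Keeps the two left singular directions with the largest singular
#' values of a channels x 3 gain block (the quasi-radial third direction
#' of a sphere model carries no signal). A deterministic sign convention
#' makes the largest-magnitude element of each kept column positive.
#'
#' @param block channels x 3 numeric matrix.
#' @return channels x 2 matrix with attribute `"sv"` (the three singular
#'   values).
#' @export
reduce_leadfield_rank <- function(block) {
  block <- as.matrix(block)
  if (!all(is.finite(block)) || all(block == 0))
    stop_ckc("lead-field block must be finite and not all-zero")
  s <- svd(block)
  red <- s$u[, 1:2, drop = FALSE] %*% diag(s$d[1:2], 2)
  for (j in 1:2) {
    i <- which.max(abs(red[, j]))
    if (red[i, j] < 0) red[, j] <- -red[, j]
  }
  attr(red, "sv") <- s$d
  red
}

#' DICS beamformer coherence map
#'
#' Scans a source grid with a frequency-domain spatial filter: with the
#' diagonally loaded CSD `C` and the rank-reduced lead field `L` of a
#' node, the filter is the unit-gain minimum-variance beamformer
#' `W = (L^H C^-1 L)^-1 L^H C^-1`, and the node's coherence with the
#' reference is maximized over source orientation inside the 2-D reduced
#' space (the dominant generalized eigen-direction), giving
#' `coh = Re(b^H M^-1 b) / Pyy` with `M = L^H C^-1 L` and
#' `b = L^H C^-1 Pxy`.
#'
#' @param csd output of [csd_at_frequency()].
#' @param leadfield a `lead_field` (full 3-component blocks; reduced
#'   internally) or a list of pre-reduced channels x 2 blocks.
#' @param reg diagonal-loading factor: `lambda = reg * mean(diag(CSD))`
#'   is added to the diagonal before inversion (default 0.05).
#' @return object of class `ckc_source_map`: per-node coherence, peak
#'   node/value, the grid, and the regularization used.
#' @export
dics_coherence_map <- function(csd, leadfield, reg = 0.05) {
  if (inherits(leadfield, "lead_field")) {
    nodes <- leadfield$grid$nodes
    blocks <- lapply(seq_len(dim(leadfield$L)[3]), function(k)
      reduce_leadfield_rank(leadfield$L[csd$channel_idx, , k]))
    grid <- leadfield$grid
  } else {
    blocks <- leadfield$blocks
    grid <- leadfield$grid
    nodes <- grid$nodes
  }
  C <- csd$csd
  lambda <- reg * mean(Re(diag(C)))
  if (lambda > 0) C <- C + diag(lambda, nrow(C))
  Ci <- tryCatch(solve(C), error = function(e)
    stop_ckc("CSD is singular; increase the diagonal loading (reg = %g)", reg))
  b_all <- Ci %*% csd$cross
  n_nodes <- length(blocks)
  coh <- numeric(n_nodes)
  for (k in seq_len(n_nodes)) {
    L2 <- blocks[[k]]
    A <- Ci %*% L2
    M <- Conj(t(L2)) %*% A                   # L^H C^-1 L, 2 x 2 Hermitian
    b <- Conj(t(L2)) %*% b_all               # L^H C^-1 cross
    v <- Re(Conj(t(b)) %*% solve(M, b)) / csd$ref_power
    coh[k] <- max(0, min(1, v))
  }
  peak <- which.max(coh)
  structure(list(coh = coh, grid = grid, peak_node = peak,
                 peak_value = coh[peak], reg = reg, freq = csd$freq,
                 K = csd$K),
            class = "ckc_source_map")
}

#' Coordinates and value of the map maximum
#'
#' @param map a `ckc_source_map`.
#' @return list with `xyz` (mm), `node` index and `value`; ties go to the
#'   lowest node index.
#' @export
peak_source_location <- function(map) {
  stopifnot(inherits(map, "ckc_source_map"))
  i <- which.max(map$coh)                    # first maximum on ties
  list(xyz = map$grid$nodes[i, ], node = i, value = map$coh[i])
}

#' @export
print.ckc_source_map <- function(x, ...) {
  p <- peak_source_location(x)
  cat(sprintf("DICS coherence map at %g Hz: %d nodes, K = %d epochs\n",
              x$freq, length(x$coh), x$K))
  cat(sprintf("  peak coherence %.3f at node %d (%.1f, %.1f, %.1f) mm [reg %g]\n",
              p$value, p$node, p$xyz[1], p$xyz[2], p$xyz[3], x$reg))
  invisible(x)
}
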