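# shared fixtures; lead fields are cached because the analytic forward
# model is deterministic and moderately expensive

.fixture_cache <- new.env(parent = emptyenv())

small_grid <- function() cubic_grid(half_extent = 6, spacing = 6)

test_grid <- function() cubic_grid(half_extent = 9, spacing = 3)

cached_leadfield <- function(n_sites = 16, grid = small_grid()) {
  key <- sprintf("lf-%d-%d", n_sites, nrow(grid$nodes))
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_toy_leadfield(grid, sensor_array(n_sites))
  .fixture_cache[[key]]
}

cached_toy <- function(key, ...) {
  key <- sprintf("toy-%s", key)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- ckc_toy_simulation(...)
  .fixture_cache[[key]]
}

# independent white-noise MEG/reference epochs
white_epochs <- function(K, n = 128, nch = 1, seed = 1, fs = 1000) {
  set.seed(seed)
  epoch_set(array(rnorm(nch * n * K), c(nch, n, K)),
            matrix(rnorm(n * K), n, K), fs)
}

# bare sensor_recording with given data matrix (for planted-artifact tests)
bare_recording <- function(data, fs = 1000, kinds = NULL) {
  nc <- nrow(data)
  kinds <- kinds %||% rep(c("grad", "grad", "mag"), length.out = nc)
  pair <- rep(NA_integer_, nc)
  g <- which(kinds == "grad")
  if (length(g) >= 2) pair[g[1:2]] <- g[2:1]
  structure(list(data = data,
                 channels = data.frame(channel = seq_len(nc), site = NA,
                                       kind = kinds,
                                       unit = ifelse(kinds == "grad", "fT/cm", "fT"),
                                       x = 0, y = 0, z = 0, pair = pair),
                 sample_rate = fs, design = NULL, onsets = NULL),
            class = "sensor_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
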