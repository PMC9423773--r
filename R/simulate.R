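#' Synthetic whole-head MEG sensor array
#'
#' Lays out a helmet-like array of sensor sites on a spherical cap, each
#' site carrying two orthogonal planar gradiometers (field-gradient
#' channels, fT/cm) and one magnetometer (field channels, fT). The
#' default 102 sites give the conventional 204 + 102 channel layout.
#'
#' @param n_sites number of sensor sites (3 channels per site).
#' @param radius sensor shell radius in mm.
#' @param zmin lowest normalized cap height (z/radius) covered by the
#'   helmet; -0.15 reaches slightly below the head equator.
#' @param grad_baseline planar-gradiometer baseline in mm (field sampled
#'   at +/- baseline along each tangential direction).
#' @return object of class `sensor_array`: channel table (`channels`),
#'   site positions/orientations, and geometry parameters.
#' @export
sensor_array <- function(n_sites = 102, radius = 120, zmin = -0.15,
                         grad_baseline = 10) {
  stopifnot(is_count(n_sites), radius > 0, grad_baseline > 0)
  i <- seq_len(n_sites)
  z <- 1 - (i - 0.5) / n_sites * (1 - zmin)
  phi <- i * pi * (3 - sqrt(5))           # golden-angle spiral
  rho <- sqrt(pmax(0, 1 - z^2))
  normals <- cbind(rho * cos(phi), rho * sin(phi), z)
  pos <- normals * radius
  # tangential frame at each site
  t1 <- cbind(-normals[, 2], normals[, 1], 0)
  degen <- row_norms(t1) < 1e-6
  t1[degen, ] <- rep(c(1, 0, 0), each = sum(degen))
  t1 <- unit_rows(t1)
  t2 <- cbind(normals[, 2] * t1[, 3] - normals[, 3] * t1[, 2],
              normals[, 3] * t1[, 1] - normals[, 1] * t1[, 3],
              normals[, 1] * t1[, 2] - normals[, 2] * t1[, 1])
  n_chan <- 3L * n_sites
  site <- rep(i, each = 3L)
  kind <- rep(c("grad", "grad", "mag"), times = n_sites)
  unit <- ifelse(kind == "grad", "fT/cm", "fT")
  ch <- seq_len(n_chan)
  pair <- rep(NA_integer_, n_chan)
  pair[kind == "grad"] <- ch[kind == "grad"] + rep(c(1L, -1L), times = n_sites)
  channels <- data.frame(channel = ch, site = site, kind = kind, unit = unit,
                         x = pos[site, 1], y = pos[site, 2], z = pos[site, 3],
                         pair = pair)
  structure(list(channels = channels, pos = pos, normals = normals,
                 t1 = t1, t2 = t2, radius = radius,
                 grad_baseline = grad_baseline, n_sites = n_sites),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("MEG sensor array: %d sites (%d planar gradiometers + %d magnetometers), radius %g mm\n",
              x$n_sites, 2 * x$n_sites, x$n_sites, x$radius))
  invisible(x)
}

#' Volumetric source grid
#'
#' @param nodes numeric N x 3 matrix of node coordinates (mm).
#' @param spacing nominal grid spacing in mm.
#' @return object of class `source_grid`.
#' @export
source_grid <- function(nodes, spacing) {
  nodes <- as.matrix(nodes)
  if (ncol(nodes) != 3L || !all(is.finite(nodes)))
    stop_ckc("nodes must be a finite N x 3 matrix")
  if (anyDuplicated(nodes)) stop_ckc("grid nodes must be unique")
  if (!is.numeric(spacing) || spacing <= 0) stop_ckc("spacing must be > 0")
  structure(list(nodes = nodes, spacing = spacing), class = "source_grid")
}

#' Cubic source grid around a point
#'
#' Convenience constructor of a regular cubic [source_grid()] centered on a
#' point of interest (default: a left-hemisphere hand-area location),
#' clipped to a maximum radius from the head origin.
#'
#' @param center grid center (mm).
#' @param half_extent half edge length of the cube (mm).
#' @param spacing grid spacing in mm (3 mm default; coarser grids are used
#'   for fast tests).
#' @param max_radius drop nodes farther than this from the origin (mm).
#' @export
cubic_grid <- function(center = c(-40, -25, 55), half_extent = 9, spacing = 3,
                       max_radius = 85) {
  ax <- seq(-half_extent, half_extent, by = spacing)
  nodes <- as.matrix(expand.grid(x = center[1] + ax, y = center[2] + ax,
                                 z = center[3] + ax))
  keep <- row_norms(nodes) < max_radius
  source_grid(nodes[keep, , drop = FALSE], spacing)
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("Source grid: %d nodes, %g mm spacing\n", nrow(x$nodes), x$spacing))
  invisible(x)
}

# Magnetic field of a tangential current dipole in a conducting sphere
# (Sarvas closed form, sphere centered at the origin; arbitrary overall
# scale). Returns, for each evaluation point, the 3 x 3 matrix of field
# vectors for unit dipoles along the three Cartesian axes, as a P x 3 x 3
# array [point, field component, dipole component].
sarvas_field <- function(pts, r0, scale = 1e5) {
  pts <- matrix(pts, ncol = 3)
  P <- nrow(pts)
  out <- array(0, dim = c(P, 3, 3))
  if (all(r0 == 0)) return(out)             # dipole at the sphere center is silent
  avec <- sweep(pts, 2, r0)                 # a = r - r0
  a <- row_norms(avec)
  R <- row_norms(pts)
  adotr <- rowSums(avec * pts)
  r0dotr <- as.vector(pts %*% r0)
  F_ <- a * (R * a + R^2 - r0dotr)
  c1 <- a^2 / R + adotr / a + 2 * a + 2 * R
  c2 <- a + 2 * R + adotr / a
  gradF <- c1 * pts - outer(c2, r0)
  Q <- rbind(c(0, -r0[3], r0[2]),           # e1 x r0
             c(r0[3], 0, -r0[1]),           # e2 x r0
             c(-r0[2], r0[1], 0))           # e3 x r0
  for (j in 1:3) {
    qr <- as.vector(pts %*% Q[j, ])
    Bj <- (F_ * matrix(Q[j, ], nrow = P, ncol = 3, byrow = TRUE) - qr * gradF) / F_^2
    out[, , j] <- Bj * scale
  }
  out
}

#' Toy single-sphere lead field
#'
#' Analytic forward model for the synthetic sensor array: the magnetic
#' field of a current dipole in a homogeneous conducting sphere (Sarvas
#' closed form). Each grid node gets a channels x 3 gain block (one column
#' per Cartesian dipole orientation); magnetometers read the field along
#' the sensor normal, planar gradiometers read its tangential derivative
#' (per cm). Gains decay with node--sensor distance and radial dipoles are
#' silent, as in a real sphere model. The map is deterministic given the
#' geometry.
#'
#' @param grid a [source_grid()]; nodes must lie strictly inside the
#'   sensor shell.
#' @param sensors a [sensor_array()].
#' @return object of class `lead_field` with `L` (channels x 3 x nodes
#'   gain array), the grid and the sensor array.
#' @export
make_toy_leadfield <- function(grid, sensors) {
  stopifnot(inherits(grid, "source_grid"), inherits(sensors, "sensor_array"))
  nodes <- grid$nodes
  if (any(row_norms(nodes) >= sensors$radius))
    stop_ckc("all grid nodes must lie strictly inside the sensor shell (radius %g mm)",
             sensors$radius)
  d <- sensors$grad_baseline
  # evaluation points per site: p, p + d t1, p - d t1, p + d t2, p - d t2
  pts <- rbind(sensors$pos,
               sensors$pos + d * sensors$t1, sensors$pos - d * sensors$t1,
               sensors$pos + d * sensors$t2, sensors$pos - d * sensors$t2)
  ns <- sensors$n_sites
  n_chan <- 3L * ns
  L <- array(0, dim = c(n_chan, 3L, nrow(nodes)))
  d_cm <- d / 10                            # baseline in cm for fT/cm units
  for (k in seq_len(nrow(nodes))) {
    B <- sarvas_field(pts, nodes[k, ])
    for (j in 1:3) {
      bn <- rowSums(B[, , j] * rbind(sensors$normals, sensors$normals,
                                     sensors$normals, sensors$normals,
                                     sensors$normals))
      b0 <- bn[seq_len(ns)]
      g1 <- (bn[ns + seq_len(ns)] - bn[2 * ns + seq_len(ns)]) / (2 * d_cm)
      g2 <- (bn[3 * ns + seq_len(ns)] - bn[4 * ns + seq_len(ns)]) / (2 * d_cm)
      block <- numeric(n_chan)
      block[seq(1, n_chan, by = 3)] <- g1
      block[seq(2, n_chan, by = 3)] <- g2
      block[seq(3, n_chan, by = 3)] <- b0
      L[, j, k] <- block
    }
  }
  structure(list(L = L, grid = grid, sensors = sensors), class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("Lead field: %d channels x 3 orientations x %d nodes\n",
              dim(x$L)[1], dim(x$L)[3]))
  invisible(x)
}

# default tangential dipole orientation at a node
tangential_orientation <- function(r0) {
  o <- c(-r0[2], r0[1], 0)
  if (sqrt(sum(o^2)) < 1e-9) o <- c(1, 0, 0)
  o / sqrt(sum(o^2))
}

# 1/f ("pink") noise with one-sided power spectral density 1/f (units^2/Hz,
# referenced to 1 Hz), synthesized by spectral shaping; multiply by an
# amplitude spectral density to set the level
pink_noise <- function(n, n_series = 1, fs = 1000) {
  x <- matrix(stats::rnorm(n * n_series), nrow = n)
  X <- stats::mvfft(x)                       # E|X_k|^2 = n for white input
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n               # |frequency| of each bin
  f[1] <- Inf                                # kill DC
  shape <- sqrt(fs / 2 / pmax(f, fs / n))
  shape[1] <- 0
  Re(stats::mvfft(X * shape, inverse = TRUE)) / n
}

#' Synthetic three-axis finger acceleration
#'
#' Each accelerometer axis is the onset train convolved with an
#' acceleration-shaped kernel, scaled by an axis-specific gain, plus white
#' sensor noise. With zero noise the magnitude (Euclidean norm of the
#' axes) is exactly periodic at each finger's stimulation frequency.
#'
#' @param train a [make_stimulus_train()] result.
#' @param kernel acceleration kernel; default the second derivative of an
#'   80-ms Hann displacement pulse.
#' @param axis_gains length-3 gains applied to the x, y, z axes.
#' @param noise_sd white-noise standard deviation (same units as the
#'   signal).
#' @param seed integer seed for the noise stream (`NULL` leaves the RNG
#'   state alone).
#' @return named list of `kinematic_signal` objects, one per finger (each
#'   with fields `finger`, `axes` (3 x samples), `sample_rate`).
#' @export
synth_acceleration <- function(train, kernel = NULL, axis_gains = c(1, 0.6, 0.3),
                               noise_sd = 0.02, seed = NULL) {
  stopifnot(inherits(train, "stimulus_train"))
  fs <- train$design$sample_rate
  kernel <- kernel %||% pulse_kernel("accel", 80, fs)
  if (length(axis_gains) != 3L) stop_ckc("axis_gains must have length 3")
  soa_min <- min(vapply(train$onsets, function(o)
    if (length(o) > 1) min(diff(o)) else Inf, numeric(1)))
  if (length(kernel) / fs > soa_min)
    warning("acceleration kernel is longer than the inter-onset interval; pulses overlap")
  set_seed_if(seed)
  n <- ncol(train$drive)
  out <- vector("list", length(train$onsets))
  names(out) <- names(train$onsets)
  for (i in seq_along(train$onsets)) {
    spikes <- numeric(n)
    idx <- round(train$onsets[[i]] * fs) + 1L
    spikes[idx[idx <= n]] <- 1
    wave <- convolve_causal(spikes, kernel)
    axes <- rbind(axis_gains[1] * wave, axis_gains[2] * wave, axis_gains[3] * wave)
    if (noise_sd > 0)
      axes <- axes + matrix(stats::rnorm(3 * n, sd = noise_sd), nrow = 3)
    out[[i]] <- structure(list(finger = names(train$onsets)[i], axes = axes,
                               sample_rate = fs),
                          class = "kinematic_signal")
  }
  out
}

#' @export
print.kinematic_signal <- function(x, ...) {
  cat(sprintf("Kinematic signal: finger %s, 3 axes x %d samples at %g Hz\n",
              x$finger, ncol(x$axes), x$sample_rate))
  invisible(x)
}

#' Ground-truth parameters for the MEG simulator
#'
#' Encodes the generative model behind a synthetic recording: which grid
#' node hosts each finger's cortical source, how strongly each source is
#' phase-locked to its stimulus train, and how much the other fingers'
#' concurrent stimulation perturbs ("distracts") that phase locking.
#' Cross-finger interference is implemented as a deterministic extra
#' latency of each cortical response proportional to the other fingers'
#' drive at that moment: when the other fingers move at the *same*
#' frequency this latency is constant and harmless, at *different*
#' frequencies it varies quasi-randomly from onset to onset and degrades
#' coherence -- the additive-afference account of multi-finger
#' stimulation.
#'
#' @param source_nodes named integer vector: grid node index per finger.
#' @param gains named numeric vector: source amplitude per finger
#'   (dimensionless; >= 0).
#' @param cross_finger_interference mixing weight (>= 0) of the other
#'   fingers' drives into each finger's response latency.
#' @param interference_scale_ms latency excursion (ms) per unit of
#'   standardized foreign drive at interference weight 1.
#' @param onset_jitter_sd independent Gaussian jitter of each cortical
#'   response onset (ms).
#' @param amp_cv coefficient of variation of per-onset response amplitude.
#' @param noise_white white sensor-noise amplitude spectral density at
#'   gradiometers (fT/cm/sqrt(Hz)); magnetometers use `mag_noise_factor`
#'   times this (fT/sqrt(Hz)). Specifying noise as a density makes the
#'   per-bin signal-to-noise ratio -- and hence coherence -- independent
#'   of the sampling rate.
#' @param noise_pink amplitude spectral density of the 1/f background at
#'   1 Hz, same units and convention.
#' @param mag_noise_factor magnetometer/gradiometer noise ratio.
#' @param evoked_kernel cortical response waveform; default a 60-ms
#'   biphasic pulse.
#' @param artifact_n number of injected high-amplitude artifact
#'   transients (0 = none).
#' @param artifact_amplitude artifact amplitude in fT/cm (square pulse on
#'   one gradiometer; default 3000, above the 2000 fT/cm rejection
#'   threshold).
#' @param seed root seed; child seeds are derived per noise stream.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(source_nodes, gains,
                         cross_finger_interference = 0.6,
                         interference_scale_ms = 60,
                         onset_jitter_sd = 2,
                         amp_cv = 0.1,
                         noise_white = 2,
                         noise_pink = 4,
                         mag_noise_factor = 2,
                         evoked_kernel = NULL,
                         artifact_n = 0,
                         artifact_amplitude = 3000,
                         seed = 1) {
  if (is.null(names(source_nodes)) || is.null(names(gains)))
    stop_ckc("source_nodes and gains must be named by finger id")
  if (any(gains < 0)) stop_ckc("gains must be >= 0")
  if (onset_jitter_sd < 0 || cross_finger_interference < 0)
    stop_ckc("jitter and interference must be >= 0")
  structure(list(source_nodes = source_nodes, gains = gains,
                 cross_finger_interference = cross_finger_interference,
                 interference_scale_ms = interference_scale_ms,
                 onset_jitter_sd = onset_jitter_sd, amp_cv = amp_cv,
                 noise_white = noise_white, noise_pink = noise_pink,
                 mag_noise_factor = mag_noise_factor,
                 evoked_kernel = evoked_kernel,
                 artifact_n = artifact_n,
                 artifact_amplitude = artifact_amplitude,
                 seed = seed),
            class = "ground_truth")
}

#' Synthesize a multichannel MEG-like recording
#'
#' Builds sensor data as the sum over fingers of a phase-locked cortical
#' response train projected through the lead field of that finger's
#' source node, plus 1/f background and white sensor noise, plus optional
#' injected artifact transients. Response onsets follow the stimulus train
#' with Gaussian jitter and, when other fingers are stimulated
#' concurrently, a latency shift proportional to their momentary drive
#' (see [ground_truth()]). Fixing the seed makes the output
#' bit-reproducible.
#'
#' @param design a [stimulus_design()].
#' @param truth a [ground_truth()].
#' @param leadfield a [make_toy_leadfield()] result covering the source
#'   nodes in `truth`.
#' @return object of class `sensor_recording`: `data` (channels x
#'   samples), the channel table, `sample_rate`, and the design (with
#'   onset trains) as attributes used downstream for epoching.
#' @export
synth_sensor_recording <- function(design, truth, leadfield) {
  stopifnot(inherits(design, "stimulus_design"), inherits(truth, "ground_truth"),
            inherits(leadfield, "lead_field"))
  fs <- design$sample_rate
  n <- round(design$total_duration * fs)
  sensors <- leadfield$sensors
  n_chan <- nrow(sensors$channels)
  n_nodes <- dim(leadfield$L)[3]
  fingers <- design$fingers
  if (!all(fingers %in% names(truth$source_nodes)))
    stop_ckc("truth lacks source nodes for finger(s): %s",
             paste(setdiff(fingers, names(truth$source_nodes)), collapse = ", "))
  if (any(truth$source_nodes[fingers] < 1 | truth$source_nodes[fingers] > n_nodes))
    stop_ckc("source node index out of range (grid has %d nodes)", n_nodes)

  train <- make_stimulus_train(design)
  kernel <- truth$evoked_kernel %||% pulse_kernel("biphasic", 60, fs)

  # standardized drive envelopes for the interference term
  zdrive <- train$drive
  for (i in seq_len(nrow(zdrive))) {
    s <- stats::sd(zdrive[i, ])
    if (s > 0) zdrive[i, ] <- (zdrive[i, ] - mean(zdrive[i, ])) / s
  }

  data <- matrix(0, nrow = n_chan, ncol = n)
  for (i in seq_along(fingers)) {
    fg <- fingers[i]
    g <- truth$gains[fg]
    if (g == 0) next
    on_t <- train$onsets[[fg]]
    set_seed_if(child_seed(truth$seed, paste0("jitter-", fg)))
    jit <- stats::rnorm(length(on_t), sd = truth$onset_jitter_sd / 1000)
    shift <- 0
    if (length(fingers) > 1L && truth$cross_finger_interference > 0) {
      others <- setdiff(seq_along(fingers), i)
      mix <- colMeans(zdrive[others, , drop = FALSE])
      idx <- pmin(pmax(round(on_t * fs) + 1L, 1L), n)
      shift <- truth$cross_finger_interference *
        truth$interference_scale_ms / 1000 * mix[idx]
    }
    t_resp <- on_t + jit + shift
    amp <- 1 + truth$amp_cv * stats::rnorm(length(on_t))
    spikes <- numeric(n)
    idx <- round(t_resp * fs) + 1L
    ok <- idx >= 1L & idx <= n
    spikes[idx[ok]] <- spikes[idx[ok]] + amp[ok]
    s_wave <- g * convolve_causal(spikes, kernel)
    node <- truth$source_nodes[fg]
    orient <- tangential_orientation(leadfield$grid$nodes[node, ])
    gain_vec <- leadfield$L[, , node] %*% orient
    data <- data + tcrossprod(as.vector(gain_vec), s_wave)
  }

  kind <- sensors$channels$kind
  noise_scale <- ifelse(kind == "grad", 1, truth$mag_noise_factor)
  if (truth$noise_white > 0) {
    set_seed_if(child_seed(truth$seed, "white"))
    data <- data + truth$noise_white * sqrt(fs / 2) * noise_scale *
      matrix(stats::rnorm(n_chan * n), nrow = n_chan)
  }
  if (truth$noise_pink > 0) {
    set_seed_if(child_seed(truth$seed, "pink"))
    data <- data + truth$noise_pink * noise_scale * t(pink_noise(n, n_chan, fs))
  }
  if (truth$artifact_n > 0) {
    set_seed_if(child_seed(truth$seed, "artifact"))
    grads <- which(kind == "grad")
    width <- round(0.2 * fs)
    for (a in seq_len(truth$artifact_n)) {
      ch <- sample(grads, 1)
      start <- sample.int(n - width, 1)
      data[ch, start:(start + width - 1L)] <-
        data[ch, start:(start + width - 1L)] + truth$artifact_amplitude
    }
  }

  structure(list(data = data, channels = sensors$channels, sample_rate = fs,
                 design = design, onsets = train$onsets),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("Sensor recording: %d channels x %d samples at %g Hz (%s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              x$design$condition %||% "no design"))
  invisible(x)
}
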