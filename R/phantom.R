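#' Phantom scene specification
#'
#' Describes a synthetic field of view mimicking a two-photon fiberscopy
#' recording site: elliptical neuron somas with curvilinear dendrites on a
#' dim autofluorescence background. Defaults target the instrument's native
#' 512x512 8-bit frame; tests and desk-scale runs pass smaller sizes.
#'
#' @param image_size Pixels per side (square frame), at least 32.
#' @param n_somas Number of somas to place (rejection-sampled, non-overlapping).
#' @param soma_radius_range Min/max soma semi-axis in pixels.
#' @param n_dendrites_per_soma Dendrites emanating from each soma.
#' @param dendrite_width_range Min/max Gaussian cross-section sigma in pixels.
#' @param dendrite_length_range Min/max dendrite length in pixels.
#' @param soma_intensity_range Min/max soma brightness, 8-bit units.
#' @param background_level Background brightness, 8-bit units.
#' @param seed Integer seed; identical spec + seed gives bit-identical scenes.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 512L, n_somas = 5L,
                         soma_radius_range = c(10, 18),
                         n_dendrites_per_soma = 3L,
                         dendrite_width_range = c(1, 2),
                         dendrite_length_range = c(30, 80),
                         soma_intensity_range = c(40, 150),
                         background_level = 2,
                         seed = 1L) {
  if (image_size < 32) stop_config("image_size must be >= 32")
  check_range(soma_radius_range, "soma_radius_range")
  check_range(dendrite_width_range, "dendrite_width_range")
  check_range(dendrite_length_range, "dendrite_length_range")
  check_range(soma_intensity_range, "soma_intensity_range")
  if (soma_intensity_range[2] > 255 || background_level < 0 ||
      background_level > 255)
    stop_config("intensities must lie within [0, 255]")
  structure(list(image_size = as.integer(image_size),
                 n_somas = as.integer(n_somas),
                 soma_radius_range = soma_radius_range,
                 n_dendrites_per_soma = as.integer(n_dendrites_per_soma),
                 dendrite_width_range = dendrite_width_range,
                 dendrite_length_range = dendrite_length_range,
                 soma_intensity_range = soma_intensity_range,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Render one filled ellipse as a logical mask.
ellipse_mask <- function(n, cy, cx, a, b, theta) {
  ii <- matrix(seq_len(n), n, n) - cy
  jj <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  u <- cos(theta) * ii + sin(theta) * jj
  v <- -sin(theta) * ii + cos(theta) * jj
  (u / a)^2 + (v / b)^2 <= 1
}

# Smoothed random-walk polyline with Gaussian cross-section, accumulated by max.
render_dendrite <- function(canvas, start, dir0, len, sigma, intensity) {
  n <- nrow(canvas)
  pos <- start
  dir <- dir0
  pts <- matrix(NA_real_, ceiling(len), 2)
  for (s in seq_len(ceiling(len))) {
    pos <- pos + c(cos(dir), sin(dir))
    dir <- dir + rnorm(1, 0, 0.2)
    pts[s, ] <- pos
  }
  rad <- ceiling(3 * sigma)
  for (s in seq_len(nrow(pts))) {
    ci <- round(pts[s, 1]); cj <- round(pts[s, 2])
    if (is.na(ci) || ci < 1 - rad || ci > n + rad || cj < 1 - rad || cj > n + rad) next
    for (di in -rad:rad) for (dj in -rad:rad) {
      i <- ci + di; j <- cj + dj
      if (i < 1 || i > n || j < 1 || j > n) next
      d2 <- (i - pts[s, 1])^2 + (j - pts[s, 2])^2
      val <- intensity * exp(-d2 / (2 * sigma^2))
      if (val > canvas[i, j]) canvas[i, j] <- val
    }
  }
  canvas
}

#' Generate a phantom neuron scene
#'
#' Places non-overlapping elliptical somas by rejection sampling and grows
#' smoothed random-walk dendrites from each, with a Gaussian cross-section.
#' The per-soma structure contributions are kept separately so that calcium
#' activity can later modulate each neuron (soma plus its dendrites)
#' independently.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_scene` with elements `structure_map`
#'   (noise-free fluorophore density, 8-bit scale), `roi_masks` (list of
#'   per-soma logical masks), `background_mask` (structure-free pixels),
#'   `neuron_maps` (per-neuron additive structure contribution) and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  with_seed_(spec$seed, {
    roi_masks <- list()
    neuron_maps <- list()
    occupied <- matrix(FALSE, n, n)
    attempts <- 0L
    max_attempts <- 200L * max(1L, spec$n_somas)
    while (length(roi_masks) < spec$n_somas) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop_data(sprintf(paste0(
          "could not place %d somas of radius %g-%g in a %dx%d frame after %d ",
          "attempts; reduce n_somas or soma_radius_range"),
          spec$n_somas, spec$soma_radius_range[1], spec$soma_radius_range[2],
          n, n, max_attempts))
      a <- runif(1, spec$soma_radius_range[1], spec$soma_radius_range[2])
      b <- runif(1, spec$soma_radius_range[1], spec$soma_radius_range[2])
      r <- max(a, b)
      cy <- runif(1, 1 + r, n - r)
      cx <- runif(1, 1 + r, n - r)
      m <- ellipse_mask(n, cy, cx, a, b, runif(1, 0, pi))
      if (any(m & occupied)) next
      intensity <- runif(1, spec$soma_intensity_range[1],
                         spec$soma_intensity_range[2])
      nm <- matrix(0, n, n)
      nm[m] <- intensity
      for (d in seq_len(spec$n_dendrites_per_soma)) {
        ang <- runif(1, 0, 2 * pi)
        start <- c(cy + (a + 1) * cos(ang), cx + (b + 1) * sin(ang))
        nm <- render_dendrite(
          nm, start, ang,
          runif(1, spec$dendrite_length_range[1], spec$dendrite_length_range[2]),
          runif(1, spec$dendrite_width_range[1], spec$dendrite_width_range[2]),
          0.6 * intensity)
      }
      nm[m] <- intensity  # soma brightness is flat, dendrites never brighten it
      roi_masks[[length(roi_masks) + 1L]] <- m
      neuron_maps[[length(neuron_maps) + 1L]] <- nm
      occupied <- occupied | (nm > 0)
    }
    structure_map <- matrix(spec$background_level, n, n)
    for (nm in neuron_maps) structure_map <- structure_map + nm
    structure_map <- pmin(structure_map, 255)
    background_mask <- !occupied
    structure(list(structure_map = structure_map, roi_masks = roi_masks,
                   background_mask = background_mask,
                   neuron_maps = neuron_maps, spec = spec),
              class = "phantom_scene")
  })
}

#' GCaMP-like activity model
#'
#' Linear spike-to-fluorescence model: per-neuron Poisson spike counts per
#' frame, each event drawing a relative amplitude, convolved with a causal
#' single-exponential decay kernel. Defaults emulate sparsely firing cortical
#' neurons recorded with a medium-kinetics indicator at video rate.
#'
#' @param spike_rate Expected events per frame per neuron.
#' @param decay_tau Fluorescence decay constant in frames.
#' @param amplitude_range Min/max relative fluorescence amplitude per event.
#' @param n_frames Number of frames to simulate.
#' @param seed Integer seed.
#' @return An object of class `activity_model`.
#' @export
activity_model <- function(spike_rate = 0.1, decay_tau = 4,
                           amplitude_range = c(0.3, 0.8), n_frames = 200L,
                           seed = 1L) {
  if (spike_rate < 0) stop_config("spike_rate must be >= 0")
  if (decay_tau <= 0) stop_config("decay_tau must be > 0")
  if (n_frames < 1) stop_config("n_frames must be >= 1")
  check_range(amplitude_range, "amplitude_range")
  structure(list(spike_rate = spike_rate, decay_tau = decay_tau,
                 amplitude_range = amplitude_range,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "activity_model")
}

#' Simulate calcium activity on a phantom scene
#'
#' Each neuron's spike train is convolved with `exp(-t/decay_tau)` to a
#' relative-fluorescence trace `a(t)`; frame `t` is the background plus each
#' neuron's structure scaled by `1 + a(t)`, clipped to the 8-bit range.
#'
#' @param scene A [generate_scene()] result.
#' @param model An [activity_model()].
#' @return A list with `stack` (noise-free `H x W x T` movie), `traces`
#'   (matrix `T x n_neurons` of the exact relative-fluorescence time series)
#'   and `spikes` (matrix of per-frame event counts per neuron).
#' @export
simulate_activity <- function(scene, model) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(model, "activity_model"))
  n_neur <- length(scene$roi_masks)
  tt <- model$n_frames
  with_seed_(model$seed, {
    traces <- matrix(0, tt, max(n_neur, 1))
    spikes <- matrix(0L, tt, max(n_neur, 1))
    kernel <- exp(-(0:(tt - 1)) / model$decay_tau)
    for (i in seq_len(n_neur)) {
      counts <- rpois(tt, model$spike_rate)
      impulse <- numeric(tt)
      for (t in which(counts > 0))
        impulse[t] <- sum(runif(counts[t], model$amplitude_range[1],
                                model$amplitude_range[2]))
      tr <- convolve(impulse, rev(kernel), type = "open")[seq_len(tt)]
      traces[, i] <- tr
      spikes[, i] <- counts
    }
    n <- scene$spec$image_size
    base <- matrix(scene$spec$background_level, n, n)
    stack <- array(0, dim = c(n, n, tt))
    for (t in seq_len(tt)) {
      f <- base
      for (i in seq_len(n_neur))
        f <- f + scene$neuron_maps[[i]] * (1 + traces[t, i])
      stack[, , t] <- pmin(f, 255)
    }
    list(stack = stack,
         traces = traces[, seq_len(max(n_neur, 0)), drop = FALSE],
         spikes = spikes[, seq_len(max(n_neur, 0)), drop = FALSE])
  })
}

#' Dwell-time-dependent noise model
#'
#' Photon-limited acquisition noise: pixel intensities are scaled to expected
#' photon counts, Poisson shot noise is drawn, counts are rescaled to
#' intensity units and zero-mean Gaussian read noise is added. The photon
#' yield per intensity unit scales inversely with scanning speed (pixel dwell
#' time is inversely proportional to speed), so faster scans are noisier.
#'
#' @param photons_per_unit_at_ref_speed Photons per 8-bit intensity unit at
#'   `ref_speed`.
#' @param ref_speed Reference scanning speed, spirals/sec. The default 165
#'   corresponds to the slow-scan regime used for high-SNR ground truth.
#' @param read_noise_sigma Gaussian read noise, 8-bit units.
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(photons_per_unit_at_ref_speed = 4, ref_speed = 165,
                        read_noise_sigma = 2.5, seed = 1L) {
  if (photons_per_unit_at_ref_speed <= 0)
    stop_config("photon scale must be > 0")
  if (read_noise_sigma < 0) stop_config("read_noise_sigma must be >= 0")
  structure(list(photons_per_unit = photons_per_unit_at_ref_speed,
                 ref_speed = ref_speed, read_noise_sigma = read_noise_sigma,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Apply acquisition noise to a frame
#'
#' @param frame Numeric matrix, intensities in `[0, 255]`.
#' @param noise A [noise_model()].
#' @param speed Scanning speed in spirals/sec; must be positive. The effective
#'   photon scale is `photons_per_unit * ref_speed / speed`.
#' @param seed Optional seed overriding the model's (useful when drawing many
#'   independent realizations).
#' @return A noisy frame clipped to `[0, 255]`.
#' @export
apply_noise <- function(frame, noise, speed, seed = noise$seed) {
  stopifnot(inherits(noise, "noise_model"))
  if (speed <= 0) stop_config("scanning speed must be > 0")
  scale <- noise$photons_per_unit * noise$ref_speed / speed
  with_seed_(seed, {
    photons <- rpois(length(frame), as.vector(frame) * scale)
    out <- photons / scale + rnorm(length(frame), 0, noise$read_noise_sigma)
    matrix(pmin(pmax(out, 0), 255), nrow(frame), ncol(frame))
  })
}

#' Average the first k frames of a stack
#'
#' Pixel-wise mean at full precision (no quantization), the standard way to
#' build high-SNR ground truth from a slow repeated acquisition.
#'
#' @param stack An image stack (`H x W x T`).
#' @param k Number of frames to average.
#' @param from First frame of the averaging window (default 1).
#' @return A numeric matrix.
#' @export
frame_average <- function(stack, k, from = 1L) {
  stack <- as_stack(stack)
  if (from + k - 1 > n_frames(stack))
    stop_data(sprintf("cannot average %d frames from %d: stack has only %d",
                      k, from, n_frames(stack)))
  apply(stack[, , from:(from + k - 1), drop = FALSE], c(1, 2), mean)
}
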