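# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; desk-scale geometry is 64x64 (the instrument's native frame is
# 512x512, scaled down for fast, deterministic tests).

fixture_spec <- function(seed = 1L, image_size = 64L,
                         n_somas = if (image_size < 48L) 2L else 3L,
                         soma_intensity_range = c(40, 150)) {
  small <- image_size < 48L
  phantom_spec(image_size = image_size, n_somas = n_somas,
               soma_radius_range = if (small) c(3, 5) else c(4, 7),
               n_dendrites_per_soma = if (small) 1L else 2L,
               dendrite_width_range = c(1, 1.5),
               dendrite_length_range = if (small) c(5, 10) else c(10, 24),
               soma_intensity_range = soma_intensity_range,
               background_level = 2, seed = seed)
}

# One phantom acquisition: scene + clean movie + noisy movie at `speed`.
# spike_rate = 0 emulates an ex-vivo (static, anatomical) slice.
fixture_stack <- function(seed, n_frames = 12L, speed = 1650,
                          spike_rate = 0.1, image_size = 64L) {
  sc <- generate_scene(fixture_spec(seed, image_size = image_size))
  act <- simulate_activity(sc, activity_model(
    spike_rate = spike_rate, decay_tau = 4, n_frames = n_frames,
    seed = seed + 1000L))
  nm <- noise_model()
  noisy <- act$stack
  for (t in seq_len(dim(noisy)[3]))
    noisy[, , t] <- apply_noise(act$stack[, , t], nm, speed,
                                seed = seed * 1000L + t)
  list(scene = sc, clean = act$stack, noisy = noisy, traces = act$traces,
       spikes = act$spikes)
}

# Small structured frames for quick GAN tasks.
fixture_frame <- function(seed, n = 32L) {
  sc <- generate_scene(phantom_spec(
    image_size = n, n_somas = 2L, soma_radius_range = c(3, 5),
    n_dendrites_per_soma = 1L, dendrite_width_range = c(1, 1.2),
    dendrite_length_range = c(5, 10), soma_intensity_range = c(40, 150),
    background_level = 2, seed = seed))
  sc$structure_map
}

tiny_gan_config <- function(n = 32L, epochs = 5L, seed = 1L, ...) {
  gan_config(image_size = n, gen_depth = 2L, base_channels = 8L,
             patch_scale = 16L, epochs = epochs, lr = 5e-4, seed = seed, ...)
}
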