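test_that("scene generation is deterministic and respects the empty case", {
  spec <- fixture_spec(seed = 7L)
  s1 <- generate_scene(spec)
  s2 <- generate_scene(spec)
  expect_identical(s1$structure_map, s2$structure_map)
  expect_identical(s1$roi_masks, s2$roi_masks)

  empty <- generate_scene(fixture_spec(seed = 1L, n_somas = 0L))
  expect_true(all(empty$structure_map == 2))
  expect_length(empty$roi_masks, 0)
  expect_true(all(empty$background_mask))
})

test_that("somas are disjoint, inside area bounds, and exclude background", {
  spec <- fixture_spec(seed = 3L, image_size = 128L, n_somas = 5L)
  sc <- generate_scene(spec)
  expect_length(sc$roi_masks, 5)
  # brute-force pixel audit: no pixel in two rois, none in roi and background
  counts <- Reduce(`+`, lapply(sc$roi_masks, function(m) m + 0))
  expect_true(all(counts <= 1))
  expect_true(all(!(sc$background_mask & counts > 0)))
  r <- spec$soma_radius_range
  for (m in sc$roi_masks) {
    a <- sum(m)
    expect_gt(a, 0.7 * pi * r[1]^2)
    expect_lt(a, 1.3 * pi * r[2]^2)
    # every roi pixel sits above background in the structure map
    expect_true(all(sc$structure_map[m] > spec$background_level))
  }
})

test_that("overly dense soma placement fails with an informative error", {
  spec <- phantom_spec(image_size = 32L, n_somas = 30L,
                       soma_radius_range = c(6, 8), background_level = 2,
                       soma_intensity_range = c(40, 150), seed = 1L)
  expect_error(generate_scene(spec), "could not place")
})

test_that("silent networks produce constant movies and single spikes decay in closed form", {
  sc <- generate_scene(fixture_spec(seed = 2L))
  silent <- simulate_activity(sc, activity_model(spike_rate = 0,
                                                 n_frames = 5L, seed = 1L))
  for (t in 1:5)
    expect_equal(silent$stack[, , t], sc$structure_map, ignore_attr = TRUE)
  expect_true(all(silent$traces == 0))

  # single impulse of amplitude a at frame k decays as a*exp(-(t-k)/tau)
  tau <- 4; tt <- 30L; k <- 5L; a <- 0.6
  kernel <- exp(-(0:(tt - 1)) / tau)
  impulse <- numeric(tt); impulse[k] <- a
  closed <- a * exp(-(seq_len(tt) - k) / tau) * (seq_len(tt) >= k)
  via_conv <- stats::convolve(impulse, rev(kernel), type = "open")[seq_len(tt)]
  expect_equal(via_conv, closed, tolerance = 1e-12)
})

test_that("spike counts match the Poisson rate within Monte-Carlo error", {
  sc <- generate_scene(fixture_spec(seed = 4L, image_size = 96L,
                                    n_somas = 10L))
  act <- simulate_activity(sc, activity_model(spike_rate = 0.05,
                                              n_frames = 300L, seed = 9L))
  counts <- colSums(act$spikes)     # independent audit of the event record
  se <- sqrt(15 / 10)
  expect_lt(abs(mean(counts) - 15), 3 * se)
})

test_that("noise is unbiased away from clipping and variance scales with speed", {
  frame <- matrix(80, 20, 20)
  nm <- noise_model(photons_per_unit_at_ref_speed = 4, ref_speed = 165,
                    read_noise_sigma = 1)
  draws <- function(speed, n = 1000)
    vapply(seq_len(n), function(i)
      apply_noise(frame, nm, speed, seed = i)[1, 1], numeric(1))
  x1 <- draws(1650); x2 <- draws(3300)
  # unbiasedness within 3 standard errors
  expect_lt(abs(mean(x1) - 80), 3 * sd(x1) / sqrt(length(x1)))
  # doubling speed halves dwell time: variance approximately doubles
  expect_gt(var(x2) / var(x1), 1.6)
  expect_lt(var(x2) / var(x1), 2.4)
})

test_that("noise vanishes in the bright-photon limit and speed must be positive", {
  frame <- matrix(seq(10, 250, length.out = 64), 8, 8)
  nm <- noise_model(photons_per_unit_at_ref_speed = 1e7, read_noise_sigma = 0)
  out <- apply_noise(frame, nm, 165, seed = 1)
  expect_equal(out, frame, tolerance = 1e-2)
  expect_error(apply_noise(frame, nm, 0), class = "fiberdl_config_error")
})

test_that("measured SNR is non-increasing in scanning speed", {
  fx <- fixture_stack(11L, n_frames = 1L, spike_rate = 0)
  roi <- annulus_roi(fx$scene$roi_masks[[1]], fx$scene$background_mask, 5, 2)
  nm <- noise_model()
  mean_snr <- function(speed)
    mean(vapply(1:100, function(i)
      snr_db(apply_noise(fx$clean[, , 1], nm, speed, seed = i), roi),
      numeric(1)))
  snrs <- vapply(c(825, 1650, 3360, 6720), mean_snr, numeric(1))
  expect_true(all(diff(snrs) < 0.05))
})

test_that("frame averaging is exact on constants and obeys the 1/k variance law", {
  f <- matrix(runif(64, 0, 255), 8, 8)
  stk <- as_stack(replicate(10, f, simplify = FALSE))
  expect_equal(frame_average(stk, 10), f, ignore_attr = TRUE)
  expect_equal(frame_average(stk, 1), f, ignore_attr = TRUE)
  expect_error(frame_average(stk, 11), class = "fiberdl_data_error")

  set.seed(42)
  clean <- matrix(100, 16, 16)
  resid1 <- resid10 <- numeric(200)
  for (r in 1:200) {
    noisy <- array(rep(clean, 10) + rnorm(256 * 10, 0, 8),
                   dim = c(16, 16, 10))
    resid1[r] <- mean((noisy[, , 1] - clean)^2)
    resid10[r] <- mean((frame_average(noisy, 10) - clean)^2)
  }
  expect_equal(mean(resid1) / mean(resid10), 10, tolerance = 0.15)
})
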