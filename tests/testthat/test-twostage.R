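# Small shared fixtures for the transfer-protocol tests (32x32 for speed).
ts_stacks <- function(seeds, n_frames = 12L, spike_rate = 0,
                      speed = 1650) {
  lapply(seeds, function(s)
    fixture_stack(s, n_frames = n_frames, speed = speed,
                  spike_rate = spike_rate, image_size = 32L)$noisy)
}

test_that("stage-1 datasets pair k-frame averages with augmented frames", {
  stacks <- ts_stacks(1:10)
  ds <- make_dnn1_dataset(stacks, k = 10, seed = 3L)
  expect_s3_class(ds, "fiberdl_dataset")
  expect_length(ds$pairs, 10)
  expect_equal(nrow(ds$provenance), 10)
  expect_equal(ds$provenance$stack, 1:10)
  for (p in ds$pairs) expect_equal(dim(p$x), c(32L, 32L))
  # regeneration under the same seed is bit-identical
  ds2 <- make_dnn1_dataset(stacks, k = 10, seed = 3L)
  expect_identical(ds$pairs, ds2$pairs)
  expect_identical(ds$provenance, ds2$provenance)
  # degenerate case: identical frames, effectively noiseless augmentation
  still <- matrix(100, 32, 32)
  const_stack <- as_stack(replicate(10, still, simplify = FALSE))
  quiet <- noise_model(photons_per_unit_at_ref_speed = 1e7,
                       read_noise_sigma = 0)
  dsq <- make_dnn1_dataset(list(const_stack), k = 10, augment = quiet,
                           speed_range = c(165, 165), seed = 1L)
  expect_equal(dsq$pairs[[1]]$y, dsq$pairs[[1]]$x, tolerance = 1e-2)
  # short stacks are skipped with a warning, or fail under strict mode
  short <- as_stack(replicate(4, still, simplify = FALSE))
  expect_warning(make_dnn1_dataset(c(stacks, list(short)), k = 10, seed = 1L),
                 "fewer than k")
  expect_error(make_dnn1_dataset(list(short), k = 10, strict = TRUE),
               class = "fiberdl_data_error")
})

test_that("stage-2 datasets use network outputs as ground truth and exact decimation", {
  stacks <- ts_stacks(21:23, n_frames = 4L)
  dnn1 <- train_gan(make_dnn1_dataset(ts_stacks(31:34), k = 10,
                                      seed = 1L)$pairs,
                    tiny_gan_config(n = 32L, epochs = 2L, seed = 1L))
  rings <- build_ring_map(32, 32)
  ds <- make_dnn2_dataset(stacks, dnn1, M = 8, rings)
  expect_length(ds$pairs, 3 * 4)
  expect_true(all(ds$provenance$ground_truth == "dnn1"))
  # kept rings of the input remain pixel-identical to the raw frame
  kept <- rings$ring_index %% 8 == 0
  raw <- stacks[[1]][, , 1]
  expect_identical(ds$pairs[[1]]$y[kept], raw[kept])
  # M = 1 passes the raw frame through; x is its enhancement
  ds1 <- make_dnn2_dataset(stacks[1], dnn1, M = 1, rings)
  expect_identical(ds1$pairs[[1]]$y, raw)
  expect_equal(ds1$pairs[[1]]$x, infer(dnn1, raw))
  expect_error(make_dnn2_dataset(list(array(0, c(16, 16, 2))), dnn1, 2, rings),
               class = "fiberdl_data_error")
})

test_that("the transfer plan trains one stage-2 network per M with pretrained init", {
  plan <- two_stage_plan(tiny_gan_config(n = 32L, epochs = 2L, seed = 2L),
                         M_list = c(4), averaging_k = 10L)
  expect_error(two_stage_plan(tiny_gan_config(), averaging_k = 1L),
               class = "fiberdl_config_error")
  res <- run_two_stage(plan, ts_stacks(41:44), ts_stacks(51:52, n_frames = 4L),
                       seed = 7L)
  expect_named(res$dnn2, "4")
  expect_s3_class(res$dnn1, "fiberdl_model")
  expect_named(res$histories, c("dnn1", "dnn2_M4"))
  # pretrain initialization contract: with a zero learning rate the stage-2
  # parameters remain exactly the inherited stage-1 parameters
  frozen_cfg <- gan_config(image_size = 32L, gen_depth = 2L,
                           base_channels = 8L, patch_scale = 16L,
                           epochs = 1L, lr = 0, seed = 99L)
  plan0 <- two_stage_plan(tiny_gan_config(n = 32L, epochs = 2L, seed = 2L),
                          frozen_cfg, M_list = c(4), averaging_k = 10L,
                          init_scheme = "pretrain")
  res0 <- run_two_stage(plan0, ts_stacks(41:44),
                        ts_stacks(51:51, n_frames = 2L), seed = 7L)
  expect_identical(res0$dnn2[["4"]]$G$layers, res0$dnn1$G$layers)
  expect_identical(res0$dnn2[["4"]]$D$layers, res0$dnn1$D$layers)
})

test_that("scratch and pretrain converge to comparable validation error", {
  trainA <- ts_stacks(61:66)
  trainB <- ts_stacks(71:73, n_frames = 6L, speed = 3360)
  mk_plan <- function(scheme) two_stage_plan(
    tiny_gan_config(n = 32L, epochs = 20L, seed = 5L),
    tiny_gan_config(n = 32L, epochs = 25L, seed = 6L),
    M_list = c(4), averaging_k = 10L, init_scheme = scheme)
  v <- vapply(c("pretrain", "scratch"), function(s) {
    r <- run_two_stage(mk_plan(s), trainA, trainB, seed = 3L,
                       val_fraction = 0.2)
    tail(r$dnn2[["4"]]$history$val_l1, 1)
  }, numeric(1))
  expect_lt(abs(v[1] - v[2]) / max(v), 0.25)
})

test_that("stack enhancement preserves order, length and trace computability", {
  fx <- fixture_stack(81L, n_frames = 30L, speed = 3360, spike_rate = 0.1,
                      image_size = 32L)
  dnn1 <- train_gan(make_dnn1_dataset(ts_stacks(91:98), k = 10, seed = 2L,
                                      pairs_per_stack = 2L)$pairs,
                    tiny_gan_config(n = 32L, epochs = 60L, seed = 3L))
  enh <- enhance_stack(dnn1, fx$noisy)
  expect_equal(dim(enh), dim(fx$noisy))
  expect_identical(enhance_stack(dnn1, fx$noisy), enh)
  expect_match(attr(enh, "model_fingerprint"), "^n16-")
  for (i in seq_along(fx$scene$roi_masks)) {
    roi <- annulus_roi(fx$scene$roi_masks[[i]], fx$scene$background_mask, 5, 2)
    v <- nrmse_trace(dff_trace(enh, roi), dff_trace(fx$noisy, roi))
    expect_true(is.finite(v))
  }
})
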