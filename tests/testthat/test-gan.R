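test_that("generator honours the shape contract, seeding and output range", {
  cfg <- tiny_gan_config(n = 32L, seed = 5L)
  G1 <- build_generator(cfg)
  G2 <- build_generator(cfg)
  expect_identical(G1$layers, G2$layers)
  for (r in 1:5) {
    x <- matrix(runif(32 * 32, -1, 1), 32)
    fw <- fiberdl:::gen_forward(G1, x)
    out <- fw$tape$vals[[fw$out]]
    expect_equal(dim(out), c(32L, 32L, 1L))
    expect_true(all(out >= -1 & out <= 1))
  }
  expect_error(gan_config(image_size = 48L, gen_depth = 5L),
               class = "fiberdl_config_error")
})

test_that("discriminator emits per-patch probabilities that shrink with patch scale", {
  x <- matrix(runif(64 * 64, -1, 1), 64)
  y <- matrix(runif(64 * 64, -1, 1), 64)
  sizes <- sapply(c(16L, 34L), function(ps) {
    D <- build_discriminator(gan_config(image_size = 64L, gen_depth = 2L,
                                        base_channels = 8L, patch_scale = ps,
                                        epochs = 1L, seed = 2L))
    p <- disc_prob(D, x, y)
    expect_true(all(p > 0 & p < 1))
    prod(dim(p)[1:2])
  })
  expect_gt(sizes[1], sizes[2])
  cfgd <- gan_config(image_size = 64L, gen_depth = 2L, base_channels = 8L,
                     patch_scale = 16L, epochs = 1L, seed = 2L)
  expect_identical(build_discriminator(cfgd)$layers,
                   build_discriminator(cfgd)$layers)
  expect_error(gan_config(image_size = 32L, patch_scale = 70L, gen_depth = 2L),
               class = "fiberdl_config_error")
})

test_that("objective matches closed forms and the discriminator-loss equilibrium", {
  cfg <- tiny_gan_config(n = 16L, seed = 3L)
  D <- build_discriminator(cfg)
  x <- matrix(runif(256, -1, 1), 16); y <- matrix(runif(256, -1, 1), 16)
  # a coin-flip discriminator: zeroed output layer gives exactly p = 0.5
  D0 <- D; D0$layers$out$W[] <- 0; D0$layers$out$b[] <- 0
  o <- gan_objective(x, x, y, D0)
  expect_equal(o$d_loss, 2 * log(2), tolerance = 1e-12)
  expect_equal(o$g_l1, 0)
  # fresh discriminators sit near the log-4 equilibrium on balanced inputs
  for (s in 1:5) {
    Ds <- build_discriminator(tiny_gan_config(n = 16L, seed = s))
    oo <- gan_objective(matrix(runif(256, -1, 1), 16), x, y, Ds)
    expect_gt(oo$d_loss, 1.0); expect_lt(oo$d_loss, 1.8)
  }
  # minimax and non-saturating conventions differ only in the adversarial term
  om <- gan_objective(x, x, y, D, gen_loss = "minimax")
  on <- gan_objective(x, x, y, D, gen_loss = "non_saturating")
  expect_equal(om$g_l1, on$g_l1)
  expect_false(isTRUE(all.equal(om$g_adv, on$g_adv)))
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_gan_config(n = 16L, seed = 7L)
  G <- build_generator(cfg); D <- build_discriminator(cfg)
  set.seed(8)
  x <- matrix(runif(256) * 2 - 1, 16); y <- matrix(runif(256) * 2 - 1, 16)
  res <- fiberdl:::generator_loss_and_grads(G, D, x, y, l1_weight = 100)
  eps <- 1e-5
  for (lname in names(G$layers)) {
    i <- which.max(abs(res$pgrads[[lname]]$W))
    Gp <- G; Gp$layers[[lname]]$W[i] <- Gp$layers[[lname]]$W[i] + eps
    Gm <- G; Gm$layers[[lname]]$W[i] <- Gm$layers[[lname]]$W[i] - eps
    fd <- (fiberdl:::generator_loss_and_grads(Gp, D, x, y, 100)$g_total -
           fiberdl:::generator_loss_and_grads(Gm, D, x, y, 100)$g_total) /
      (2 * eps)
    expect_lt(abs(fd - res$pgrads[[lname]]$W[i]) / abs(fd), 1e-4)
  }
  # discriminator side
  g_out <- res$g_out
  dres <- fiberdl:::discriminator_loss_and_grads(D, fiberdl:::as_act(x),
                                                 fiberdl:::as_act(y), g_out)
  for (lname in c("d1", "out")) {
    i <- which.max(abs(dres$pgrads[[lname]]$W))
    loss_at <- function(Dm) fiberdl:::discriminator_loss_and_grads(
      Dm, fiberdl:::as_act(x), fiberdl:::as_act(y), g_out)$d_loss
    Dp <- D; Dp$layers[[lname]]$W[i] <- Dp$layers[[lname]]$W[i] + eps
    Dm_ <- D; Dm_$layers[[lname]]$W[i] <- Dm_$layers[[lname]]$W[i] - eps
    fd <- (loss_at(Dp) - loss_at(Dm_)) / (2 * eps)
    expect_lt(abs(fd - dres$pgrads[[lname]]$W[i]) / abs(fd), 1e-4)
  }
})

test_that("training is deterministic, bookkept per epoch, and converges on identity", {
  f <- lapply(1:8, function(i) fixture_frame(i))
  pairs <- lapply(f, function(x) training_pair(x, x))
  cfg <- tiny_gan_config(n = 32L, epochs = 3L, seed = 4L)
  m1 <- train_gan(pairs, cfg, val_pairs = pairs[1:2])
  m2 <- train_gan(pairs, cfg, val_pairs = pairs[1:2])
  expect_equal(nrow(m1$history), 3L)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$G$layers, m2$G$layers)
  expect_error(train_gan(list(), cfg), class = "fiberdl_data_error")
  expect_error(train_gan(list(training_pair(matrix(0, 16, 16),
                                            matrix(0, 16, 16))), cfg),
               class = "fiberdl_data_error")

  conv <- train_gan(lapply(1:12, function(i)
    training_pair(fixture_frame(i + 20L), fixture_frame(i + 20L))),
    tiny_gan_config(n = 32L, epochs = 30L, seed = 1L),
    val_pairs = pairs[1:2])
  ratio <- conv$history$val_l1[30] / conv$history$val_l1[1]
  expect_lt(ratio, 0.2)
})

test_that("a dominant L1 weight reduces training to L1 regression", {
  pairs <- lapply(1:6, function(i) {
    x <- fixture_frame(i + 40L)[9:24, 9:24]   # 16x16 crop of a 32x32 scene
    training_pair(x, x)
  })
  val <- pairs[5:6]
  run <- function(lam) train_gan(pairs[1:4],
    gan_config(image_size = 16L, gen_depth = 2L, base_channels = 4L,
               patch_scale = 16L, epochs = 12L, lr = 5e-4,
               l1_weight = lam, seed = 6L), val_pairs = val)
  v_l1 <- tail(run(1e4)$history$val_l1, 1)
  v_def <- tail(run(100)$history$val_l1, 1)
  expect_lte(v_l1, v_def * 1.05)
})

test_that("inference is deterministic, shape-preserving and 8-bit scaled", {
  pairs <- lapply(1:4, function(i)
    training_pair(fixture_frame(i), fixture_frame(i)))
  m <- train_gan(pairs, tiny_gan_config(n = 32L, epochs = 2L, seed = 9L))
  fr <- fixture_frame(50L)
  o1 <- infer(m, fr); o2 <- infer(m, fr)
  expect_identical(o1, o2)
  expect_equal(dim(o1), dim(fr))
  expect_true(all(o1 >= 0 & o1 <= 255))
  expect_error(infer(m, matrix(0, 16, 16)), class = "fiberdl_data_error")
  # checkpoint round trip preserves the bundle
  p <- tempfile(fileext = ".rds")
  save_model(m, p)
  m2 <- load_model(p)
  expect_identical(infer(m2, fr), o1)
  expect_error(load_model(tempfile()), class = "fiberdl_data_error")
})
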