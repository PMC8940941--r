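#' Conditional-GAN configuration
#'
#' Hyperparameters of the restoration cGAN. Defaults follow the pix2pix
#' convention the method descends from: L1 weight 100, ~70-pixel PatchGAN
#' receptive field, Adam at learning rate 2e-4 with beta1 = 0.9, and the
#' non-saturating generator update (the minimax form of the adversarial
#' objective is selectable). The latent input z is realized as dropout in the
#' generator's decoder during training; inference is deterministic.
#'
#' @param image_size Frame side in pixels; must be divisible by `2^gen_depth`.
#' @param gen_depth Number of U-Net down/up levels.
#' @param base_channels Channels of the first encoder level (doubled per
#'   level, capped at 8x).
#' @param patch_scale Target discriminator receptive field in pixels; the
#'   closest realizable architecture is chosen.
#' @param l1_weight Weight of the L1 term added to the adversarial loss.
#' @param lr Adam learning rate.
#' @param adam_beta1,adam_beta2 Adam moment decays.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param dropout Decoder dropout rate during training (the z mechanism);
#'   0 disables it.
#' @param gen_loss `"non_saturating"` (default) or `"minimax"`.
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(image_size = 512L, gen_depth = 3L, base_channels = 16L,
                       patch_scale = 70L, l1_weight = 100, lr = 2e-4,
                       adam_beta1 = 0.9, adam_beta2 = 0.999, epochs = 200L,
                       batch_size = 1L, dropout = 0.5,
                       gen_loss = c("non_saturating", "minimax"), seed = 1L) {
  gen_loss <- match.arg(gen_loss)
  if (image_size %% 2^gen_depth != 0)
    stop_config(sprintf("image_size %d is not divisible by 2^gen_depth = %d",
                        image_size, 2^gen_depth))
  if (l1_weight < 0) stop_config("l1_weight must be >= 0")
  if (epochs < 1) stop_config("epochs must be >= 1")
  if (patch_scale > image_size)
    stop_config("patch_scale cannot exceed image_size")
  if (dropout < 0 || dropout >= 1) stop_config("dropout must be in [0, 1)")
  structure(list(image_size = as.integer(image_size),
                 gen_depth = as.integer(gen_depth),
                 base_channels = as.integer(base_channels),
                 patch_scale = as.integer(patch_scale),
                 l1_weight = l1_weight, lr = lr,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 dropout = dropout, gen_loss = gen_loss,
                 seed = as.integer(seed)),
            class = "gan_config")
}

gen_channels <- function(depth, base) pmin(base * 2^(seq_len(depth) - 1), 8 * base)

# Canonical intensity normalization: 8-bit [0,255] <-> symmetric unit range.
norm_img <- function(x) x / 127.5 - 1
denorm_img <- function(x) pmin(pmax((x + 1) * 127.5, 0), 255)

#' Build the U-Net generator
#'
#' Encoder-decoder with skip connections: `gen_depth` stride-2 4x4
#' convolutions (leaky ReLU 0.2) down, a 3x3 bottleneck, and a decoder of
#' nearest-neighbour 2x upsampling followed by 3x3 convolutions (ReLU) with
#' the encoder activation of matching resolution concatenated at each level.
#' Output is a single channel through tanh, so untrained outputs already lie
#' in the canonical normalized range. Initialization is Gaussian (sd 0.02),
#' deterministic under the config seed.
#'
#' @param cfg A [gan_config()].
#' @return An object of class `fiberdl_gen`.
#' @export
build_generator <- function(cfg) {
  stopifnot(inherits(cfg, "gan_config"))
  d <- cfg$gen_depth
  ch <- gen_channels(d, cfg$base_channels)
  with_seed_(derive_seed(cfg$seed, "generator"), {
    layers <- list()
    for (i in seq_len(d))
      layers[[paste0("enc", i)]] <-
        conv_layer(if (i == 1) 1 else ch[i - 1], ch[i], k = 4, stride = 2, pad = 1)
    layers[["mid"]] <- conv_layer(ch[d], ch[d], k = 3, stride = 1, pad = 1)
    for (i in seq.int(d, 1))
      layers[[paste0("dec", i)]] <-
        conv_layer(if (i == d) ch[d] else 2 * ch[i], ch[max(i - 1, 1)],
                   k = 3, stride = 1, pad = 1)
    layers[["out"]] <- conv_layer(ch[1], 1, k = 3, stride = 1, pad = 1)
    structure(list(layers = layers,
                   arch = list(depth = d, channels = ch,
                               image_size = cfg$image_size,
                               dropout = cfg$dropout)),
              class = "fiberdl_gen")
  })
}

# Forward pass; x is a normalized H x W (x1) array. Returns tape + output id.
gen_forward <- function(G, x, training = FALSE) {
  tp <- tape_new(G$layers)
  d <- G$arch$depth
  id <- tp_input(tp, x)
  skips <- integer(d)
  for (i in seq_len(d)) {
    id <- tp_conv(tp, id, paste0("enc", i))
    id <- tp_lrelu(tp, id)
    skips[i] <- id
  }
  id <- tp_conv(tp, id, "mid")
  id <- tp_lrelu(tp, id)
  for (i in seq.int(d, 1)) {
    id <- tp_up2(tp, id)
    id <- tp_conv(tp, id, paste0("dec", i))
    id <- tp_lrelu(tp, id, alpha = 0)
    if (training && G$arch$dropout > 0) id <- tp_dropout(tp, id, G$arch$dropout)
    if (i > 1) id <- tp_concat(tp, id, skips[i - 1])
  }
  id <- tp_conv(tp, id, "out")
  id <- tp_tanh(tp, id)
  list(tape = tp, out = id)
}

# Receptive field of n stride-2 4x4 layers followed by two stride-1 4x4 layers.
disc_receptive_field <- function(n2) {
  rf <- 1
  rf <- rf + 3  # output conv, k4 s1
  rf <- rf + 3  # mid conv, k4 s1
  for (i in seq_len(n2)) rf <- rf * 2 + 2
  rf
}

#' Build the PatchGAN discriminator
#'
#' Convolutional classifier over (candidate, condition) image pairs emitting
#' a per-patch decision field. The number of stride-2 levels is chosen so the
#' receptive field best matches `patch_scale` (16, 34, 70, 142, ... pixels);
#' larger patch scales therefore yield spatially smaller decision fields.
#' The network outputs logits; [disc_prob()] maps them through the logistic
#' function to per-patch probabilities in (0, 1).
#'
#' @param cfg A [gan_config()].
#' @return An object of class `fiberdl_disc`.
#' @export
build_discriminator <- function(cfg) {
  stopifnot(inherits(cfg, "gan_config"))
  max_n2 <- max(1, floor(log2(cfg$image_size / 4)))
  cand <- seq_len(max_n2)
  n2 <- cand[which.min(abs(vapply(cand, disc_receptive_field, numeric(1)) -
                             cfg$patch_scale))]
  ch <- gen_channels(n2, cfg$base_channels)
  with_seed_(derive_seed(cfg$seed, "discriminator"), {
    layers <- list()
    for (i in seq_len(n2))
      layers[[paste0("d", i)]] <-
        conv_layer(if (i == 1) 2 else ch[i - 1], ch[i], k = 4, stride = 2, pad = 1)
    layers[["mid"]] <- conv_layer(ch[n2], 2 * ch[n2], k = 4, stride = 1, pad = 1)
    layers[["out"]] <- conv_layer(2 * ch[n2], 1, k = 4, stride = 1, pad = 1)
    structure(list(layers = layers,
                   arch = list(n2 = n2, channels = ch,
                               image_size = cfg$image_size,
                               receptive_field = disc_receptive_field(n2))),
              class = "fiberdl_disc")
  })
}

# Forward pass over (candidate, condition); returns tape, logit output id and
# the id of the stacked input (channel 1 = candidate) for gradient routing.
disc_forward <- function(D, cand, cond) {
  tp <- tape_new(D$layers)
  x <- array(c(as_act(cand), as_act(cond)),
             dim = c(dim(as_act(cand))[1:2], 2))
  id_in <- tp_input(tp, x)
  id <- id_in
  for (i in seq_len(D$arch$n2)) {
    id <- tp_conv(tp, id, paste0("d", i))
    id <- tp_lrelu(tp, id)
  }
  id <- tp_conv(tp, id, "mid")
  id <- tp_lrelu(tp, id)
  id <- tp_conv(tp, id, "out")
  list(tape = tp, out = id, input = id_in)
}

#' Per-patch probability field of the discriminator
#'
#' @param D A [build_discriminator()] result.
#' @param cand Candidate image (normalized scale).
#' @param cond Conditional input image (normalized scale).
#' @return Array of probabilities in (0, 1).
#' @export
disc_prob <- function(D, cand, cond) {
  fw <- disc_forward(D, cand, cond)
  sigmoid(fw$tape$vals[[fw$out]])
}

# Loss terms from per-patch probability fields (clamped for finite logs).
gan_losses_from_probs <- function(p_real, p_fake, eps = 1e-12) {
  p_real <- pmin(pmax(p_real, eps), 1 - eps)
  p_fake <- pmin(pmax(p_fake, eps), 1 - eps)
  list(d_loss = -(mean(log(p_real)) + mean(log(1 - p_fake))),
       g_adv_non_saturating = -mean(log(p_fake)),
       g_adv_minimax = mean(log(1 - p_fake)))
}

#' Evaluate the cGAN objective on one training pair
#'
#' Computes the adversarial terms of the conditional-GAN objective together
#' with the L1 fidelity term: the discriminator loss is
#' `-(mean log D(x, y) + mean log(1 - D(G_out, y)))` over the per-patch
#' decision fields, and the combined generator loss adds `l1_weight` times
#' the mean absolute deviation between the generated image and the ground
#' truth to the adversarial term (non-saturating by default, minimax
#' selectable).
#'
#' @param G_out Generated image (normalized scale, matrix or HxWx1 array).
#' @param x Ground-truth image (same scale).
#' @param y Conditional input image (same scale).
#' @param D A [build_discriminator()] result.
#' @param l1_weight Weight of the L1 term.
#' @param gen_loss `"non_saturating"` or `"minimax"`.
#' @return List with `d_loss`, `g_adv`, `g_l1`, `g_total`.
#' @export
gan_objective <- function(G_out, x, y, D, l1_weight = 100,
                          gen_loss = c("non_saturating", "minimax")) {
  gen_loss <- match.arg(gen_loss)
  stopifnot(all(dim(as_act(G_out))[1:2] == dim(as_act(x))[1:2]),
            all(dim(as_act(x))[1:2] == dim(as_act(y))[1:2]))
  p_real <- disc_prob(D, x, y)
  p_fake <- disc_prob(D, G_out, y)
  terms <- gan_losses_from_probs(p_real, p_fake)
  g_adv <- if (gen_loss == "non_saturating") terms$g_adv_non_saturating
           else terms$g_adv_minimax
  g_l1 <- mean(abs(as_act(G_out) - as_act(x)))
  list(d_loss = terms$d_loss, g_adv = g_adv, g_l1 = g_l1,
       g_total = g_adv + l1_weight * g_l1)
}

# Generator loss and parameter gradients for one pair (normalized scale).
# Used by the training loop and by the finite-difference gradient checks.
generator_loss_and_grads <- function(G, D, x, y, l1_weight,
                                     gen_loss = "non_saturating",
                                     training = FALSE) {
  gf <- gen_forward(G, y, training = training)
  g_out <- gf$tape$vals[[gf$out]]
  df <- disc_forward(D, g_out, y)
  logits <- df$tape$vals[[df$out]]
  np <- length(logits)
  adv <- if (gen_loss == "non_saturating") mean(softplus(-logits))
         else -mean(softplus(logits))
  dlogits <- if (gen_loss == "non_saturating") -sigmoid(-logits) / np
             else -sigmoid(logits) / np
  dbk <- tape_backward(df$tape, df$out, dlogits)
  d_cand <- dbk$grads[[df$input]][, , 1, drop = FALSE]
  xa <- as_act(x)
  l1 <- mean(abs(g_out - xa))
  d_l1 <- l1_weight * sign(g_out - xa) / length(g_out)
  gbk <- tape_backward(gf$tape, gf$out, d_cand + d_l1)
  list(g_adv = adv, g_l1 = l1, g_total = adv + l1_weight * l1,
       pgrads = gbk$pgrads, g_out = g_out)
}

# Discriminator loss and parameter gradients for one pair.
discriminator_loss_and_grads <- function(D, x, y, g_out) {
  fr <- disc_forward(D, x, y)
  lr_ <- fr$tape$vals[[fr$out]]
  ff <- disc_forward(D, g_out, y)
  lf <- ff$tape$vals[[ff$out]]
  loss <- mean(softplus(-lr_)) + mean(softplus(lf))
  bk_r <- tape_backward(fr$tape, fr$out, -sigmoid(-lr_) / length(lr_))
  bk_f <- tape_backward(ff$tape, ff$out, sigmoid(lf) / length(lf))
  pg <- bk_r$pgrads
  for (nm in names(bk_f$pgrads)) {
    pg[[nm]]$W <- pg[[nm]]$W + bk_f$pgrads[[nm]]$W
    pg[[nm]]$b <- pg[[nm]]$b + bk_f$pgrads[[nm]]$b
  }
  list(d_loss = loss, pgrads = pg)
}

scale_pgrads <- function(pg, s) {
  for (nm in names(pg)) {
    pg[[nm]]$W <- pg[[nm]]$W * s
    pg[[nm]]$b <- pg[[nm]]$b * s
  }
  pg
}

add_pgrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}

#' Train the conditional GAN
#'
#' Alternating discriminator/generator Adam updates over shuffled
#' mini-batches. All randomness (initialization, shuffling, dropout) derives
#' from the config seed, so identical data + config + seed reproduce the
#' training history exactly on a fixed backend.
#'
#' @param pairs List of training pairs, each `list(x = , y = )` with 8-bit
#'   scale matrices (see [training_pair()]).
#' @param cfg A [gan_config()].
#' @param val_pairs Optional held-out pairs; per-epoch mean validation L1
#'   (normalized scale, inference mode) is recorded when given.
#' @param init Optional list with `G` and/or `D` layer parameter sets used as
#'   initialization (the learning-transfer mechanism); architectures must
#'   match the config.
#' @return An object of class `fiberdl_model`: list with `G`, `D`, `config`,
#'   `history` (tibble of class `fiberdl_history`) and `provenance`.
#' @export
train_gan <- function(pairs, cfg, val_pairs = NULL, init = NULL) {
  stopifnot(inherits(cfg, "gan_config"))
  if (length(pairs) == 0) stop_data("training requires at least one pair")
  for (p in pairs)
    if (!all(dim(p$x) == c(cfg$image_size, cfg$image_size)) ||
        !all(dim(p$y) == c(cfg$image_size, cfg$image_size)))
      stop_data("training pair geometry does not match the config image_size")
  G <- build_generator(cfg)
  D <- build_discriminator(cfg)
  if (!is.null(init$G)) {
    if (!identical(lapply(init$G, function(l) dim(l$W)),
                   lapply(G$layers, function(l) dim(l$W))))
      stop_config("generator init parameters do not match the architecture")
    G$layers <- init$G
  }
  if (!is.null(init$D)) {
    if (!identical(lapply(init$D, function(l) dim(l$W)),
                   lapply(D$layers, function(l) dim(l$W))))
      stop_config("discriminator init parameters do not match the architecture")
    D$layers <- init$D
  }
  opt_g <- adam_new(G$layers)
  opt_d <- adam_new(D$layers)
  xs <- lapply(pairs, function(p) norm_img(p$x))
  ys <- lapply(pairs, function(p) norm_img(p$y))
  hist <- vector("list", cfg$epochs)
  with_seed_(derive_seed(cfg$seed, "training"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(pairs))
      ed <- eg <- el1 <- 0
      nb <- 0L
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        # discriminator step (generator outputs treated as constants)
        pg_d <- NULL
        g_outs <- vector("list", length(idx))
        dl <- 0
        for (j in seq_along(idx)) {
          i <- idx[j]
          gf <- gen_forward(G, ys[[i]], training = TRUE)
          g_outs[[j]] <- gf$tape$vals[[gf$out]]
          res <- discriminator_loss_and_grads(D, xs[[i]], ys[[i]], g_outs[[j]])
          dl <- dl + res$d_loss
          pg_d <- add_pgrads(pg_d, res$pgrads)
        }
        upd <- adam_step(D$layers, scale_pgrads(pg_d, 1 / length(idx)), opt_d,
                         cfg$lr, cfg$adam_beta1, cfg$adam_beta2)
        D$layers <- upd$params; opt_d <- upd$state
        # generator step against the updated discriminator
        pg_g <- NULL
        gl <- ll <- 0
        for (j in seq_along(idx)) {
          i <- idx[j]
          res <- generator_loss_and_grads(G, D, xs[[i]], ys[[i]],
                                          cfg$l1_weight, cfg$gen_loss,
                                          training = TRUE)
          gl <- gl + res$g_adv; ll <- ll + res$g_l1
          pg_g <- add_pgrads(pg_g, res$pgrads)
        }
        upd <- adam_step(G$layers, scale_pgrads(pg_g, 1 / length(idx)), opt_g,
                         cfg$lr, cfg$adam_beta1, cfg$adam_beta2)
        G$layers <- upd$params; opt_g <- upd$state
        if (!is.finite(dl) || !is.finite(gl) || !is.finite(ll))
          stop_data(sprintf(
            "non-finite loss at epoch %d, batch %d (D %.3g, G adv %.3g, L1 %.3g)",
            ep, nb + 1L, dl, gl, ll))
        ed <- ed + dl / length(idx); eg <- eg + gl / length(idx)
        el1 <- el1 + ll / length(idx)
        nb <- nb + 1L
      }
      val_l1 <- NA_real_
      if (!is.null(val_pairs)) {
        v <- vapply(val_pairs, function(p) {
          gf <- gen_forward(G, norm_img(p$y), training = FALSE)
          mean(abs(gf$tape$vals[[gf$out]] - as_act(norm_img(p$x))))
        }, numeric(1))
        val_l1 <- mean(v)
      }
      hist[[ep]] <- tibble::tibble(
        epoch = ep, d_loss = ed / nb, g_adv = eg / nb, g_l1 = el1 / nb,
        g_total = eg / nb + cfg$l1_weight * el1 / nb, val_l1 = val_l1)
    }
  })
  history <- do.call(rbind, hist)
  class(history) <- c("fiberdl_history", class(history))
  structure(list(G = G, D = D, config = cfg, history = history,
                 provenance = list(seed = cfg$seed, n_pairs = length(pairs),
                                   data_fingerprint = data_fingerprint(pairs))),
            class = "fiberdl_model")
}

# Cheap dataset fingerprint: pair count plus moments of all pixels.
data_fingerprint <- function(pairs) {
  s <- vapply(pairs, function(p) c(sum(p$x), sum(p$y), sum(p$x^2), sum(p$y^2)),
              numeric(4))
  paste0("n", length(pairs), "-",
         format(sum(s) %% 1e9, digits = 15, scientific = FALSE))
}

#' Restore a single frame with a trained model
#'
#' Deterministic forward pass through the generator (dropout disabled);
#' input is taken on the 8-bit scale and the output is de-normalized back to
#' `[0, 255]`.
#'
#' @param bundle A trained [train_gan()] model.
#' @param frame Numeric matrix matching the model's image size.
#' @return Restored frame (numeric matrix, `[0, 255]`).
#' @export
infer <- function(bundle, frame) {
  stopifnot(inherits(bundle, "fiberdl_model"))
  if (!all(dim(frame) == rep(bundle$config$image_size, 2)))
    stop_data(sprintf("frame is %dx%d but the model expects %dx%d",
                      nrow(frame), ncol(frame),
                      bundle$config$image_size, bundle$config$image_size))
  gf <- gen_forward(bundle$G, norm_img(frame), training = FALSE)
  denorm_img(gf$tape$vals[[gf$out]][, , 1])
}

#' Construct a training pair
#'
#' @param x Ground-truth frame (8-bit scale).
#' @param y Conditional input frame (same geometry).
#' @param z Optional noise-source seed recorded for provenance.
#' @return A list with class `training_pair`.
#' @export
training_pair <- function(x, y, z = NULL) {
  if (!all(dim(x) == dim(y))) stop_data("x and y must share geometry")
  structure(list(x = x, y = y, z = z), class = "training_pair")
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the config, seed and dataset fingerprint alongside the
#' parameters.
#'
#' @param bundle A `fiberdl_model`.
#' @param path Destination file.
#' @return `save_model` returns `path` invisibly; `load_model` the bundle.
#' @export
save_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "fiberdl_model"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("no checkpoint at '%s'", path))
  b <- readRDS(path)
  if (!inherits(b, "fiberdl_model")) stop_data("file is not a model checkpoint")
  b
}
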