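#' Build the stage-1 (denoiser) training dataset
#'
#' Per field of view: the ground truth x is the k-frame average of the slow
#' high-SNR stack and the input y is one uniformly chosen frame with
#' augmentation noise added at a scanning speed drawn from `speed_range`,
#' mimicking the range of imaging conditions the denoiser must handle.
#'
#' @param stacks List of image stacks (one per field of view).
#' @param k Frames averaged into the ground truth (default 10).
#' @param augment A [noise_model()] supplying the augmentation noise.
#' @param speed_range Range of scanning speeds (spirals/sec) the augmentation
#'   noise is drawn at.
#' @param seed Integer seed; the dataset regenerates bit-identically.
#' @param pairs_per_stack Input frames sampled per stack (default 1).
#' @param strict Error (rather than warn and skip) on stacks shorter than k.
#' @return An object of class `fiberdl_dataset`: `pairs` plus a `provenance`
#'   tibble sufficient to regenerate the dataset.
#' @export
make_dnn1_dataset <- function(stacks, k = 10, augment = noise_model(),
                              speed_range = c(1650, 3360), seed = 1L,
                              pairs_per_stack = 1L, strict = FALSE) {
  if (length(stacks) == 0) stop_data("no input stacks")
  pairs <- list()
  prov <- list()
  with_seed_(derive_seed(seed, "dnn1-dataset"), {
    for (s in seq_along(stacks)) {
      st <- as_stack(stacks[[s]])
      if (n_frames(st) < k) {
        msg <- sprintf("stack %d has %d frames, fewer than k = %d", s,
                       n_frames(st), k)
        if (strict) stop_data(msg)
        warning(msg, call. = FALSE)
        next
      }
      x <- frame_average(st, k)
      for (r in seq_len(pairs_per_stack)) {
        frame_idx <- sample.int(n_frames(st), 1)
        speed <- runif(1, speed_range[1], speed_range[2])
        pair_seed <- derive_seed(seed, sprintf("augment-%d-%d", s, r))
        y <- apply_noise(get_frame(st, frame_idx), augment, speed,
                         seed = pair_seed)
        pairs[[length(pairs) + 1L]] <- training_pair(x, y, z = pair_seed)
        prov[[length(prov) + 1L]] <- tibble::tibble(
          stack = s, frame = frame_idx, speed = speed, seed = pair_seed,
          ground_truth = sprintf("avg%d", k))
      }
    }
  })
  if (length(pairs) == 0) stop_data("no usable stacks (all shorter than k)")
  structure(list(pairs = pairs, provenance = do.call(rbind, prov),
                 meta = list(k = k, speed_range = speed_range, seed = seed)),
            class = "fiberdl_dataset")
}

#' Build the stage-2 (denoise + inpaint) training dataset
#'
#' Per frame of each stack: the intermediate ground truth x is the stage-1
#' network's output on that frame (never the raw frame), and the input y is
#' the frame radially down-sampled by M. Pairs are aligned frame by frame.
#'
#' @param stacks List of image stacks.
#' @param dnn1 Trained stage-1 model ([train_gan()]).
#' @param M Radial down-sampling factor.
#' @param rings Ring map matching the stack geometry ([build_ring_map()]).
#' @param fill Fill policy passed to [radial_downsample()].
#' @return A `fiberdl_dataset`.
#' @export
make_dnn2_dataset <- function(stacks, dnn1, M, rings,
                              fill = "nearest_ring") {
  stopifnot(inherits(dnn1, "fiberdl_model"), inherits(rings, "ring_map"))
  pairs <- list()
  prov <- list()
  for (s in seq_along(stacks)) {
    st <- as_stack(stacks[[s]])
    if (!all(dim(st)[1:2] == dim(rings$ring_index)))
      stop_data(sprintf("stack %d geometry does not match the ring map", s))
    for (t in seq_len(n_frames(st))) {
      fr <- get_frame(st, t)
      x <- infer(dnn1, fr)
      y <- radial_downsample(fr, rings, M, fill)
      pairs[[length(pairs) + 1L]] <- training_pair(x, y)
      prov[[length(prov) + 1L]] <- tibble::tibble(
        stack = s, frame = t, M = M, fill = fill, ground_truth = "dnn1")
    }
  }
  structure(list(pairs = pairs, provenance = do.call(rbind, prov),
                 meta = list(M = M, fill = fill,
                             dnn1_fingerprint = dnn1$provenance$data_fingerprint)),
            class = "fiberdl_dataset")
}

#' Two-stage training plan
#'
#' One stage-1 denoiser configuration plus one stage-2 configuration per
#' down-sampling factor (a given stage-2 network corresponds to one scanning
#' density). Under the `pretrain` initialization scheme each stage-2 network
#' starts from the stage-1 generator and discriminator weights rather than
#' random weights; `scratch` uses fresh random initialization.
#'
#' @param dnn1_config [gan_config()] for the stage-1 denoiser.
#' @param dnn2_configs Either a single [gan_config()] reused for every M or a
#'   named list keyed by M.
#' @param averaging_k Frames averaged into stage-1 ground truth (>= 2).
#' @param M_list Down-sampling factors to train stage-2 networks for.
#' @param init_scheme `"pretrain"` or `"scratch"`.
#' @param fill Regridding policy for down-sampled inputs.
#' @param augment Stage-1 augmentation [noise_model()].
#' @param augment_speed_range Speed range for stage-1 augmentation.
#' @param scanning_density Full radial density of the ring map; defaults to
#'   the image size (the admissible maximum for a square frame).
#' @param pairs_per_stack Input frames sampled per field of view when building
#'   the stage-1 dataset (one random frame is the protocol's default; more
#'   enlarge small synthetic datasets).
#' @param mode `"two_stage"` (default) or `"single_stage"` (the ablation that
#'   trains one network directly on averaged-ground-truth pairs to denoise
#'   and inpaint simultaneously).
#' @return An object of class `two_stage_plan`.
#' @export
two_stage_plan <- function(dnn1_config, dnn2_configs = dnn1_config,
                           averaging_k = 10L, M_list = c(2, 4, 8, 16, 32),
                           init_scheme = c("pretrain", "scratch"),
                           fill = "nearest_ring", augment = noise_model(),
                           augment_speed_range = c(1650, 3360),
                           scanning_density = NULL, pairs_per_stack = 1L,
                           mode = c("two_stage", "single_stage")) {
  init_scheme <- match.arg(init_scheme)
  mode <- match.arg(mode)
  if (averaging_k < 2) stop_config("averaging_k must be >= 2")
  if (inherits(dnn2_configs, "gan_config"))
    dnn2_configs <- stats::setNames(rep(list(dnn2_configs), length(M_list)),
                                    as.character(M_list))
  if (!all(as.character(M_list) %in% names(dnn2_configs)))
    stop_config("dnn2_configs must provide a config for every M in M_list")
  structure(list(dnn1_config = dnn1_config, dnn2_configs = dnn2_configs,
                 averaging_k = as.integer(averaging_k), M_list = M_list,
                 init_scheme = init_scheme, fill = fill, augment = augment,
                 augment_speed_range = augment_speed_range,
                 scanning_density = scanning_density,
                 pairs_per_stack = as.integer(pairs_per_stack), mode = mode),
            class = "two_stage_plan")
}

#' Run the two-stage learning-transfer protocol
#'
#' Stage 1 trains the denoiser on (k-frame-average, noisy-frame) pairs from
#' `trainA`. Its outputs on `trainB` then serve as intermediate ground truth,
#' paired with radially down-sampled versions of the same frames, to train
#' one stage-2 denoise-and-inpaint network per down-sampling factor. `trainA`
#' and `trainB` must be disjoint acquisitions (different fields of view).
#'
#' @param plan A [two_stage_plan()].
#' @param trainA Stacks for stage 1 (slow, high-SNR acquisitions).
#' @param trainB Stacks for stage 2 (fast full-density acquisitions).
#' @param seed Integer seed for dataset construction.
#' @param val_fraction Fraction of each stage's pairs held out for per-epoch
#'   validation L1 (0 disables).
#' @return List with `dnn1` (model), `dnn2` (named list of models keyed by
#'   M) and `histories`.
#' @export
run_two_stage <- function(plan, trainA, trainB, seed = 1L,
                          val_fraction = 0) {
  stopifnot(inherits(plan, "two_stage_plan"))
  split_val <- function(pairs) {
    if (val_fraction <= 0 || length(pairs) < 4)
      return(list(train = pairs, val = NULL))
    nv <- max(1L, floor(val_fraction * length(pairs)))
    list(train = pairs[seq_len(length(pairs) - nv)],
         val = pairs[seq.int(length(pairs) - nv + 1L, length(pairs))])
  }
  if (plan$mode == "single_stage") {
    img <- plan$dnn1_config$image_size
    dens <- if (is.null(plan$scanning_density)) img else plan$scanning_density
    rings <- build_ring_map(img, dens)
    ds <- make_dnn1_dataset(trainA, plan$averaging_k, plan$augment,
                            plan$augment_speed_range, seed = seed,
                            pairs_per_stack = plan$pairs_per_stack)
    m <- plan$M_list[1]
    ds$pairs <- lapply(ds$pairs, function(p)
      training_pair(p$x, radial_downsample(p$y, rings, m, plan$fill), p$z))
    sv <- split_val(ds$pairs)
    net <- train_gan(sv$train, plan$dnn1_config, val_pairs = sv$val)
    return(list(dnn1 = NULL, dnn2 = stats::setNames(list(net), as.character(m)),
                histories = list(single = net$history)))
  }
  ds1 <- make_dnn1_dataset(trainA, plan$averaging_k, plan$augment,
                           plan$augment_speed_range, seed = seed,
                           pairs_per_stack = plan$pairs_per_stack)
  sv1 <- split_val(ds1$pairs)
  dnn1 <- tryCatch(train_gan(sv1$train, plan$dnn1_config, val_pairs = sv1$val),
                   error = function(e)
                     stop_data(paste0("stage 1 failed: ", conditionMessage(e))))
  img <- plan$dnn1_config$image_size
  dens <- if (is.null(plan$scanning_density)) img else plan$scanning_density
  rings <- build_ring_map(img, dens)
  dnn2 <- list()
  histories <- list(dnn1 = dnn1$history)
  for (m in plan$M_list) {
    ds2 <- make_dnn2_dataset(trainB, dnn1, m, rings, plan$fill)
    stopifnot(all(ds2$provenance$ground_truth == "dnn1"))
    cfg2 <- plan$dnn2_configs[[as.character(m)]]
    init <- if (plan$init_scheme == "pretrain")
      list(G = dnn1$G$layers, D = dnn1$D$layers) else NULL
    sv2 <- split_val(ds2$pairs)
    net <- tryCatch(
      train_gan(sv2$train, cfg2, val_pairs = sv2$val, init = init),
      error = function(e)
        stop_data(sprintf("stage 2 (M = %d) failed: %s", m,
                          conditionMessage(e))))
    dnn2[[as.character(m)]] <- net
    histories[[paste0("dnn2_M", m)]] <- net$history
  }
  list(dnn1 = dnn1, dnn2 = dnn2, histories = histories)
}

#' Enhance a stack frame by frame
#'
#' @param bundle Trained model.
#' @param stack Image stack matching the model geometry.
#' @return Enhanced stack with provenance attributes (`model_fingerprint`,
#'   `config`).
#' @export
enhance_stack <- function(bundle, stack) {
  stack <- as_stack(stack)
  out <- stack_map(stack, function(fr) infer(bundle, fr))
  attr(out, "model_fingerprint") <- bundle$provenance$data_fingerprint
  attr(out, "config") <- bundle$config
  out
}
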