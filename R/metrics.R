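#' Soma region of interest with adjacent background
#'
#' @param mask Logical matrix selecting the soma pixels.
#' @param background_mask Logical matrix of adjacent structure-free pixels,
#'   disjoint from `mask`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, background_mask) {
  if (!any(mask) || !any(background_mask))
    stop_data("both the soma mask and the background mask must be non-empty")
  if (any(mask & background_mask))
    stop_data("soma and background masks must be disjoint")
  structure(list(mask = mask, background_mask = background_mask),
            class = "roi_mask")
}

#' Build an annular background ROI around a soma
#'
#' Morphological annulus of the given width around the soma, restricted to
#' structure-free pixels, the usual "background adjacent to the neuron".
#'
#' @param soma Logical soma mask.
#' @param structure_free Logical mask of pixels free of any structure
#'   (e.g. a phantom scene's `background_mask`).
#' @param width Annulus outer extent in pixels (Chebyshev distance from the
#'   soma).
#' @param inner_margin Pixels immediately around the soma excluded from the
#'   annulus, guarding against spill-over from the soma edge.
#' @return An [roi_mask()].
#' @export
annulus_roi <- function(soma, structure_free, width = 4, inner_margin = 2) {
  if (inner_margin >= width)
    stop_config("inner_margin must be smaller than width")
  dilate_box <- function(mask, rad) {
    n <- nrow(mask)
    w <- which(mask, arr.ind = TRUE)
    out <- matrix(FALSE, n, ncol(mask))
    for (k in seq_len(nrow(w))) {
      i0 <- max(1, w[k, 1] - rad); i1 <- min(n, w[k, 1] + rad)
      j0 <- max(1, w[k, 2] - rad); j1 <- min(ncol(mask), w[k, 2] + rad)
      out[i0:i1, j0:j1] <- TRUE
    }
    out
  }
  ring <- dilate_box(soma, ceiling(width)) &
    !dilate_box(soma, ceiling(inner_margin))
  bg <- ring & structure_free & !soma
  if (!any(bg))
    stop_data("no structure-free background found adjacent to the soma; widen the annulus")
  roi_mask(soma, bg)
}

#' Signal-to-noise ratio of a neuron, in dB
#'
#' `10 * log10(P_signal / P_noise)` where `P_signal` is the mean intensity
#' over the soma mask and `P_noise` the mean intensity over the adjacent
#' background mask.
#'
#' @param frame Numeric intensity matrix.
#' @param roi An [roi_mask()].
#' @return SNR in decibels.
#' @export
snr_db <- function(frame, roi) {
  stopifnot(inherits(roi, "roi_mask"))
  p_sig <- mean(frame[roi$mask])
  p_noise <- mean(frame[roi$background_mask])
  if (p_noise <= 0)
    stop_data("mean background intensity is not positive; SNR undefined")
  10 * log10(p_sig / p_noise)
}

#' Extract a peak-normalized dF/F calcium trace
#'
#' Per frame, the soma-mean intensity minus the adjacent-background mean;
#' the baseline F_b is a low percentile of that background-subtracted trace;
#' dF/F = (F - F_b)/F_b is then divided by its maximum so the peak equals 1.
#' An all-zero (inactive) trace is returned as zeros.
#'
#' @param stack Image stack (`H x W x T`).
#' @param roi An [roi_mask()].
#' @param baseline_percentile Percentile (0-100) of the background-subtracted
#'   trace used as baseline; default 10.
#' @return Numeric vector of length T, class `calcium_trace`.
#' @export
dff_trace <- function(stack, roi, baseline_percentile = 10) {
  stack <- as_stack(stack)
  stopifnot(inherits(roi, "roi_mask"))
  tt <- n_frames(stack)
  f <- vapply(seq_len(tt), function(t) {
    fr <- get_frame(stack, t)
    mean(fr[roi$mask]) - mean(fr[roi$background_mask])
  }, numeric(1))
  fb <- quantile(f, baseline_percentile / 100, names = FALSE)
  if (fb <= 0)
    stop_data(sprintf(
      "baseline (percentile %g of the background-subtracted trace) is not positive",
      baseline_percentile))
  dff <- (f - fb) / fb
  m <- max(dff)
  out <- if (m > 0) dff / m else dff * 0
  structure(out, class = "calcium_trace")
}

#' Per-neuron trace NRMSE
#'
#' Root-mean-square error between two traces divided by the range
#' `max(F) - min(F)` of the evaluated trace `F` (the first argument) —
#' deliberately asymmetric: the normalizer is the evaluated signal's range,
#' not the reference's.
#'
#' @param f Evaluated trace (e.g. from a network-enhanced movie).
#' @param f0 Reference trace (e.g. from the raw movie).
#' @return NRMSE as a fraction.
#' @export
nrmse_trace <- function(f, f0) {
  f <- as.numeric(f); f0 <- as.numeric(f0)
  if (length(f) != length(f0)) stop_data("traces must have equal length")
  rng <- max(f) - min(f)
  if (rng <= 0) stop_data("evaluated trace is constant; NRMSE undefined")
  sqrt(mean((f - f0)^2)) / rng
}

#' Per-image NRMSE
#'
#' Root-mean-square error over all pixels divided by the intensity range of
#' the evaluated image `i` (not the reference `i0`).
#'
#' @param i Evaluated image (numeric matrix).
#' @param i0 Reference / ground-truth image of the same size.
#' @return NRMSE as a fraction.
#' @export
nrmse_image <- function(i, i0) {
  if (!all(dim(i) == dim(i0))) stop_data("images must have equal dimensions")
  rng <- max(i) - min(i)
  if (rng <= 0) stop_data("evaluated image is constant; NRMSE undefined")
  sqrt(mean((i - i0)^2)) / rng
}

# Valid-region separable Gaussian filtering via banded matrices.
gauss_kernel_1d <- function(size = 11, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

filter_valid <- function(x, g) {
  k <- length(g)
  n1 <- nrow(x) - k + 1
  n2 <- ncol(x) - k + 1
  B1 <- matrix(0, n1, nrow(x))
  for (i in seq_len(n1)) B1[i, i:(i + k - 1)] <- g
  B2 <- matrix(0, n2, ncol(x))
  for (i in seq_len(n2)) B2[i, i:(i + k - 1)] <- g
  B1 %*% x %*% t(B2)
}

ssim_maps <- function(i, i0, window, sigma, k1, k2, dynamic_range) {
  g <- gauss_kernel_1d(window, sigma)
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  mu1 <- filter_valid(i, g); mu2 <- filter_valid(i0, g)
  s11 <- filter_valid(i * i, g) - mu1^2
  s22 <- filter_valid(i0 * i0, g) - mu2^2
  s12 <- filter_valid(i * i0, g) - mu1 * mu2
  lum <- (2 * mu1 * mu2 + c1) / (mu1^2 + mu2^2 + c1)
  cs <- (2 * s12 + c2) / (s11 + s22 + c2)
  list(lum = lum, cs = cs)
}

downsample2 <- function(x) {
  n1 <- floor(nrow(x) / 2); n2 <- floor(ncol(x) / 2)
  x <- x[seq_len(2 * n1), seq_len(2 * n2), drop = FALSE]
  0.25 * (x[seq(1, 2 * n1, 2), seq(1, 2 * n2, 2)] +
          x[seq(2, 2 * n1, 2), seq(1, 2 * n2, 2)] +
          x[seq(1, 2 * n1, 2), seq(2, 2 * n2, 2)] +
          x[seq(2, 2 * n1, 2), seq(2, 2 * n2, 2)])
}

#' Multi-scale structural similarity (MS-SSIM)
#'
#' Standard multi-scale SSIM: contrast/structure terms at every dyadic scale
#' and the luminance term at the coarsest, combined with exponent weights.
#' Defaults are the canonical published constants: 5 scales with weights
#' (0.0448, 0.2856, 0.3001, 0.2363, 0.1333), an 11x11 Gaussian window with
#' sigma 1.5, and stabilizers K1 = 0.01, K2 = 0.03 on an 8-bit dynamic range.
#' With fewer scales the leading weights are renormalized to sum to one.
#'
#' @param i,i0 Images to compare (numeric matrices, same size).
#' @param n_scales Number of dyadic scales (default 5).
#' @param scale_weights Exponent weights, one per scale.
#' @param window,sigma Gaussian window size and standard deviation.
#' @param k1,k2 Stabilization constants.
#' @param dynamic_range Intensity dynamic range (255 for 8-bit data).
#' @return MS-SSIM index in `[0, 1]` for non-negative inputs.
#' @export
ms_ssim <- function(i, i0, n_scales = 5,
                    scale_weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333),
                    window = 11, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                    dynamic_range = 255) {
  if (!all(dim(i) == dim(i0))) stop_data("images must have equal dimensions")
  if (n_scales < 1) stop_config("n_scales must be >= 1")
  w <- scale_weights[seq_len(n_scales)]
  w <- w / sum(w)
  if (min(dim(i)) < window * 2^(n_scales - 1))
    stop_data(sprintf(paste0(
      "image of size %dx%d is too small for %d scales with a %d-pixel ",
      "window; reduce n_scales"), nrow(i), ncol(i), n_scales, window))
  val <- 1
  for (s in seq_len(n_scales)) {
    m <- ssim_maps(i, i0, window, sigma, k1, k2, dynamic_range)
    if (s < n_scales) {
      val <- val * max(mean(m$cs), 0)^w[s]
      i <- downsample2(i); i0 <- downsample2(i0)
    } else {
      val <- val * max(mean(m$lum * m$cs), 0)^w[s]
    }
  }
  val
}

#' Evaluate a down-sampling sweep
#'
#' Per-frame MS-SSIM and NRMSE of each stack against a reference stack,
#' aggregated to mean and standard deviation per down-sampling factor M —
#' the analysis shape behind a reconstruction-accuracy-vs-density curve.
#'
#' @param enhanced Named list mapping M (as character or integer names) to
#'   image stacks aligned with `reference`.
#' @param reference Reference image stack.
#' @param n_scales Scales passed to [ms_ssim()] (use fewer for small frames).
#' @return A tibble of class `fiberdl_sweep` with columns `M`, `n`,
#'   `msssim_mean`, `msssim_sd`, `nrmse_mean`, `nrmse_sd`.
#' @export
evaluate_sweep <- function(enhanced, reference, n_scales = 5) {
  reference <- as_stack(reference)
  rows <- lapply(names(enhanced), function(mname) {
    st <- as_stack(enhanced[[mname]])
    if (n_frames(st) != n_frames(reference))
      stop_data(sprintf("stack for M=%s has %d frames but reference has %d",
                        mname, n_frames(st), n_frames(reference)))
    ms <- numeric(n_frames(st)); nr <- numeric(n_frames(st))
    for (t in seq_len(n_frames(st))) {
      ms[t] <- ms_ssim(get_frame(st, t), get_frame(reference, t),
                       n_scales = n_scales)
      nr[t] <- nrmse_image(get_frame(st, t), get_frame(reference, t))
    }
    tibble::tibble(M = as.integer(mname), n = n_frames(st),
                   msssim_mean = mean(ms), msssim_sd = if (length(ms) > 1) sd(ms) else 0,
                   nrmse_mean = mean(nr), nrmse_sd = if (length(nr) > 1) sd(nr) else 0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fiberdl_sweep", class(out))
  out
}
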