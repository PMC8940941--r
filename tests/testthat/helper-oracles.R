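# Independent metric oracles, deliberately built on different primitives than
# the package implementations (EBImage FFT filtering vs banded-matrix
# convolution; direct formula transcriptions vs the package's vectorized
# forms). Used to cross-check every metric on random inputs.

oracle_snr_db <- function(frame, soma, bg) {
  10 * log10(sum(frame * soma) / sum(soma) / (sum(frame * bg) / sum(bg)))
}

oracle_nrmse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s / length(a)) / (max(a) - min(a))
}

# Valid-region Gaussian filtering via EBImage (FFT, circular boundary; the
# crop keeps only pixels whose neighbourhood never wraps).
oracle_filter_valid <- function(x, size = 11, sigma = 1.5) {
  g1 <- exp(-((seq_len(size) - (size + 1) / 2)^2) / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  k <- outer(g1, g1)
  full <- EBImage::imageData(EBImage::filter2(EBImage::Image(x), k))
  h <- (size - 1) / 2
  full[(1 + h):(nrow(x) - h), (1 + h):(ncol(x) - h)]
}

oracle_ssim_maps <- function(i, i0, dynamic_range = 255) {
  c1 <- (0.01 * dynamic_range)^2
  c2 <- (0.03 * dynamic_range)^2
  mu1 <- oracle_filter_valid(i); mu2 <- oracle_filter_valid(i0)
  s11 <- oracle_filter_valid(i * i) - mu1^2
  s22 <- oracle_filter_valid(i0 * i0) - mu2^2
  s12 <- oracle_filter_valid(i * i0) - mu1 * mu2
  list(lum = (2 * mu1 * mu2 + c1) / (mu1^2 + mu2^2 + c1),
       cs = (2 * s12 + c2) / (s11 + s22 + c2))
}

oracle_ms_ssim <- function(i, i0, n_scales = 5) {
  w <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)[seq_len(n_scales)]
  w <- w / sum(w)
  pool2 <- function(x) {
    n1 <- floor(nrow(x) / 2); n2 <- floor(ncol(x) / 2)
    out <- matrix(0, n1, n2)
    for (a in 1:n1) for (b in 1:n2)
      out[a, b] <- mean(x[(2 * a - 1):(2 * a), (2 * b - 1):(2 * b)])
    out
  }
  val <- 1
  for (s in seq_len(n_scales)) {
    m <- oracle_ssim_maps(i, i0)
    if (s < n_scales) {
      val <- val * max(mean(m$cs), 0)^w[s]
      i <- pool2(i); i0 <- pool2(i0)
    } else val <- val * max(mean(m$lum * m$cs), 0)^w[s]
  }
  val
}
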