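#' Spiral-scan configuration
#'
#' Captures the acquisition arithmetic of a resonant spiral-scanning
#' fiberscope: the scanner traces `scanning_speed` spirals per second, a frame
#' is assembled from `scanning_density` spirals sampled along the radial
#' direction, only the open (acquiring) fraction `duty_ratio` of the scan
#' cycle contributes, and radial down-sampling by the integer factor `M`
#' reduces the effective density to `ceiling(scanning_density / M)`.
#'
#' @param scanning_speed Spirals per second (resonant frequency of the fiber
#'   cantilever).
#' @param scanning_density Spirals per frame at full sampling.
#' @param duty_ratio Acquiring fraction of the scan cycle, in `(0, 1]`;
#'   instruments typically run around 0.5-0.8.
#' @param M Radial down-sampling factor (positive integer).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(scanning_speed, scanning_density, duty_ratio = 0.5,
                        M = 1L) {
  if (scanning_density < 1) stop_config("scanning_density must be >= 1")
  if (M < 1 || M != round(M)) stop_config("M must be a positive integer")
  if (duty_ratio <= 0 || duty_ratio > 1)
    stop_config("duty_ratio must lie in (0, 1]")
  if (scanning_speed <= 0) stop_config("scanning_speed must be > 0")
  structure(list(scanning_speed = scanning_speed,
                 scanning_density = scanning_density,
                 duty_ratio = duty_ratio, M = as.integer(M)),
            class = "scan_config")
}

#' Imaging frame rate of a spiral-scan configuration
#'
#' The frame rate equals the duty ratio times the scanning speed divided by
#' the effective scanning density, where down-sampling by `M` reduces the
#' density to `ceiling(scanning_density / M)`. At 3360 spirals/s, density
#' 512 and duty 0.5 this gives ~3.3 fps at full density and ~26 fps at M = 8
#' (64 spirals/frame).
#'
#' @param cfg A [scan_config()].
#' @return Frames per second (numeric scalar).
#' @export
frame_rate <- function(cfg) {
  stopifnot(inherits(cfg, "scan_config"))
  eff <- ceiling(cfg$scanning_density / cfg$M)
  if (eff <= 0) stop_config("effective scanning density must be positive")
  cfg$duty_ratio * cfg$scanning_speed / eff
}

#' Concentric-ring map for radial down-sampling
#'
#' Labels every pixel of a square frame with the index of the spiral ring it
#' belongs to. Rings are concentric annuli of uniform width
#' `R_corner / scanning_density` centred on the central pixel, so ring 0
#' contains the centre and the outermost ring reaches the frame corners.
#' Densities so high that rings would be narrower than the pixel diagonal
#' (and hence some ring labels empty) are rejected; for a square frame the
#' admissible maximum is the frame side length.
#'
#' @param image_size Pixels per side.
#' @param scanning_density Number of rings (spirals per frame).
#' @return An object of class `ring_map` with `ring_index` (integer matrix,
#'   labels in `[0, n_rings - 1]`), `n_rings`, `center` (row/col, 1-based) and
#'   `ring_width` in pixels.
#' @export
build_ring_map <- function(image_size, scanning_density) {
  if (image_size < 2) stop_config("image_size must be >= 2")
  if (scanning_density < 1) stop_config("scanning_density must be >= 1")
  n <- as.integer(image_size)
  center <- floor(n / 2) + 1L           # central pixel, 1-based
  ii <- matrix(seq_len(n), n, n) - center
  jj <- matrix(seq_len(n), n, n, byrow = TRUE) - center
  r <- sqrt(ii^2 + jj^2)
  rmax <- max(r)
  dr <- rmax / scanning_density
  if (dr < sqrt(0.5))
    stop_config(sprintf(paste0(
      "scanning_density %d exceeds what a %dx%d frame can represent ",
      "(ring width %.3f px is below the pixel diagonal; some rings would ",
      "hold no pixel)"), scanning_density, n, n, dr))
  idx <- pmin(floor(r / dr), scanning_density - 1)
  structure(list(ring_index = matrix(as.integer(idx), n, n),
                 n_rings = as.integer(scanning_density),
                 center = c(center, center), ring_width = dr,
                 radius = r),
            class = "ring_map")
}

#' Radially down-sample a frame
#'
#' Emulates acquisition at a scanning density reduced by the factor `M`:
#' pixels on rings whose index is divisible by `M` are preserved exactly
#' (`ceiling(n_rings / M)` rings are kept) and all other pixels are filled
#' according to `fill`:
#' \describe{
#'   \item{`nearest_ring`}{replicate the radially closest kept ring (default;
#'     resembles a low-density reconstruction).}
#'   \item{`zero`}{set unsampled pixels to zero (ring-striped raw view).}
#'   \item{`linear_radial`}{interpolate linearly in radius between the two
#'     neighbouring kept rings.}
#' }
#'
#' @param frame Numeric matrix matching the ring map geometry.
#' @param rings A [build_ring_map()] result.
#' @param M Down-sampling factor.
#' @param fill Fill policy for unsampled rings.
#' @return A numeric matrix of the same size.
#' @export
radial_downsample <- function(frame, rings, M,
                              fill = c("nearest_ring", "zero", "linear_radial")) {
  stopifnot(inherits(rings, "ring_map"))
  if (!is.matrix(frame) || !all(dim(frame) == dim(rings$ring_index)))
    stop_data("frame geometry does not match the ring map")
  if (M < 1 || M != round(M)) stop_config("M must be a positive integer")
  fill <- match.arg(fill)
  if (M == 1) return(frame)
  idx <- rings$ring_index
  kept <- idx %% M == 0L
  if (fill == "zero") {
    out <- matrix(0, nrow(frame), ncol(frame))
    out[kept] <- frame[kept]
    return(out)
  }
  # Sample the frame at a target radius along each pixel's ray from center.
  sample_at_radius <- function(target_r) {
    n <- nrow(frame)
    cy <- rings$center[1]; cx <- rings$center[2]
    ii <- matrix(seq_len(n), n, n) - cy
    jj <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
    r <- rings$radius
    s <- ifelse(r > 0, target_r / r, 0)
    si <- pmin(pmax(round(cy + ii * s), 1), n)
    sj <- pmin(pmax(round(cx + jj * s), 1), n)
    matrix(frame[cbind(as.vector(si), as.vector(sj))], n, n)
  }
  ring_center_r <- function(k) (k + 0.5) * rings$ring_width
  out <- frame
  if (fill == "nearest_ring") {
    k_near <- pmin(round(idx / M) * M, max(idx[kept]))
    vals <- sample_at_radius(ring_center_r(k_near))
    out[!kept] <- vals[!kept]
  } else {  # linear_radial
    k0 <- floor(idx / M) * M
    k1 <- pmin(k0 + M, max(idx[kept]))
    v0 <- sample_at_radius(ring_center_r(k0))
    v1 <- sample_at_radius(ring_center_r(k1))
    r0 <- ring_center_r(k0); r1 <- ring_center_r(k1)
    w <- ifelse(r1 > r0, (rings$radius - r0) / (r1 - r0), 0)
    w <- pmin(pmax(w, 0), 1)
    vals <- (1 - w) * v0 + w * v1
    out[!kept] <- vals[!kept]
  }
  out
}
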