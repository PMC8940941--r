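#' Write an image stack as multi-page 8-bit grayscale TIFF
#'
#' Frames are rounded to integers and stored losslessly; a sidecar JSON
#' (`<path>.json`) records metadata such as seeds, ROI masks and true traces.
#'
#' @param stack Image stack (`H x W x T`), intensities in `[0, 255]`.
#' @param path Output TIFF path.
#' @param metadata Named list written to the sidecar JSON (optional).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, metadata = NULL) {
  stack <- as_stack(stack)
  frames <- lapply(seq_len(n_frames(stack)),
                   function(t) round(get_frame(stack, t)) / 255)
  ok <- tryCatch({
    tiff::writeTIFF(frames, path, bits.per.sample = 8)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_data(sprintf("cannot write TIFF at '%s'", path))
  if (!is.null(metadata)) {
    meta <- c(list(dim = dim(stack)), metadata)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF as an image stack
#'
#' @param path TIFF path.
#' @return Numeric `H x W x T` array on the 8-bit scale; any sidecar JSON is
#'   attached as the `metadata` attribute.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("no TIFF at '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    round(p * 255)
  })
  out <- as_stack(frames)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(out, "metadata") <- jsonlite::read_json(sidecar,
                                                 simplifyVector = FALSE)
  out
}

# Logical mask <-> run-length encoding for JSON sidecars.
mask_to_rle <- function(mask) {
  r <- rle(as.vector(mask))
  list(dim = dim(mask), lengths = r$lengths, values = r$values)
}

rle_to_mask <- function(x) {
  d <- unlist(x$dim)
  matrix(inverse.rle(list(lengths = as.integer(unlist(x$lengths)),
                          values = as.logical(unlist(x$values)))),
         d[1], d[2])
}
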