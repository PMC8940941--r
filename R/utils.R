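#' @useDynLib fiberdl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif quantile sd cor convolve
#' @importFrom utils modifyList
NULL

# Classed conditions so the CLI can map failures to exit codes
# (2 = configuration error, 3 = data error).
stop_config <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("fiberdl_config_error", "error", "condition"),
                 list(message = msg, call = call)))
}

stop_data <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("fiberdl_data_error", "error", "condition"),
                 list(message = msg, call = call)))
}

#' Derive a module-level seed from a global seed
#'
#' A single run seed is fanned out deterministically to sub-seeds so that one
#' integer reproduces every stochastic stage of a pipeline run. The derivation
#' is a small polynomial hash of the label mixed with the global seed, kept
#' within the 32-bit range R accepts in [set.seed()].
#'
#' @param seed Global integer seed.
#' @param label Character tag naming the consumer (e.g. `"phantom"`, `"dnn1"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- 7
  for (c in utf8ToInt(label)) h <- (h * 131 + c) %% 1000000007
  as.integer((abs(seed) %% 2147483646 * 2 + h) %% 2147483645 + 1)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed_ <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# ---- image stack helpers ----------------------------------------------------

#' Coerce frames to an image stack
#'
#' Stacks are plain numeric arrays of dimension `H x W x T` holding 8-bit-scale
#' intensities in `[0, 255]` (stored as doubles; quantization only happens at
#' TIFF write time). A single matrix becomes a one-frame stack.
#'
#' @param x A matrix, a `H x W x T` array, or a list of equal-sized matrices.
#' @return A numeric array of dimension `H x W x T`.
#' @export
as_stack <- function(x) {
  if (is.list(x)) {
    d <- dim(x[[1]])
    if (!all(vapply(x, function(f) identical(dim(f), d), logical(1))))
      stop_data("all frames in a stack must share the same geometry")
    return(array(unlist(x), dim = c(d, length(x))))
  }
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L)))
  if (is.array(x) && length(dim(x)) == 3) return(x)
  stop_data("cannot interpret input as an image stack")
}

n_frames <- function(stack) dim(stack)[3]

get_frame <- function(stack, t) stack[, , t, drop = TRUE]

stack_map <- function(stack, f) {
  out <- stack
  for (t in seq_len(n_frames(stack))) out[, , t] <- f(get_frame(stack, t))
  out
}

check_range <- function(r, what) {
  if (length(r) != 2 || r[1] > r[2])
    stop_config(sprintf("%s must be a length-2 range with low <= high", what))
  invisible(r)
}
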