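#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a training history
#'
#' One row per completed epoch with discriminator loss, generator adversarial
#' loss, L1 term, combined generator loss and (if recorded) validation L1.
#'
#' @param x A `fiberdl_history`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fiberdl_history <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a trained model
#'
#' @param x A `fiberdl_model`.
#' @param ... Unused.
#' @return A tibble with architecture size, epochs and final losses.
#' @export
glance.fiberdl_model <- function(x, ...) {
  np <- sum(vapply(c(x$G$layers, x$D$layers),
                   function(l) length(l$W) + length(l$b), numeric(1)))
  last <- x$history[nrow(x$history), ]
  tibble::tibble(image_size = x$config$image_size,
                 gen_depth = x$config$gen_depth,
                 n_parameters = np, epochs = nrow(x$history),
                 d_loss = last$d_loss, g_adv = last$g_adv,
                 g_l1 = last$g_l1, val_l1 = last$val_l1,
                 seed = x$config$seed)
}

#' Plot training loss curves
#'
#' @param object A `fiberdl_history`.
#' @param ... Unused.
#' @return A ggplot object with one panel per loss component.
#' @export
autoplot.fiberdl_history <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- do.call(rbind, lapply(
    intersect(c("d_loss", "g_adv", "g_l1", "val_l1"), names(df)),
    function(nm) tibble::tibble(epoch = df$epoch, loss = nm, value = df[[nm]])))
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~loss, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history")
}

#' Plot a down-sampling sweep
#'
#' Mean with standard-deviation error bars of MS-SSIM and NRMSE against the
#' down-sampling factor M (the reconstruction-accuracy trade-off curve).
#'
#' @param object A `fiberdl_sweep` from [evaluate_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fiberdl_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- rbind(
    tibble::tibble(M = df$M, metric = "MS-SSIM", mean = df$msssim_mean,
                   sd = df$msssim_sd),
    tibble::tibble(M = df$M, metric = "NRMSE", mean = df$nrmse_mean,
                   sd = df$nrmse_sd))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$M, y = .data$mean)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.1) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "down-sampling factor M", y = NULL)
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
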