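# broom-style accessors and plotting for fitted models.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Per-epoch training history of a fitted model
#'
#' @param x A `cpi_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.cpi_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x A `cpi_fit`.
#' @param ... Unused.
#' @return Tibble with epochs run, best epoch, best monitored loss, final
#'   training loss and parameter count.
#' @export
glance.cpi_fit <- function(x, ...) {
  tibble::tibble(
    epochs_run = x$epochs_run,
    best_epoch = x$best_epoch,
    best_loss = x$best_loss,
    final_train_loss = x$history$train_loss[nrow(x$history)],
    n_parameters = sum(vapply(x$params, length, integer(1))))
}

#' Plot the training history of a fitted model
#'
#' @param object A `cpi_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch.
#' @export
autoplot.cpi_fit <- function(object, ...) {
  hh <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "series", values_to = "loss")
  hh <- dplyr::filter(hh, is.finite(.data$loss))
  ggplot2::ggplot(hh, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
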