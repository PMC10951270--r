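#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a training run
#'
#' @param x A `glyco_fit` from [train()], [finetune()] or
#'   [train_b_model()].
#' @param ... Unused.
#' @return The per-epoch history tibble (epoch, learning rate, train and
#'   validation losses, per-task losses, DWA weights).
#' @export
tidy.glyco_fit <- function(x, ...) x$history

#' @rdname tidy.glyco_fit
#' @export
glance.glyco_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    final_train_loss = x$history$train_loss[nrow(x$history)],
    n_frozen = length(x$frozen)
  )
}

#' Tidy a model's parameter inventory
#'
#' @param x A `glyco_model`.
#' @param ... Unused.
#' @return Tibble: parameter tensor name, dimensions, size.
#' @export
tidy.glyco_model <- function(x, ...) {
  flat <- .flatten_params(x$params)
  tibble::tibble(
    tensor = names(flat),
    dims = vapply(flat, function(v) {
      if (is.null(dim(v))) as.character(length(v))
      else paste(dim(v), collapse = "x")
    }, character(1)),
    size = vapply(flat, length, integer(1))
  )
}

#' @rdname tidy.glyco_model
#' @export
glance.glyco_model <- function(x, ...) {
  tibble::tibble(
    hidden = x$config$hidden,
    dropout = x$config$dropout,
    with_B = x$config$with_B,
    max_charge = x$config$max_charge,
    n_parameters = n_parameters(x)
  )
}

#' Tidy an annotated spectrum
#'
#' @param x An `annotated_spectrum`.
#' @param ... Unused.
#' @return The fragment tibble with the precursor id attached.
#' @export
tidy.annotated_spectrum <- function(x, ...) {
  out <- x$fragments
  out$precursor <- precursor_id(x$precursor)
  tibble::as_tibble(out)
}

#' Tidy a fragmentation graph
#'
#' @param x A `fragmentation_graph`.
#' @param ... Unused.
#' @return Tibble of structure fragments: ion class, composition, number
#'   of boundary cleavages, retained node count.
#' @export
tidy.fragmentation_graph <- function(x, ...) {
  purrr::map_dfr(seq_along(x$fragments), function(j) {
    f <- x$fragments[[j]]
    tibble::tibble(
      fragment = j, ion_class = f$ion_class,
      comp = format_composition(f$comp),
      n_retained = length(f$retained),
      n_cleavages = length(f$cleavages)
    )
  })
}

#' Plot training curves
#'
#' @param object A `glyco_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss against epoch.
#' @export
autoplot.glyco_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(
    object$history[, c("epoch", "train_loss", "val_loss")],
    cols = c("train_loss", "val_loss"),
    names_to = "set", values_to = "loss"
  )
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "epoch", y = "mean loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an annotated spectrum
#'
#' Stick spectrum colored by fragment class.
#'
#' @param object An `annotated_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.annotated_spectrum <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$intensity > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                  y = 0, yend = .data$intensity,
                                  colour = .data$part)) +
    ggplot2::geom_segment() +
    ggplot2::labs(x = "m/z", y = "intensity", colour = "ion class",
                  title = precursor_id(object$precursor)) +
    ggplot2::theme_minimal()
}

#' Mirror plot of predicted against observed intensities
#'
#' @param prediction A prediction tibble from [predict.glyco_model()].
#' @param observed An `annotated_spectrum` of the same precursor.
#' @return A ggplot with the prediction above and the (normalized)
#'   observation below the axis.
#' @export
plot_mirror <- function(prediction, observed) {
  obs <- tidy(observed)
  obs <- obs[obs$intensity > 0, ]
  obs$intensity <- -obs$intensity / sum(obs$intensity)
  pred <- prediction[prediction$intensity > 0, ]
  d <- dplyr::bind_rows(
    dplyr::mutate(pred[, c("mz", "intensity", "part")],
                  which = "predicted"),
    dplyr::mutate(obs[, c("mz", "intensity", "part")],
                  which = "observed")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                  y = 0, yend = .data$intensity,
                                  colour = .data$part)) +
    ggplot2::geom_segment() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30") +
    ggplot2::labs(x = "m/z", y = "relative intensity (mirrored)",
                  colour = "ion class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
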