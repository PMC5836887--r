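# autoplot() methods for the package's result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Bayesian-optimization trace
#'
#' Per-iteration objective scores with the running best overlaid; the
#' random-initialization phase is distinguished from the GP-guided phase.
#'
#' @param object A `bo_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bo_result <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$score, colour = .data$phase),
                        alpha = 0.6, size = 1) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_score), linewidth = 0.6) +
    ggplot2::labs(x = "iteration", y = "score",
                  title = "Latent-space Bayesian optimization") +
    ggplot2::theme_minimal()
}

#' Plot a similarity-probe curve
#'
#' Median Tanimoto similarity to the query and fraction of valid SMILES as a
#' function of latent-space distance.
#'
#' @param object A `probe_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.probe_curve <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(distance = object$distance,
                   value = object$median_tanimoto,
                   measure = "median Tanimoto to query"),
    tibble::tibble(distance = object$distance,
                   value = object$valid_fraction,
                   measure = "valid fraction")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$distance, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "latent-space distance", y = NULL,
                  title = "Similarity preservation around the query") +
    ggplot2::theme_minimal()
}

#' Plot an autoencoder training log
#'
#' @param object A `molecular_autoencoder`.
#' @param ... Unused.
#' @return A ggplot of the per-epoch losses.
#' @export
autoplot.molecular_autoencoder <- function(object, ...) {
  lg <- object$log
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = lg$epoch, value = lg$reconstruction_loss,
                   measure = "reconstruction loss"),
    tibble::tibble(epoch = lg$epoch, value = lg$regularizer,
                   measure = if (grepl("^vae", object$variant)) "KL divergence"
                             else "discriminator loss")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = object$variant) +
    ggplot2::theme_minimal()
}
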