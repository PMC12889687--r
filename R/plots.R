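# ggplot2 visualization methods for the main result types.

#' Plot a likelihood profile
#'
#' Per-position normalized likelihood of the observed base; planted or known
#' motif spans can be highlighted.
#'
#' @param object A [reconstruct_likelihoods()] result.
#' @param spans Optional tibble with `start`, `end` (0-based half-open).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.likelihood_profile <- function(object, spans = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$p_norm)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "position (bp)", y = "normalized likelihood p_norm") +
    ggplot2::theme_minimal()
  if (!is.null(spans) && nrow(spans) > 0) {
    p <- p + ggplot2::geom_rect(
      data = spans,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end - 0.5,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15
    )
  }
  p
}

#' Plot a nucleotide dependency map
#'
#' Signed log2 odds shifts as a heatmap; motif spans appear as diagonal
#' blocks of strong mutual dependency.
#'
#' @param object A [dependency_map()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.dependency_map <- function(object, ...) {
  e <- unclass(object)
  df <- tidyr::expand_grid(i = seq_len(nrow(e)), j = seq_len(ncol(e)))
  df$e <- e[cbind(df$i, df$j)]
  lim <- max(abs(df$e), 1e-9)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$e)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  limits = c(-lim, lim)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "target position j", y = "substituted position i",
                  fill = "e[i,j]") +
    ggplot2::theme_minimal()
}

#' Plot a design trajectory
#'
#' Best-of-pool objective per beam-search step (non-decreasing by
#' construction), with the seed score as a baseline.
#'
#' @param object A [targeted_design()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.design_result <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$step, y = .data$best_score)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$seed_score, linetype = 2,
                        colour = "grey60") +
    ggplot2::labs(x = "beam-search step", y = "best objective in pool") +
    ggplot2::theme_minimal()
}

#' Plot training curves
#'
#' Train/validation masked-LM loss (and the prior term) per epoch.
#'
#' @param object A trained `dna_lm`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.dna_lm <- function(object, ...) {
  if (is.null(object$log)) rlang::abort("model has no training log")
  df <- tidyr::pivot_longer(object$log, -"epoch",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss") +
    ggplot2::theme_minimal()
}
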