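#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation evaluation
#'
#' @param x A `cad_eval` object from [evaluate()].
#' @param ... Unused.
#' @return The per-run metric tibble: one row per family set and classifier
#'   with pooled confusion counts, accuracy, sensitivity, specificity, MCC
#'   (percent) and kappa.
#' @method tidy cad_eval
#' @export
tidy.cad_eval <- function(x, ...) {
  x$results
}

#' One-row summary of a cross-validation evaluation
#'
#' @param x A `cad_eval` object.
#' @param ... Unused.
#' @return A one-row tibble with the evaluation size and the best run by
#'   pooled accuracy.
#' @method glance cad_eval
#' @export
glance.cad_eval <- function(x, ...) {
  best <- x$results[which.max(x$results$accuracy), ]
  tibble::tibble(
    n = x$n, k = x$k, n_runs = nrow(x$results),
    best_family_set = best$family_set, best_classifier = best$classifier,
    best_accuracy = best$accuracy, best_mcc = best$mcc,
    best_kappa = best$kappa
  )
}

#' Plot evaluation metrics per classifier and family set
#'
#' @param object A `cad_eval` object.
#' @param metrics Which metric columns to draw.
#' @param ... Unused.
#' @return A ggplot: metric bars per classifier, facetted by family set.
#' @method autoplot cad_eval
#' @export
autoplot.cad_eval <- function(object,
                              metrics = c("accuracy", "sensitivity",
                                          "specificity", "mcc"), ...) {
  long <- tidyr::pivot_longer(object$results, cols = dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$classifier, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$family_set)) +
    ggplot2::labs(x = NULL, y = "percent",
                  title = sprintf("%d-fold cross-validation, n = %d",
                                  object$k, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot a phantom with its ground-truth lesion outline
#'
#' @param object A `mammocad_phantom` from [generate_phantom()].
#' @param ... Unused.
#' @return A ggplot raster of the phantom with the truth-mask boundary
#'   overlaid.
#' @method autoplot mammocad_phantom
#' @export
autoplot.mammocad_phantom <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$pixels)),
                           col = seq_len(ncol(object$pixels)))
  df$value <- object$pixels[as.matrix(df[, c("row", "col")])]
  bnd <- as.data.frame(trace_boundary(object$truth_mask))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_path(data = rbind(bnd, bnd[1L, ]),
                       ggplot2::aes(x = .data$col, y = .data$row),
                       colour = "red", linewidth = 0.4) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s phantom (seed %d)",
                                  object$spec$lesion_class, object$spec$seed),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Overlay a segmentation mask on its ROI
#'
#' @param image Gray matrix (the ROI).
#' @param mask Logical mask of the same size.
#' @return A ggplot raster with the mask boundary in red.
#' @export
plot_mask_overlay <- function(image, mask) {
  assert_gray_image(image)
  assert_mask(mask, image)
  ph <- structure(list(pixels = image, truth_mask = mask,
                       spec = list(lesion_class = "segmented", seed = NA)),
                  class = "mammocad_phantom")
  autoplot(ph) + ggplot2::labs(title = "segmentation")
}

#' Dice overlap between two masks
#'
#' `2 |A & B| / (|A| + |B|)`; 1 for identical non-empty masks, 0 for
#' disjoint ones. Used to score segmentation recovery against phantom
#' ground truth.
#'
#' @param a,b Logical mask matrices of equal size.
#' @return Dice coefficient in `[0, 1]` (`NaN` for two empty masks).
#' @export
dice_coefficient <- function(a, b) {
  assert_mask(a, arg = "a"); assert_mask(b, a, arg = "b")
  2 * sum(a & b) / (sum(a) + sum(b))
}
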