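#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot group-mean spectra
#'
#' @param ds An [ev_dataset()].
#' @param by Label column to colour by.
#' @return A ggplot.
#' @export
plot_spectra <- function(ds, by = "fraction") {
  long <- ev_spectra_long(ds)
  means <- long |>
    dplyr::group_by(.data[[by]], .data$wavenumber) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(.data$wavenumber, .data$intensity,
                                      colour = .data[[by]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Hexagon map of neuron modal classes
#'
#' @param model A trained `skinet` model.
#' @param ds The training [ev_dataset()].
#' @param label Label column (defaults to the training label).
#' @return A ggplot: one hexagon per neuron coloured by modal class,
#'   unactivated/tied neurons in white.
#' @export
plot_som_map <- function(model, ds, label = model$label) {
  mc <- som_modal_classes(model, ds, label)
  ggplot2::ggplot(mc, ggplot2::aes(.data$x, .data$y, fill = .data$modal_class)) +
    ggplot2::geom_point(shape = 21, size = 9, colour = "grey40") +
    ggplot2::scale_fill_manual(
      values = c(none = "white",
                 stats::setNames(scales_hue(length(setdiff(unique(mc$modal_class), "none"))),
                                 setdiff(sort(unique(mc$modal_class)), "none"))),
      name = "modal class") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

scales_hue <- function(n) {
  if (n == 0) return(character(0))
  grDevices::hcl(h = seq(15, 375, length.out = n + 1)[seq_len(n)], c = 100, l = 65)
}

#' @method autoplot ev_somdi
#' @export
autoplot.ev_somdi <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavenumber, .data$somdi,
                                       colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "SOMDI (max-normalized)") +
    ggplot2::theme_minimal()
}

#' @method autoplot ev_roc
#' @export
autoplot.ev_roc <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC %.3f (95%% CI %.3f-%.3f)",
                                  g$auc, g$ci_low, g$ci_high)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @method autoplot ev_barcode
#' @export
autoplot.ev_barcode <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$bit == 1),
                  ggplot2::aes(x = .data$wavenumber)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$wavenumber, y = 0, yend = 1)) +
    ggplot2::xlim(range(object$wavenumber)) +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")), y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
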