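#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained SKiNET model
#'
#' One row per neuron: grid position, planar coordinates and the class
#' weight carried for each class.
#'
#' @param x A `skinet` model.
#' @param ... Unused.
#' @return A tibble with `neuron`, `row`, `col`, `x`, `y` and one
#'   `weight_<class>` column per class.
#' @method tidy skinet
#' @export
tidy.skinet <- function(x, ...) {
  K <- nrow(x$W)
  pos_x <- x$positions[, 1]
  pos_y <- x$positions[, 2]
  out <- tibble::tibble(neuron = seq_len(K),
                        row = rep(seq_len(x$params$rows), each = x$params$cols),
                        col = rep(seq_len(x$params$cols), times = x$params$rows),
                        x = pos_x, y = pos_y)
  Cw <- x$C
  colnames(Cw) <- paste0("weight_", x$classes)
  dplyr::bind_cols(out, tibble::as_tibble(Cw))
}

#' @rdname tidy.skinet
#' @method glance skinet
#' @export
glance.skinet <- function(x, ...) {
  tibble::tibble(rows = x$params$rows, cols = x$params$cols,
                 n_vars = ncol(x$W), n_classes = length(x$classes),
                 epochs = x$params$epochs, steps = x$steps %||% NA_integer_,
                 eta0 = x$params$eta0,
                 quantization_error = if (length(x$qe)) utils::tail(x$qe, 1) else NA_real_,
                 trained = x$trained)
}

#' Tidy a SKiNET hold-out evaluation
#'
#' @param x A `skinet_eval` from [som_evaluate()].
#' @param ... Unused.
#' @return Per-class confusion counts with diagnostic metrics appended.
#' @method tidy skinet_eval
#' @export
tidy.skinet_eval <- function(x, ...) confusion_metrics(x$confusion)

#' @rdname tidy.skinet_eval
#' @method glance skinet_eval
#' @export
glance.skinet_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_test = x$n_test,
                 n_train = x$model$n_train, n_classes = length(x$model$classes))
}

#' Tidy an ROC result
#'
#' @param x An `ev_roc` from [ev_roc()].
#' @param ... Unused.
#' @return The threshold/TPR/FPR sweep as a plain tibble.
#' @method tidy ev_roc
#' @export
tidy.ev_roc <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, tpr = x$tpr, fpr = x$fpr)
}

#' @rdname tidy.ev_roc
#' @method glance ev_roc
#' @export
glance.ev_roc <- function(x, ...) {
  ci <- attr(x, "ci95")
  tibble::tibble(auc = attr(x, "auc"), ci_low = ci[1], ci_high = ci[2],
                 n_pos = attr(x, "n_pos"), n_neg = attr(x, "n_neg"))
}

#' Tidy a separation-efficiency report
#'
#' @param x An `ev_efficiency` from [ev_separation_efficiency()].
#' @param ... Unused.
#' @return Per-well counts, purity and verbatim ratio.
#' @method tidy ev_efficiency
#' @export
tidy.ev_efficiency <- function(x, ...) x$per_well

#' @rdname tidy.ev_efficiency
#' @method glance ev_efficiency
#' @export
glance.ev_efficiency <- function(x, ...) {
  tibble::tibble(routing_accuracy = x$routing_accuracy,
                 paper_efficiency = x$paper_efficiency, n = x$n)
}
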