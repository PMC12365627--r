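#' Training parameters for the supervised SOM
#'
#' Defaults follow the published configuration: a 10 x 10 hexagonal grid,
#' initial learning rate 0.1, and a training length of 4 epochs of the
#' training set (so `steps = 4 * n_train` rather than a hard-coded count).
#' Learning rate and neighborhood radius decay exponentially:
#' eta(t) = eta0 exp(-t/steps) and sigma(t) = sigma0 exp(-t log(sigma0)/steps),
#' which brings the radius from sigma0 = max(rows, cols)/2 down to 1 by the
#' final step. The neighborhood kernel is Gaussian in hexagonal lattice
#' distance.
#'
#' @param rows,cols Grid dimensions.
#' @param epochs Passes over the training set.
#' @param eta0 Initial learning rate in (0, 1].
#' @param sigma0 Initial neighborhood radius (> 0).
#' @param topology Only `"hexagonal"` is implemented.
#' @return A list of class `som_params`.
#' @export
som_params <- function(rows = 10, cols = 10, epochs = 4, eta0 = 0.1,
                       sigma0 = max(rows, cols) / 2, topology = "hexagonal") {
  stopifnot(rows >= 1, cols >= 1, epochs >= 1, eta0 > 0, eta0 <= 1, sigma0 > 0)
  topology <- match.arg(topology, "hexagonal")
  structure(list(rows = rows, cols = cols, epochs = epochs, eta0 = eta0,
                 sigma0 = sigma0, topology = topology),
            class = "som_params")
}

# Planar coordinates of a hexagonal lattice (odd rows offset by half a cell);
# squared Euclidean distance between these positions is the lattice metric.
hex_positions <- function(rows, cols) {
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  x <- g$col + ifelse(g$row %% 2 == 0, 0.5, 0)
  y <- (g$row - 1) * sqrt(3) / 2
  cbind(x = x, y = y)
}

#' Initialize an untrained SOM
#'
#' Spectral weights are drawn uniformly within the per-variable data range
#' (or \[-1, 1\] when no ranges are supplied); class weights start uniform at
#' 1/K so every neuron is initially agnostic.
#'
#' @param params A [som_params()].
#' @param n_vars Spectral dimension D.
#' @param classes Character vector of class names.
#' @param seed Integer seed.
#' @param ranges Optional 2 x D matrix of per-variable (min, max).
#' @return A list of class `skinet` with `trained = FALSE`.
#' @export
som_init <- function(params, n_vars, classes, seed = 1, ranges = NULL) {
  stopifnot(n_vars >= 1, length(classes) >= 1)
  K <- params$rows * params$cols
  if (is.null(ranges)) ranges <- rbind(rep(-1, n_vars), rep(1, n_vars))
  W <- withr_seed(seed, {
    matrix(stats::runif(K * n_vars), nrow = K) *
      matrix(ranges[2, ] - ranges[1, ], K, n_vars, byrow = TRUE) +
      matrix(ranges[1, ], K, n_vars, byrow = TRUE)
  })
  C <- matrix(1 / length(classes), nrow = K, ncol = length(classes),
              dimnames = list(NULL, classes))
  structure(list(params = params, W = W, C = C, classes = classes,
                 positions = hex_positions(params$rows, params$cols),
                 wavenumber = NULL, trained = FALSE, qe = numeric(0)),
            class = "skinet")
}

# squared lattice distances from one neuron to all neurons
lattice_d2 <- function(positions, i) {
  (positions[, 1] - positions[i, 1])^2 + (positions[, 2] - positions[i, 2])^2
}

#' Best-matching unit
#'
#' Index of the neuron whose spectral weight vector is nearest (Euclidean)
#' to the query; the class-weight block plays no part, so matching is
#' label-free. Ties break to the lowest index.
#'
#' @param model A `skinet` model.
#' @param x Numeric vector of length D.
#' @return Integer neuron index.
#' @export
som_bmu <- function(model, x) {
  if (length(x) != ncol(model$W)) {
    stop("spectrum length ", length(x), " does not match model dimension ",
         ncol(model$W), call. = FALSE)
  }
  d2 <- rowSums(sweep(model$W, 2, x)^2)
  which.min(d2)  # which.min returns the first (lowest-index) minimum
}

# BMU for every row of X at once; returns integer vector.
som_bmu_matrix <- function(model, X) {
  cross <- model$W %*% t(X)                        # K x n
  d2 <- rowSums(model$W^2) - 2 * cross             # + colSums(X^2), constant per column
  apply(d2, 2, which.min)
}

#' Train the supervised SOM (SKiNET)
#'
#' Presents training spectra cyclically in a seed-shuffled order. At each
#' step the BMU is found on the spectral weights; every neuron's spectral
#' weight moves toward the input and its class weight toward the one-hot
#' label, both scaled by the decaying learning rate and the Gaussian
#' neighborhood of the BMU. The joint class-weight update is the supervised
#' step that lets labeled neurons classify new data.
#'
#' @param ds Training [ev_dataset()].
#' @param label Name of the label column.
#' @param params A [som_params()].
#' @param seed Integer seed (initialization and presentation order).
#' @return A trained `skinet` model; `$qe` holds the mean quantization error
#'   on the training set after each epoch.
#' @export
#' @examples
#' ds <- ev_simulate_spectra(
#'   tibble::tibble(fraction = "small", state = c("healthy", "cvd"), n = 8),
#'   noise = ev_noise_none(), seed = 1)
#' fit <- som_fit(ds, "state", som_params(rows = 3, cols = 3), seed = 1)
som_fit <- function(ds, label, params = som_params(), seed = 1) {
  X <- ev_intensities(ds)
  y <- ev_labels(ds, label)
  classes <- sort(unique(y))
  if (nrow(X) == 0) stop("empty training set", call. = FALSE)
  ranges <- apply(X, 2, range)
  model <- som_init(params, ncol(X), classes, seed = seed, ranges = ranges)
  n <- nrow(X)
  steps <- params$epochs * n
  order_idx <- withr_seed(child_seed(seed, 999983L), sample.int(n))
  Y <- matrix(0, n, length(classes))
  Y[cbind(seq_len(n), match(y, classes))] <- 1
  W <- model$W; C <- model$C
  pos <- model$positions
  sig_decay <- max(log(params$sigma0), 0)
  qe <- numeric(params$epochs)
  for (t in seq_len(steps)) {
    i <- order_idx[(t - 1L) %% n + 1L]
    x <- X[i, ]
    diffW <- W - matrix(x, nrow(W), ncol(W), byrow = TRUE)
    bmu <- which.min(rowSums(diffW^2))
    eta <- params$eta0 * exp(-t / steps)
    sigma <- params$sigma0 * exp(-t * sig_decay / steps)
    h <- exp(-lattice_d2(pos, bmu) / (2 * sigma^2))
    etah <- eta * h
    W <- W - etah * diffW
    C <- C - etah * (C - matrix(Y[i, ], nrow(C), ncol(C), byrow = TRUE))
    if (t %% n == 0) {
      d2 <- rowSums(W^2) - 2 * (W %*% t(X))
      qe[t / n] <- mean(sqrt(pmax(apply(d2, 2, min) + rowSums(X^2), 0)))
    }
  }
  model$W <- W
  model$C <- C
  model$wavenumber <- ev_wavenumbers(ds)
  model$label <- label
  model$trained <- TRUE
  model$qe <- qe
  model$n_train <- n
  model$steps <- steps
  model
}

#' Classify spectra with a trained SOM
#'
#' Each spectrum's BMU is found on the spectral weights; the BMU's class
#' weights, normalized to sum 1, are the class scores and the argmax is the
#' prediction. A BMU with all-zero class mass (impossible under the default
#' initialization) falls back to the nearest neuron with nonzero mass.
#'
#' @param object A trained `skinet` model.
#' @param ds An [ev_dataset()] (or numeric matrix) to classify.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `.bmu`, `.pred_class` and one
#'   `.score_<class>` column per class.
#' @export
predict.skinet <- function(object, ds, ...) {
  if (!object$trained) stop("model is not trained", call. = FALSE)
  if (is.matrix(ds)) {
    X <- ds
    ids <- sprintf("s%04d", seq_len(nrow(X)))
  } else {
    X <- ev_intensities(ds)
    ids <- ds$sample_id
  }
  if (ncol(X) != ncol(object$W)) {
    stop("spectrum length does not match model dimension", call. = FALSE)
  }
  bmu <- som_bmu_matrix(object, X)
  S <- object$C[bmu, , drop = FALSE]
  mass <- rowSums(S)
  if (any(mass == 0)) {
    nonzero <- which(rowSums(object$C) > 0)
    for (r in which(mass == 0)) {
      d2 <- rowSums(sweep(object$W[nonzero, , drop = FALSE], 2, X[r, ])^2)
      S[r, ] <- object$C[nonzero[which.min(d2)], ]
    }
    mass <- rowSums(S)
  }
  S <- S / mass
  pred <- object$classes[max.col(S, ties.method = "first")]
  out <- tibble::tibble(sample_id = ids, .bmu = bmu, .pred_class = pred)
  colnames(S) <- paste0(".score_", object$classes)
  dplyr::bind_cols(out, tibble::as_tibble(S))
}

#' Modal class of each neuron
#'
#' Colours the map: each neuron gets the modal class of the training
#' spectra whose BMU it is, `"none"` when unactivated or tied — the rule
#' behind the hexagon map display.
#'
#' @param model A trained `skinet` model.
#' @param ds Training [ev_dataset()].
#' @param label Label column (defaults to the one used in training).
#' @return Tibble with `neuron`, `row`, `col`, `x`, `y`, `modal_class`,
#'   `n_hits`.
#' @export
som_modal_classes <- function(model, ds, label = model$label) {
  bmu <- som_bmu_matrix(model, ev_intensities(ds))
  y <- ev_labels(ds, label)
  K <- nrow(model$W)
  modal <- rep("none", K)
  hits <- integer(K)
  for (k in unique(bmu)) {
    tab <- table(y[bmu == k])
    hits[k] <- sum(tab)
    top <- tab[tab == max(tab)]
    modal[k] <- if (length(top) == 1) names(top) else "none"
  }
  tibble::tibble(neuron = seq_len(K),
                 row = rep(seq_len(model$params$rows), each = model$params$cols),
                 col = rep(seq_len(model$params$cols), times = model$params$rows),
                 x = model$positions[, 1], y = model$positions[, 2],
                 modal_class = modal, n_hits = hits)
}

#' SOM discriminant index (SOMDI)
#'
#' For class k the discriminant spectrum is the class-weight-weighted sum of
#' centred neuron weights, S_k = sum_i C_ik (W_i - Wbar); wavenumbers where
#' neurons loyal to class k carry above-average weight score high. Negative
#' entries are rectified to zero and each non-degenerate class is normalized
#' to maximum 1, so SOMDI peaks mark the bands driving the clustering.
#'
#' @param model A trained `skinet` model.
#' @return A tibble of class `ev_somdi` with columns `class`, `wavenumber`,
#'   `somdi`, and attribute `degenerate` naming classes with no weight mass.
#' @export
ev_somdi <- function(model) {
  if (!model$trained) stop("model is not trained", call. = FALSE)
  Wc <- sweep(model$W, 2, colMeans(model$W))
  S <- t(Wc) %*% model$C                       # D x K classes
  S[S < 0] <- 0
  degenerate <- character(0)
  for (k in seq_along(model$classes)) {
    mx <- max(S[, k])
    if (mx > 0) S[, k] <- S[, k] / mx else degenerate <- c(degenerate, model$classes[k])
  }
  wn <- model$wavenumber %||% seq_len(nrow(S))
  out <- tibble::tibble(
    class = rep(model$classes, each = nrow(S)),
    wavenumber = rep(wn, times = length(model$classes)),
    somdi = as.vector(S))
  class(out) <- c("ev_somdi", class(out))
  attr(out, "degenerate") <- degenerate
  out
}

#' Ranked SOMDI peaks
#'
#' Local maxima of each class's discriminant spectrum, ranked by score with
#' greedy non-maximum suppression: once a peak is taken, nearby maxima
#' within `min_sep` cm^-1 (shoulder ripples of the same band) are skipped.
#'
#' @param somdi Output of [ev_somdi()].
#' @param n Peaks to keep per class.
#' @param min_sep Minimum separation between reported peaks, cm^-1
#'   (default 10, just under one band FWHM).
#' @return Tibble with `class`, `wavenumber`, `somdi`, `rank`.
#' @export
somdi_peaks <- function(somdi, n = 6, min_sep = 10) {
  somdi |>
    dplyr::group_by(.data$class) |>
    dplyr::group_modify(function(df, key) {
      v <- df$somdi
      m <- length(v)
      is_peak <- v > c(-Inf, v[-m]) & v >= c(v[-1], -Inf) & v > 0
      pk <- df[is_peak, c("wavenumber", "somdi")]
      pk <- pk[order(-pk$somdi), ]
      keep <- integer(0)
      for (i in seq_len(nrow(pk))) {
        if (length(keep) == n) break
        if (all(abs(pk$wavenumber[i] - pk$wavenumber[keep]) >= min_sep)) {
          keep <- c(keep, i)
        }
      }
      pk <- pk[keep, , drop = FALSE]
      pk$rank <- seq_len(nrow(pk))
      pk
    }) |>
    dplyr::ungroup()
}

#' Stratified k-fold cross-validation over a parameter grid
#'
#' Mean validation accuracy per parameter combination over stratified
#' folds of the training data; the winner is the highest mean accuracy with
#' ties broken toward the smaller grid, then fewer training steps.
#'
#' @param ds An [ev_dataset()] (typically the training split).
#' @param label Label column.
#' @param grid Data frame of parameter combinations with any of the columns
#'   `rows`, `cols`, `epochs`, `eta0` (missing columns take [som_params()]
#'   defaults).
#' @param folds Number of folds (default 10); must not exceed the smallest
#'   class count.
#' @param seed Integer seed.
#' @return A tibble of class `som_cv`: the grid plus `mean_accuracy`, with
#'   the selected row index in attribute `best`.
#' @export
som_cv <- function(ds, label, grid = tibble::tibble(rows = 10, cols = 10),
                   folds = 10, seed = 1) {
  grid <- tibble::as_tibble(grid)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  y <- ev_labels(ds, label)
  if (min(table(y)) < folds) {
    stop("infeasible stratification: smallest class (", min(table(y)),
         ") has fewer members than folds (", folds, ")", call. = FALSE)
  }
  fold_id <- integer(nrow(ds))
  withr_seed(child_seed(seed, 7L), {
    for (cl in unique(y)) {
      rows <- sample(which(y == cl))
      fold_id[rows] <- rep_len(seq_len(folds), length(rows))
    }
  })
  defaults <- som_params()
  gcol <- function(name, i) {
    if (name %in% names(grid)) grid[[name]][i] else defaults[[name]]
  }
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- som_params(rows = gcol("rows", g), cols = gcol("cols", g),
                    epochs = gcol("epochs", g), eta0 = gcol("eta0", g))
    fold_acc <- numeric(folds)
    for (f in seq_len(folds)) {
      fit <- som_fit(ds[fold_id != f, , drop = FALSE], label, p,
                     seed = child_seed(seed, g * 100L + f))
      pred <- predict(fit, ds[fold_id == f, , drop = FALSE])
      fold_acc[f] <- mean(pred$.pred_class == y[fold_id == f])
    }
    acc[g] <- mean(fold_acc)
  }
  out <- dplyr::mutate(grid, mean_accuracy = acc)
  size <- vapply(seq_len(nrow(out)), function(i) gcol("rows", i) * gcol("cols", i), 1)
  eps <- vapply(seq_len(nrow(out)), function(i) gcol("epochs", i), 1)
  best <- order(-out$mean_accuracy, size, eps)[1]
  class(out) <- c("som_cv", class(out))
  attr(out, "best") <- best
  attr(out, "fold_id") <- fold_id
  out
}

#' Train/test evaluation of the SKiNET classifier
#'
#' Stratified 20:80 hold-out split, training on the 80% and classifying the
#' held-out 20%; returns per-class one-vs-rest confusion counts, overall
#' accuracy, the predictions and the fitted model.
#'
#' @param ds An [ev_dataset()].
#' @param label Label column.
#' @param params A [som_params()].
#' @param test_fraction Held-out share (default 0.2).
#' @param seed Integer seed (split, initialization, presentation order).
#' @return A list of class `skinet_eval`: `model`, `predictions`, `truth`,
#'   `accuracy`, `confusion` (per-class TP/TN/FP/FN tibble), `n_test`.
#' @export
som_evaluate <- function(ds, label, params = som_params(),
                         test_fraction = 0.2, seed = 1) {
  split <- ev_split(ds, label, test_fraction, seed = child_seed(seed, 11L))
  y_train <- ev_labels(split$train, label)
  y_test <- ev_labels(split$test, label)
  if (!all(unique(y_test) %in% unique(y_train))) {
    stop("a class is absent from the training split", call. = FALSE)
  }
  fit <- som_fit(split$train, label, params, seed = child_seed(seed, 13L))
  pred <- predict(fit, split$test)
  confusion <- purrr::map_dfr(fit$classes, function(cl) {
    tibble::tibble(class = cl,
                   TP = sum(pred$.pred_class == cl & y_test == cl),
                   TN = sum(pred$.pred_class != cl & y_test != cl),
                   FP = sum(pred$.pred_class == cl & y_test != cl),
                   FN = sum(pred$.pred_class != cl & y_test == cl))
  })
  structure(list(model = fit, predictions = pred, truth = y_test,
                 accuracy = mean(pred$.pred_class == y_test),
                 confusion = confusion, n_test = length(y_test),
                 train = split$train, test = split$test),
            class = "skinet_eval")
}

#' @export
print.skinet <- function(x, ...) {
  cat("SKiNET supervised SOM:", x$params$rows, "x", x$params$cols,
      "hexagonal grid,", ncol(x$W), "variables,",
      length(x$classes), "classes\n")
  if (x$trained) {
    cat("  trained:", x$steps, "steps (", x$params$epochs, "epochs of",
        x$n_train, "spectra ); final quantization error",
        signif(utils::tail(x$qe, 1), 4), "\n")
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
print.skinet_eval <- function(x, ...) {
  cat(sprintf("SKiNET hold-out evaluation: accuracy %.1f%% on %d test spectra\n",
              100 * x$accuracy, x$n_test))
  print(x$confusion)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
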