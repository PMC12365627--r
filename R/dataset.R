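#' Raman dataset container
#'
#' Datasets are ordinary tibbles with one row per spectrum: identifier and
#' label columns (`sample_id`, `fraction`, `state`, plus anything the caller
#' adds) and a matrix column `spectra` whose columns are named by wavenumber.
#' Matrix columns keep the n x D intensity block dense for the numerical
#' stages while the labels stay dplyr-friendly.
#'
#' @param spectra Numeric matrix, one spectrum per row, D columns.
#' @param wavenumber Strictly increasing numeric axis of length D.
#' @param meta Data frame of per-spectrum metadata with `nrow(spectra)` rows;
#'   if it lacks `sample_id` one is generated.
#' @return A tibble of class `ev_dataset`.
#' @export
ev_dataset <- function(spectra, wavenumber, meta = NULL) {
  spectra <- as.matrix(spectra)
  if (!is.numeric(spectra)) stop("spectra must be numeric", call. = FALSE)
  if (ncol(spectra) != length(wavenumber)) {
    stop("spectra has ", ncol(spectra), " columns but the axis has ",
         length(wavenumber), " points", call. = FALSE)
  }
  if (any(diff(wavenumber) <= 0)) {
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(spectra))) stop("spectra contain non-finite values", call. = FALSE)
  n <- nrow(spectra)
  if (is.null(meta)) meta <- tibble::tibble(sample_id = sprintf("s%04d", seq_len(n)))
  meta <- tibble::as_tibble(meta)
  if (nrow(meta) != n) stop("meta must have one row per spectrum", call. = FALSE)
  if (!"sample_id" %in% names(meta)) meta$sample_id <- sprintf("s%04d", seq_len(n))
  dimnames(spectra) <- list(NULL, format_wn(wavenumber))
  out <- meta
  out$spectra <- spectra
  class(out) <- c("ev_dataset", class(out))
  out
}

format_wn <- function(w) formatC(w, format = "fg", digits = 10)

#' @rdname ev_dataset
#' @param ds An `ev_dataset`.
#' @export
ev_wavenumbers <- function(ds) as.numeric(colnames(ds$spectra))

#' @rdname ev_dataset
#' @export
ev_intensities <- function(ds) {
  m <- ds$spectra
  if (is.null(m)) stop("not an ev_dataset: no 'spectra' column", call. = FALSE)
  m
}

#' Replace the intensity block of a dataset
#'
#' @param ds An `ev_dataset`.
#' @param spectra Replacement matrix, same shape as `ev_intensities(ds)`.
#' @return The dataset with its `spectra` column replaced.
#' @export
ev_set_intensities <- function(ds, spectra) {
  spectra <- as.matrix(spectra)
  stopifnot(nrow(spectra) == nrow(ds$spectra), ncol(spectra) == ncol(ds$spectra))
  dimnames(spectra) <- dimnames(ds$spectra)
  ds$spectra <- spectra
  ds
}

#' Long-format view of a dataset
#'
#' Unnests the matrix column into (`sample_id`, label columns, `wavenumber`,
#' `intensity`) rows, the shape ggplot2 and dplyr summaries want.
#'
#' @param ds An `ev_dataset`.
#' @return A long tibble.
#' @export
ev_spectra_long <- function(ds) {
  m <- ev_intensities(ds)
  wn <- ev_wavenumbers(ds)
  meta <- ds[setdiff(names(ds), "spectra")]
  idx <- rep(seq_len(nrow(m)), each = length(wn))
  out <- meta[idx, , drop = FALSE]
  out$wavenumber <- rep(wn, times = nrow(m))
  out$intensity <- as.vector(t(m))
  tibble::as_tibble(out)
}

#' Bind the label column used for classification
#'
#' @param ds An `ev_dataset`.
#' @param label Name of the label column (e.g. `"fraction"` or `"state"`).
#' @return Character vector of labels.
#' @keywords internal
ev_labels <- function(ds, label) {
  if (!label %in% names(ds)) {
    stop("label column '", label, "' not found in dataset", call. = FALSE)
  }
  as.character(ds[[label]])
}

#' Stratified train/test split
#'
#' Splits a dataset into training and held-out test subsets, stratified by
#' the label column so class proportions are preserved within one sample.
#'
#' @param ds An `ev_dataset`.
#' @param label Label column to stratify on.
#' @param test_fraction Held-out share, strictly between 0 and 1 (default
#'   0.2, i.e. a 20:80 test:train split).
#' @param seed Integer seed controlling the assignment.
#' @return A list with elements `train` and `test`, both `ev_dataset`s.
#' @export
ev_split <- function(ds, label, test_fraction = 0.2, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  y <- ev_labels(ds, label)
  test_idx <- logical(nrow(ds))
  withr_seed(seed, {
    for (cl in unique(y)) {
      rows <- which(y == cl)
      n_test <- max(1L, round(length(rows) * test_fraction))
      test_idx[sample(rows, n_test)] <- TRUE
    }
  })
  list(train = ds[!test_idx, , drop = FALSE], test = ds[test_idx, , drop = FALSE])
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Derive a per-item child seed from a root seed; keeps values in [1, 2^31-2]
# so prefixes of a dataset are invariant to the total count requested.
child_seed <- function(seed, i) {
  s <- (as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483646
  as.integer(s) + 1L
}
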