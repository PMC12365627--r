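#' Cosmic-ray despiking by running-median residuals
#'
#' Points whose residual from a running median exceeds `z` robust scale
#' units (1.4826 x MAD of the residuals) are replaced by the running median;
#' every other point is returned unchanged. A label-free single-spectrum
#' rule: no neighbour spectra are needed.
#'
#' The robust scale is the MAD of the residuals, floored at a small
#' fraction of the spectrum's overall amplitude so that noise-free smooth
#' curvature is never mistaken for a spike.
#'
#' @param x Numeric intensity vector.
#' @param window Odd window length for the running median (default 7).
#' @param z Detection threshold in robust SD units (default 8).
#' @param min_scale Scale floor as a fraction of `max(|x - median(x)|)`.
#' @return Despiked numeric vector.
#' @export
ev_despike <- function(x, window = 7, z = 8, min_scale = 1e-3) {
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3", call. = FALSE)
  if (window >= length(x)) stop("window must be shorter than the spectrum", call. = FALSE)
  med <- stats::runmed(x, k = window, endrule = "median")
  resid <- x - med
  scale <- max(stats::mad(resid), min_scale * max(abs(x - stats::median(x))),
               .Machine$double.eps)
  bad <- abs(resid) > z * scale
  x[bad] <- med[bad]
  x
}

#' Iterative polynomial baseline subtraction
#'
#' Fits a polynomial of the given order to the spectrum, clips the working
#' signal to the fitted curve wherever the fit exceeds it, and refits —
#' the standard peak-preserving modified-polyfit scheme. Returns the
#' spectrum minus the converged baseline.
#'
#' @param x Numeric intensity vector.
#' @param wavenumber Axis values (only relative spacing matters; scaled
#'   internally for conditioning).
#' @param order Polynomial degree (default 5).
#' @param iters Clipping iterations (default 30).
#' @return Baseline-corrected numeric vector.
#' @export
ev_baseline <- function(x, wavenumber = seq_along(x), order = 5, iters = 30) {
  n <- length(x)
  if (order < 1 || order >= n) stop("order must be in [1, length(x))", call. = FALSE)
  if (length(unique(wavenumber)) < order + 1) {
    stop("degenerate axis: too few distinct wavenumbers", call. = FALSE)
  }
  t <- (wavenumber - mean(wavenumber)) / (diff(range(wavenumber)) / 2)
  basis <- stats::poly(t, degree = order, raw = FALSE)
  B <- cbind(1, basis)
  work <- x
  fit <- x
  for (k in seq_len(iters)) {
    co <- qr.coef(qr(B), work)
    fit <- drop(B %*% co)
    work <- pmin(work, fit)
  }
  x - fit
}

#' Average consecutive replicate spectra
#'
#' Pointwise arithmetic mean over consecutive groups of `g` rows (map
#' acquisitions are stored in acquisition order, so replicates are
#' positional). Residual noise SD shrinks by about 1/sqrt(g).
#'
#' @param spectra Numeric matrix, one spectrum per row; `nrow` must be a
#'   multiple of `g`.
#' @param g Group size (default 10 replicates per map location).
#' @return Matrix with `nrow(spectra)/g` averaged rows.
#' @export
ev_average_replicates <- function(spectra, g = 10) {
  spectra <- as.matrix(spectra)
  if (g < 1) stop("g must be >= 1", call. = FALSE)
  if (nrow(spectra) %% g != 0) {
    stop("number of spectra (", nrow(spectra), ") is not a multiple of g = ", g,
         call. = FALSE)
  }
  if (g == 1) return(spectra)
  grp <- rep(seq_len(nrow(spectra) / g), each = g)
  out <- rowsum(spectra, grp) / g
  rownames(out) <- NULL
  out
}

#' Standard normal variate normalization
#'
#' Centers each spectrum to mean 0 and scales to unit sample SD (n-1
#' convention), removing additive offsets and multiplicative scatter.
#'
#' @param x Numeric intensity vector.
#' @return SNV-normalized vector (mean 0, SD 1).
#' @export
ev_snv <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("SNV undefined for a constant spectrum (SD = 0)", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Preprocess a spectral dataset
#'
#' Applies the cleaning chain in fixed order: despike, iterative polynomial
#' baseline subtraction, optional replicate averaging, SNV. Averaging before
#' SNV mirrors map acquisition (replicates share one scatter realization);
#' set `average = 1` (the default) when each row is already an independent
#' sample.
#'
#' @param ds An [ev_dataset()].
#' @param despike,baseline,snv Logical switches for the three stages.
#' @param despike_window,despike_z Despiking parameters, see [ev_despike()].
#' @param baseline_order,baseline_iters Baseline parameters, see
#'   [ev_baseline()].
#' @param average Replicate group size (1 = no averaging). When averaging,
#'   metadata of the first row of each group is kept.
#' @return A preprocessed [ev_dataset()].
#' @export
ev_preprocess <- function(ds, despike = TRUE, baseline = TRUE, snv = TRUE,
                          despike_window = 7, despike_z = 8,
                          baseline_order = 5, baseline_iters = 30,
                          average = 1) {
  m <- ev_intensities(ds)
  wn <- ev_wavenumbers(ds)
  if (despike) m <- t(apply(m, 1, ev_despike, window = despike_window, z = despike_z))
  if (baseline) {
    m <- t(apply(m, 1, ev_baseline, wavenumber = wn,
                 order = baseline_order, iters = baseline_iters))
  }
  if (average > 1) {
    keep <- seq(1, nrow(m), by = average)
    m <- ev_average_replicates(m, g = average)
    meta <- ds[keep, setdiff(names(ds), "spectra"), drop = FALSE]
    ds <- ev_dataset(m, wn, meta)
  } else {
    ds <- ev_set_intensities(ds, m)
  }
  if (snv) {
    m <- ev_intensities(ds)
    m <- t(apply(m, 1, ev_snv))
    ds <- ev_set_intensities(ds, m)
  }
  ds
}
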