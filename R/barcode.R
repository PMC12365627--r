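#' Savitzky-Golay second derivative
#'
#' Windowed least-squares polynomial differentiation (default window 21,
#' polynomial order 2, derivative order 2). Interior points use the central
#' SG convolution; edge points come from the polynomial fit of the terminal
#' windows, so the output is exact for polynomials up to the fit order
#' everywhere.
#'
#' @param x Numeric intensity vector, longer than `window`.
#' @param window Odd window length.
#' @param polyorder Fit order, `deriv <= polyorder < window`.
#' @param deriv Derivative order (default 2).
#' @param delta Axis spacing (default 1 cm^-1).
#' @return Numeric derivative vector of the same length.
#' @export
sg_derivative <- function(x, window = 21, polyorder = 2, deriv = 2, delta = 1) {
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  if (deriv > polyorder) stop("deriv must be <= polyorder", call. = FALSE)
  if (window >= length(x)) stop("window must be shorter than the spectrum", call. = FALSE)
  signal::sgolayfilt(x, p = polyorder, n = window, m = deriv, ts = delta)
}

#' Binary spectral barcode
#'
#' Thresholds the absolute Savitzky-Golay second derivative of a spectrum
#' at a fraction (default 40%) of its maximum absolute value: positions
#' above threshold become 1, the rest 0. Because the rule is scale-free it
#' is invariant to multiplicative scaling and to SNV.
#'
#' @param x Numeric intensity vector (a spectrum, typically a class
#'   average), or a precomputed derivative when `derivative = TRUE`.
#' @param wavenumber Axis values (defaults to indices).
#' @param threshold Fraction of the maximum absolute derivative in (0, 1).
#' @param window,polyorder SG parameters, see [sg_derivative()].
#' @param derivative Set `TRUE` when `x` is already a second derivative.
#' @param peak_local When `TRUE`, only local extrema of |d| may fire,
#'   giving the sparse barcode variant used for display.
#' @return A tibble of class `ev_barcode` with columns `wavenumber`, `bit`,
#'   and the derivative in attribute `derivative`.
#' @export
#' @examples
#' sp <- ev_simulate_spectrum(ev_peak_table(), ev_noise_none(), seed = 1)
#' bc <- ev_barcode(sp$intensity, sp$wavenumber)
ev_barcode <- function(x, wavenumber = seq_along(x), threshold = 0.40,
                       window = 21, polyorder = 2, derivative = FALSE,
                       peak_local = FALSE) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)", call. = FALSE)
  d <- if (derivative) x else sg_derivative(x, window = window, polyorder = polyorder)
  if (!all(is.finite(d))) stop("derivative contains non-finite values", call. = FALSE)
  mx <- max(abs(d))
  if (mx == 0) stop("degenerate input: derivative is identically zero", call. = FALSE)
  bit <- as.integer(abs(d) > threshold * mx)
  if (peak_local) {
    a <- abs(d)
    m <- length(a)
    is_ext <- a > c(-Inf, a[-m]) & a >= c(a[-1], -Inf)
    bit[!is_ext] <- 0L
  }
  out <- tibble::tibble(wavenumber = wavenumber, bit = bit)
  class(out) <- c("ev_barcode", class(out))
  attr(out, "derivative") <- d
  attr(out, "threshold") <- threshold
  out
}

#' Annotate a barcode with band assignments
#'
#' For each band in a peak table, reports the barcode bit at the nearest
#' axis position together with the biochemical assignment — the overlay
#' used to read barcodes against the main peaks of interest.
#'
#' @param barcode An [ev_barcode()].
#' @param peaks Band table with `center` and `assignment` columns (default
#'   [ev_base_peaks()] via [ev_peak_table()]).
#' @return Tibble with `center`, `assignment`, `bit`.
#' @export
barcode_overlay <- function(barcode, peaks = ev_peak_table()) {
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(center = numeric(0), assignment = character(0),
                          bit = integer(0)))
  }
  idx <- vapply(peaks$center, function(ctr) which.min(abs(barcode$wavenumber - ctr)), 1L)
  tibble::tibble(center = peaks$center, assignment = peaks$assignment,
                 bit = barcode$bit[idx])
}

#' Compact hexadecimal encoding of a barcode
#'
#' @param barcode An [ev_barcode()].
#' @return A single hex string (bits packed 4 per character, zero-padded).
#' @export
barcode_hex <- function(barcode) {
  bits <- barcode$bit
  pad <- (4 - length(bits) %% 4) %% 4
  bits <- c(bits, rep(0L, pad))
  nib <- matrix(bits, nrow = 4)
  paste(sprintf("%x", 8 * nib[1, ] + 4 * nib[2, ] + 2 * nib[3, ] + nib[4, ]),
        collapse = "")
}
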