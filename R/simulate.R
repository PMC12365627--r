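#' Acquisition-noise configuration for the spectrum simulator
#'
#' Bundles the artifact model applied on top of the noiseless band spectrum:
#' additive detector noise, a per-spectrum multiplicative scatter factor, a
#' smooth polynomial background and sparse cosmic-ray spikes — the artifacts
#' the preprocessing stage is built to remove.
#'
#' @param additive_sd SD of iid additive noise, as a fraction of the largest
#'   base band amplitude.
#' @param scatter_sigma Log-scale SD of the per-spectrum multiplicative
#'   scatter factor (factor = exp(N(0, scatter_sigma))).
#' @param baseline_coeffs_sd SDs of the random polynomial background
#'   coefficients on (constant, linear, quadratic, ...) terms of the raw
#'   wavenumber in cm^-1.
#' @param cosmic_rate Expected number of cosmic-ray spikes per spectrum
#'   (Poisson).
#' @param cosmic_amp_range Two-vector: spike amplitudes are uniform in this
#'   range, in multiples of the largest band amplitude.
#' @return A list of class `ev_noise`.
#' @export
ev_noise_config <- function(additive_sd = 0.02, scatter_sigma = 0.10,
                            baseline_coeffs_sd = c(0.1, 1e-4, 1e-7),
                            cosmic_rate = 0.2, cosmic_amp_range = c(5, 20)) {
  stopifnot(additive_sd >= 0, scatter_sigma >= 0, all(baseline_coeffs_sd >= 0),
            cosmic_rate >= 0, length(cosmic_amp_range) == 2,
            cosmic_amp_range[1] <= cosmic_amp_range[2])
  structure(list(additive_sd = additive_sd, scatter_sigma = scatter_sigma,
                 baseline_coeffs_sd = baseline_coeffs_sd,
                 cosmic_rate = cosmic_rate, cosmic_amp_range = cosmic_amp_range),
            class = "ev_noise")
}

#' Zero-noise configuration
#' @return An `ev_noise` with every artifact switched off.
#' @export
ev_noise_none <- function() {
  ev_noise_config(additive_sd = 0, scatter_sigma = 0,
                  baseline_coeffs_sd = c(0, 0, 0), cosmic_rate = 0)
}

gaussian_bands <- function(peaks, axis) {
  y <- numeric(length(axis))
  if (nrow(peaks) == 0) return(y)
  if (any(peaks$center < min(axis) | peaks$center > max(axis))) {
    stop("peak center outside the wavenumber axis", call. = FALSE)
  }
  sigma <- peaks$fwhm / (2 * sqrt(2 * log(2)))
  for (j in seq_len(nrow(peaks))) {
    y <- y + peaks$amplitude[j] * exp(-((axis - peaks$center[j])^2) / (2 * sigma[j]^2))
  }
  y
}

simulate_one <- function(peaks, noise, axis, seed) {
  base_amp <- if (nrow(peaks) > 0) max(peaks$amplitude) else 1
  signal <- gaussian_bands(peaks, axis)
  withr_seed(seed, {
    coeffs <- stats::rnorm(length(noise$baseline_coeffs_sd), 0, noise$baseline_coeffs_sd)
    baseline <- numeric(length(axis))
    for (k in seq_along(coeffs)) baseline <- baseline + coeffs[k] * axis^(k - 1)
    scatter <- exp(stats::rnorm(1, 0, noise$scatter_sigma))
    y <- scatter * (signal + baseline)
    y <- y + stats::rnorm(length(axis), 0, noise$additive_sd * base_amp)
    n_spikes <- stats::rpois(1, noise$cosmic_rate)
    if (n_spikes > 0) {
      pos <- sample.int(length(axis), n_spikes, replace = FALSE)
      amp <- stats::runif(n_spikes, noise$cosmic_amp_range[1], noise$cosmic_amp_range[2])
      y[pos] <- y[pos] + amp * base_amp
    }
    y
  })
}

#' Simulate one Raman spectrum
#'
#' Forward model: sum of Gaussian bands plus a random polynomial baseline,
#' scaled by a multiplicative scatter factor, plus additive noise and
#' cosmic-ray spikes. Bit-reproducible for a fixed seed.
#'
#' @param peaks Band table as returned by [ev_peak_table()].
#' @param noise An [ev_noise_config()].
#' @param axis Wavenumber axis from [ev_axis()].
#' @param seed Integer seed.
#' @return A tibble with columns `wavenumber`, `intensity`.
#' @export
#' @examples
#' sp <- ev_simulate_spectrum(ev_peak_table("small", "cvd"), seed = 7)
ev_simulate_spectrum <- function(peaks, noise = ev_noise_config(),
                                 axis = ev_axis(), seed = 1) {
  tibble::tibble(wavenumber = axis,
                 intensity = simulate_one(peaks, noise, axis, seed))
}

#' Simulate a labeled spectral dataset
#'
#' Generates `n` spectra per (fraction, state) design cell with the
#' fraction- and disease-specific band structure of [ev_peak_table()],
#' sharing one axis. Each spectrum gets its own child seed derived from the
#' root seed, so the realization of spectrum i does not depend on how many
#' others were requested.
#'
#' @param design Data frame with columns `fraction`, `state`, `n`.
#' @param noise An [ev_noise_config()].
#' @param axis Wavenumber axis.
#' @param seed Integer root seed.
#' @param fwhm Band FWHM in cm^-1 passed to [ev_peak_table()].
#' @return An [ev_dataset()] with columns `sample_id`, `fraction`, `state`,
#'   `spectra`.
#' @export
#' @examples
#' design <- tibble::tibble(fraction = "small", state = c("healthy", "cvd"), n = 5)
#' ds <- ev_simulate_spectra(design, seed = 42)
ev_simulate_spectra <- function(design, noise = ev_noise_config(),
                                axis = ev_axis(), seed = 1, fwhm = 12) {
  design <- tibble::as_tibble(design)
  req <- c("fraction", "state", "n")
  if (nrow(design) == 0 || !all(req %in% names(design))) {
    stop("design must be a non-empty data frame with columns fraction, state, n",
         call. = FALSE)
  }
  if (any(design$n < 1)) stop("every design n must be >= 1", call. = FALSE)
  rows <- vector("list", nrow(design))
  counter <- 0L
  mats <- list()
  meta <- list()
  for (r in seq_len(nrow(design))) {
    peaks <- ev_peak_table(design$fraction[r], design$state[r], fwhm = fwhm)
    n <- design$n[r]
    m <- matrix(0, nrow = n, ncol = length(axis))
    for (i in seq_len(n)) {
      counter <- counter + 1L
      m[i, ] <- simulate_one(peaks, noise, axis, child_seed(seed, counter))
    }
    mats[[r]] <- m
    meta[[r]] <- tibble::tibble(
      sample_id = sprintf("%s_%s_%03d", design$fraction[r], design$state[r], seq_len(n)),
      fraction = design$fraction[r], state = design$state[r])
  }
  ev_dataset(do.call(rbind, mats), axis, dplyr::bind_rows(meta))
}

#' Reference EV size populations
#'
#' The three size populations recovered by the cascade: small, mid and large
#' EVs with mean +/- SD diameters of 61 +/- 23, 189 +/- 84 and 432 +/- 143 nm.
#' Small EVs carry a 30 nm truncation floor (free protein and lipoprotein
#' scale lies below it); the others are truncated at zero.
#'
#' @param n Particles per population.
#' @return Tibble with columns `label`, `mean_d`, `sd_d`, `n`, `floor_d`.
#' @export
ev_size_populations <- function(n = 10000) {
  tibble::tibble(label = c("small", "mid", "large"),
                 mean_d = c(61, 189, 432), sd_d = c(23, 84, 143),
                 n = n, floor_d = c(30, 0, 0))
}

#' Simulate particle diameters
#'
#' Draws each population from a left-truncated normal by rejection, so the
#' printed mean/SD stay the untruncated-parameter interpretation.
#'
#' @param populations Data frame with columns `label`, `mean_d`, `sd_d`,
#'   `n` and optionally `floor_d` (default 0).
#' @param seed Integer seed.
#' @return Tibble with columns `label`, `diameter_nm`.
#' @export
#' @examples
#' ev_simulate_particles(ev_size_populations(n = 100), seed = 1)
ev_simulate_particles <- function(populations, seed = 1) {
  populations <- tibble::as_tibble(populations)
  if (!all(c("label", "mean_d", "sd_d", "n") %in% names(populations))) {
    stop("populations needs columns label, mean_d, sd_d, n", call. = FALSE)
  }
  if (!"floor_d" %in% names(populations)) populations$floor_d <- 0
  if (any(populations$mean_d <= 0)) stop("mean_d must be > 0", call. = FALSE)
  if (any(populations$sd_d < 0)) stop("sd_d must be >= 0", call. = FALSE)
  if (any(populations$n < 1)) stop("n must be >= 1", call. = FALSE)
  out <- vector("list", nrow(populations))
  for (r in seq_len(nrow(populations))) {
    p <- populations[r, ]
    d <- withr_seed(child_seed(seed, r), rtruncnorm(p$n, p$mean_d, p$sd_d, p$floor_d))
    out[[r]] <- tibble::tibble(label = p$label, diameter_nm = d)
  }
  dplyr::bind_rows(out)
}

# Left-truncated normal draws by rejection; exact, adequate for the mild
# truncations used here (floor at most ~1.35 SD below the mean).
rtruncnorm <- function(n, mean, sd, floor) {
  if (sd == 0) return(rep(max(mean, floor), n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, draw[draw >= floor])
  }
  out[seq_len(n)]
}

# Closed-form moments of a left-truncated normal; the independent oracle the
# particle generator is tested against.
truncnorm_moments <- function(mean, sd, floor) {
  if (sd == 0) return(list(mean = max(mean, floor), sd = 0))
  a <- (floor - mean) / sd
  lambda <- stats::dnorm(a) / (1 - stats::pnorm(a))
  delta <- lambda * (lambda - a)
  list(mean = mean + sd * lambda, sd = sd * sqrt(1 - delta))
}

#' Simulate the seven-size fluorescent bead panel
#'
#' Nominal diameters 40, 100, 200, 450, 500, 1000 and 5000 nm — the bead
#' proxies for small, mid and large EVs used to measure cascade separation
#' efficiency. Each bead is labeled with the membrane expected to trap it
#' under the diameter >= pore rule, so the routing model and the efficiency
#' statistic share one ground truth.
#'
#' @param n_per_size Beads per nominal size.
#' @param dispersion Relative Gaussian diameter dispersion (0 = monodisperse).
#' @param pore_sizes Cascade pore sizes used to derive the expected well.
#' @param seed Integer seed (used only when `dispersion > 0`).
#' @return Tibble with columns `label`, `diameter_nm`, `expected_well`.
#' @export
ev_bead_panel <- function(n_per_size = 1000, dispersion = 0,
                          pore_sizes = c(5000, 500, 200, 100, 40), seed = 1) {
  if (n_per_size < 1) stop("n_per_size must be >= 1", call. = FALSE)
  nominal <- c(40, 100, 200, 450, 500, 1000, 5000)
  out <- vector("list", length(nominal))
  for (r in seq_along(nominal)) {
    d <- rep(nominal[r], n_per_size)
    if (dispersion > 0) {
      d <- withr_seed(child_seed(seed, r),
                      stats::rnorm(n_per_size, nominal[r], dispersion * nominal[r]))
      d <- pmax(d, 1)
    }
    out[[r]] <- tibble::tibble(label = paste0("bead", nominal[r]),
                               diameter_nm = d,
                               expected_well = expected_well(nominal[r], pore_sizes))
  }
  dplyr::bind_rows(out)
}
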