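#' Fingerprint-region wavenumber axis
#'
#' Builds the Raman-shift axis the pipeline operates on. The default covers
#' the biological fingerprint region, 700 to 1700 cm^-1 inclusive at
#' 1 cm^-1 steps (1001 points), where the protein, lipid and nucleic-acid
#' bands used throughout the package live.
#'
#' @param start,stop Axis limits in cm^-1; `start` must be below `stop`.
#' @param step Positive increment in cm^-1.
#' @return A strictly increasing numeric vector of wavenumbers.
#' @export
#' @examples
#' ax <- ev_axis()
#' length(ax)
ev_axis <- function(start = 700, stop = 1700, step = 1) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step)) {
    stop("ev_axis: start, stop and step must be numeric", call. = FALSE)
  }
  if (start >= stop) stop("ev_axis: start must be < stop", call. = FALSE)
  if (step <= 0) stop("ev_axis: step must be > 0", call. = FALSE)
  seq(start, stop, by = step)
}

EV_FRACTIONS <- c("raw", "large", "mid", "small")
EV_STATES <- c("healthy", "cvd")

# Base band table for healthy raw plasma: dominant fingerprint-region bands
# with their standard biochemical assignments. Amplitudes are generator knobs
# in arbitrary intensity units, graded so protein/lipid bands dominate.
ev_base_peaks <- function() {
  tibble::tribble(
    ~center, ~amplitude, ~assignment,
    752,  0.5, "Nucleic acids",
    759,  0.4, "Tryptophan ring breathing",
    785,  0.4, "Nucleic acids",
    851,  0.5, "Tyrosine doublet (protein)",
    875,  0.4, "Phosphatidylcholine",
    882,  0.5, "Phosphatidylcholine",
    920,  0.4, "Phosphate deformation and bending",
    960,  0.6, "Polysaccharide structure",
    1003, 0.9, "Phenylalanine, carotenoids",
    1045, 0.4, "Proline",
    1124, 0.6, "Lipids",
    1131, 0.5, "C-N stretching of proteins",
    1144, 0.4, "Lipids",
    1307, 0.6, "Phospholipids, lipids, adenine",
    1341, 0.7, "Glycine backbone and proline side chain",
    1368, 0.4, "Tryptophan, guanine, thymine",
    1440, 1.0, "Lipid and protein",
    1450, 0.4, "CH2 deformation",
    1472, 0.4, "CH2 bending of lipids and proteins",
    1550, 0.4, "Amide II / protein",
    1553, 0.5, "Tryptophan",
    1656, 1.0, "Amide I / lipid"
  )
}

# Fraction multipliers: lipid/protein bands fall monotonically from raw
# plasma to small EVs; phosphatidylcholine (882) and tryptophan (1553) are
# enriched in all EV fractions; the glycine/proline band (1341) is elevated
# in small EVs.
ev_fraction_multipliers <- function(fraction) {
  fraction <- match.arg(fraction, EV_FRACTIONS)
  lipid_protein <- c(`1124` = 1, `1440` = 1, `1656` = 1)
  lp_scale <- c(raw = 1.0, large = 0.8, mid = 0.65, small = 0.5)[[fraction]]
  m <- lipid_protein * lp_scale
  if (fraction != "raw") m <- c(m, `882` = 1.4, `1553` = 1.4)
  if (fraction == "small") m <- c(m, `1341` = 1.5)
  m
}

# Disease (CVD) multipliers, all intensity increases within the 17-68% band
# except the tryptophan 1553 cm^-1 decrease; the phenylalanine 1003 cm^-1
# increase is specific to small EVs.
ev_state_multipliers <- function(state, fraction) {
  state <- match.arg(state, EV_STATES)
  fraction <- match.arg(fraction, EV_FRACTIONS)
  if (state == "healthy") return(stats::setNames(numeric(0), character(0)))
  m <- c(`752` = 1.30, `851` = 1.40, `960` = 1.50, `1144` = 1.25,
         `1440` = 1.20, `1656` = 1.35, `1553` = 0.80)
  if (fraction == "small") m <- c(m, `1003` = 1.40)
  m
}

apply_multipliers <- function(peaks, multipliers) {
  if (length(multipliers) == 0) return(peaks)
  centers <- as.numeric(names(multipliers))
  missing <- setdiff(centers, peaks$center)
  if (length(missing) > 0) {
    stop("multipliers reference centers absent from the base peak table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(multipliers <= 0)) {
    stop("all multipliers must be > 0", call. = FALSE)
  }
  idx <- match(centers, peaks$center)
  peaks$amplitude[idx] <- peaks$amplitude[idx] * unname(multipliers)
  peaks
}

#' Band table for one EV fraction and disease state
#'
#' Returns the Gaussian band parameters used by the spectrum simulator:
#' the base fingerprint-region peak table scaled by fraction-specific and
#' disease-state-specific intensity multipliers. Disease multipliers encode
#' the reported CVD signature: increases at 752, 851, 960, 1144, 1440 and
#' 1656 cm^-1 (plus 1003 cm^-1 in small EVs) and a decrease of the
#' tryptophan band at 1553 cm^-1.
#'
#' @param fraction One of `"raw"`, `"large"`, `"mid"`, `"small"`.
#' @param state One of `"healthy"`, `"cvd"`.
#' @param fwhm Full width at half maximum of every band, cm^-1.
#' @param fraction_multipliers,state_multipliers Optional named numeric
#'   vectors (names are band centers) overriding the built-in tables; all
#'   values must be positive and name existing centers.
#' @return A tibble with columns `center`, `fwhm`, `amplitude`, `assignment`.
#' @export
#' @examples
#' ev_peak_table("small", "cvd")
ev_peak_table <- function(fraction = "raw", state = "healthy", fwhm = 12,
                          fraction_multipliers = NULL,
                          state_multipliers = NULL) {
  if (!fraction %in% EV_FRACTIONS) {
    stop("ev_peak_table: unknown fraction '", fraction, "' (expected one of ",
         paste(EV_FRACTIONS, collapse = ", "), ")", call. = FALSE)
  }
  if (!state %in% EV_STATES) {
    stop("ev_peak_table: unknown state '", state, "' (expected one of ",
         paste(EV_STATES, collapse = ", "), ")", call. = FALSE)
  }
  if (fwhm <= 0) stop("ev_peak_table: fwhm must be > 0", call. = FALSE)
  peaks <- ev_base_peaks()
  fm <- if (is.null(fraction_multipliers)) ev_fraction_multipliers(fraction) else fraction_multipliers
  sm <- if (is.null(state_multipliers)) ev_state_multipliers(state, fraction) else state_multipliers
  peaks <- apply_multipliers(peaks, fm)
  peaks <- apply_multipliers(peaks, sm)
  tibble::tibble(center = peaks$center, fwhm = fwhm,
                 amplitude = peaks$amplitude, assignment = peaks$assignment)
}
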