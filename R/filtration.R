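#' Membrane cascade configuration
#'
#' @param pore_sizes Strictly decreasing pore diameters in nm, top membrane
#'   first. Default is the five-membrane cascade 5000/500/200/100/40 nm
#'   (the 40 nm stage traps free protein).
#' @return Validated numeric vector of pore sizes.
#' @export
ev_chip <- function(pore_sizes = c(5000, 500, 200, 100, 40)) {
  if (length(pore_sizes) < 1 || any(pore_sizes <= 0)) {
    stop("pore sizes must be positive", call. = FALSE)
  }
  if (any(diff(pore_sizes) >= 0)) {
    stop("pore sizes must be strictly decreasing top-to-bottom", call. = FALSE)
  }
  pore_sizes
}

# Well name for a diameter under the ideal trap rule: first membrane
# (top-down) whose pore the particle cannot pass (diameter >= pore).
expected_well <- function(diameter, pore_sizes) {
  hit <- which(diameter >= pore_sizes)
  if (length(hit) == 0) "eluate" else as.character(pore_sizes[hit[1]])
}

#' Route particles through the size-exclusion cascade
#'
#' Ideal trapping model: a particle is deposited in the well of the first
#' membrane, top-down, whose pore size it equals or exceeds; anything
#' smaller than every pore reaches the eluate. Deterministic; an optional
#' misrouting probability (default 0) sends a particle one membrane deeper
#' for leakage sensitivity studies.
#'
#' @param particles Data frame with a `diameter_nm` column (labels and other
#'   columns are carried through).
#' @param chip Pore-size vector from [ev_chip()].
#' @param misroute_prob Per-particle probability of slipping past its
#'   trapping membrane.
#' @param seed Seed, used only when `misroute_prob > 0`.
#' @return The input tibble with a `well` column (pore size as character, or
#'   `"eluate"`), one row per input particle.
#' @export
#' @examples
#' ev_route_particles(ev_bead_panel(10))
ev_route_particles <- function(particles, chip = ev_chip(), misroute_prob = 0,
                               seed = 1) {
  particles <- tibble::as_tibble(particles)
  if (!"diameter_nm" %in% names(particles)) {
    stop("particles needs a diameter_nm column", call. = FALSE)
  }
  d <- particles$diameter_nm
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("all diameters must be positive and finite", call. = FALSE)
  }
  chip <- ev_chip(chip)
  # index of trapping membrane; length(chip)+1 means eluate
  idx <- rowSums(outer(d, chip, `<`)) + 1L
  if (misroute_prob > 0) {
    slip <- withr_seed(seed, stats::runif(length(d)) < misroute_prob)
    idx[slip] <- pmin(idx[slip] + 1L, length(chip) + 1L)
  }
  wells <- c(as.character(chip), "eluate")
  particles$well <- wells[idx]
  particles
}

#' Separation efficiency of the cascade
#'
#' Computes two readings of cascade performance from routed particles:
#' `routing_accuracy` — the fraction of particles collected in the well
#' their label is expected to reach — and `paper_efficiency`, a per-well
#' purity (particles whose expected well is this well, over all particles
#' in the well) averaged over non-empty wells. A per-well `verbatim_ratio`
#' (total particles across all wells divided by this well's count) is also
#' reported for the total-over-single-membrane reading.
#'
#' @param routed Output of [ev_route_particles()].
#' @param expected Data frame mapping `label` to `expected_well`; defaults
#'   to an `expected_well` column already present in `routed` (as emitted by
#'   [ev_bead_panel()]).
#' @return A list of class `ev_efficiency`: `routing_accuracy`,
#'   `paper_efficiency`, and a `per_well` tibble with counts, purity and the
#'   verbatim ratio.
#' @export
ev_separation_efficiency <- function(routed, expected = NULL) {
  routed <- tibble::as_tibble(routed)
  if (!all(c("label", "well") %in% names(routed))) {
    stop("routed needs label and well columns", call. = FALSE)
  }
  if (is.null(expected)) {
    if (!"expected_well" %in% names(routed)) {
      stop("supply expected or include an expected_well column", call. = FALSE)
    }
  } else {
    expected <- tibble::as_tibble(expected)
    missing <- setdiff(unique(routed$label), expected$label)
    if (length(missing) > 0) {
      stop("labels missing from expected map: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    routed$expected_well <- expected$expected_well[match(routed$label, expected$label)]
  }
  total <- nrow(routed)
  hit <- routed$well == routed$expected_well
  per_well <- routed |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(n = dplyr::n(),
                     n_expected_here = sum(.data$well == .data$expected_well),
                     purity = .data$n_expected_here / .data$n,
                     .groups = "drop") |>
    dplyr::mutate(verbatim_ratio = total / .data$n)
  structure(list(routing_accuracy = mean(hit),
                 paper_efficiency = mean(per_well$purity[per_well$n > 0]),
                 per_well = per_well,
                 n = total),
            class = "ev_efficiency")
}

#' @export
print.ev_efficiency <- function(x, ...) {
  cat("Cascade separation efficiency (n =", x$n, "particles)\n")
  cat(sprintf("  routing accuracy: %.1f%%\n", 100 * x$routing_accuracy))
  cat(sprintf("  mean well purity: %.1f%%\n", 100 * x$paper_efficiency))
  print(x$per_well)
  invisible(x)
}

#' Per-well diameter summary
#'
#' Arithmetic mean, SD and count of particle diameters per collection well.
#' Wells named in `chip` but receiving no particles are reported with count
#' 0 and `NA` moments, flagged by the `empty` column.
#'
#' @param routed Output of [ev_route_particles()].
#' @param chip Optional pore-size vector used to list empty wells.
#' @return Tibble with columns `well`, `n`, `mean_d`, `sd_d`, `empty`.
#' @export
ev_well_summary <- function(routed, chip = NULL) {
  routed <- tibble::as_tibble(routed)
  out <- routed |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(n = dplyr::n(), mean_d = mean(.data$diameter_nm),
                     sd_d = stats::sd(.data$diameter_nm), .groups = "drop")
  if (!is.null(chip)) {
    all_wells <- c(as.character(ev_chip(chip)), "eluate")
    missing <- setdiff(all_wells, out$well)
    if (length(missing) > 0) {
      out <- dplyr::bind_rows(out, tibble::tibble(well = missing, n = 0L,
                                                  mean_d = NA_real_, sd_d = NA_real_))
    }
    out <- out[match(all_wells, out$well), ]
  }
  dplyr::mutate(out, empty = .data$n == 0)
}
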