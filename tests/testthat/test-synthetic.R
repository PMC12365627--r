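test_that("peak tables carry the expected bands and class structure", {
  raw <- ev_peak_table("raw", "healthy")
  expect_true(1003 %in% raw$center)
  expect_equal(raw$assignment[raw$center == 1003], "Phenylalanine, carotenoids")

  # disease signature: tryptophan band lower in CVD, in every fraction
  for (f in c("raw", "large", "mid", "small")) {
    h <- ev_peak_table(f, "healthy")
    c_ <- ev_peak_table(f, "cvd")
    expect_lt(c_$amplitude[c_$center == 1553], h$amplitude[h$center == 1553])
  }

  # identity: unit multipliers reproduce the base table
  ident <- ev_peak_table("raw", "healthy",
                         fraction_multipliers = c(`1003` = 1),
                         state_multipliers = c(`1440` = 1))
  expect_equal(ident$amplitude, ev_base_peaks()$amplitude)

  expect_error(ev_peak_table("plasma", "healthy"), "unknown fraction")
  expect_error(ev_peak_table("raw", "sick"), "unknown state")
})

test_that("CVD intensity increases lie within the 17-68% band", {
  for (f in c("large", "mid", "small")) {
    m <- evraman:::ev_state_multipliers("cvd", f)
    ups <- m[m > 1]
    expect_true(all(ups >= 1.17 & ups <= 1.68))
    expect_equal(unname(m["1553"]), 0.80)
  }
})

test_that("spectrum forward model is exact and reproducible", {
  axis <- ev_axis()
  pk <- tibble::tibble(center = 1003, fwhm = 12, amplitude = 1, assignment = "phe")
  sp <- ev_simulate_spectrum(pk, ev_noise_none(), axis, seed = 5)
  expect_equal(sp$wavenumber[which.max(sp$intensity)], 1003)
  expect_equal(max(sp$intensity), 1, tolerance = 1e-12)

  empty <- tibble::tibble(center = numeric(0), fwhm = numeric(0),
                          amplitude = numeric(0), assignment = character(0))
  expect_equal(ev_simulate_spectrum(empty, ev_noise_none(), axis, seed = 1)$intensity,
               rep(0, length(axis)))

  a <- ev_simulate_spectrum(pk, ev_noise_config(), axis, seed = 11)
  b <- ev_simulate_spectrum(pk, ev_noise_config(), axis, seed = 11)
  expect_identical(a, b)

  out_of_axis <- tibble::tibble(center = 2000, fwhm = 12, amplitude = 1,
                                assignment = "x")
  expect_error(ev_simulate_spectrum(out_of_axis, ev_noise_none(), axis),
               "outside")
})

test_that("dataset generation respects the design and the seed", {
  design <- tibble::tibble(fraction = "small", state = c("healthy", "cvd"), n = 5)
  ds <- ev_simulate_spectra(design, seed = 42)
  expect_equal(nrow(ds), 10)
  expect_equal(as.vector(table(ds$state)), c(5, 5))
  expect_equal(length(unique(ds$state)), 2)

  ds2 <- ev_simulate_spectra(design, seed = 42)
  expect_identical(ev_intensities(ds), ev_intensities(ds2))

  ds3 <- ev_simulate_spectra(design, seed = 43)
  expect_false(identical(ev_intensities(ds), ev_intensities(ds3)))
  expect_identical(ds$state, ds3$state)

  # child-seed streams: first rows of a longer run replicate a shorter one
  long <- ev_simulate_spectra(tibble::tibble(fraction = "small",
                                             state = "healthy", n = 8), seed = 9)
  short <- ev_simulate_spectra(tibble::tibble(fraction = "small",
                                              state = "healthy", n = 3), seed = 9)
  expect_identical(ev_intensities(long)[1:3, ], ev_intensities(short))

  expect_error(ev_simulate_spectra(tibble::tibble()), "non-empty")
  expect_error(ev_simulate_spectra(tibble::tibble(fraction = "small",
                                                  state = "healthy", n = 0)),
               "n must be >= 1")
})

test_that("noiseless class means reproduce every stated effect direction", {
  ax <- ev_axis()
  at <- function(v, w) v[ax == w]
  m <- list()
  for (f in c("raw", "large", "mid", "small"))
    for (s in c("healthy", "cvd"))
      m[[paste(f, s)]] <- mean_spectrum(f, s, ax)

  for (f in c("mid", "small")) {
    for (w in c(752, 851, 960, 1144, 1440, 1656)) {
      expect_gt(at(m[[paste(f, "cvd")]], w), at(m[[paste(f, "healthy")]], w))
    }
  }
  expect_gt(at(m[["small cvd"]], 1003), at(m[["small healthy"]], 1003))
  for (f in c("raw", "large", "mid", "small")) {
    expect_lt(at(m[[paste(f, "cvd")]], 1553), at(m[[paste(f, "healthy")]], 1553))
  }
  for (f in c("large", "mid", "small")) {
    for (w in c(1440, 1656)) {
      expect_gt(at(m[["raw healthy"]], w), at(m[[paste(f, "healthy")]], w))
    }
    for (w in c(882, 1553)) {
      expect_gt(at(m[[paste(f, "healthy")]], w), at(m[["raw healthy"]], w))
    }
  }
  expect_gt(at(m[["small healthy"]], 1341), at(m[["raw healthy"]], 1341))
})

test_that("particle draws match the truncated-normal closed form", {
  pops <- ev_size_populations(n = 10000)
  p <- ev_simulate_particles(pops, seed = 3)
  for (r in seq_len(nrow(pops))) {
    d <- p$diameter_nm[p$label == pops$label[r]]
    o <- oracle_truncnorm(pops$mean_d[r], pops$sd_d[r], pops$floor_d[r])
    expect_equal(mean(d), unname(o["mean"]), tolerance = 0.02)
    expect_equal(sd(d), unname(o["sd"]), tolerance = 0.05)
    expect_true(all(d >= pops$floor_d[r]))
  }

  const <- ev_simulate_particles(
    tibble::tibble(label = "x", mean_d = 50, sd_d = 0, n = 3), seed = 1)
  expect_equal(const$diameter_nm, c(50, 50, 50))

  expect_error(ev_simulate_particles(
    tibble::tibble(label = "x", mean_d = 50, sd_d = -1, n = 3)), "sd_d")
})

test_that("bead panel covers the seven nominal sizes with correct labels", {
  panel <- ev_bead_panel(n_per_size = 1000)
  expect_equal(nrow(panel), 7000)
  expect_equal(length(unique(panel$label)), 7)
  expect_equal(sort(unique(panel$diameter_nm)),
               c(40, 100, 200, 450, 500, 1000, 5000))
  means <- tapply(panel$diameter_nm, panel$label, mean)
  expect_equal(as.vector(means[paste0("bead", c(40, 100, 200, 450, 500, 1000, 5000))]),
               c(40, 100, 200, 450, 500, 1000, 5000))
  # expected wells follow the trap rule applied to nominal sizes
  expect_equal(unique(panel$expected_well[panel$label == "bead1000"]), "500")
  expect_equal(unique(panel$expected_well[panel$label == "bead450"]), "200")
  expect_equal(unique(panel$expected_well[panel$label == "bead40"]), "40")
})
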