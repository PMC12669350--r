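test_that("trimming clips to the analysis window and enforces coverage", {
  sp <- gaussian_spectrum(960, 8, 100)
  tr <- trim_spectrum(sp)
  expect_gte(min(tr$wavenumber), 350)
  expect_lte(max(tr$wavenumber), 1800)
  expect_identical(trim_spectrum(tr)$wavenumber, tr$wavenumber)
  short <- raman_spectrum(seq(400, 1700), rep(1, 1301))
  expect_error(trim_spectrum(short), "coverage")
})

test_that("rubber-band correction recovers band areas over flat and linear backgrounds", {
  # Gaussian band on a constant offset
  sp <- gaussian_spectrum(960, 12, 100, offset = 40)
  rb <- rubberband_baseline(sp)
  expect_equal(min(rb$corrected$intensity), 0, tolerance = 1e-8)
  a <- integrate_band(rb$corrected, 900, 1020)
  truth <- 100 * 12 * sqrt(2 * pi) * (pnorm(60 / 12) - pnorm(-60 / 12))
  expect_lt(abs(a - truth) / truth, 0.01)
  # endpoints anchored at zero
  expect_lt(abs(rb$corrected$intensity[1]), 1e-6)
  expect_lt(abs(rev(rb$corrected$intensity)[1]), 1e-6)

  # Gaussian band on a linear background
  sp2 <- gaussian_spectrum(960, 12, 100, offset = 80, slope = -0.03)
  a2 <- integrate_band(rubberband_baseline(sp2)$corrected, 900, 1020)
  expect_lt(abs(a2 - truth) / truth, 0.02)
})

test_that("rubber-band correction is idempotent on flat input and nearly so in general", {
  zero <- raman_spectrum(seq(350, 1800), rep(0, 1451))
  rb <- rubberband_baseline(zero)
  expect_equal(rb$corrected$intensity, zero$intensity)
  expect_equal(rb$baseline, rep(0, 1451))

  sp <- gaussian_spectrum(960, 12, 100, offset = 40, slope = 0.01)
  once <- rubberband_baseline(sp)$corrected
  twice <- rubberband_baseline(once)$corrected
  expect_lt(max(abs(twice$intensity - once$intensity)), 0.02 * max(once$intensity))
})

test_that("band integration matches geometry and closed forms", {
  flat <- raman_spectrum(seq(300, 1900), rep(1, 1601))
  expect_equal(integrate_band(flat, 410, 460), 50)
  # window edges between grid points are interpolated
  expect_equal(integrate_band(flat, 410.5, 460.5), 50)
  # triangle peak of height 6 and base 40
  grid <- seq(300, 1900)
  tri <- raman_spectrum(grid, pmax(0, 6 * (1 - abs(grid - 800) / 20)))
  expect_equal(integrate_band(tri, 760, 840), 6 * 40 / 2, tolerance = 0.01)
  # partial Gaussian integral against the erf closed form
  g <- gaussian_spectrum(430, 12, 100)
  truth <- 100 * 12 * sqrt(2 * pi) * (pnorm((460 - 430) / 12) - pnorm((410 - 430) / 12))
  expect_lt(abs(integrate_band(g, 410, 460) - truth) / truth, 0.005)
  expect_error(integrate_band(g, 200, 400), "outside")
})

test_that("peak height interpolates linearly", {
  sp <- raman_spectrum(c(1650, 1659, 1661, 1670), c(1, 4, 6, 2))
  expect_equal(peak_height(sp, 1660), 5)
  sp2 <- raman_spectrum(seq(300, 1900), rep(3, 1601))
  expect_equal(peak_height(sp2, 1660), 3)
  g <- gaussian_spectrum(1660, 20, 57)
  expect_equal(peak_height(g, 1660), 57, tolerance = 1e-6)
  expect_error(peak_height(raman_spectrum(1:10, 1:10), 1660), "support")
})

test_that("band FWHM matches Gaussian and Lorentzian closed forms", {
  g <- gaussian_spectrum(960, 5, 80)
  expect_lt(abs(band_fwhm(g) - 2 * sqrt(2 * log(2)) * 5) / 11.774, 0.01)
  grid <- seq(300, 1900)
  lor <- raman_spectrum(grid, 80 * 4^2 / ((grid - 958)^2 + 4^2))
  expect_lt(abs(band_fwhm(lor) - 8) / 8, 0.02)
  ramp <- raman_spectrum(grid, grid / 100)
  expect_error(band_fwhm(ramp), "band-shape")
})

test_that("the five metrics match analytic values on synthetic spectra", {
  b <- default_bone_bands()
  # configure the v2PO4 amplitude so the analytic mineral/matrix ratio is 1.80
  t0 <- analytic_raman_params(spectrum_spec(bands = b, noise_sd = 0))
  b$amplitude[b$name == "v2PO4"] <- b$amplitude[b$name == "v2PO4"] * 1.80 / t0$mm
  spec <- spectrum_spec(bands = b, noise_sd = 0)
  truth <- analytic_raman_params(spec)
  expect_equal(truth$mm, 1.80, tolerance = 1e-9)
  got <- process_spectrum(render_spectrum(spec)$spectrum)
  expect_lt(abs(got$mm - 1.80) / 1.80, 0.02)
  for (m in c("gag", "nanoporosity", "pyd", "mmc"))
    expect_lt(abs(got[[m]] - truth[[m]]) / truth[[m]], 0.02)
})

test_that("all metrics are invariant under global intensity scaling", {
  rs <- render_spectrum(spectrum_spec(noise_sd = 0.01), seed = 51)
  doubled <- raman_spectrum(rs$spectrum$wavenumber, 2 * rs$spectrum$intensity)
  expect_equal(process_spectrum(doubled), process_spectrum(rs$spectrum),
               tolerance = 1e-9)
})

test_that("a spectrum without organic matrix content is rejected", {
  only_mineral <- gaussian_spectrum(430, 12, 100)
  trimmed <- trim_spectrum(only_mineral)
  expect_error(compute_params(trimmed), "degenerate")
})

test_that("aggregation averages per statistical unit and drops flagged ROIs", {
  d <- data.frame(
    subject = c(1, 1, 1, 1, 2),
    compartment = c("osteonal", "osteonal", "osteonal", "cancellous", "osteonal"),
    position = c("TA1", "TA1", "TA1", "TA1", "Os"),
    roi_id = 1:5,
    label_quality = c("two-labels", "two-labels", "two-labels",
                      "overlapping-label", "single-label"),
    mm = c(1, 2, 3, 9, 9))
  expect_message(out <- aggregate_statistical_units(d), "excluded")
  expect_equal(nrow(out), 1)  # flagged ROIs vanish, subject 2 has no row
  expect_equal(out$mm, 2)
})

test_that("a full ROI layout collapses to at most positions x compartments rows", {
  pos <- c("Os", "TA1", "TA2", "TA3", "In")
  d <- expand.grid(subject = 1, compartment = c("osteonal", "cancellous"),
                   position = pos, roi_id = 1:3)
  d$label_quality <- "two-labels"
  d$mm <- rnorm(nrow(d), 2)
  out <- aggregate_statistical_units(d)
  expect_equal(nrow(out), 10)
})

test_that("tissue-age gradients in the generator survive aggregation in order", {
  pos <- c("Os", "TA1", "TA2", "TA3", "In")
  mm_levels <- c(0.4, 0.9, 1.2, 1.5, 1.8)
  set.seed(52)
  d <- do.call(rbind, lapply(seq_along(pos), function(i) {
    data.frame(subject = rep(1:6, each = 3), compartment = "osteonal",
               position = pos[i], roi_id = 1:3,
               label_quality = "two-labels",
               mm = rnorm(18, mm_levels[i], 0.05))
  }))
  out <- aggregate_statistical_units(d)
  means <- tapply(out$mm, factor(out$position, levels = pos), mean)
  expect_true(all(diff(means) > 0))
})

test_that("despiking removes isolated cosmic spikes and little else", {
  set.seed(53)
  rs <- render_spectrum(spectrum_spec(noise_sd = 0.005))
  spiked <- rs$spectrum
  idx <- c(200, 700, 1200)
  spiked$intensity[idx] <- spiked$intensity[idx] + 800
  clean <- despike(spiked)
  expect_true(all(abs(clean$intensity[idx] - rs$spectrum$intensity[idx]) < 20))
  # away from the spikes the spectrum is nearly untouched; median filtering
  # may shave a few units off sharp band tops (why despiking defaults off)
  untouched <- setdiff(seq_along(clean$intensity), idx)
  changed <- which(clean$intensity[untouched] != spiked$intensity[untouched])
  expect_lt(length(changed), 10)
  expect_lt(max(abs(clean$intensity - spiked$intensity)[untouched]),
            0.04 * max(rs$spectrum$intensity))
})
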