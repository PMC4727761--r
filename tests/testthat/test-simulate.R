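test_that("band profiles have the right peak value, FWHM and additivity", {
  grid <- seq(900, 1100, by = 0.5)
  g <- band(1000, 30, 2.5)
  prof <- component_spectrum(list(g), grid)
  expect_equal(prof[grid == 1000], 2.5)
  expect_equal(prof[grid == 1015], 1.25, tolerance = 1e-12)
  expect_equal(prof[grid == 985], 1.25, tolerance = 1e-12)

  l <- band(1050, 20, 1.2, "lorentzian")
  lp <- component_spectrum(list(l), grid)
  expect_equal(lp[grid == 1050], 1.2)
  expect_equal(lp[grid == 1060], 0.6, tolerance = 1e-12)

  both <- component_spectrum(list(g, l), grid)
  expect_equal(both, prof + lp)
  expect_equal(component_spectrum(list(), grid), numeric(length(grid)))
  expect_error(band(1000, 0, 1), "fwhm")
})

test_that("spike mass converts stock volume to mg", {
  expect_equal(spike_mass(0), 0)
  expect_equal(spike_mass(100), 0.0244)
  expect_equal(spike_mass(500), 0.122)
  expect_equal(spike_mass(100, 0.5), 0.05)
  expect_error(spike_mass(-1), ">= 0")
})

test_that("simulate_mixture is linear, deterministic and validated", {
  d <- noiseless_design()
  d_nomatrix <- d
  d_nomatrix$matrix_bands <- list()

  zero <- simulate_mixture(c(daidzin = 0, genistin = 0, glycitin = 0),
                           d_nomatrix, "z", seed = 1)
  expect_equal(zero$absorbance, numeric(length(d$grid)))

  c1 <- c(daidzin = 0.02, genistin = 0.03, glycitin = 0.01)
  s1 <- simulate_mixture(c1, d, "a", seed = 1)
  s2 <- simulate_mixture(2 * c1, d, "b", seed = 1)
  pure <- simulate_mixture(c1, d_nomatrix, "c", seed = 1)
  expect_equal(s2$absorbance - s1$absorbance, pure$absorbance,
               tolerance = 1e-12)

  r1 <- simulate_mixture(c1, small_design(seed = 4), "r", seed = 77)
  r2 <- simulate_mixture(c1, small_design(seed = 4), "r", seed = 77)
  expect_identical(r1$absorbance, r2$absorbance)

  expect_error(simulate_mixture(c(daidzin = -1, genistin = 0, glycitin = 0),
                                d, "x", 1), ">= 0")
})

test_that("the spiking layout yields the documented sample count", {
  d <- small_design(seed = 1, n_base = 3, spike_volumes = c(100, 250, 400))
  expect_equal(design_sample_count(d), 3 + 3 * 3 + 3)
  dat <- generate_calibration_set(d)
  expect_equal(nrow(dat$set$matrix), 15)
  expect_equal(dat$reference$total,
               dat$reference$daidzin + dat$reference$genistin +
                 dat$reference$glycitin)

  dat2 <- generate_calibration_set(d)
  expect_identical(dat$set$matrix, dat2$set$matrix)

  d5 <- small_design(seed = 1, n_replicates = 2)
  expect_equal(design_sample_count(d5),
               2 * (3 + 3 * length(d5$spike_volumes) + 3))
})

test_that("replicates redraw distortions but share ground truth", {
  d <- small_design(seed = 8, n_replicates = 2, n_base = 1,
                    spike_volumes = c(200))
  dat <- generate_calibration_set(d)
  lay <- design_concentration_layout(d)
  r1 <- grepl("_r1$", lay$sample_id)
  r2 <- grepl("_r2$", lay$sample_id)
  expect_equal(lay[r1, -1], lay[r2, -1], ignore_attr = TRUE)
  expect_false(identical(dat$set$matrix[which(r1)[1], ],
                         dat$set$matrix[which(r2)[1], ]))
})

test_that("the default study-scale design emulates the 335-sample campaign", {
  d <- default_paper_like_design(seed = 3)
  expect_equal(design_sample_count(d), 335)
  expect_equal(d$stock_concentration, 0.244)

  # pairwise overlap of analyte band sets inside the 1500-900 cm-1 window
  bands_in_window <- lapply(d$analyte_bands, function(bl)
    Filter(function(b) b$center >= 900 && b$center <= 1500, bl))
  pairs <- combn(names(bands_in_window), 2, simplify = FALSE)
  for (pr in pairs) {
    overlap <- any(outer(
      vapply(bands_in_window[[pr[1]]], `[[`, numeric(1), "center"),
      vapply(bands_in_window[[pr[2]]], `[[`, numeric(1), "center"),
      function(c1, c2) abs(c1 - c2) < 40))
    expect_true(overlap, info = paste(pr, collapse = "/"))
  }
})

test_that("noiseless sets are exactly low-rank after centering", {
  d <- noiseless_design()
  dat <- generate_calibration_set(d)
  Xc <- scale(dat$set$matrix, scale = FALSE)
  sv <- svd(Xc)$d
  expect_lt(sv[4] / sv[1], 1e-10)   # 3 analyte directions only
  expect_gt(sv[3] / sv[1], 1e-8)
})

test_that("test sets stay inside the calibration concentration domain", {
  d <- small_design(seed = 31)
  lay <- design_concentration_layout(d)
  ts <- generate_test_set(d, 25, seed = 5)
  for (a in c("daidzin", "genistin", "glycitin")) {
    expect_true(all(ts$truth[[a]] >= min(lay[[a]]) - 1e-12))
    expect_true(all(ts$truth[[a]] <= max(lay[[a]]) + 1e-12))
  }
  ts2 <- generate_test_set(d, 25, seed = 5)
  expect_identical(ts$set$matrix, ts2$set$matrix)
  expect_false(identical(ts$set$matrix,
                         generate_test_set(d, 25, seed = 6)$set$matrix))
})

test_that("reference noise perturbs reported, not true, concentrations", {
  d <- small_design(seed = 12)
  exact <- generate_calibration_set(d)
  noisy <- generate_calibration_set(d, reference_noise_sd = 0.002)
  expect_identical(exact$truth, noisy$truth)
  expect_identical(exact$set$matrix, noisy$set$matrix)
  expect_false(identical(exact$reference$genistin, noisy$reference$genistin))
  expect_true(all(noisy$reference$genistin >= 0))
})

test_that("design YAML serialization round-trips", {
  d <- small_design(seed = 17, interferent_level = 0.02)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_design_yaml(d, f)
  d2 <- read_design_yaml(f)
  expect_equal(d2$base_levels, d$base_levels)
  expect_equal(d2$grid, d$grid)
  expect_equal(d2$seed, d$seed)
  a <- generate_calibration_set(d)
  b <- generate_calibration_set(d2)
  expect_equal(a$set$matrix, b$set$matrix, tolerance = 1e-12)
})
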