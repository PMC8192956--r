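test_that("spectrum generation is deterministic and additive in its bands", {
  s1 <- generate_spectrum(seed = 7)
  s2 <- generate_spectrum(seed = 7)
  expect_identical(s1$absorbance, s2$absorbance)
  s3 <- generate_spectrum(seed = 8)
  expect_false(identical(s1$absorbance, s3$absorbance))
  # zero noise: exact Gaussian mixture
  quiet <- noise_model(0, 0, 0)
  s0 <- generate_spectrum(noise = quiet, seed = 1)
  bt <- default_band_table()
  expected <- rowSums(vapply(seq_len(nrow(bt)), function(b) {
    gauss(s0$wavenumbers, bt$center[b], bt$sigma[b], bt$amplitude[b])
  }, numeric(length(s0$wavenumbers))))
  expect_equal(s0$absorbance, expected, tolerance = 1e-12)
})

test_that("treatment effects multiply the right bands, respecting layer restrictions", {
  quiet <- noise_model(0, 0, 0)
  eff <- default_group_effects()
  ctrl <- generate_spectrum(noise = quiet, effect = eff$control, seed = 1)
  h <- generate_spectrum(noise = quiet, effect = eff$H2O2,
                         meta = specimen_meta("v", "leaflet", "H2O2"), seed = 1)
  # at 2850 the H2O2 spectrum is ~1.5x the control
  at <- function(s, nu) s$absorbance[s$wavenumbers == nu]
  expect_equal(at(h, 2850) / at(ctrl, 2850), 1.5, tolerance = 0.01)
  expect_equal(at(h, 2500), at(ctrl, 2500), tolerance = 1e-10)
  # stored_37C only acts in the externa layer
  s_leaf <- generate_spectrum(noise = quiet, effect = eff$stored_37C,
                              meta = specimen_meta("v", "leaflet", "stored_37C"),
                              seed = 1)
  s_ext <- generate_spectrum(noise = quiet, effect = eff$stored_37C,
                             meta = specimen_meta("v", "externa", "stored_37C"),
                             seed = 1)
  expect_identical(s_leaf$absorbance, ctrl$absorbance)
  expect_equal(at(s_ext, 2850) / at(ctrl, 2850), 1.15, tolerance = 0.01)
  expect_error(group_effect("H2O2", c("2850" = -1)),
               class = "valvespectra_value_error")
  expect_error(generate_spectrum(effect = group_effect("H2O2", c("9999" = 2)),
                                 seed = 1),
               class = "valvespectra_value_error")
})

test_that("zero-noise control and freeze-dried spectra give identical band ratios", {
  quiet <- noise_model(0, 0, 0)
  eff <- default_group_effects()
  sc <- generate_spectrum(noise = quiet, effect = eff$control,
                          meta = specimen_meta("v", "leaflet", "control"), seed = 1)
  sf <- generate_spectrum(noise = quiet, effect = eff$freeze_dried,
                          meta = specimen_meta("v", "leaflet", "freeze_dried"),
                          seed = 1)
  expect_identical(quiet_ratio(ch2_ch3_ratio(sc)), quiet_ratio(ch2_ch3_ratio(sf)))
})

test_that("a lone amide-I band makes the amide area ratio degenerate", {
  quiet <- noise_model(0, 0, 0)
  s <- generate_spectrum(bands = tibble::tibble(label = "1640", center = 1640,
                                                sigma = 12, amplitude = 1,
                                                assignment = "amide I"),
                         noise = quiet, seed = 1)
  expect_error(amide_area_ratio(s), class = "valvespectra_degenerate_ratio_error")
})

test_that("generated datasets have the full design, unique IDs, and reproduce bitwise", {
  set <- generate_dataset(seed = 42)
  expect_length(set$spectra, 36)
  md <- set_metadata(set)
  expect_equal(sort(unique(md$treatment)), sort(treatment_levels()))
  expect_true(all(table(md$treatment) == 6))
  expect_false(any(duplicated(md[, c("valve_id", "treatment", "layer")])))
  set2 <- generate_dataset(seed = 42)
  for (i in seq_along(set$spectra)) {
    expect_identical(set$spectra[[i]]$absorbance, set2$spectra[[i]]$absorbance)
  }
  expect_false(identical(generate_dataset(seed = 43)$spectra[[1]]$absorbance,
                         set$spectra[[1]]$absorbance))
})

test_that("the default band table matches the qualitative shape of tissue spectra", {
  quiet <- noise_model(0, 0, 0)
  s <- generate_spectrum(noise = quiet, seed = 1)
  fp <- extract_region(s, 900, 1800)
  # amide I is the strongest feature of the fingerprint region
  expect_lte(abs(fp$wavenumbers[which.max(fp$absorbance)] - 1650), 10)
  # a distinct OD-stretch band near 2500
  at <- function(nu) s$absorbance[s$wavenumbers == nu]
  expect_gt(at(2500), at(2300))
  expect_gt(at(2500), at(2700))
  expect_gt(at(2500), 0.3)
})

test_that("injected effects are recovered by the band ratios with < 10% bias", {
  folds_ch2 <- folds_ba <- numeric(3)
  for (k in 1:3) {
    set <- generate_dataset(seed = 100 + k)
    tbl <- suppressWarnings(band_ratio_table(set))
    m <- function(f, g) mean(tbl[[f]][tbl$treatment == g])
    folds_ch2[k] <- m("ch2_ch3", "H2O2") / m("ch2_ch3", "control")
    folds_ba[k] <- m("beta_alpha", "FeCl3") / m("beta_alpha", "control")
  }
  expect_lt(abs(mean(folds_ch2) - 1.5) / 1.5, 0.10)
  true_ba <- (0.45 * 1.4 / (0.55 * 0.9)) / (0.45 / 0.55)
  expect_lt(abs(mean(folds_ba) - true_ba) / true_ba, 0.10)
})

test_that("synthetic NBT micrographs honor mask, mean and seed", {
  im <- generate_nbt_image(100, noise_sd = 0, seed = 1)
  expect_true(all(im$image[im$mask] == 100))
  expect_true(all(im$image[!im$mask] == 255))
  im2 <- generate_nbt_image(100, noise_sd = 10, seed = 2)
  expect_lt(abs(mean(im2$image[im2$mask]) - 100), 1)
  im3 <- generate_nbt_image(100, noise_sd = 10, seed = 2)
  expect_identical(im2$image, im3$image)
  expect_error(generate_nbt_image(300), class = "valvespectra_value_error")
})
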