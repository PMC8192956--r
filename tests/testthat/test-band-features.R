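test_that("equal CH2/CH3 bands give a unit intensity ratio", {
  grid <- default_grid()
  s <- band_spectrum(bands_df(c(2850, 2870), c(8, 8), c(1, 1)), grid)
  # identical bands placed symmetrically about 2860: exact symmetry
  expect_equal(quiet_ratio(ch2_ch3_ratio(s)), 1, tolerance = 1e-6)
})

test_that("CH2/CH3 ratio responds to the 2850 amplitude as the derivative oracle predicts", {
  grid <- default_grid()
  s1 <- band_spectrum(bands_df(c(2850, 2870), c(8, 8), c(1, 1)), grid)
  s2 <- band_spectrum(bands_df(c(2850, 2870), c(8, 8), c(2, 1)), grid)
  r1 <- quiet_ratio(ch2_ch3_ratio(s1))
  r2 <- quiet_ratio(ch2_ch3_ratio(s2))
  # independent local-polyfit oracle, same published definition
  o1 <- peak_ratio_oracle(s1, 2830, 2900, 2850, 2870)
  o2 <- peak_ratio_oracle(s2, 2830, 2900, 2850, 2870)
  expect_equal(r1, o1, tolerance = 1e-8)
  expect_equal(r2, o2, tolerance = 1e-8)
  # doubling one amplitude at least doubles the ratio here: the negative
  # second-derivative side lobe of the neighboring band amplifies the
  # response beyond exact proportionality (the oracle equality above is the
  # quantitative check)
  expect_gt(r2 / r1, 2)
  expect_gt(r2, r1)
})

test_that("degenerate CH spectra raise a degenerate-ratio error", {
  grid <- default_grid()
  flat <- ftir_spectrum(grid, rep(1, length(grid)))
  expect_error(suppressWarnings(ch2_ch3_ratio(flat)),
               class = "valvespectra_degenerate_ratio_error")
})

test_that("amide area ratio is exact for identical and scaled bands", {
  grid <- default_grid()
  s <- band_spectrum(bands_df(c(1640, 1560), c(12, 12), c(1, 1)), grid)
  expect_equal(amide_area_ratio(s), 1, tolerance = 0.03)
  s2 <- band_spectrum(bands_df(c(1640, 1560), c(12, 12), c(2, 1)), grid)
  expect_equal(amide_area_ratio(s2), 2, tolerance = 0.06)
  line <- ftir_spectrum(grid, 0.1 + 2e-4 * grid)
  expect_error(amide_area_ratio(line),
               class = "valvespectra_degenerate_ratio_error")
})

test_that("beta/alpha ratio is unity for equal sub-bands and monotone in the 1630 amplitude", {
  grid <- default_grid()
  s <- band_spectrum(bands_df(c(1630, 1650), c(7, 7), c(1, 1)), grid)
  expect_equal(quiet_ratio(beta_alpha_ratio(s)), 1, tolerance = 0.10)
  amps <- c(1, 1.2, 1.5, 2)
  vals <- vapply(amps, function(a) {
    sp <- band_spectrum(bands_df(c(1630, 1650), c(7, 7), c(a, 1)), grid)
    quiet_ratio(beta_alpha_ratio(sp))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[2], 1)
  # agreement with the independent derivative oracle at every amplitude
  for (a in amps) {
    sp <- band_spectrum(bands_df(c(1630, 1650), c(7, 7), c(a, 1)), grid)
    expect_equal(quiet_ratio(beta_alpha_ratio(sp)),
                 peak_ratio_oracle(sp, 1600, 1700, 1630, 1650),
                 tolerance = 1e-8)
  }
})

test_that("a single broad amide band is flagged as unresolved at the window boundaries", {
  grid <- default_grid()
  s <- band_spectrum(bands_df(1640, 30, 1), grid)
  w <- capture_warnings(r <- beta_alpha_ratio(s))
  expect_true(any(grepl("unresolved", w)))
  expect_true(attr(r, "boundary"))
})

test_that("all three ratios are invariant to global scaling; derivative ratios to affine baselines", {
  set <- generate_dataset(n_per_group = 1, treatments = c("control", "H2O2"),
                          seed = 31)
  for (s in set$spectra) {
    s_scaled <- ftir_spectrum(s$wavenumbers, 2.7 * s$absorbance, meta = s$meta)
    expect_equal(quiet_ratio(ch2_ch3_ratio(s_scaled)),
                 quiet_ratio(ch2_ch3_ratio(s)), tolerance = 1e-6)
    expect_equal(quiet_ratio(beta_alpha_ratio(s_scaled)),
                 quiet_ratio(beta_alpha_ratio(s)), tolerance = 1e-6)
    expect_equal(amide_area_ratio(s_scaled), amide_area_ratio(s),
                 tolerance = 1e-6)
    s_affine <- ftir_spectrum(s$wavenumbers,
                              s$absorbance + 0.3 - 5e-5 * s$wavenumbers,
                              meta = s$meta)
    expect_equal(quiet_ratio(ch2_ch3_ratio(s_affine)),
                 quiet_ratio(ch2_ch3_ratio(s)), tolerance = 1e-6)
    expect_equal(quiet_ratio(beta_alpha_ratio(s_affine)),
                 quiet_ratio(beta_alpha_ratio(s)), tolerance = 1e-6)
  }
})

test_that("band_ratio_table flags failures as NA with a note, never silently", {
  grid <- default_grid()
  good <- generate_dataset(n_per_group = 1, treatments = "control", seed = 5)
  flat <- ftir_spectrum(grid, rep(1, length(grid)),
                        meta = specimen_meta("V09", "leaflet", "control"))
  set <- spectrum_set(c(good$spectra, list(flat)), common_grid = grid)
  tbl <- band_ratio_table(set)
  expect_equal(nrow(tbl), 2)
  expect_false(anyNA(tbl$ch2_ch3[1]))
  expect_true(is.na(tbl$ch2_ch3[2]))
  expect_match(tbl$note[2], "ratio undefined|negligible")
})

test_that("ANOVA + Tukey separates a displaced group and letters match a studentized-range oracle", {
  set.seed(77)
  g <- rep(c("control", "freeze_dried", "H2O2"), each = 6)
  y <- c(rnorm(6, 0, 0.1), rnorm(6, 0, 0.1), rnorm(6, 10, 0.1))
  gc <- group_comparison(y, g)
  lt <- setNames(gc$table$letters, gc$table$group)
  expect_equal(lt[["control"]], lt[["freeze_dried"]])
  expect_false(lt[["H2O2"]] == lt[["control"]])
  expect_equal(lt[["H2O2"]], "a")  # letters start at the largest mean
  expect_lt(gc$anova_p, 1e-10)

  # oracle: Tukey p for a pair by direct studentized-range computation
  fit <- stats::aov(y ~ factor(g))
  mse <- sum(fit$residuals^2) / fit$df.residual
  means <- tapply(y, g, mean)
  qstat <- abs(means[["H2O2"]] - means[["control"]]) / sqrt(mse / 6)
  p_oracle <- stats::ptukey(qstat, nmeans = 3, df = fit$df.residual,
                            lower.tail = FALSE)
  p_impl <- gc$tukey["H2O2-control", "p adj"]
  expect_equal(p_impl, p_oracle, tolerance = 1e-8)
})

test_that("group comparison rejects degenerate designs", {
  expect_error(group_comparison(c(1, 2, 3), c("a", "b", "b")),
               class = "valvespectra_precondition_error")
  expect_error(group_comparison(rep(c(1, 2), each = 3),
                                rep(c("a", "b"), each = 3)),
               class = "valvespectra_degenerate_statistics_error")
})

test_that("compact letters never join groups whose Tukey p is below alpha", {
  set.seed(123)
  for (rep_i in 1:5) {
    k <- sample(3:5, 1)
    shift <- runif(k, 0, 3)
    g <- rep(letters[1:k], each = 5)
    y <- rnorm(5 * k, rep(shift, each = 5), 0.5)
    gc <- group_comparison(y, g)
    lt <- setNames(gc$table$letters, gc$table$group)
    pairs <- strsplit(rownames(gc$tukey), "-", fixed = TRUE)
    for (j in seq_along(pairs)) {
      shared <- any(strsplit(lt[[pairs[[j]][1]]], "")[[1]] %in%
                      strsplit(lt[[pairs[[j]][2]]], "")[[1]])
      if (gc$tukey[j, "p adj"] <= 0.05) expect_false(shared)
      else expect_true(shared)
    }
  }
})

test_that("H2O2-type oxidative damage raises the CH2/CH3 ratio with distinct Tukey letters", {
  set <- generate_dataset(seed = 42)
  tbl <- suppressWarnings(band_ratio_table(set))
  gc <- group_comparison(tbl$ch2_ch3, tbl$treatment)
  m <- setNames(gc$table$mean, gc$table$group)
  expect_gt(m[["H2O2"]], m[["control"]])
  lt <- setNames(gc$table$letters, gc$table$group)
  expect_false(lt[["H2O2"]] == lt[["control"]])
  smry <- summarize_band_ratios(tbl)
  expect_true(all(c("layer", "feature", "letters", "anova_p") %in% names(smry)))
  expect_equal(nrow(smry), 18)  # 1 layer x 3 features x 6 groups
})
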