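# shared fixture builders; everything is generated in code at test time

gauss <- function(nu, center, sigma, amplitude = 1) {
  amplitude * exp(-(nu - center)^2 / (2 * sigma^2))
}

# spectrum made of Gaussian bands on an optional affine baseline
band_spectrum <- function(bands, grid = default_grid(), offset = 0, slope = 0,
                          meta = NULL) {
  ab <- rep(offset, length(grid)) + slope * grid
  for (b in seq_len(nrow(bands))) {
    ab <- ab + gauss(grid, bands$center[b], bands$sigma[b], bands$amplitude[b])
  }
  ftir_spectrum(grid, ab, meta = meta)
}

bands_df <- function(center, sigma, amplitude) {
  data.frame(center = center, sigma = sigma, amplitude = amplitude)
}

# independent Savitzky-Golay oracle: local least-squares polynomial fit at
# every point (explicit lm-style normal equations), one-sided at the edges;
# no shared code with the signal-based implementation path
sg2_oracle <- function(x, y, window = 21, order = 3) {
  n <- length(x)
  h <- x[2] - x[1]
  half <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, min(i - half, n - window + 1))
    idx <- lo:(lo + window - 1)
    t <- x[idx] - x[i]
    A <- outer(t, 0:order, "^")
    cf <- qr.solve(A, y[idx])
    out[i] <- 2 * cf[3]
  }
  out
}

# oracle for the inverted-derivative peak ratio pipeline (ch2/ch3 style):
# same published definition, fully independent numerical path
peak_ratio_oracle <- function(s, lo, hi, num_center, den_center, hw = 10) {
  pad <- 20
  keep <- s$wavenumbers >= lo - pad & s$wavenumbers <= hi + pad
  x <- s$wavenumbers[keep]
  y <- s$absorbance[keep]
  d <- -sg2_oracle(x, y)
  pick <- function(center) {
    w <- x >= center - hw & x <= center + hw & x >= lo & x <= hi
    max(d[w])
  }
  pick(num_center) / pick(den_center)
}

# small 6-class synthetic design where every treatment carries its own large
# distinct band effect: all classes separable (used for structural LOOCV
# checks where perfect prediction must be attainable)
fully_separable_effects <- function(strength = 2) {
  list(
    control = group_effect("control"),
    freeze_dried = group_effect("freeze_dried", c("1240" = strength)),
    stored_4C = group_effect("stored_4C", c("1080" = strength)),
    stored_37C = group_effect("stored_37C", c("1450" = strength)),
    H2O2 = group_effect("H2O2", c("1650" = 1 / strength, "1630" = 1 / strength)),
    FeCl3 = group_effect("FeCl3", c("1630" = strength))
  )
}

quiet_ratio <- function(expr) as.numeric(suppressWarnings(expr))
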