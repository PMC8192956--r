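#' Define an absorbance band by its nominal center and search window
#'
#' Band positions in tissue spectra are approximate ("~2850 cm^-1"); peak
#' picking searches within `center +/- window_halfwidth`.
#'
#' @param label Band label, e.g. `"CH2_sym"`.
#' @param center Nominal band center (cm^-1).
#' @param window_halfwidth Half-width of the search window (cm^-1), > 0.
#' @return A `band_definition` object.
#' @export
band_definition <- function(label, center, window_halfwidth = 10) {
  if (!(window_halfwidth > 0)) {
    vs_abort("window_halfwidth must be > 0", "valvespectra_value_error")
  }
  structure(list(label = label, center = as.numeric(center),
                 window_halfwidth = as.numeric(window_halfwidth)),
            class = "band_definition")
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Local least-squares polynomial fitting (default 21-point window, cubic)
#' differentiated twice with respect to wavenumber; units are
#' absorbance * cm^2. The first and last (window-1)/2 points come from
#' one-sided polynomial fits. With `invert = TRUE` the result is multiplied
#' by -1 so that absorbance maxima appear as positive peaks (the usual
#' "inverted second derivative" convention for band picking).
#'
#' @param s An [ftir_spectrum()] on a uniform grid.
#' @param window_points Odd window length, > `poly_order`. Default 21.
#' @param poly_order Polynomial order of the local fit. Default 3.
#' @param invert Multiply the derivative by -1.
#' @return A `derivative_spectrum`: list with `wavenumbers`, `values`,
#'   `inverted`, `meta`.
#' @export
second_derivative <- function(s, window_points = 21, poly_order = 3,
                              invert = FALSE) {
  stopifnot(inherits(s, "ftir_spectrum"))
  window_points <- as.integer(window_points)
  if (window_points %% 2L == 0L || window_points <= poly_order) {
    vs_abort("window_points must be odd and greater than poly_order",
             "valvespectra_value_error")
  }
  n <- length(s$wavenumbers)
  if (n < window_points) {
    vs_abort(sprintf("spectrum has %d points, shorter than the %d-point window",
                     n, window_points), "valvespectra_size_error")
  }
  h <- diff(s$wavenumbers)
  if (max(h) - min(h) > 1e-6 * mean(h)) {
    vs_abort("second_derivative requires a uniform wavenumber grid",
             "valvespectra_grid_error")
  }
  if (poly_order < 2) {
    vs_abort("poly_order must be >= 2 for a second derivative",
             "valvespectra_value_error")
  }
  vals <- signal::sgolayfilt(s$absorbance, p = poly_order, n = window_points,
                             m = 2, ts = mean(h))
  if (invert) vals <- -vals
  structure(list(wavenumbers = s$wavenumbers, values = vals,
                 inverted = isTRUE(invert), meta = s$meta),
            class = "derivative_spectrum")
}

#' Normalize a vector of spectral intensities
#'
#' `unit_norm` (the default used throughout): divide by the Euclidean norm so
#' the region has unit length, removing pathlength/contact-pressure scaling.
#' `snv`: standard normal variate, subtract the mean and divide by the
#' standard deviation.
#'
#' @param values Numeric vector.
#' @param method `"unit_norm"` or `"snv"`.
#' @return Normalized numeric vector.
#' @export
vector_normalize <- function(values, method = c("unit_norm", "snv")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (method == "unit_norm") {
    nrm <- sqrt(sum(values^2))
    if (nrm == 0) {
      vs_abort("cannot vector-normalize an all-zero vector",
               "valvespectra_degenerate_input_error")
    }
    values / nrm
  } else {
    s <- sd(values)
    if (!is.finite(s) || s == 0) {
      vs_abort("cannot SNV-normalize a constant vector",
               "valvespectra_degenerate_input_error")
    }
    (values - mean(values)) / s
  }
}

#' Baseline-corrected band area
#'
#' Subtracts the straight line through the two window-endpoint samples and
#' integrates the residual by the trapezoidal rule over `[lo, hi]`. The
#' result is invariant under adding any affine function of the wavenumber.
#'
#' @param s An [ftir_spectrum()] covering `[lo, hi]`.
#' @param lo,hi Integration limits (cm^-1); at least 3 points must fall inside.
#' @return Area in absorbance * cm^-1.
#' @export
baseline_corrected_area <- function(s, lo, hi) {
  stopifnot(inherits(s, "ftir_spectrum"))
  if (lo < min(s$wavenumbers) || hi > max(s$wavenumbers)) {
    vs_abort("integration window outside spectrum support",
             "valvespectra_range_error")
  }
  r <- extract_region(s, lo, hi)
  n <- length(r$wavenumbers)
  if (n < 3L) {
    vs_abort("need at least 3 points in the integration window",
             "valvespectra_range_error")
  }
  x <- r$wavenumbers
  y <- r$absorbance
  slope <- (y[n] - y[1]) / (x[n] - x[1])
  baseline <- y[1] + slope * (x - x[1])
  pracma::trapz(x, y - baseline)
}

#' Pick a band maximum in an inverted second-derivative spectrum
#'
#' Returns the maximum value within `center +/- window_halfwidth` and its
#' wavenumber. If two grid points tie exactly, the lower wavenumber is
#' reported. A maximum attained at a window boundary is flagged
#' (`boundary = TRUE`, plus a warning) rather than rejected: it usually means
#' the band is unresolved in this window.
#'
#' @param d A `derivative_spectrum` from [second_derivative()], normally with
#'   `inverted = TRUE`.
#' @param band A [band_definition()].
#' @return List with `intensity`, `located_center`, `boundary`.
#' @export
peak_intensity <- function(d, band) {
  stopifnot(inherits(d, "derivative_spectrum"), inherits(band, "band_definition"))
  lo <- band$center - band$window_halfwidth
  hi <- band$center + band$window_halfwidth
  keep <- d$wavenumbers >= lo & d$wavenumbers <= hi
  if (!any(keep)) {
    vs_abort(sprintf("peak search window [%g, %g] is outside the derivative support",
                     lo, hi), "valvespectra_range_error")
  }
  w <- d$wavenumbers[keep]
  v <- d$values[keep]
  i <- which.max(v)  # first index on exact ties = lower wavenumber (ascending)
  boundary <- (i == 1L || i == length(v))
  if (boundary) {
    vs_warn(sprintf("band '%s': maximum at window boundary (%g cm^-1); band may be unresolved",
                    band$label, w[i]), "valvespectra_boundary_warning")
  }
  list(intensity = v[i], located_center = w[i], boundary = boundary)
}
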